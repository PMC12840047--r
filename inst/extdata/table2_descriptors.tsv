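descriptor	definition	reference_substance
Starchy	Aroma of bread and flour	Boiled starch:water (1:5) and cool
Grainy	A flavor reminiscent of raw grain	28 mg/kg Butyraldehyde
Floral	The smell produced by a non-specific type of flower	1600 mg/kg phenethyl alcohol
Popcorn	Aroma of popcorn	1300 mg/kg 2-Acetyl-1-pyrrolidine
Sweet	Aroma of Demerara sugar	255 mg/kg 4-Hydroxy-2,5-dimethylfuran-3-one
Grassy	A green, slightly earthy, and slightly sweet flavor	26.3 mg/kg 1-Octanol
Woody	Aroma of the dry, freshly cut wood smell	Toothpick
Oatmeal	Aroma of cooked oatmeal	Quaker Oatmeal
Dairy	Aroma of uncooked milk	High-quality 2% pasteurized milk
Corn	Aroma of canned creamed corn	Cream Style Sweet Corn
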