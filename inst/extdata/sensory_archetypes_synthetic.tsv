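# Synthetic QDA archetype profiles (0-9 scale) for the three aroma types.
# Chosen to qualitatively match the reported spider-plot narrative:
# A = sweet/popcorn-forward with grainy and grassy notes and no floral;
# B = starchy/grainy-dominant with clearly reduced sweet and popcorn;
# C = balanced-high complex profile (grainy, sweet, starchy elevated,
#     plus floral and corn notes absent from A and B, so the three types
#     span distinct directions rather than one axis -- the geometry under
#     which the reported WCSS curve drops sharply to three clusters and
#     then flattens).
# Numeric values are this package's own choice; the source figures print none.
archetype	Starchy	Grainy	Floral	Popcorn	Sweet	Grassy	Woody	Oatmeal	Dairy	Corn
A	4.5	6.0	0.5	6.5	7.0	5.5	2.0	3.0	2.5	3.0
B	7.0	7.0	1.0	3.0	3.5	3.0	4.0	5.0	3.0	3.5
C	6.0	6.0	4.0	5.0	5.5	4.0	3.5	4.5	4.0	5.5
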