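#!/usr/bin/env Rscript
# Step 1 — aroma typing from QDA sensory profiles.
# Simulates a 10-panelist QDA panel over the 11-sample / 3-archetype
# study design, averages panelist scores, and Ward-clusters the sample
# profiles; the cluster count comes from the WCSS elbow. Writes the WCSS
# curve, the cluster assignments and the per-cluster spider-plot
# profiles under results/.

suppressPackageStartupMessages(library(ricearoma))
dir.create("results", showWarnings = FALSE)

design <- study_design(seed = 42)
panel <- simulate_sensory(load_archetypes(), design,
                          n_panelists = 10, noise_sd = 0.5)
profiles <- aggregate_qda(panel)

curve <- wcss_curve(profiles, k_max = 6)
k_star <- elbow_k(curve)
cl <- ward_cluster(profiles, k = k_star)

cat("WCSS by number of clusters:\n")
print(round(curve, 2))
cat(sprintf("\nElbow at k = %d; Ward assignments at that cut:\n", k_star))
print(cl$assignments)
cat(sprintf("\nWithin-cluster SS at k=%d: %.2f\n", k_star, cl$wcss))

write.table(data.frame(k = names(curve), wcss = as.numeric(curve)),
            "results/wcss_curve.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(sample = names(cl$assignments),
                       group = attr(profiles, "groups"),
                       cluster = cl$assignments),
            "results/cluster_assignments.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
spider <- cluster_profiles(profiles, cl$assignments)
write.table(data.frame(cluster = rownames(spider), round(spider, 2),
                       check.names = FALSE),
            "results/cluster_profiles.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("\nWrote results/wcss_curve.tsv, cluster_assignments.tsv,",
    "cluster_profiles.tsv\n")
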