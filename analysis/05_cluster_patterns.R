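#!/usr/bin/env Rscript
# Hierarchical clustering (Euclidean, average linkage) of the log2
# treated/untreated expression ratios for transcripts differentially
# expressed in at least one genotype, and archetype classification of the
# resulting pattern clusters.

source("analysis/00_common.R")

sim <- simulate_nascent(genomewide_config())
de_ids <- unlist(lapply(c("WT", "AT"), function(g) {
  de <- nb_de_test(sim$counts, list(group = g, condition = "Untr"),
                   list(group = g, condition = "R0"))
  unlist(apply_preset(de, "transcript_preset")[c("up", "down")])
}))
de_ids <- sort(unique(de_ids))
message(length(de_ids), " transcripts DE in at least one genotype")

mat <- log2ratio_matrix(sim$counts, feature_ids = de_ids)
cl <- cluster_patterns(mat, k = 4)
write_table(cl$membership, "clusters.tsv")
write_table(cbind(cl$clusters, round(cl$mean_profiles, 3)),
            "cluster_archetypes.tsv")
for (i in seq_len(nrow(cl$clusters)))
  message(sprintf("cluster %d: n=%d, archetype=%s", i,
                  cl$clusters$size[i], cl$clusters$archetype[i]))
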