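#!/usr/bin/env Rscript
# Transcript-level differential expression after CPT (R0 vs Untr) in each
# genotype, threshold calls, overlap arithmetic, and the gene-length
# association of the down-regulated set.

source("analysis/00_common.R")

sim <- simulate_nascent(genomewide_config())
de_calls <- list()
for (g in c("WT", "AT")) {
  de <- nb_de_test(sim$counts, list(group = g, condition = "Untr"),
                   list(group = g, condition = "R0"))
  de_calls[[g]] <- apply_preset(de, "transcript_preset")
  write_table(de_calls[[g]]$results, paste0("de_", g, ".tsv"))
  message(sprintf("%s: %d tested, %d up, %d down (|log2FC|>=1, padj<=0.1)",
                  g, nrow(de), length(de_calls[[g]]$up),
                  length(de_calls[[g]]$down)))
}
ov <- set_overlap(c(de_calls$WT$up, de_calls$WT$down),
                  c(de_calls$AT$up, de_calls$AT$down))
message(sprintf("DE in WT %d, AT %d, common %d, in >=1 group %d",
                length(c(de_calls$WT$up, de_calls$WT$down)),
                length(c(de_calls$AT$up, de_calls$AT$down)),
                length(ov$common), ov$union_count))

la <- length_association(de_calls$WT$results, sim$annotation, "down")
write_table(data.frame(direction = "down", R = la$R, n = la$n,
                       mean_length_down = la$mean_length_down,
                       mean_length_up = la$mean_length_up,
                       location_test_p = la$location_test_p),
            "length_association.tsv")
message(sprintf(
  "length association (WT, down set): R=%.3f; mean length down %.1f kb vs up %.1f kb (p=%.2g)",
  la$R, la$mean_length_down / 1000, la$mean_length_up / 1000,
  la$location_test_p))
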