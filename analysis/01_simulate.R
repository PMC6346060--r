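#!/usr/bin/env Rscript
# Generate the two synthetic nascent-RNA experiments the analysis uses and
# export them in the standard formats (GTF + counts/metadata TSV), with the
# generative ground truth alongside.

source("analysis/00_common.R")

for (name in c("genomewide", "panel")) {
  cfg <- if (name == "genomewide") genomewide_config() else panel_config()
  sim <- simulate_nascent(cfg)
  dir <- file.path(SCRATCH, name)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gtf(sim$annotation, file.path(dir, "annotation.gtf"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"),
               file.path(dir, "meta.tsv"))
  write_truth(sim$truth, file.path(dir, "truth.tsv"))

  strata <- stratify_by_length(sim$annotation)
  sizes <- table(strata$assignment$stratum)
  message(sprintf(
    "%s: %d transcripts (%d specimens); strata short/mid/long = %d/%d/%d",
    name, nrow(sim$annotation$transcripts), ncol(sim$counts$counts),
    sizes["short"], sizes["mid"], sizes["long"]))
}
message("simulated inputs under ", SCRATCH)
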