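# Shared settings for the numbered analysis scripts.
# Each script is self-contained: datasets are regenerated from these seeded
# configurations (bit-identical every run), so scripts can be run in any
# order. Small derived tables go to results/; bulky intermediates to
# scratch/.

library(elongrec)

RESULTS <- "results/analysis"
SCRATCH <- "scratch/analysis"
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)

ANALYSIS_SEED <- 42L

# Genome-wide experiment: length spread of an annotated transcriptome,
# immediate-early genes included; used for DE, length association and
# pattern clustering.
genomewide_config <- function()
  sim_config(n_transcripts = 800, seed = ANALYSIS_SEED)

# Long-gene coverage panel: every transcript in the long stratum, used for
# profile screening, ICC recovery comparison and wavefront estimation.
panel_config <- function(...)
  sim_config_coverage_panel(n_transcripts = 300, seed = ANALYSIS_SEED, ...)

write_table <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message("wrote ", path)
  invisible(path)
}
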