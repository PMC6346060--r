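#!/usr/bin/env Rscript
# Screen the long-gene coverage panel for CPT-altered profiles: Pearson
# correlation of every treated-vs-untreated replicate pair, a transcript
# called changed when all pairs fall below 0.2, then the WT/AT overlap
# arithmetic.

source("analysis/00_common.R")

sim <- simulate_nascent(panel_config())
strata <- stratify_by_length(sim$annotation)
profiles <- coverage_groups_filter(build_profiles(sim$counts, sim$annotation),
                                   strata)
message(length(profiles), " long-stratum transcripts profiled")

calls <- rbind(detect_changed(profiles, "WT"), detect_changed(profiles, "AT"))
write_table(calls, "change_calls.tsv")

changed <- split(calls$transcript_id[calls$changed], calls$group[calls$changed])
ov <- set_overlap(changed$WT, changed$AT)
overlap_tab <- data.frame(
  set = c("WT_changed", "AT_changed", "common", "union"),
  n = c(length(changed$WT), length(changed$AT),
        length(ov$common), ov$union_count))
write_table(overlap_tab, "change_overlap.tsv")
message(sprintf(
  "changed profiles: WT %d, AT %d, common %d, union %d (of %d screened)",
  length(changed$WT), length(changed$AT), length(ov$common), ov$union_count,
  length(profiles)))
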