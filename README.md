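# elongrec

Coverage-profile analysis of RNA polymerase II elongation blocks and their
recovery, for exon-level nascent RNA-seq.

## The problem

Camptothecin (CPT) stabilizes topoisomerase-I cleavage complexes (Top1cc)
on DNA and thereby blocks transcription elongation. A polymerase must pass
every lesion between the TSS and its position, so the expected polymerase
density at position *x* decays as *a·e^(−λx)* under a lesion density λ —
long genes are repressed far more than short ones. After drug washout,
transcription re-initiates and an elongation wavefront advances at
velocity *v*; at *t* minutes the profile is fully recovered up to *v·t*
and still depleted beyond it. Whether ATM-deficient (A-T) neurons, which
accumulate Top1ccs, recover more slowly than wild-type is the comparison
this analysis chain was built for.

`elongrec` is aimed at analysts of exon-level nascent RNA-seq experiments
with a blocked/timed-recovery design (conditions `Untr`, `R0`, `R15`,
`R30` in genotype groups `WT`/`AT` with replicates). It provides:

* **Synthetic data with ground truth** — a seeded generator for the full
  design: uniform baseline, exponential lesion-survival block, a
  wavefront-limited recovery, immediate-early-gene induction, reproducible
  per-exon capture bias, negative-binomial noise (`sim_config()`,
  `simulate_nascent()`).
* **Coverage profiles** — per-exon densities (count / exon length / size
  factor), 5'→3' ordered, restricted to the long length stratum
  (> 1300 nt; strata boundaries 175/1300 nt) (`build_profiles()`,
  `stratify_by_length()`, `coverage_groups_filter()`).
* **The change screen** — a transcript is "changed" when the Pearson
  correlation between treated and untreated profiles is below 0.2 in *all*
  replicate pairs (`detect_changed()`), with overlap arithmetic between
  genotypes (`set_overlap()`).
* **Recovery comparison** — per-transcript dissimilarity
  *d = 1 − mean pair correlation* between untreated and recovery
  profiles, compared across genotypes by integrative correlation with a
  permutation null and a sign-flip verdict on the mean difference
  (`dissimilarity_records()`, `icc_compare()`), plus a changepoint
  estimator of the recovery wavefront (`estimate_wavefront()`).
* **Expression statistics** — a generic NB Wald test with BH adjustment
  and the printed threshold presets (|log2FC| ≥ 1 & padj ≤ 0.1;
  |FC| ≥ 1.5 & FDR ≤ 0.05), the gene-length association of the
  down-regulated set, and average-linkage pattern clustering with
  archetype labels (`nb_de_test()`, `apply_preset()`,
  `length_association()`, `cluster_patterns()`).
* **Orchestration** — `run_pipeline()` runs every stage from a seeded
  config into flat TSV artifacts with a hashed manifest and a plain-text
  report; the numbered scripts under `analysis/` are narrative drivers
  for each stage.

## Worked example

Simulate a long-gene panel in which the AT group recovers at half the WT
velocity, screen for CPT-altered profiles, and ask whether the genotypes
differ consistently in recovery:

```r
library(elongrec)

cfg <- sim_config_coverage_panel(n_transcripts = 150, v_AT = 750,
                                 conditions = c("Untr", "R0", "R15"),
                                 seed = 101)
sim <- simulate_nascent(cfg)

profiles <- coverage_groups_filter(
  build_profiles(sim$counts, sim$annotation),
  stratify_by_length(sim$annotation))

calls <- rbind(detect_changed(profiles, "WT"), detect_changed(profiles, "AT"))
changed <- split(calls$transcript_id[calls$changed], calls$group[calls$changed])
ov <- set_overlap(changed$WT, changed$AT)

ids <- union(changed$WT, changed$AT)
cmp <- icc_compare(
  dissimilarity_records(profiles, "WT", "R15", transcripts = ids),
  dissimilarity_records(profiles, "AT", "R15", transcripts = ids),
  n_perm = 1000, seed = 101)

wf <- sapply(c("WT", "AT"), function(g) {
  est <- sapply(profiles, function(p)
    estimate_wavefront(rowMeans(p$mat[, paste0(g, "_Untr_", 1:3)]),
                       rowMeans(p$mat[, paste0(g, "_R15_", 1:3)]),
                       p$exon_lengths))
  median(est[is.finite(est)])
})

cat(sprintf("changed: WT %d, AT %d, common %d, union %d\n",
            length(changed$WT), length(changed$AT),
            length(ov$common), ov$union_count))
cat(sprintf("icc = %.3f, mean d(WT) - d(AT) = %.3f (null %.3f..%.3f)\n",
            cmp$icc, cmp$mean_delta,
            cmp$mean_delta_band[1], cmp$mean_delta_band[2]))
cat(sprintf("consistent difference between genotypes: %s\n",
            cmp$consistent_difference))
cat(sprintf("median R15 wavefront: WT %.0f nt, AT %.0f nt\n",
            wf["WT"], wf["AT"]))
```

which prints:

```
changed: WT 39, AT 37, common 36, union 40
icc = 0.362, mean d(WT) - d(AT) = -0.048 (null -0.021..0.022)
consistent difference between genotypes: TRUE
median R15 wavefront: WT 22490 nt, AT 11196 nt
```

Reading the numbers: the screen flags ~95% of the profiled blocked
transcripts in each genotype (36 in common, union 40). The mean
dissimilarity difference is negative — AT recovery profiles are farther
from untreated than WT's — and falls outside its sign-flip null band, so
the verdict is a consistent genotype difference. The estimated wavefronts
match the generative truth: 15 min × 1500 nt/min = 22 500 nt for WT and
half that for AT. With identical velocities in both groups (the default),
the same code returns `consistent difference: FALSE` at the nominal ~5%
false-positive rate — the negative-result configuration.

The numbered scripts under `analysis/` run the full chain stage by stage
on seeded simulated experiments (`Rscript analysis/01_simulate.R`, then
`02`–`06` in any order); each writes its tables under `results/analysis/`
and narrates what it found.

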