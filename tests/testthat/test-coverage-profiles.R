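toy_counts <- function(mat, meta, transcript = "TXB") {
  counts_table(mat, data.frame(transcript_id = rep(transcript, nrow(mat)),
                               exon_index = seq_len(nrow(mat))), meta)
}

test_that("size factors: symmetry, scale equivariance, and oracle agreement", {
  meta <- one_group_meta(n_reps = 1, conditions = c("Untr", "R0"))
  m <- matrix(c(5L, 10L, 20L, 5L, 10L, 20L), ncol = 2,
              dimnames = list(NULL, meta$specimen_id))
  ct <- toy_counts(m, meta, "TXA")
  expect_equal(unname(size_factors(ct)), c(1, 1))
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf <- size_factors(toy_counts(m2, meta, "TXA"))
  expect_equal(unname(sf[2] / sf[1]), 2)
  # mixed 4-row matrix against the median-of-ratios oracle in DESeq2
  meta4 <- one_group_meta(n_reps = 2, conditions = c("Untr", "R0"))
  m4 <- matrix(c(10L, 40L, 7L, 120L,
                 20L, 35L, 9L, 300L,
                 12L, 50L, 5L, 150L,
                 18L, 60L, 11L, 200L), ncol = 4,
               dimnames = list(NULL, meta4$specimen_id))
  ours <- size_factors(toy_counts(m4, meta4, "TXA"))
  oracle <- DESeq2::estimateSizeFactorsForMatrix(m4)
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(ours), unname(oracle))
  expect_error(size_factors(matrix(0L, 2, 2)), "all-zero")
})

test_that("profiles are densities, 5'->3' ordered, with reasoned exclusions", {
  ann <- toy_annotation()
  meta <- one_group_meta(n_reps = 1, conditions = c("Untr", "R0"))
  # TXB is minus strand with exon lengths 100, 400 (genomic order)
  m <- matrix(c(10L, 40L, 10L, 40L), ncol = 2,
              dimnames = list(NULL, meta$specimen_id))
  ct <- toy_counts(m, meta, "TXB")
  prof <- build_profiles(ct, ann, min_exons = 2, min_mean_count = 0,
                         sf = stats::setNames(c(1, 1), meta$specimen_id))
  p <- prof[["TXB"]]
  # genomic densities (0.1, 0.1) -> flat; 5'->3' order reverses exon lengths
  expect_equal(unname(p$mat[, 1]), c(0.1, 0.1))
  expect_equal(p$exon_lengths, c(400, 100))
  # strand reversal: distinguishable densities flip order
  m2 <- matrix(c(10L, 80L, 10L, 80L), ncol = 2,
               dimnames = list(NULL, meta$specimen_id))
  p2 <- build_profiles(toy_counts(m2, meta, "TXB"), ann, min_exons = 2,
                       min_mean_count = 0,
                       sf = stats::setNames(c(1, 1), meta$specimen_id))[["TXB"]]
  expect_equal(unname(p2$mat[, 1]), c(0.2, 0.1))  # genomic (0.1, 0.2) reversed
  # exclusion reasons
  exc <- attr(build_profiles(ct, ann, min_exons = 4, min_mean_count = 0),
              "excluded")
  expect_true("too_few_exons" %in%
              exc$reason[exc$transcript_id == "TXB"])
  exc2 <- attr(build_profiles(ct, ann, min_exons = 2, min_mean_count = 100),
               "excluded")
  expect_true("low_expression" %in%
              exc2$reason[exc2$transcript_id == "TXB"])
  # transcript absent from annotation is a validation error
  bad <- toy_counts(m, meta, "GHOST")
  expect_error(build_profiles(bad, ann), "absent from annotation")
})

test_that("rescaling a specimen's column leaves profile shape unchanged", {
  # median-of-ratios factors are defined up to one common constant, so
  # densities after rescaling one column differ by a single global factor
  # and every profile correlation is unchanged
  sim <- simulate_nascent(sim_config(n_transcripts = 12, seed = 3,
                                     groups = "WT",
                                     conditions = c("Untr", "R0"), n_reps = 2))
  ct <- sim$counts
  p1 <- build_profiles(ct, sim$annotation, min_mean_count = 0)
  ct2 <- ct
  ct2$counts[, 1] <- ct2$counts[, 1] * 3L
  p2 <- build_profiles(ct2, sim$annotation, min_mean_count = 0)
  ratios <- unlist(lapply(names(p1), function(id) {
    r <- p2[[id]]$mat / p1[[id]]$mat
    r[is.finite(r)]
  }))
  expect_lt(diff(range(ratios)), 1e-8)
  for (id in names(p1)[1:3]) {
    m1 <- p1[[id]]$mat; m2 <- p2[[id]]$mat
    expect_equal(profile_pearson(m2[, 1], m2[, 3]),
                 profile_pearson(m1[, 1], m1[, 3]))
  }
})

test_that("noiseless baseline profiles are flat and blocked ones non-increasing", {
  cfg <- sim_config_coverage_panel(n_transcripts = 4, exon_bias_sd = 0,
                                   dispersion = 0, depth = 20000, n_reps = 1,
                                   groups = "WT", conditions = c("Untr", "R0"),
                                   seed = 21)
  sim <- simulate_nascent(cfg)
  prof <- build_profiles(sim$counts, sim$annotation)
  for (p in prof) {
    untr <- p$mat[, "WT_Untr_1"]
    expect_lt(max(untr) / min(untr), 1.05)
    r0 <- p$mat[, "WT_R0_1"]
    # monotone up to counting noise at the far (near-zero) end
    expect_true(all(diff(r0[r0 > max(r0) * 0.01]) < max(r0) * 0.05))
  }
})

test_that("coverage comparison is restricted to the long stratum", {
  lens <- data.frame(transcript_id = c("S", "M", "L"),
                     length = c(100L, 1300L, 5000L))
  strata <- stratify_by_length(lens)
  meta <- one_group_meta(n_reps = 1, conditions = c("Untr", "R0"))
  mats <- lapply(c(S = 1, M = 1, L = 1), function(i)
    matrix(1, 4, 2, dimnames = list(NULL, meta$specimen_id)))
  prof <- make_profile_set(mats, meta)
  kept <- coverage_groups_filter(prof, strata)
  expect_equal(names(kept), "L")
  # empty long stratum -> empty result, no error
  empty <- coverage_groups_filter(
    make_profile_set(mats["S"], meta),
    stratify_by_length(lens[1, , drop = FALSE]))
  expect_length(empty, 0)
  # all long -> identity
  all_long <- coverage_groups_filter(
    prof, stratify_by_length(transform(lens, length = 9999L)))
  expect_setequal(names(all_long), c("S", "M", "L"))
})
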