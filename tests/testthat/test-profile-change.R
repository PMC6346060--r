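# Independent Pearson oracle: textbook sum formula.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt(n * sum(x^2) - sum(x)^2) * sqrt(n * sum(y^2) - sum(y)^2)
  num / den
}

test_that("profile Pearson matches an independent implementation and edge cases", {
  p <- c(1, 2, 3, 4)
  expect_equal(profile_pearson(p, p), 1)
  expect_equal(profile_pearson(p, rev(p)), -1)
  expect_true(is.na(profile_pearson(rep(1, 4), p)))
  expect_error(profile_pearson(p, p[1:3]), "different exon counts")
  # flat baseline vs exponential-decay profile on a 6-exon toy
  mids <- c(100, 300, 500, 700, 900, 1100)
  q <- exp(-1e-3 * mids)
  flat_noisy <- c(1.02, 0.97, 1.01, 0.99, 1.03, 0.98)
  expect_equal(profile_pearson(flat_noisy, q), pearson_oracle(flat_noisy, q))
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    expect_equal(profile_pearson(x, y), pearson_oracle(x, y))
  }
})

test_that("the changed call is an all-replicate-pairs conjunction", {
  meta <- one_group_meta(n_reps = 2, conditions = c("Untr", "R0"))
  up <- c(1, 2, 3, 4, 5)
  down <- rev(up)
  # both R0 replicates anti-correlated with both Untr replicates -> changed
  m_changed <- cbind(up, up + c(0.1, 0, 0.2, 0, 0.1), down, down + 0.1)
  colnames(m_changed) <- meta$specimen_id[c(1, 2, 3, 4)]
  # one concordant pair keeps the transcript unchanged
  m_mixed <- m_changed
  m_mixed[, "WT_R0_2"] <- up
  prof <- make_profile_set(list(TC = m_changed, TM = m_mixed), meta)
  calls <- detect_changed(prof, "WT")
  expect_true(calls$changed[calls$transcript_id == "TC"])
  expect_false(calls$changed[calls$transcript_id == "TM"])
  expect_equal(calls$n_pairs, c(4L, 4L))
  # treated == untreated: diagonal pairs r = 1, never changed
  self <- detect_changed(prof, "WT", treated = "Untr", untreated = "Untr")
  expect_false(any(self$changed))
  expect_equal(self$max_r, c(1, 1))
  # zero-variance profile vetoes the call
  m_flat <- m_changed
  m_flat[, "WT_R0_1"] <- 1
  flat_calls <- detect_changed(make_profile_set(list(TF = m_flat), meta), "WT")
  expect_false(flat_calls$changed)
  expect_equal(flat_calls$n_undefined, 2L)
  expect_error(detect_changed(prof, "WT", treated = "R30"), "absent")
})

test_that("the changed set is monotone in the threshold", {
  sim <- simulate_nascent(sim_config_coverage_panel(
    n_transcripts = 30, conditions = c("Untr", "R0"), groups = "WT", seed = 8))
  prof <- coverage_groups_filter(build_profiles(sim$counts, sim$annotation),
                                 stratify_by_length(sim$annotation))
  strict <- detect_changed(prof, "WT", threshold = 0.1)
  loose <- detect_changed(prof, "WT", threshold = 0.2)
  expect_true(all(strict$transcript_id[strict$changed] %in%
                  loose$transcript_id[loose$changed]))
})

test_that("dissimilarity records average over pairs and stay in [0, 2]", {
  meta <- one_group_meta(n_reps = 2, conditions = c("Untr", "R15"))
  up <- c(1, 2, 3, 4)
  m <- cbind(up, up, rev(up), up)
  colnames(m) <- meta$specimen_id
  d <- dissimilarity_records(make_profile_set(list(TX = m), meta), "WT", "R15")
  # pair correlations: (-1, 1, -1, 1) -> mean 0 -> d = 1
  expect_equal(d$d, 1)
  expect_equal(d$condition_pair, "Untr-R15")
})

test_that("icc_compare: identity, independence, and a detectable shift", {
  set.seed(2)
  d <- runif(50, 0.2, 1.2)
  rec <- function(x, g) data.frame(transcript_id = sprintf("T%02d", seq_along(x)),
                                   group = g, condition_pair = "Untr-R15", d = x)
  same <- icc_compare(rec(d, "WT"), rec(d, "AT"), n_perm = 200, seed = 1)
  expect_equal(same$icc, 1)
  expect_true(all(same$per_transcript_delta == 0))
  expect_false(same$consistent_difference)
  # independent vectors: |icc| small in nearly all seeded runs
  hits <- 0
  for (s in 1:20) {
    set.seed(100 + s)
    a <- runif(200); b <- runif(200)
    if (abs(icc_compare(rec(a, "WT"), rec(b, "AT"),
                        n_perm = 50, seed = s)$icc) < 0.2) hits <- hits + 1
  }
  expect_gte(hits, 19)
  # constant shift of 0.4 on 50 transcripts is a consistent difference
  shifted <- icc_compare(rec(d + 0.4, "WT"), rec(d, "AT"),
                         n_perm = 1000, seed = 3)
  expect_true(shifted$consistent_difference)
  expect_equal(shifted$mean_delta, 0.4)
  expect_error(icc_compare(rec(d[1:2], "WT"), rec(d[1:2], "AT")),
               "at least 3")
})

test_that("icc_compare is symmetric up to the sign of the deltas", {
  set.seed(4)
  a <- runif(30); b <- runif(30)
  rec <- function(x, g) data.frame(transcript_id = sprintf("T%02d", seq_along(x)),
                                   group = g, condition_pair = "Untr-R15", d = x)
  ab <- icc_compare(rec(a, "WT"), rec(b, "AT"), n_perm = 100, seed = 9)
  ba <- icc_compare(rec(b, "AT"), rec(a, "WT"), n_perm = 100, seed = 9)
  expect_equal(ab$icc, ba$icc)
  expect_equal(ab$per_transcript_delta, -ba$per_transcript_delta)
})

test_that("wavefront changepoint search matches a brute-force scan", {
  # 8-exon toy with a clear step after exon 3
  exlen <- rep(100, 8)
  untr <- rep(2, 8)
  rec <- c(2.1, 1.9, 2.0, 0.3, 0.2, 0.25, 0.15, 0.2)
  scan_oracle <- function(z, mid) {
    best <- NULL; best_sse <- Inf
    for (k in 1:(length(z) - 1)) {
      hi <- mean(z[1:k]); lo <- mean(z[-(1:k)])
      sse <- sum((z[1:k] - hi)^2) + sum((z[-(1:k)] - lo)^2)
      if (sse < best_sse) { best_sse <- sse; best <- (mid[k] + mid[k + 1]) / 2 }
    }
    best
  }
  mid <- cumsum(exlen) - exlen / 2
  expect_equal(estimate_wavefront(untr, rec, exlen),
               scan_oracle(rec / untr, mid))
  expect_equal(estimate_wavefront(untr, rec, exlen), 300)
  # fully recovered profile -> beyond transcript end
  expect_equal(estimate_wavefront(untr, untr * 1.01, exlen), Inf)
  # unstable ratio
  expect_error(estimate_wavefront(c(0, 0, 0, 0, 0, 1, 1, 1), rec, exlen),
               "ratio unstable")
  set.seed(5)
  for (i in 1:15) {
    z <- abs(rnorm(8, c(2, 2, 2, 2, .3, .3, .3, .3), 0.3)) + 0.01
    expect_equal(estimate_wavefront(rep(1, 8), z, exlen),
                 scan_oracle(z, mid))
  }
})
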