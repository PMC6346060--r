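#' Pearson correlation between two coverage profiles
#'
#' @param p,q Numeric density vectors over the same exons of the same
#'   transcript (length >= 2), 5'->3' ordered.
#' @return The Pearson correlation in `[-1, 1]`, or `NA` if either vector
#'   has zero variance (the correlation is undefined).
#' @export
profile_pearson <- function(p, q) {
  if (length(p) != length(q))
    stop("profiles have different exon counts")
  if (length(p) < 2) stop("need at least 2 exons")
  if (stats::sd(p) == 0 || stats::sd(q) == 0) return(NA_real_)
  stats::cor(p, q)
}

#' Screen for CPT-altered coverage profiles
#'
#' For each transcript, the Pearson correlation between every
#' (treated replicate, untreated replicate) profile pair within one genotype
#' group is computed. A transcript is called `changed` when every defined
#' pair correlation is strictly below `threshold` and no pair is undefined
#' (a zero-variance profile vetoes the call). The all-pairs conjunction is
#' the pairing-free reading of requiring the change "in all replicates".
#'
#' @param profiles A `coverage_profile_set`.
#' @param group `"WT"` or `"AT"`.
#' @param threshold Correlation threshold (default 0.2, strict `<`).
#' @param treated,untreated Condition labels to compare (defaults `"R0"` vs
#'   `"Untr"`).
#' @return data.frame with one row per transcript: `transcript_id`, `group`,
#'   `min_r`, `max_r`, `n_pairs`, `n_undefined`, `changed`.
#' @export
detect_changed <- function(profiles, group, threshold = 0.2,
                           treated = "R0", untreated = "Untr") {
  stopifnot(inherits(profiles, "coverage_profile_set"))
  meta <- attr(profiles, "meta")
  t_ids <- meta$specimen_id[meta$group == group & meta$condition == treated]
  u_ids <- meta$specimen_id[meta$group == group & meta$condition == untreated]
  if (length(t_ids) == 0 || length(u_ids) == 0)
    stop("condition ", if (length(t_ids) == 0) treated else untreated,
         " absent in group ", group)
  res <- lapply(profiles, function(p) {
    r <- as.vector(outer(t_ids, u_ids, Vectorize(function(ti, ui)
      profile_pearson(p$mat[, ti], p$mat[, ui]))))
    n_undef <- sum(is.na(r))
    defined <- r[!is.na(r)]
    data.frame(
      transcript_id = p$transcript_id,
      group = group,
      min_r = if (length(defined)) min(defined) else NA_real_,
      max_r = if (length(defined)) max(defined) else NA_real_,
      n_pairs = length(r),
      n_undefined = n_undef,
      changed = n_undef == 0 && all(defined < threshold),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-transcript recovery dissimilarity
#'
#' Dissimilarity between untreated and recovery coverage, defined as
#' `1 - mean` over all (untreated replicate, recovery replicate) pairs of
#' the Pearson correlation of their profiles; values lie in `[0, 2]`.
#' Undefined pair correlations (zero-variance profiles) are dropped from the
#' mean; a transcript with no defined pair gets `NA`.
#'
#' @param profiles A `coverage_profile_set`.
#' @param group `"WT"` or `"AT"`.
#' @param recovery Recovery condition (`"R15"` or `"R30"`).
#' @param untreated Baseline condition (default `"Untr"`).
#' @param transcripts Optional transcript_id subset.
#' @return data.frame `transcript_id`, `group`, `condition_pair`, `d`.
#' @export
dissimilarity_records <- function(profiles, group, recovery,
                                  untreated = "Untr", transcripts = NULL) {
  stopifnot(inherits(profiles, "coverage_profile_set"))
  meta <- attr(profiles, "meta")
  u_ids <- meta$specimen_id[meta$group == group & meta$condition == untreated]
  r_ids <- meta$specimen_id[meta$group == group & meta$condition == recovery]
  if (length(u_ids) == 0 || length(r_ids) == 0)
    stop("condition ", if (length(u_ids) == 0) untreated else recovery,
         " absent in group ", group)
  use <- if (is.null(transcripts)) names(profiles)
         else intersect(transcripts, names(profiles))
  d <- vapply(use, function(id) {
    p <- profiles[[id]]
    r <- as.vector(outer(u_ids, r_ids, Vectorize(function(ui, ri)
      profile_pearson(p$mat[, ui], p$mat[, ri]))))
    if (all(is.na(r))) NA_real_ else 1 - mean(r, na.rm = TRUE)
  }, numeric(1))
  data.frame(transcript_id = use, group = group,
             condition_pair = paste(untreated, recovery, sep = "-"),
             d = unname(d), stringsAsFactors = FALSE)
}

#' Integrative-correlation comparison of recovery dissimilarity
#'
#' Asks whether two genotype groups agree in their per-transcript recovery
#' dissimilarities and whether one group is consistently more dissimilar.
#' `icc` is the Pearson correlation, across the shared transcripts, between
#' the two groups' dissimilarity vectors (the integrative-correlation
#' construct). Its `null_band` is the central 95% interval of the same
#' statistic under `n_perm` random permutations of group B's transcript
#' labels. The `consistent_difference` verdict comes from a paired
#' permutation (random sign-flip) test on the per-transcript deltas
#' `d_A - d_B`: group labels are exchangeable within a transcript under the
#' null, and the verdict is true when the observed mean delta falls outside
#' the central 95% interval of the sign-flip null.
#'
#' @param d_a,d_b data.frames from [dissimilarity_records()] for groups A
#'   and B, covering the same transcripts (rows with `NA` dissimilarity in
#'   either group are dropped).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @return List with `icc`, `null_band` (length-2), `per_transcript_delta`
#'   (named vector, A - B), `mean_delta`, `mean_delta_band` (sign-flip null
#'   central 95%), `consistent_difference`, `n`.
#' @export
icc_compare <- function(d_a, d_b, n_perm = 1000, seed = 1L) {
  shared <- intersect(d_a$transcript_id, d_b$transcript_id)
  va <- d_a$d[match(shared, d_a$transcript_id)]
  vb <- d_b$d[match(shared, d_b$transcript_id)]
  ok <- !is.na(va) & !is.na(vb)
  va <- va[ok]; vb <- vb[ok]; shared <- shared[ok]
  n <- length(shared)
  if (n < 3) stop("icc_compare needs at least 3 shared transcripts")
  icc <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_
         else stats::cor(va, vb)
  delta <- stats::setNames(va - vb, shared)
  set.seed(seed)
  perm_icc <- replicate(n_perm, {
    pb <- vb[sample.int(n)]
    if (stats::sd(pb) == 0) NA_real_ else stats::cor(va, pb)
  })
  null_band <- stats::quantile(perm_icc, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), nrow = n_perm)
  null_means <- as.vector(flips %*% delta) / n
  mean_delta_band <- stats::quantile(null_means, c(0.025, 0.975), names = FALSE)
  mean_delta <- mean(delta)
  list(icc = icc,
       null_band = null_band,
       per_transcript_delta = delta,
       mean_delta = mean_delta,
       mean_delta_band = mean_delta_band,
       consistent_difference = mean_delta < mean_delta_band[1] ||
                               mean_delta > mean_delta_band[2],
       n = n)
}

#' Estimate the recovery wavefront position
#'
#' Fits a one-changepoint step function (high plateau then low plateau) to
#' the per-exon ratio of recovery to untreated density, over exon midpoint
#' positions, by exhaustive changepoint search minimizing squared error.
#' Returns the position (nt from the TSS) interpolated midway between the
#' last high-plateau exon midpoint and the first low-plateau one. If no
#' exon ratio falls below half the fitted high plateau the transcript is
#' considered fully recovered and `Inf` ("beyond transcript end") is
#' returned.
#'
#' @param untr,rec Density vectors (5'->3') for the untreated and recovery
#'   profiles of one transcript, >= 4 exons.
#' @param exon_lengths Exon lengths (nt) matching the vectors.
#' @return Wavefront position in nt, or `Inf` if beyond the transcript end.
#' @export
estimate_wavefront <- function(untr, rec, exon_lengths) {
  m <- length(untr)
  stopifnot(length(rec) == m, length(exon_lengths) == m)
  if (m < 4) stop("need at least 4 exons")
  if (sum(untr == 0) > m / 2)
    stop("untreated density is zero on more than half of the exons; ratio unstable")
  ratio <- rec / ifelse(untr == 0, NA, untr)
  mid <- cumsum(exon_lengths) - exon_lengths / 2
  ok <- !is.na(ratio)
  z <- ratio[ok]; pos <- mid[ok]
  k_best <- NULL; sse_best <- Inf; hi_best <- NA
  for (k in seq_len(length(z) - 1)) {
    hi <- mean(z[1:k]); lo <- mean(z[(k + 1):length(z)])
    sse <- sum((z[1:k] - hi)^2) + sum((z[(k + 1):length(z)] - lo)^2)
    if (sse < sse_best - 1e-12) {
      sse_best <- sse; k_best <- k; hi_best <- hi
    }
  }
  if (!any(z < hi_best / 2)) return(Inf)
  (pos[k_best] + pos[k_best + 1]) / 2
}
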