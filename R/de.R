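#' Negative-binomial Wald test for differential expression
#'
#' A generic two-group NB test over size-factor-normalized counts.
#' Per feature (transcript by default: exon counts are summed), the
#' normalized group means are compared on the log2 scale with a pseudocount
#' of 0.5; the NB dispersion is estimated per feature by method of moments
#' from the pooled within-group variance and shrunk 50% toward the global
#' mean dispersion; the Wald statistic `log2FC / SE(log2FC)` is referred to
#' the standard normal (the shrunken dispersion pools information across
#' features, so the SE is not a per-feature small-sample variance estimate)
#' and p-values are Benjamini-Hochberg adjusted over the tested features.
#' Features whose mean normalized count across the selected specimens is
#' below `min_mean` are excluded before testing (an independent filter).
#'
#' @param ct A [counts_table()].
#' @param side_a,side_b Specimen selectors: either character vectors of
#'   specimen_ids or lists with `group` and/or `condition` elements. Each
#'   side needs >= 2 replicates.
#' @param features `"transcript"` (sum exon counts per transcript) or
#'   `"exon"`.
#' @param min_mean Independent mean-count filter (default 5).
#' @param pseudocount Added to normalized means before log2 (default 0.5).
#' @return data.frame with `feature_id`, `mean_a`, `mean_b`, `log2fc`,
#'   `stat`, `p`, `padj`, ordered as the input features.
#' @export
nb_de_test <- function(ct, side_a, side_b, features = c("transcript", "exon"),
                       min_mean = 5, pseudocount = 0.5) {
  features <- match.arg(features)
  resolve <- function(sel) {
    if (is.character(sel)) return(sel)
    specimens(ct, group = sel$group, condition = sel$condition)
  }
  a_ids <- resolve(side_a)
  b_ids <- resolve(side_b)
  if (length(a_ids) < 2 || length(b_ids) < 2)
    stop("each side needs at least 2 replicates")
  if (length(intersect(a_ids, b_ids)))
    stop("sides overlap: ", paste(intersect(a_ids, b_ids), collapse = ", "))
  m <- ct$counts[, c(a_ids, b_ids), drop = FALSE]
  if (features == "transcript")
    m <- rowsum(m, ct$row_info$transcript_id)
  sf <- size_factors(m)
  y <- sweep(m, 2, sf, "/")
  keep <- rowMeans(y) >= min_mean
  y <- y[keep, , drop = FALSE]
  if (nrow(y) == 0) stop("no feature passes the mean-count filter")
  ya <- y[, a_ids, drop = FALSE]
  yb <- y[, b_ids, drop = FALSE]
  na <- length(a_ids); nb <- length(b_ids)
  ma <- rowMeans(ya); mb <- rowMeans(yb)
  mu <- (na * ma + nb * mb) / (na + nb)
  s2 <- (rowSums((ya - ma)^2) + rowSums((yb - mb)^2)) / (na + nb - 2)
  inv_s <- mean(1 / sf)
  phi <- pmax(0, (s2 - mu * inv_s) / mu^2)
  phi <- 0.5 * phi + 0.5 * mean(phi)
  log2fc <- log2((mb + pseudocount) / (ma + pseudocount))
  var_a <- (ma + pseudocount) * sum(1 / sf[a_ids]) / na^2 +
           phi * (ma + pseudocount)^2 / na
  var_b <- (mb + pseudocount) * sum(1 / sf[b_ids]) / nb^2 +
           phi * (mb + pseudocount)^2 / nb
  se <- sqrt(var_a / (ma + pseudocount)^2 + var_b / (mb + pseudocount)^2) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  data.frame(feature_id = rownames(y),
             mean_a = unname(ma), mean_b = unname(mb),
             log2fc = unname(log2fc), stat = unname(stat),
             p = unname(p),
             padj = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Differential-expression threshold presets
#'
#' Two printed call rules: `transcript_preset` calls features with
#' `|log2FC| >= 1` and adjusted p `<= 0.1`; `kcl_preset` calls features with
#' linear fold change `|FC| >= 1.5` (i.e. `2^|log2FC| >= 1.5`) and FDR
#' `<= 0.05`. All comparisons are inclusive.
#'
#' @param name `"transcript_preset"` or `"kcl_preset"`.
#' @return A list of class `threshold_preset`.
#' @export
threshold_preset <- function(name) {
  preset <- switch(name,
    transcript_preset = list(name = name, min_abs_log2fc = 1, max_padj = 0.1),
    kcl_preset = list(name = name, min_abs_fc = 1.5, max_padj = 0.05),
    stop("unknown preset: ", name))
  class(preset) <- "threshold_preset"
  preset
}

#' Apply a threshold preset to DE results
#'
#' @param results data.frame from [nb_de_test()].
#' @param preset A [threshold_preset()] or its name.
#' @return List with `up` and `down` (character vectors of feature_ids) and
#'   `results` with added `called` and `direction` columns.
#' @export
apply_preset <- function(results, preset) {
  if (is.character(preset)) preset <- threshold_preset(preset)
  stopifnot(inherits(preset, "threshold_preset"))
  effect_ok <- if (!is.null(preset$min_abs_log2fc))
    abs(results$log2fc) >= preset$min_abs_log2fc
  else
    2^abs(results$log2fc) >= preset$min_abs_fc
  called <- effect_ok & results$padj <= preset$max_padj
  direction <- ifelse(!called, "none", ifelse(results$log2fc > 0, "up", "down"))
  results$called <- called
  results$direction <- direction
  list(up = results$feature_id[direction == "up"],
       down = results$feature_id[direction == "down"],
       results = results)
}

#' Gene-length association of differential expression
#'
#' Within the called features of one direction, the Pearson correlation `R`
#' between log10 transcript length and the test statistic quantifies
#' length-dependent repression; the mean lengths of the up- and down-called
#' sets and a two-sided rank-sum test on their log10 lengths are reported
#' alongside.
#'
#' @param results Called results (the `results` element of
#'   [apply_preset()]'s value).
#' @param ann A [transcript_annotation()] (or data.frame with
#'   `transcript_id`, `length`).
#' @param direction `"up"` or `"down"`: the set within which `R` is
#'   computed.
#' @return List with `R`, `n`, `mean_length_up`, `mean_length_down`,
#'   `location_test_p`.
#' @export
length_association <- function(results, ann, direction = c("down", "up")) {
  direction <- match.arg(direction)
  stopifnot(all(c("called", "direction") %in% names(results)))
  tx <- if (inherits(ann, "transcript_annotation")) ann$transcripts else ann
  len <- tx$length[match(results$feature_id, tx$transcript_id)]
  if (anyNA(len)) stop("called feature missing from annotation")
  in_dir <- results$direction == direction
  if (sum(in_dir) < 3)
    stop("fewer than 3 called features in direction ", direction)
  up_len <- len[results$direction == "up"]
  down_len <- len[results$direction == "down"]
  loc_p <- if (length(up_len) && length(down_len))
    stats::wilcox.test(log10(down_len), log10(up_len))$p.value
  else NA_real_
  list(R = stats::cor(log10(len[in_dir]), results$stat[in_dir]),
       n = sum(in_dir),
       mean_length_up = if (length(up_len)) mean(up_len) else NA_real_,
       mean_length_down = if (length(down_len)) mean(down_len) else NA_real_,
       location_test_p = loc_p)
}
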