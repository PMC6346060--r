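#' Log2 treated/untreated ratio matrix per group
#'
#' Builds the features x conditions matrix consumed by
#' [cluster_patterns()]: for each group and each treated condition, the log2
#' ratio of the mean normalized feature count to the group's untreated mean
#' (pseudocount 0.5 on both).
#'
#' @param ct A [counts_table()] containing both groups and all conditions.
#' @param features `"transcript"` or `"exon"`.
#' @param feature_ids Optional subset of features (e.g. the union of DE
#'   calls) to keep as rows.
#' @param groups,treated Conditions/groups to include as columns (named
#'   `<group>_<condition>`).
#' @param pseudocount Added to normalized means before log2.
#' @return Numeric matrix, rows = features, columns = group x treated
#'   condition.
#' @export
log2ratio_matrix <- function(ct, features = c("transcript", "exon"),
                             feature_ids = NULL,
                             groups = c("WT", "AT"),
                             treated = c("R0", "R15", "R30"),
                             pseudocount = 0.5) {
  features <- match.arg(features)
  m <- ct$counts
  if (features == "transcript") m <- rowsum(m, ct$row_info$transcript_id)
  sf <- size_factors(m)
  y <- sweep(m, 2, sf, "/")
  cols <- list()
  for (g in groups) {
    u_ids <- specimens(ct, group = g, condition = "Untr")
    if (length(u_ids) == 0) stop("no untreated specimens in group ", g)
    base <- rowMeans(y[, u_ids, drop = FALSE]) + pseudocount
    for (cond in treated) {
      t_ids <- specimens(ct, group = g, condition = cond)
      if (length(t_ids) == 0) stop("no ", cond, " specimens in group ", g)
      cols[[paste(g, cond, sep = "_")]] <-
        log2((rowMeans(y[, t_ids, drop = FALSE]) + pseudocount) / base)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(y)
  if (!is.null(feature_ids)) {
    missing <- setdiff(feature_ids, rownames(out))
    if (length(missing)) stop("features absent from counts: ",
                              paste(utils::head(missing, 5), collapse = ", "))
    out <- out[feature_ids, , drop = FALSE]
  }
  out
}

#' Cluster expression patterns and assign archetypes
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of a features x conditions log2-ratio matrix, cut into `k`
#' clusters. Each cluster's mean profile is classified into an expression
#' archetype by comparing, per treated condition, the mean AT and WT log2
#' ratios against a margin `delta`:
#' `similar_both` (AT-WT within `delta` everywhere), `up_in_AT` (AT above
#' WT by more than `delta` in every condition), `up_in_AT_after_washout`
#' (above only in the washout columns R15/R30), `down_in_AT` (below in
#' every condition), else `other`.
#'
#' @param mat Numeric matrix, rows = features, columns named
#'   `<group>_<condition>` as from [log2ratio_matrix()]; all entries finite.
#' @param k Number of clusters (default 4).
#' @param delta Archetype margin in log2 units (default 0.5).
#' @return List with `membership` (data.frame feature_id, cluster_id,
#'   archetype), `clusters` (data.frame cluster_id, size, archetype),
#'   `mean_profiles` (clusters x conditions matrix) and `tree` (the hclust
#'   object).
#' @export
cluster_patterns <- function(mat, k = 4, delta = 0.5) {
  if (!all(is.finite(mat))) stop("non-finite entries in the log2-ratio matrix")
  if (nrow(mat) < k) stop("fewer features than clusters")
  tree <- stats::hclust(stats::dist(mat, method = "euclidean"),
                        method = "average")
  cl <- stats::cutree(tree, k = k)
  mean_profiles <- do.call(rbind, lapply(seq_len(k), function(i)
    colMeans(mat[cl == i, , drop = FALSE])))
  rownames(mean_profiles) <- seq_len(k)
  archetypes <- vapply(seq_len(k), function(i)
    classify_archetype(mean_profiles[i, ], delta), character(1))
  list(
    membership = data.frame(feature_id = rownames(mat),
                            cluster_id = unname(cl),
                            archetype = archetypes[cl],
                            stringsAsFactors = FALSE),
    clusters = data.frame(cluster_id = seq_len(k),
                          size = as.vector(table(factor(cl, levels = seq_len(k)))),
                          archetype = archetypes,
                          stringsAsFactors = FALSE),
    mean_profiles = mean_profiles,
    tree = tree)
}

classify_archetype <- function(profile, delta) {
  nm <- names(profile)
  conds <- unique(sub("^(WT|AT)_", "", nm))
  diffs <- vapply(conds, function(cond) {
    at <- profile[paste0("AT_", cond)]
    wt <- profile[paste0("WT_", cond)]
    if (anyNA(c(at, wt))) stop("matrix must carry WT_ and AT_ columns per condition")
    unname(at - wt)
  }, numeric(1))
  washout <- intersect(conds, c("R15", "R30"))
  if (all(abs(diffs) < delta)) "similar_both"
  else if (all(diffs > delta)) "up_in_AT"
  else if (length(washout) && all(diffs[washout] > delta) &&
           !any(diffs[setdiff(conds, washout)] > delta)) "up_in_AT_after_washout"
  else if (all(diffs < -delta)) "down_in_AT"
  else "other"
}
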