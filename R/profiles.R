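#' Median-of-ratios size factors
#'
#' Per-specimen scale factors computed as the median across exon rows of the
#' ratio to the row geometric mean, using only rows with all-positive
#' counts, then rescaled to geometric mean 1. Multiplying one specimen's
#' counts by k multiplies its factor by k.
#'
#' @param ct A [counts_table()] or a count matrix.
#' @return Named numeric vector of positive factors, one per specimen.
#' @export
size_factors <- function(ct) {
  m <- if (inherits(ct, "counts_table")) ct$counts else as.matrix(ct)
  if (all(m == 0)) stop("all-zero count table: size factors undefined")
  log_m <- log(m)
  geo <- rowMeans(log_m)                     # -Inf where any zero
  use <- is.finite(geo)
  if (!any(use))
    stop("no exon row with nonzero counts in every specimen")
  sf <- apply(log_m[use, , drop = FALSE], 2, function(col)
    exp(stats::median(col - geo[use])))
  sf / exp(mean(log(sf)))
}

#' Build ordered, normalized coverage profiles
#'
#' Converts exon counts to per-exon densities
#' `count / (exon length x size factor)` and orders them 5' to 3' (reversing
#' the genomic exon order on the minus strand). Transcripts with fewer than
#' `min_exons` exons, or a mean raw count across all specimens below
#' `min_mean_count`, are excluded and reported with a reason: a Pearson
#' screen over a handful of exons is unstable, and near-zero transcripts
#' give noise-only profiles.
#'
#' @param ct A [counts_table()].
#' @param ann A [transcript_annotation()] covering every transcript in `ct`.
#' @param min_exons Minimum number of exons (default 4).
#' @param min_mean_count Minimum mean raw exon count across specimens
#'   (default 5).
#' @param sf Optional precomputed size factors; default [size_factors()].
#' @return An object of class `coverage_profile_set`: a named list (by
#'   transcript_id) of lists with `mat` (exons x specimens density matrix in
#'   5'->3' order), `exon_lengths`, `transcript_id`; attributes `meta`
#'   (specimen metadata), `excluded` (data.frame transcript_id, reason) and
#'   `size_factors`.
#' @export
build_profiles <- function(ct, ann, min_exons = 4, min_mean_count = 5,
                           sf = NULL) {
  stopifnot(inherits(ct, "counts_table"), inherits(ann, "transcript_annotation"))
  unknown <- setdiff(unique(ct$row_info$transcript_id),
                     ann$transcripts$transcript_id)
  if (length(unknown))
    stop("transcripts in counts but absent from annotation: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  if (is.null(sf)) sf <- size_factors(ct)
  tx <- ann$transcripts
  ex <- ann$exons
  exon_len <- ex$end - ex$start
  names(exon_len) <- paste0(ex$transcript_id, ":", ex$exon_index)

  by_tx <- split(seq_len(nrow(ct$counts)), ct$row_info$transcript_id)
  profiles <- list()
  excluded <- list()
  for (id in names(by_tx)) {
    rows <- by_tx[[id]]
    rows <- rows[order(ct$row_info$exon_index[rows])]
    if (length(rows) < min_exons) {
      excluded[[id]] <- "too_few_exons"
      next
    }
    sub <- ct$counts[rows, , drop = FALSE]
    if (mean(sub) < min_mean_count) {
      excluded[[id]] <- "low_expression"
      next
    }
    el <- exon_len[rownames(sub)]
    if (anyNA(el)) stop("exon of transcript ", id, " missing from annotation")
    dens <- sweep(sub / el, 2, sf, "/")
    strand <- tx$strand[match(id, tx$transcript_id)]
    if (strand == "-") {
      dens <- dens[rev(seq_len(nrow(dens))), , drop = FALSE]
      el <- rev(el)
    }
    profiles[[id]] <- list(transcript_id = id, mat = dens,
                           exon_lengths = unname(el))
  }
  excluded_df <- data.frame(
    transcript_id = names(excluded),
    reason = unlist(excluded, use.names = FALSE),
    stringsAsFactors = FALSE)
  if (nrow(excluded_df) == 0)
    excluded_df <- data.frame(transcript_id = character(), reason = character())
  structure(profiles,
            meta = ct$meta,
            excluded = excluded_df,
            size_factors = sf,
            class = "coverage_profile_set")
}

#' @export
print.coverage_profile_set <- function(x, ...) {
  cat(sprintf("coverage_profile_set: %d transcripts x %d specimens (%d excluded)\n",
              length(x), nrow(attr(x, "meta")), nrow(attr(x, "excluded"))))
  invisible(x)
}

#' Restrict profiles to the long length stratum
#'
#' Coverage comparison is only meaningful for transcripts long enough to
#' resolve an elongation gradient; this keeps profiles whose transcript falls
#' in the long stratum (length above the upper boundary, 1300 nt by
#' default).
#'
#' @param profiles A `coverage_profile_set`.
#' @param strata A `length_strata` from [stratify_by_length()].
#' @return The filtered `coverage_profile_set` (attributes preserved).
#' @export
coverage_groups_filter <- function(profiles, strata) {
  stopifnot(inherits(profiles, "coverage_profile_set"),
            inherits(strata, "length_strata"))
  long_ids <- strata$assignment$transcript_id[strata$assignment$stratum == "long"]
  keep <- intersect(names(profiles), long_ids)
  out <- profiles[keep]
  attributes(out) <- c(attributes(out),
                       attributes(profiles)[c("meta", "excluded", "size_factors")])
  class(out) <- "coverage_profile_set"
  names(out) <- keep
  out
}

#' Serialize coverage profiles to long-format TSV
#'
#' @param profiles A `coverage_profile_set`.
#' @param path Output TSV with columns transcript_id, specimen_id,
#'   exon_rank (1 = 5'-most), density.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    data.frame(transcript_id = p$transcript_id,
               specimen_id = rep(colnames(p$mat), each = nrow(p$mat)),
               exon_rank = rep(seq_len(nrow(p$mat)), ncol(p$mat)),
               density = as.vector(p$mat),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
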