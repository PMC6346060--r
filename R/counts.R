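#' Exon-by-specimen count table
#'
#' Holds non-negative integer counts for exon rows (identified by
#' `transcript_id` and `exon_index`) across specimens, together with the
#' specimen metadata: genotype group (`WT`/`AT`), treatment condition
#' (`Untr` untreated, `R0` sampled immediately after a 1 h camptothecin
#' pulse, `R15`/`R30` after 15/30 min of drug-free recovery) and replicate
#' index.
#'
#' @param counts Integer matrix, one row per exon, one column per specimen;
#'   rownames of the form `"<transcript_id>:<exon_index>"` (set from
#'   `row_info` if absent).
#' @param row_info data.frame with columns `transcript_id`, `exon_index`
#'   aligned with the rows of `counts`.
#' @param meta data.frame with columns `specimen_id`, `group`, `condition`,
#'   `replicate`; one row per column of `counts`.
#' @return An object of class `counts_table`.
#' @export
counts_table <- function(counts, row_info, meta) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column %d", idx[1], idx[2]))
  }
  if (any(counts != round(counts))) {
    idx <- which(counts != round(counts), arr.ind = TRUE)[1, ]
    stop(sprintf("non-integer count at row %d, column %d", idx[1], idx[2]))
  }
  storage.mode(counts) <- "integer"
  stopifnot(nrow(row_info) == nrow(counts),
            all(c("transcript_id", "exon_index") %in% names(row_info)))
  rownames(counts) <- paste0(row_info$transcript_id, ":", row_info$exon_index)
  validate_specimen_meta(meta)
  missing_meta <- setdiff(colnames(counts), meta$specimen_id)
  extra_meta <- setdiff(meta$specimen_id, colnames(counts))
  if (length(missing_meta) || length(extra_meta))
    stop("counts/metadata specimen mismatch; missing metadata for: ",
         paste(missing_meta, collapse = ", "),
         "; metadata without counts column: ",
         paste(extra_meta, collapse = ", "))
  meta <- meta[match(colnames(counts), meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(
    list(counts = counts,
         row_info = data.frame(transcript_id = as.character(row_info$transcript_id),
                               exon_index = as.integer(row_info$exon_index),
                               stringsAsFactors = FALSE),
         meta = meta),
    class = "counts_table"
  )
}

validate_specimen_meta <- function(meta) {
  need <- c("specimen_id", "group", "condition", "replicate")
  if (!all(need %in% names(meta)))
    stop("specimen metadata is missing columns: ",
         paste(setdiff(need, names(meta)), collapse = ", "))
  if (!all(meta$group %in% c("WT", "AT")))
    stop("group must be WT or AT")
  if (!all(meta$condition %in% c("Untr", "R0", "R15", "R30")))
    stop("condition must be one of Untr, R0, R15, R30")
  if (any(meta$replicate < 1) || any(meta$replicate != round(meta$replicate)))
    stop("replicate must be a positive integer")
  key <- paste(meta$group, meta$condition, meta$replicate)
  if (anyDuplicated(key))
    stop("duplicated (group, condition, replicate) triplet: ",
         key[duplicated(key)][1])
  invisible(meta)
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table: %d exon rows x %d specimens (%d transcripts)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$row_info$transcript_id))))
  invisible(x)
}

#' Read an exon count table and its specimen metadata from TSV
#'
#' @param path TSV of counts: columns `transcript_id`, `exon_index`, then one
#'   integer column per specimen.
#' @param meta_path TSV of specimen metadata with columns `specimen_id`,
#'   `group`, `condition`, `replicate`.
#' @return A [counts_table()] object.
#' @export
read_counts <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("transcript_id", "exon_index") %in% names(tab)))
    stop("counts TSV must start with transcript_id and exon_index columns")
  meta <- utils::read.delim(meta_path, check.names = FALSE, stringsAsFactors = FALSE)
  spec_cols <- setdiff(names(tab), c("transcript_id", "exon_index"))
  mat <- as.matrix(tab[spec_cols])
  if (!is.numeric(mat)) stop("non-numeric count cell in ", path)
  counts_table(mat, tab[c("transcript_id", "exon_index")], meta)
}

#' Write an exon count table and its specimen metadata to TSV
#'
#' @param ct A [counts_table()] object.
#' @param path,meta_path Output TSV paths for counts and metadata.
#' @return `path`, invisibly.
#' @export
write_counts <- function(ct, path, meta_path) {
  stopifnot(inherits(ct, "counts_table"))
  out <- cbind(ct$row_info, as.data.frame(ct$counts, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ct$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Select specimen columns of a counts table
#'
#' @param ct A [counts_table()].
#' @param group,condition Optional filters on the specimen metadata.
#' @return Character vector of specimen_ids matching the filters.
#' @export
specimens <- function(ct, group = NULL, condition = NULL) {
  keep <- rep(TRUE, nrow(ct$meta))
  if (!is.null(group)) keep <- keep & ct$meta$group %in% group
  if (!is.null(condition)) keep <- keep & ct$meta$condition %in% condition
  ct$meta$specimen_id[keep]
}
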