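#' Transcript annotation container
#'
#' A `transcript_annotation` object holds the exon structure of a set of
#' transcripts. Exon coordinates are stored 0-based half-open so that exon
#' length is simply `end - start`; GTF input/output converts at the boundary.
#'
#' @param transcripts data.frame with columns `transcript_id`, `gene_id`,
#'   `chrom`, `strand` (one of `"+"`, `"-"`) and `length` (sum of exon
#'   lengths, nt).
#' @param exons data.frame with columns `transcript_id`, `exon_index`
#'   (1-based, in genomic start order), `start`, `end` (0-based half-open).
#'
#' @return An object of class `transcript_annotation`: a list with elements
#'   `transcripts` and `exons`.
#' @export
transcript_annotation <- function(transcripts, exons) {
  stopifnot(is.data.frame(transcripts), is.data.frame(exons))
  need_tx <- c("transcript_id", "gene_id", "chrom", "strand", "length")
  need_ex <- c("transcript_id", "exon_index", "start", "end")
  if (!all(need_tx %in% names(transcripts)))
    stop("transcripts is missing columns: ",
         paste(setdiff(need_tx, names(transcripts)), collapse = ", "))
  if (!all(need_ex %in% names(exons)))
    stop("exons is missing columns: ",
         paste(setdiff(need_ex, names(exons)), collapse = ", "))
  obj <- structure(
    list(transcripts = transcripts[need_tx],
         exons = exons[need_ex]),
    class = "transcript_annotation"
  )
  validate_annotation(obj)
  obj
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf("transcript_annotation: %d transcripts, %d exons\n",
              nrow(x$transcripts), nrow(x$exons)))
  invisible(x)
}

validate_annotation <- function(ann) {
  tx <- ann$transcripts
  ex <- ann$exons
  if (anyDuplicated(tx$transcript_id))
    stop("duplicated transcript_id in annotation")
  if (!all(tx$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (!all(ex$transcript_id %in% tx$transcript_id))
    stop("exons reference unknown transcript_id")
  if (any(ex$end <= ex$start))
    stop("exon with end <= start (coordinates are 0-based half-open)")
  # per-transcript: sorted, non-overlapping, lengths consistent
  by_tx <- split(ex, ex$transcript_id)
  for (id in names(by_tx)) {
    e <- by_tx[[id]]
    e <- e[order(e$exon_index), , drop = FALSE]
    if (is.unsorted(e$start, strictly = TRUE) && nrow(e) > 1)
      stop("exons of transcript ", id, " are not sorted by genomic start")
    if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)]))
      stop("overlapping exons within transcript ", id)
    len <- sum(e$end - e$start)
    if (len != tx$length[match(id, tx$transcript_id)])
      stop("length of transcript ", id, " does not equal the sum of its exons")
    if (len < 1) stop("transcript ", id, " has length < 1")
  }
  invisible(ann)
}

#' Read transcript models from a GTF file
#'
#' Exon features are collected per `transcript_id`; coordinates are converted
#' from the GTF 1-based closed convention to the internal 0-based half-open
#' convention and transcript lengths are computed as the sum of exon lengths.
#'
#' @param path Path to a GTF (GTF2.2 attribute syntax) file whose exon
#'   features carry `transcript_id` and `gene_id` attributes.
#' @return A [transcript_annotation()] object.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[S4Vectors::mcols(gr)$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", path)
  m <- S4Vectors::mcols(gr)
  if (is.null(m$transcript_id) || anyNA(m$transcript_id)) {
    bad <- if (is.null(m$transcript_id)) seq_along(gr) else which(is.na(m$transcript_id))
    stop("exon record(s) without transcript_id attribute: record ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (is.null(m$gene_id) || anyNA(m$gene_id)) {
    bad <- if (is.null(m$gene_id)) seq_along(gr) else which(is.na(m$gene_id))
    stop("exon record(s) without gene_id attribute: record ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  ex <- data.frame(
    transcript_id = as.character(m$transcript_id),
    gene_id = as.character(m$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based closed -> 0-based half-open
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  ex <- ex[order(ex$transcript_id, ex$start), ]
  ex$exon_index <- stats::ave(ex$start, ex$transcript_id, FUN = seq_along)
  first <- !duplicated(ex$transcript_id)
  tx <- data.frame(
    transcript_id = ex$transcript_id[first],
    gene_id = ex$gene_id[first],
    chrom = ex$chrom[first],
    strand = ex$strand[first],
    stringsAsFactors = FALSE
  )
  tx$length <- as.integer(rowsum(ex$end - ex$start, ex$transcript_id)[tx$transcript_id, 1])
  transcript_annotation(tx, ex[c("transcript_id", "exon_index", "start", "end")])
}

#' Write transcript models to a GTF file
#'
#' The inverse of [read_gtf()]: exon records are emitted with 1-based closed
#' coordinates and `transcript_id`/`gene_id` attributes, so that
#' `read_gtf(write_gtf(ann, f))` reproduces `ann` exactly.
#'
#' @param ann A [transcript_annotation()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "transcript_annotation"))
  ex <- ann$exons
  tx <- ann$transcripts
  i <- match(ex$transcript_id, tx$transcript_id)
  gr <- GenomicRanges::GRanges(
    seqnames = tx$chrom[i],
    ranges = IRanges::IRanges(start = ex$start + 1L, end = ex$end),
    strand = tx$strand[i]
  )
  S4Vectors::mcols(gr)$type <- "exon"
  S4Vectors::mcols(gr)$source <- "elongrec"
  S4Vectors::mcols(gr)$transcript_id <- ex$transcript_id
  S4Vectors::mcols(gr)$gene_id <- tx$gene_id[i]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Stratify transcripts by length
#'
#' Partitions transcripts into three strata by mature length: short
#' (`length <= b1`), mid (`b1 < length <= b2`) and long (`length > b2`).
#' The default boundaries of 175 and 1300 nt separate structural/small RNAs,
#' mid-sized transcripts, and the long transcripts on which coverage-profile
#' comparison is meaningful.
#'
#' @param ann A [transcript_annotation()] object, or a data.frame with
#'   columns `transcript_id` and `length`.
#' @param b1,b2 Stratum boundaries in nt, `b1 < b2`.
#' @return A list of class `length_strata` with `boundaries = c(b1, b2)` and
#'   `assignment`: a data.frame with `transcript_id`, `length` and `stratum`
#'   (factor with levels short/mid/long).
#' @export
stratify_by_length <- function(ann, b1 = 175, b2 = 1300) {
  if (!(is.numeric(b1) && is.numeric(b2) && b1 < b2))
    stop("stratum boundaries must satisfy b1 < b2")
  tx <- if (inherits(ann, "transcript_annotation")) ann$transcripts else ann
  stopifnot(all(c("transcript_id", "length") %in% names(tx)))
  if (any(tx$length < 1)) stop("all transcript lengths must be >= 1")
  stratum <- cut(tx$length, breaks = c(-Inf, b1, b2, Inf),
                 labels = c("short", "mid", "long"), right = TRUE)
  structure(
    list(boundaries = c(b1 = b1, b2 = b2),
         assignment = data.frame(transcript_id = tx$transcript_id,
                                 length = tx$length,
                                 stratum = stratum,
                                 stringsAsFactors = FALSE)),
    class = "length_strata"
  )
}

#' Overlap arithmetic for two identifier sets
#'
#' @param a,b Character vectors of identifiers (duplicates are ignored).
#' @return A list with `only_a`, `only_b`, `common` (character vectors that
#'   partition the union) and `union_count` (`|a| + |b| - |a intersect b|`).
#' @export
set_overlap <- function(a, b) {
  a <- unique(as.character(a))
  b <- unique(as.character(b))
  common <- intersect(a, b)
  list(
    only_a = setdiff(a, b),
    only_b = setdiff(b, a),
    common = common,
    union_count = length(a) + length(b) - length(common)
  )
}
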