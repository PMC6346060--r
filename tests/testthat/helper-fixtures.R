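# Shared fixture builders; everything is generated in code.

# A tiny two-transcript annotation: TXA (+ strand, 3 exons) and TXB
# (- strand, 2 exons). Coordinates 0-based half-open.
toy_annotation <- function() {
  tx <- data.frame(
    transcript_id = c("TXA", "TXB"),
    gene_id = c("GA", "GB"),
    chrom = c("chr1", "chr2"),
    strand = c("+", "-"),
    length = c(300L, 500L))
  ex <- data.frame(
    transcript_id = c("TXA", "TXA", "TXA", "TXB", "TXB"),
    exon_index = c(1L, 2L, 3L, 1L, 2L),
    start = c(100L, 300L, 600L, 1000L, 2000L),
    end = c(200L, 400L, 700L, 1100L, 2400L))
  transcript_annotation(tx, ex)
}

# Build a coverage_profile_set directly from per-transcript density
# matrices (exons x specimens, 5'->3') and specimen metadata.
make_profile_set <- function(mats, meta, exon_lengths = NULL) {
  profiles <- lapply(names(mats), function(id) {
    m <- mats[[id]]
    list(transcript_id = id, mat = m,
         exon_lengths = exon_lengths %||% rep(100, nrow(m)))
  })
  names(profiles) <- names(mats)
  structure(profiles, meta = meta,
            excluded = data.frame(transcript_id = character(),
                                  reason = character()),
            size_factors = stats::setNames(rep(1, nrow(meta)), meta$specimen_id),
            class = "coverage_profile_set")
}

one_group_meta <- function(group = "WT", conditions = c("Untr", "R0"),
                           n_reps = 2) {
  meta <- expand.grid(replicate = seq_len(n_reps), condition = conditions,
                      group = group, stringsAsFactors = FALSE)
  meta$specimen_id <- with(meta, paste(group, condition, replicate, sep = "_"))
  meta[c("specimen_id", "group", "condition", "replicate")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
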