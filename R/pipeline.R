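#' Pipeline run configuration
#'
#' Collects every stage parameter with defaults matching the analysis the
#' package implements: Pearson change threshold 0.2, length strata at
#' 175/1300 nt, profile filters (>= 4 exons, mean count >= 5), the
#' transcript DE preset (|log2FC| >= 1, adjusted p <= 0.1) and the KCl
#' preset (|FC| >= 1.5, FDR <= 0.05), archetype margin 0.5 log2 units,
#' 1000 permutations for the integrative-correlation null.
#'
#' @param simulate If `TRUE` (default) the run starts from
#'   [simulate_nascent()]; otherwise `gtf_path`, `counts_path` and
#'   `meta_path` must point to existing inputs.
#' @param sim List of [sim_config()] overrides used when `simulate = TRUE`.
#' @param gtf_path,counts_path,meta_path Input paths when `simulate = FALSE`.
#' @param pearson_threshold,strata_b1,strata_b2,min_exons,min_mean_count,
#'   n_perm,de_preset,cluster_k,archetype_delta Stage parameters.
#' @param seed Integer seed for the simulator and permutation draws.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulate = TRUE,
                       sim = list(),
                       gtf_path = NULL, counts_path = NULL, meta_path = NULL,
                       pearson_threshold = 0.2,
                       strata_b1 = 175, strata_b2 = 1300,
                       min_exons = 4, min_mean_count = 5,
                       n_perm = 1000,
                       de_preset = "transcript_preset",
                       cluster_k = 4, archetype_delta = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  if (!cfg$simulate &&
      (is.null(cfg$gtf_path) || is.null(cfg$counts_path) || is.null(cfg$meta_path)))
    stop("simulate = FALSE requires gtf_path, counts_path and meta_path")
  stopifnot(cfg$strata_b1 < cfg$strata_b2, cfg$n_perm >= 1)
  class(cfg) <- "run_config"
  cfg
}

#' Read/write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return [read_run_config()] returns a `run_config`;
#'   [write_run_config()] returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @param config A `run_config` object.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full elongation-recovery analysis
#'
#' Executes the stages in dependency order: input (simulation or file
#' loading), coverage profiles over the long length stratum, the Pearson
#' change screen per group with overlap arithmetic, recovery dissimilarity
#' and the integrative-correlation comparison, transcript-level NB
#' differential expression per group with the configured preset, the
#' gene-length association, pattern clustering of the symmetric-difference
#' DE set, and a plain-text report. Every artifact is a flat TSV/GTF under
#' `outdir` and is listed with its MD5 hash in the returned manifest;
#' rerunning with the same config and seed reproduces identical hashes.
#'
#' @param config A [run_config()].
#' @param outdir Output directory (created if needed).
#' @return List with `manifest` (data.frame file, md5), `summary` (the
#'   quantities the report prints) and `outdir`, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  add <- function(p) { paths[[length(paths) + 1L]] <<- p; p }

  # --- stage: inputs -------------------------------------------------------
  if (config$simulate) {
    sim_args <- utils::modifyList(list(seed = config$seed), config$sim)
    sim <- simulate_nascent(do.call(sim_config, sim_args))
    ann <- sim$annotation
    ct <- sim$counts
    add(write_gtf(ann, file.path(outdir, "annotation.gtf")))
    write_counts(ct, file.path(outdir, "counts.tsv"), file.path(outdir, "meta.tsv"))
    add(file.path(outdir, "counts.tsv")); add(file.path(outdir, "meta.tsv"))
    add(write_truth(sim$truth, file.path(outdir, "truth.tsv")))
  } else {
    for (p in c(config$gtf_path, config$counts_path, config$meta_path))
      if (!file.exists(p)) stop("input file not found: ", p)
    ann <- read_gtf(config$gtf_path)
    ct <- read_counts(config$counts_path, config$meta_path)
  }
  groups <- intersect(c("WT", "AT"), unique(ct$meta$group))

  # --- stage: profiles -----------------------------------------------------
  strata <- stratify_by_length(ann, config$strata_b1, config$strata_b2)
  profiles <- build_profiles(ct, ann, config$min_exons, config$min_mean_count)
  long_profiles <- coverage_groups_filter(profiles, strata)
  add(write_profiles(long_profiles, file.path(outdir, "profiles_long.tsv")))

  # --- stage: change screen ------------------------------------------------
  calls <- do.call(rbind, lapply(groups, function(g)
    detect_changed(long_profiles, g, config$pearson_threshold)))
  add(write_tsv(calls, file.path(outdir, "change_calls.tsv")))
  changed_by_group <- lapply(stats::setNames(groups, groups), function(g)
    calls$transcript_id[calls$group == g & calls$changed])
  ov <- if (length(groups) == 2)
    set_overlap(changed_by_group[[1]], changed_by_group[[2]])
  else NULL

  # --- stage: recovery dissimilarity + ICC ---------------------------------
  icc <- list()
  if (!is.null(ov) && ov$union_count >= 3) {
    union_ids <- unique(unlist(changed_by_group))
    diss <- list()
    for (rec in intersect(c("R15", "R30"), unique(ct$meta$condition))) {
      d_a <- dissimilarity_records(long_profiles, groups[1], rec,
                                   transcripts = union_ids)
      d_b <- dissimilarity_records(long_profiles, groups[2], rec,
                                   transcripts = union_ids)
      diss[[rec]] <- rbind(d_a, d_b)
      cmp <- icc_compare(d_a, d_b, n_perm = config$n_perm, seed = config$seed)
      icc[[rec]] <- data.frame(
        condition_pair = paste0("Untr-", rec), n = cmp$n, icc = cmp$icc,
        null_lo = cmp$null_band[1], null_hi = cmp$null_band[2],
        mean_delta = cmp$mean_delta,
        delta_null_lo = cmp$mean_delta_band[1],
        delta_null_hi = cmp$mean_delta_band[2],
        consistent_difference = cmp$consistent_difference)
    }
    add(write_tsv(do.call(rbind, diss), file.path(outdir, "dissimilarity.tsv")))
    add(write_tsv(do.call(rbind, icc), file.path(outdir, "icc_summary.tsv")))
  }

  # --- stage: differential expression --------------------------------------
  de_called <- list()
  length_assoc <- NULL
  for (g in groups) {
    de <- nb_de_test(ct, list(group = g, condition = "Untr"),
                     list(group = g, condition = "R0"))
    de_called[[g]] <- apply_preset(de, config$de_preset)
    add(write_tsv(de_called[[g]]$results,
                  file.path(outdir, paste0("de_", g, ".tsv"))))
  }
  de_first <- de_called[[groups[1]]]
  if (length(de_first$down) >= 3 && length(de_first$up) >= 3)
    length_assoc <- length_association(de_first$results, ann, "down")

  # --- stage: pattern clustering -------------------------------------------
  cluster_summary <- NULL
  if (length(groups) == 2 &&
      all(c("R0", "R15", "R30") %in% unique(ct$meta$condition))) {
    de_ov <- set_overlap(
      c(de_called[[1]]$up, de_called[[1]]$down),
      c(de_called[[2]]$up, de_called[[2]]$down))
    de_union <- c(de_ov$only_a, de_ov$only_b, de_ov$common)  # DE in >= 1 group
    if (length(de_union) >= config$cluster_k) {
      mat <- log2ratio_matrix(ct, feature_ids = sort(de_union))
      cl <- cluster_patterns(mat, k = config$cluster_k,
                             delta = config$archetype_delta)
      add(write_tsv(cl$membership, file.path(outdir, "clusters.tsv")))
      cluster_summary <- cl$clusters
    }
  }

  summary <- list(
    seed = config$seed,
    n_transcripts = nrow(ann$transcripts),
    strata_sizes = as.list(table(strata$assignment$stratum)),
    n_profiled_long = length(long_profiles),
    changed_counts = lapply(changed_by_group, length),
    overlap = if (!is.null(ov)) list(common = length(ov$common),
                                     union_count = ov$union_count),
    icc = lapply(icc, function(x) as.list(x)),
    de_counts = lapply(de_called, function(x)
      list(up = length(x$up), down = length(x$down))),
    length_association = length_assoc,
    clusters = if (!is.null(cluster_summary))
      apply(cluster_summary, 1, as.list, simplify = FALSE)
  )
  yaml::write_yaml(summary, add(file.path(outdir, "summary.yaml")))
  add(write_report(outdir))

  manifest <- data.frame(file = basename(unlist(paths)),
                         md5 = unname(tools::md5sum(unlist(paths))),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(outdir, "manifest.tsv"))
  invisible(list(manifest = manifest, summary = summary, outdir = outdir))
}

#' Write the human-readable run report
#'
#' Renders `report.txt` from the artifacts already present in `outdir`
#' (deterministic: regenerating from the same artifacts is byte-identical).
#'
#' @param outdir A directory produced by [run_pipeline()].
#' @return The report path, invisibly.
#' @export
write_report <- function(outdir) {
  s <- yaml::read_yaml(file.path(outdir, "summary.yaml"))
  ln <- character(0)
  out <- function(...) ln[[length(ln) + 1L]] <<- sprintf(...)
  out("Transcription elongation recovery analysis")
  out("==========================================")
  out("seed: %s", s$seed)
  out("transcripts: %d (strata short/mid/long: %s/%s/%s)",
      s$n_transcripts,
      s$strata_sizes$short %||% 0, s$strata_sizes$mid %||% 0,
      s$strata_sizes$long %||% 0)
  out("long-stratum transcripts profiled: %d", s$n_profiled_long)
  out("")
  out("Changed coverage profiles (Pearson screen, treated vs untreated):")
  for (g in names(s$changed_counts))
    out("  %s: %d", g, s$changed_counts[[g]])
  if (!is.null(s$overlap))
    out("  common: %d, union: %d", s$overlap$common, s$overlap$union_count)
  out("")
  if (length(s$icc)) {
    out("Integrative-correlation comparison of recovery dissimilarity:")
    for (rec in names(s$icc)) {
      x <- s$icc[[rec]]
      out("  %s: icc=%.3f (null %.3f..%.3f), mean delta=%.4f (null %.4f..%.4f) -> %s",
          x$condition_pair, x$icc, x$null_lo, x$null_hi, x$mean_delta,
          x$delta_null_lo, x$delta_null_hi,
          if (isTRUE(x$consistent_difference)) "consistent difference"
          else "no consistent difference")
    }
    out("")
  }
  out("Differential expression (R0 vs Untr, %s):", "per group")
  for (g in names(s$de_counts))
    out("  %s: %d up, %d down", g, s$de_counts[[g]]$up, s$de_counts[[g]]$down)
  if (!is.null(s$length_association)) {
    la <- s$length_association
    out("")
    out("Gene-length association (down-called set): R=%.3f (n=%d)", la$R, la$n)
    out("  mean length down=%.0f nt, up=%.0f nt (rank-sum p=%.3g)",
        la$mean_length_down, la$mean_length_up, la$location_test_p)
  }
  if (!is.null(s$clusters)) {
    out("")
    out("Expression-pattern clusters:")
    for (cl in s$clusters)
      out("  cluster %s: n=%s, archetype=%s", cl$cluster_id, cl$size, cl$archetype)
  }
  path <- file.path(outdir, "report.txt")
  writeLines(ln, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
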