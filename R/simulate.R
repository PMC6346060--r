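#' Configuration for the synthetic nascent-RNA generator
#'
#' The generator emulates a 1 h topoisomerase-I-poison (camptothecin) pulse
#' followed by timed washout, sampled by exon-level nascent RNA-seq in two
#' genotype groups (WT and ATM-deficient, "AT"). Per condition the expected
#' polymerase density along a transcript is:
#'
#' * `Untr`: uniform baseline `a` (polymerases per nt);
#' * `R0` (end of pulse): `a * exp(-lambda * x)` — survival of elongating
#'   polymerases past independently placed Top1 lesions at density `lambda`
#'   per nt, giving the 5'-biased blocked profile;
#' * `R15`/`R30` (t = 15/30 min washout): a fresh initiation wave has
#'   re-elongated to `v * t` nt, so density is `a` up to the wavefront and
#'   `a * (r + (1 - r) * exp(-lambda * x))` beyond it, `r` being the
#'   residual read-through fraction.
#'
#' Immediate-early genes (a fraction of transcripts shorter than
#' `ieg_max_len`) are additionally induced `ieg_fold`-fold in every treated
#' condition. Exon counts are drawn negative-binomially around
#' `depth * integral of density over the exon`, modulated by a reproducible
#' per-exon capture bias (log-normal, `exon_bias_sd` on the log scale) that
#' emulates the exon-to-exon efficiency differences of capture-based
#' nascent-RNA protocols.
#'
#' @param n_transcripts Number of transcripts to simulate.
#' @param length_log10_mean,length_log10_sd Parameters of the log10-normal
#'   transcript length distribution; lengths are floored at 200 nt.
#' @param exon_target_len Approximate exon length in nt; each transcript is
#'   split into `round(length / exon_target_len)` exons of jittered size.
#' @param init_density Baseline polymerase density `a` (per nt).
#' @param lambda_WT,lambda_AT Lesion density under CPT (per nt) per group.
#' @param v_WT,v_AT Recovery elongation velocity (nt per minute) per group.
#' @param residual_fraction Residual density fraction `r` beyond the
#'   wavefront, in `[0, 1]`.
#' @param ieg_fraction Fraction of short (`<= ieg_max_len`) transcripts
#'   flagged as immediate-early genes.
#' @param ieg_fold Fold induction of IEGs under treatment.
#' @param ieg_max_len Maximum length (nt) for IEG candidates.
#' @param depth Expected reads per unit (density x nt).
#' @param dispersion Negative-binomial dispersion `phi`
#'   (variance `mu + phi * mu^2`); 0 gives Poisson counts.
#' @param exon_bias_sd Log-scale sd of the per-exon capture bias shared by
#'   all specimens; 0 disables the bias.
#' @param n_reps Replicates per (group, condition).
#' @param groups,conditions Which groups/conditions to simulate.
#' @param seed Integer seed governing every random draw.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 300,
                       length_log10_mean = 4.2,
                       length_log10_sd = 0.7,
                       exon_target_len = 200,
                       init_density = 0.01,
                       lambda_WT = 7.5e-4,
                       lambda_AT = 7.5e-4,
                       v_WT = 1500,
                       v_AT = 1500,
                       residual_fraction = 0.1,
                       ieg_fraction = 0.1,
                       ieg_fold = 4,
                       ieg_max_len = 2000,
                       depth = 5,
                       dispersion = 0.05,
                       exon_bias_sd = 0.2,
                       n_reps = 3,
                       groups = c("WT", "AT"),
                       conditions = c("Untr", "R0", "R15", "R30"),
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(
    cfg$n_transcripts >= 1,
    cfg$lambda_WT >= 0, cfg$lambda_AT >= 0,
    cfg$v_WT > 0, cfg$v_AT > 0,
    cfg$residual_fraction >= 0, cfg$residual_fraction <= 1,
    cfg$ieg_fraction >= 0, cfg$ieg_fraction <= 1,
    cfg$depth > 0, cfg$dispersion >= 0, cfg$exon_bias_sd >= 0,
    cfg$n_reps >= 1,
    all(cfg$groups %in% c("WT", "AT")),
    all(cfg$conditions %in% c("Untr", "R0", "R15", "R30"))
  )
  class(cfg) <- "sim_config"
  cfg
}

washout_minutes <- c(Untr = NA_real_, R0 = 0, R15 = 15, R30 = 30)

#' Coverage-panel configuration
#'
#' A [sim_config()] preset for the coverage-profile analyses: the same
#' generative effect sizes as the defaults but transcript lengths drawn
#' from a tight long-gene panel (log10-normal, median ~50 kb) so that every
#' transcript falls in the long stratum, resolves the elongation gradient
#' over hundreds of exons, and spans the 15/30-min recovery wavefronts.
#' IEG induction is disabled: IEGs are too short for coverage comparison.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` object.
#' @export
sim_config_coverage_panel <- function(...) {
  args <- utils::modifyList(
    list(length_log10_mean = 4.7, length_log10_sd = 0.15,
         ieg_fraction = 0),
    list(...))
  do.call(sim_config, args)
}

#' Expected polymerase density at a transcript position
#'
#' @param x Position(s) in nt from the TSS, `0 <= x < L`.
#' @param condition One of `"Untr"`, `"R0"`, `"R15"`, `"R30"`.
#' @param params List with fields `a` (baseline density), `lambda` (lesions
#'   per nt), `v` (nt/min), `r` (residual fraction), `L` (transcript length),
#'   and optionally `is_ieg` and `ieg_fold`.
#' @return Expected density (per nt) at each `x`.
#' @export
expected_density <- function(x, condition, params) {
  L <- params$L
  if (any(x < 0) || any(x >= L))
    stop("position x outside [0, L)")
  a <- params$a
  lam <- params$lambda
  r <- params$r
  fold <- if (isTRUE(params$is_ieg)) params$ieg_fold else 1
  d <- switch(condition,
    Untr = rep(a, length(x)),
    R0 = fold * a * exp(-lam * x),
    R15 = ,
    R30 = {
      w <- params$v * washout_minutes[[condition]]
      fold * a * ifelse(x <= w, 1, r + (1 - r) * exp(-lam * x))
    },
    stop("unknown condition: ", condition)
  )
  unname(d)
}

# Integral of expected_density over [x0, x1), analytic, vectorized over exons.
expected_exon_signal <- function(x0, x1, condition, params) {
  a <- params$a
  lam <- params$lambda
  r <- params$r
  fold <- if (isTRUE(params$is_ieg)) params$ieg_fold else 1
  int_exp <- function(u0, u1) {
    # integral of exp(-lam x) on [u0, u1)
    if (lam == 0) u1 - u0 else (exp(-lam * u0) - exp(-lam * u1)) / lam
  }
  val <- switch(condition,
    Untr = a * (x1 - x0),
    R0 = fold * a * int_exp(x0, x1),
    R15 = ,
    R30 = {
      w <- params$v * washout_minutes[[condition]]
      below <- pmax(0, pmin(x1, w) - x0)          # fully recovered stretch
      u0 <- pmax(x0, w)
      u1 <- pmax(x1, w)
      beyond <- r * (u1 - u0) + (1 - r) * int_exp(u0, u1)
      fold * a * (below + beyond)
    },
    stop("unknown condition: ", condition)
  )
  unname(val)
}

group_params <- function(cfg, group) {
  if (group == "WT") list(lambda = cfg$lambda_WT, v = cfg$v_WT)
  else list(lambda = cfg$lambda_AT, v = cfg$v_AT)
}

#' Simulate an exon-level nascent-RNA experiment
#'
#' Draws transcript lengths, exon structures, genomic placements, IEG flags,
#' per-exon capture biases and negative-binomial exon counts for every
#' (group, condition, replicate) specimen, from a single seeded stream in a
#' fixed documented order (lengths, IEG flags, exonization, biases,
#' placement, then counts specimen-by-specimen in metadata row order).
#' Identical configuration (including `seed`) gives bit-identical output.
#'
#' @param cfg A [sim_config()] object.
#' @return A list with `annotation` ([transcript_annotation()]), `counts`
#'   ([counts_table()]), `truth` (list: `transcripts` data.frame with
#'   per-transcript generative values, `exon_bias` data.frame, `params`
#'   per-group lambda/v and shared r), and `config`.
#' @export
simulate_nascent <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_transcripts
  ids <- sprintf("TX%04d", seq_len(n))

  # 1. lengths
  len <- pmax(200, round(10^stats::rnorm(n, cfg$length_log10_mean, cfg$length_log10_sd)))

  # 2. IEG flags among short transcripts
  is_ieg <- rep(FALSE, n)
  short <- which(len <= cfg$ieg_max_len)
  if (length(short) && cfg$ieg_fraction > 0)
    is_ieg[short] <- stats::runif(length(short)) < cfg$ieg_fraction

  # 3. exonization: jittered segment lengths summing to the transcript length
  exon_list <- vector("list", n)
  for (i in seq_len(n)) {
    m <- max(1, round(len[i] / cfg$exon_target_len))
    wgt <- stats::runif(m, 0.5, 1.5)
    el <- floor(len[i] * wgt / sum(wgt))
    el[1] <- el[1] + (len[i] - sum(el))  # rounding remainder to first exon
    exon_list[[i]] <- el
  }

  # 4. per-exon capture bias, shared by all specimens
  bias_list <- lapply(exon_list, function(el)
    if (cfg$exon_bias_sd > 0) stats::rlnorm(length(el), -cfg$exon_bias_sd^2 / 2, cfg$exon_bias_sd)
    else rep(1, length(el)))

  # 5. genomic placement: round-robin chromosomes, random strand and introns
  chrom <- paste0("chr", (seq_len(n) - 1L) %% 5L + 1L)
  strand <- ifelse(stats::runif(n) < 0.5, "+", "-")
  offset <- stats::setNames(rep(0L, 5), paste0("chr", 1:5))
  ex_rows <- vector("list", n)
  for (i in seq_len(n)) {
    el <- exon_list[[i]]
    introns <- if (length(el) > 1) round(stats::runif(length(el) - 1, 200, 2000)) else integer(0)
    starts <- offset[[chrom[i]]] + cumsum(c(0, el[-length(el)] + introns))
    ex_rows[[i]] <- data.frame(transcript_id = ids[i],
                               exon_index = seq_along(el),
                               start = as.integer(starts),
                               end = as.integer(starts + el))
    offset[[chrom[i]]] <- ex_rows[[i]]$end[length(el)] + 5000L
  }
  exons <- do.call(rbind, ex_rows)
  tx <- data.frame(transcript_id = ids, gene_id = sub("TX", "G", ids),
                   chrom = chrom, strand = strand, length = as.integer(len),
                   stringsAsFactors = FALSE)
  ann <- transcript_annotation(tx, exons)

  # specimen metadata in fixed order: group-major, then condition, replicate
  meta <- expand.grid(replicate = seq_len(cfg$n_reps),
                      condition = cfg$conditions,
                      group = cfg$groups,
                      stringsAsFactors = FALSE)[, c("group", "condition", "replicate")]
  meta$specimen_id <- with(meta, paste(group, condition, replicate, sep = "_"))
  meta <- meta[c("specimen_id", "group", "condition", "replicate")]

  # expected per-exon signal (before bias/depth), per group x condition
  # transcript coordinates run 5'->3'; on the minus strand the genomically
  # first exon is the 3' end, so cumulative positions are taken in reverse
  x_rel <- vector("list", n)
  for (i in seq_len(n)) {
    el <- exon_list[[i]]
    el53 <- if (strand[i] == "-") rev(el) else el
    ends53 <- cumsum(el53)
    x0_53 <- ends53 - el53
    if (strand[i] == "-") {
      x_rel[[i]] <- cbind(x0 = rev(x0_53), x1 = rev(ends53))
    } else {
      x_rel[[i]] <- cbind(x0 = x0_53, x1 = ends53)
    }
  }

  # 6. counts, specimen by specimen in meta row order
  nr <- nrow(exons)
  counts <- matrix(0L, nrow = nr, ncol = nrow(meta),
                   dimnames = list(NULL, meta$specimen_id))
  bias <- unlist(bias_list, use.names = FALSE)
  mu_cache <- new.env(parent = emptyenv())
  mu_for <- function(group, condition) {
    key <- paste(group, condition)
    if (!is.null(mu_cache[[key]])) return(mu_cache[[key]])
    gp <- group_params(cfg, group)
    mu <- numeric(nr)
    at <- 1L
    for (i in seq_len(n)) {
      m <- length(exon_list[[i]])
      pars <- list(a = cfg$init_density, lambda = gp$lambda, v = gp$v,
                   r = cfg$residual_fraction, L = len[i],
                   is_ieg = is_ieg[i], ieg_fold = cfg$ieg_fold)
      mu[at:(at + m - 1L)] <- expected_exon_signal(
        x_rel[[i]][, "x0"], x_rel[[i]][, "x1"], condition, pars)
      at <- at + m
    }
    mu_cache[[key]] <- cfg$depth * mu
    mu_cache[[key]]
  }
  for (j in seq_len(nrow(meta))) {
    mu <- mu_for(meta$group[j], meta$condition[j]) * bias
    counts[, j] <- if (cfg$dispersion == 0) stats::rpois(nr, mu)
                   else stats::rnbinom(nr, mu = mu, size = 1 / cfg$dispersion)
  }

  ct <- counts_table(counts, exons[c("transcript_id", "exon_index")], meta)
  truth <- list(
    transcripts = data.frame(transcript_id = ids, length = len,
                             n_exons = lengths(exon_list),
                             is_ieg = is_ieg, a = cfg$init_density,
                             stringsAsFactors = FALSE),
    exon_bias = data.frame(transcript_id = exons$transcript_id,
                           exon_index = exons$exon_index, bias = bias,
                           stringsAsFactors = FALSE),
    params = list(
      WT = c(group_params(cfg, "WT"), r = cfg$residual_fraction),
      AT = c(group_params(cfg, "AT"), r = cfg$residual_fraction))
  )
  list(annotation = ann, counts = ct, truth = truth, config = cfg)
}

#' Write the simulator truth table to TSV
#'
#' @param truth The `truth` element of a [simulate_nascent()] result.
#' @param path Output TSV path (one row per transcript).
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  utils::write.table(truth$transcripts, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
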