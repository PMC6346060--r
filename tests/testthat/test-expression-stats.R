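# Brute-force BH oracle: adjusted p_(i) = min over j >= i of p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  for (i in seq_len(m))
    adj[o[i]] <- min(1, min(p[o[i:m]] * m / seq(i, m)))
  adj
}

de_fixture <- function(seed, n = 400, lambda_b = 0) {
  cfg <- sim_config(n_transcripts = n, length_log10_mean = 3.6,
                    length_log10_sd = 0.4, ieg_fraction = 0,
                    lambda_WT = lambda_b, n_reps = 6, groups = "WT",
                    conditions = "Untr", seed = seed)
  simulate_nascent(cfg)$counts
}

test_that("log2 fold change uses the declared pseudocount", {
  ct <- de_fixture(31)
  de <- nb_de_test(ct, paste0("WT_Untr_", 1:3), paste0("WT_Untr_", 4:6))
  i <- which.max(de$mean_a)
  expect_equal(de$log2fc[i],
               log2((de$mean_b[i] + 0.5) / (de$mean_a[i] + 0.5)))
  # declared example: normalized means 5 vs 20
  expect_equal(log2((20 + 0.5) / (5 + 0.5)), 1.8982, tolerance = 1e-4)
  expect_error(nb_de_test(ct, "WT_Untr_1", paste0("WT_Untr_", 2:3)),
               "at least 2 replicates")
})

test_that("BH adjustment matches the brute-force oracle and its invariances", {
  expect_equal(bh_oracle(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  ct <- de_fixture(32)
  de <- nb_de_test(ct, paste0("WT_Untr_", 1:3), paste0("WT_Untr_", 4:6))
  expect_equal(de$padj, bh_oracle(de$p))
  expect_true(all(de$padj >= de$p))
  # permutation invariance
  set.seed(6)
  p <- runif(50)
  perm <- sample(50)
  expect_equal(bh_oracle(p)[perm], bh_oracle(p[perm]))
  expect_equal(stats::p.adjust(p, "BH"), bh_oracle(p))
  # monotone non-decreasing in raw p order
  expect_true(all(diff(bh_oracle(p)[order(p)]) >= -1e-12))
})

test_that("threshold presets apply inclusive printed cutoffs", {
  res <- data.frame(
    feature_id = c("a", "b", "c", "d", "e"),
    mean_a = 10, mean_b = 10,
    log2fc = c(1.0, log2(1.49), -2, 0.2, -1.2),
    stat = 0,
    p = 0.01,
    padj = c(0.10, 0.01, 0.5, 0.01, 0.05))
  tp <- apply_preset(res, "transcript_preset")
  expect_equal(tp$up, "a")          # log2FC exactly 1, padj exactly 0.1
  expect_equal(tp$down, "e")
  kcl <- apply_preset(res, "kcl_preset")
  expect_false("b" %in% c(kcl$up, kcl$down))   # FC 1.49 misses 1.5
  expect_false("c" %in% c(kcl$up, kcl$down))   # padj 0.5 misses 0.05
  expect_true("e" %in% kcl$down)               # FC -2.3, padj 0.05
  expect_length(intersect(tp$up, tp$down), 0)
  expect_error(apply_preset(res, "mystery_preset"), "unknown preset")
})

test_that("DE on permuted labels of identical specimens makes no calls", {
  ct <- de_fixture(33, n = 500)
  de <- nb_de_test(ct, paste0("WT_Untr_", c(1, 3, 5)),
                   paste0("WT_Untr_", c(2, 4, 6)))
  tp <- apply_preset(de, "transcript_preset")
  expect_lt(max(abs(de$log2fc)), 1.5)
  expect_length(c(tp$up, tp$down), 0)
})

test_that("length association: exact anti-correlation and null behavior", {
  lens <- round(10^runif(60, 3, 5.5))
  res <- data.frame(feature_id = sprintf("T%02d", 1:60),
                    mean_a = 10, mean_b = 10,
                    log2fc = rep(c(-2, 2), each = 30),
                    stat = -log10(lens),
                    p = 0.001, padj = 0.001)
  res <- apply_preset(res, "transcript_preset")$results
  ann <- data.frame(transcript_id = res$feature_id, length = lens)
  la <- length_association(res, ann, "down")
  expect_equal(la$R, -1)
  expect_equal(la$n, 30)
  # stat independent of length: |R| small for n = 1000 in most seeded runs
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    n <- 1000
    null_res <- data.frame(feature_id = sprintf("N%04d", 1:n),
                           mean_a = 10, mean_b = 10, log2fc = -2,
                           stat = rnorm(n), p = 0.001, padj = 0.001)
    null_res <- apply_preset(null_res, "transcript_preset")$results
    null_ann <- data.frame(transcript_id = null_res$feature_id,
                           length = round(10^runif(n, 3, 5.5)))
    if (abs(length_association(null_res, null_ann, "down")$R) < 0.1)
      hits <- hits + 1
  }
  expect_gte(hits, 19)
  expect_error(length_association(res[res$direction == "up", ], ann, "down"),
               "fewer than 3")
})

test_that("average-linkage merge heights match a naive agglomeration oracle", {
  naive_average_linkage_heights <- function(mat) {
    d <- as.matrix(stats::dist(mat))
    active <- lapply(seq_len(nrow(mat)), identity)
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (i >= j) next
        h <- mean(d[active[[i]], active[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
      heights <- c(heights, best[1])
      active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
      active[[best[3]]] <- NULL
    }
    heights
  }
  set.seed(9)
  for (i in 1:5) {
    mat <- matrix(rnorm(6 * 4), nrow = 6,
                  dimnames = list(paste0("f", 1:6),
                                  c("WT_R0", "WT_R15", "AT_R0", "AT_R15")))
    tree <- stats::hclust(stats::dist(mat), method = "average")
    expect_equal(sort(tree$height),
                 sort(naive_average_linkage_heights(mat)))
  }
})

test_that("planted archetype patterns are recovered by clustering", {
  set.seed(10)
  conds <- c("R0", "R15", "R30")
  wt_base <- c(1, 0.6, 0.3)
  templates <- list(
    similar_both = c(wt_base, wt_base),
    up_in_AT = c(wt_base, wt_base + 1.5),
    up_in_AT_after_washout = c(wt_base, wt_base + c(0, 1.5, 1.5)),
    down_in_AT = c(wt_base, wt_base - 1.5))
  mat <- do.call(rbind, lapply(names(templates), function(a)
    matrix(rep(templates[[a]], each = 10), nrow = 10) +
      matrix(rnorm(60, sd = 0.05), nrow = 10)))
  colnames(mat) <- c(paste0("WT_", conds), paste0("AT_", conds))
  rownames(mat) <- sprintf("f%02d", seq_len(nrow(mat)))
  truth <- rep(names(templates), each = 10)
  cl <- cluster_patterns(mat, k = 4)
  expect_setequal(cl$clusters$archetype, names(templates))
  # each planted block lands in a single cluster with its archetype
  for (a in names(templates))
    expect_true(all(cl$membership$archetype[truth == a] == a))
  # identical rows always share a cluster
  mat2 <- rbind(mat, mat[1, , drop = FALSE])
  rownames(mat2)[nrow(mat2)] <- "dup"
  for (k in c(2, 4, 8)) {
    cl2 <- cluster_patterns(mat2, k = k)
    ids <- cl2$membership$cluster_id[cl2$membership$feature_id %in%
                                     c("f01", "dup")]
    expect_equal(ids[1], ids[2])
  }
  # determinism
  expect_identical(cluster_patterns(mat, k = 4)$membership, cl$membership)
  expect_error(cluster_patterns(mat * NA, k = 2), "non-finite")
})
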