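toy_qc_matrix <- function() {
  # 4 cells x 10 genes (1 mitochondrial); engineered mito fractions and
  # feature counts: drop/drop/drop/keep
  genes <- c("MT-1", paste0("G", 1:9))
  counts <- matrix(0L, 4, 10, dimnames = list(paste0("c", 1:4), genes))
  counts["c1", "MT-1"] <- 40L; counts["c1", paste0("G", 1:6)] <- 10L  # 40% mito
  counts["c2", "MT-1"] <- 10L; counts["c2", "G1"] <- 90L             # 2 features
  counts["c3", "MT-1"] <- 10L; counts["c3", paste0("G", 1:9)] <- 10L # 10 features
  counts["c4", "MT-1"] <- 10L; counts["c4", paste0("G", 1:5)] <- 18L # 10% mito
  counts
}

test_that("QC filter applies the three rules with per-cell attribution", {
  counts <- toy_qc_matrix()
  q <- qc_params(mito_max = 0.30, feat_min = 3L, feat_max = 8L)
  res <- qc_filter(counts, mito = "MT-1", params = q)
  expect_equal(rownames(res$counts), "c4")
  rep <- res$report
  expect_equal(rep$rule[rep$cell == "c1"], "mito")
  expect_equal(rep$rule[rep$cell == "c2"], "low_features")
  expect_equal(rep$rule[rep$cell == "c3"], "high_features")
  expect_equal(rep$rule[rep$cell == "c4"], "pass")
})

test_that("boundary cells are kept (strict inequalities)", {
  genes <- c("MT-1", paste0("G", 1:299))
  counts <- matrix(0L, 1, 300, dimnames = list("edge", genes))
  counts["edge", "MT-1"] <- 300L                     # 300 / 1000 = 30% mito
  counts["edge", paste0("G", 1:199)] <- 3L           # + MT-1 = 200 features
  counts["edge", "G1"] <- 106L                       # non-mito total 700
  res <- qc_filter(counts, mito = "MT-1",
                   params = qc_params(0.30, 200L, 6000L))
  expect_equal(res$report$rule, "pass")
  expect_equal(res$report$mito_frac, 0.30)
  expect_equal(res$report$n_features, 200)
})

test_that("QC filter is idempotent and handles empty output", {
  sim <- simulate_cell_counts(n_cells = 100L, n_genes = 200L, seed = 4)
  q <- qc_params(mito_max = 0.2, feat_min = 20L, feat_max = 180L)
  r1 <- qc_filter(sim$counts, sim$mito, q)
  r2 <- qc_filter(r1$counts, sim$mito, q)
  expect_identical(r2$counts, r1$counts)
  expect_true(all(r2$report$rule == "pass"))

  strict <- qc_params(mito_max = 0.01, feat_min = 199L, feat_max = 200L)
  expect_warning(res <- qc_filter(toy_qc_matrix(), "MT-1", strict),
                 "every cell")
  expect_equal(nrow(res$counts), 0)
})

test_that("cluster signatures rank planted markers on top", {
  recov <- vapply(1:5, function(s) {
    sim <- simulate_cluster_counts(cells_per_cluster = 40L, n_genes = 200L,
                                   n_markers = 30L, fold = 4, seed = s)
    sig <- cluster_signature(sim$counts, sim$labels, "C1", top_n = 50L)
    mean(sim$markers %in% sig$gene)
  }, numeric(1))
  expect_gte(median(recov), 0.9)
})

test_that("cluster signature orders by p then fold change and validates size", {
  sim <- simulate_cluster_counts(seed = 2)
  sig <- cluster_signature(sim$counts, sim$labels, "C1", top_n = 20L)
  expect_equal(nrow(sig), 20)
  expect_true(all(diff(sig$p) >= 0))
  expect_true(all(sig$log2fc[sig$p < 0.001] > 0))
  tiny <- sim$labels; tiny[] <- "C2"; tiny[1:2] <- "C1"
  expect_error(cluster_signature(sim$counts, tiny, "C1"), "at least 3")
})

test_that("NNLS deconvolution recovers exact and pure mixtures", {
  set.seed(8)
  ref <- matrix(rlnorm(4 * 60, 2, 1), 4, 60,
                dimnames = list(paste0("ct", 1:4), sprintf("g%02d", 1:60)))
  f_true <- c(0.7, 0.3, 0, 0)
  bulk <- matrix(drop(f_true %*% ref), ncol = 1,
                 dimnames = list(colnames(ref), "mix"))
  expect_equal(unname(deconvolve(bulk, ref)["mix", ]), f_true,
               tolerance = 1e-9)
  pure <- matrix(ref["ct1", ], ncol = 1,
                 dimnames = list(colnames(ref), "pure"))
  expect_equal(unname(deconvolve(pure, ref)["pure", ]), c(1, 0, 0, 0),
               tolerance = 1e-9)
})

test_that("deconvolution fractions sum to 1 and are order-equivariant", {
  set.seed(9)
  ref <- matrix(rlnorm(3 * 50, 2, 1), 3, 50,
                dimnames = list(paste0("ct", 1:3), sprintf("g%02d", 1:50)))
  bulk <- matrix(rlnorm(50 * 5, 2, 1), 50, 5,
                 dimnames = list(colnames(ref), paste0("s", 1:5)))
  fr <- deconvolve(bulk, ref)
  expect_equal(unname(rowSums(fr)), rep(1, 5), tolerance = 1e-9)
  perm <- c(3, 1, 2)
  fr_p <- deconvolve(bulk, ref[perm, ])
  expect_equal(fr_p, fr[, perm], tolerance = 1e-9)
  ref_bad <- ref; ref_bad[2, ] <- 2 * ref_bad[1, ]
  expect_error(deconvolve(bulk, ref_bad), "rank-deficient")
})

test_that("noisy Dirichlet mixtures are recovered within tolerance", {
  set.seed(10)
  ref <- matrix(rlnorm(5 * 80, 2, 1), 5, 80,
                dimnames = list(paste0("ct", 1:5), sprintf("g%02d", 1:80)))
  n <- 100
  f_true <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(5, 1); g / sum(g)
  }, numeric(5)))
  signal <- f_true %*% ref
  noisy <- t(signal + matrix(rnorm(length(signal), 0, 0.05 * mean(signal)),
                             nrow = n))
  noisy <- pmax(noisy, 0)
  dimnames(noisy) <- list(colnames(ref), paste0("s", 1:n))
  fr <- deconvolve(noisy, ref)
  expect_lt(mean(abs(fr - f_true)), 0.05)
})

test_that("treatment staging follows the stated precedence", {
  hist <- data.frame(
    patient_id = c("A", "B", "C", "D"),
    tki_generation = c(0L, 1L, 2L, 1L),
    t790m = c(FALSE, FALSE, TRUE, TRUE),
    osimertinib = c(FALSE, FALSE, FALSE, TRUE))
  st <- stage_patients(hist)
  expect_equal(unname(st), c("BASELINE", "POST1", "POST2", "POST3"))
  bad <- data.frame(patient_id = "X", tki_generation = 0L, t790m = FALSE,
                    osimertinib = TRUE)
  expect_error(stage_patients(bad), "contradictory")
})

test_that("ROC AUC matches pair enumeration, ties and the complement law", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 0, 1, 0)), 0.25)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(12)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    scores <- sample(seq_len(100), n)          # tie-free
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    a <- roc_auc(scores, labels)
    expect_equal(a, roc_auc_pairs(scores, labels), tolerance = 1e-12)
    expect_equal(a + roc_auc(-scores, labels), 1, tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with pROC on a labelled example", {
  skip_if_not_installed("pROC")
  set.seed(23)
  scores <- rnorm(60)
  labels <- as.integer(runif(60) < plogis(scores))
  if (length(unique(labels)) == 2) {
    ref <- suppressMessages(as.numeric(pROC::auc(labels, scores)))
    expect_equal(roc_auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("stage prediction from planted fractions separates groups", {
  # fractions of a 'late' cell type drive a planted stage label; ROC on the
  # deconvolved fraction should beat chance decisively
  set.seed(25)
  ref <- matrix(rlnorm(4 * 70, 2, 1), 4, 70,
                dimnames = list(c("early1", "early2", "late1", "late2"),
                                sprintf("g%02d", 1:70)))
  n <- 60
  is_post <- rep(0:1, each = n / 2)
  f <- t(vapply(seq_len(n), function(i) {
    g <- rgamma(4, 1) + c(0, 0, 0, 3) * is_post[i]
    g / sum(g)
  }, numeric(4)))
  bulk <- t(f %*% ref) + matrix(rnorm(70 * n, 0, 1), 70, n)
  bulk <- pmax(bulk, 0)
  dimnames(bulk) <- list(colnames(ref), paste0("s", 1:n))
  fr <- deconvolve(bulk, ref)
  expect_gt(roc_auc(fr[, "late2"], is_post), 0.8)
})
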