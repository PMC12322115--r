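test_that("ES equals the brute-force running-sum oracle on random instances", {
  set.seed(55)
  for (i in 1:1000) {
    n <- sample(5:50, 1)
    stat <- setNames(rnorm(n), paste0("g", sample(1000, n)))
    k <- sample(seq_len(n - 1), 1)
    set <- sample(names(stat), k)
    es_pkg <- longipharm:::gsea_es(stat, set)$es
    expect_equal(es_pkg, gsea_es_bruteforce(stat, set), tolerance = 1e-12)
  }
})

test_that("singleton top-ranked set gives ES = 1", {
  stat <- setNames(seq(10, 1), paste0("g", 1:10))
  g <- preranked_gsea(stat, "g1", n_perm = 99, seed = 1)
  expect_equal(g$es, 1.0)
  expect_equal(g$leading_edge, "g1")
})

test_that("degenerate sets are rejected", {
  stat <- setNames(seq(5, 1), paste0("g", 1:5))
  expect_error(preranked_gsea(stat, paste0("g", 1:5)), "whole ranked list")
  expect_error(preranked_gsea(stat, "absent_gene"), "empty intersection")
  expect_error(preranked_gsea(setNames(1, "g1"), "g1"), "at least 2")
})

test_that("negating and reversing the statistic negates ES", {
  set.seed(66)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    stat <- setNames(rnorm(n), paste0("g", seq_len(n)))
    set <- sample(names(stat), sample(2:(n - 2), 1))
    ra <- longipharm:::gsea_es(stat, set)
    # antisymmetry holds when the peak magnitude is unique; exact +M/-M
    # ties are resolved by the documented positive-peak convention
    if (abs(max(ra$running) + min(ra$running)) < 1e-9) next
    b <- longipharm:::gsea_es(-stat, set)$es
    expect_equal(b, -ra$es, tolerance = 1e-12)
  }
})

test_that("permutation p uses add-one smoothing with the stated floor", {
  stat <- setNames(seq(20, 1), paste0("g", 1:20))
  g <- preranked_gsea(stat, paste0("g", 1:3), n_perm = 50, seed = 2)
  expect_gte(g$p, 1 / 51)
  expect_lte(g$p, 1)
  expect_equal(sign(g$nes), sign(g$es))
})

test_that("ES agrees with fgsea's statistic on preranked input", {
  skip_if_not_installed("fgsea")
  set.seed(91)
  for (i in 1:20) {
    n <- 40
    stat <- setNames(sort(rnorm(n), decreasing = TRUE), sprintf("g%02d", 1:n))
    set <- sample(names(stat), 8)
    es_pkg <- longipharm:::gsea_es(stat, set)$es
    es_ref <- fgsea::calcGseaStat(stat, selectedStats = which(names(stat) %in% set),
                                  gseaParam = 1)
    expect_equal(es_pkg, es_ref, tolerance = 1e-9)
  }
})

test_that("all-equal statistics match the exhaustive permutation oracle", {
  # N = 8, |set| = 3: ES depends only on hit positions; enumerate all 56
  stat <- setNames(rep(1, 8), paste0("g", 1:8))
  combos <- combn(8, 3)
  oracle <- apply(combos, 2, function(idx) {
    gsea_es_bruteforce(setNames(rep(1, 8), paste0("g", 1:8)),
                       paste0("g", idx))
  })
  pkg <- apply(combos, 2, function(idx) {
    longipharm:::gsea_es(stat, paste0("g", idx))$es
  })
  expect_equal(pkg, oracle, tolerance = 1e-12)
})

test_that("sample set scores are deterministic and monotone in set ranks", {
  set.seed(14)
  expr <- matrix(rlnorm(100 * 4, 2, 1), 100, 4,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:4)))
  expr[, 2] <- expr[, 1]                      # identical samples
  sets <- list(SETA = sprintf("g%03d", 1:10), SETB = sprintf("g%03d", 50:70))
  sc <- sample_set_score(expr, sets)
  expect_equal(sc[, 1], sc[, 2], ignore_attr = TRUE)

  # push every SETA gene to the top of sample 3: the score must increase
  expr2 <- expr
  expr2[sets$SETA, 3] <- max(expr[, 3]) + seq_along(sets$SETA)
  sc2 <- sample_set_score(expr2, sets)
  expect_gt(sc2["SETA", 3], sc["SETA", 3])
})

test_that("set scores are invariant to strictly monotone transforms", {
  set.seed(15)
  expr <- matrix(rlnorm(80 * 3, 2, 1), 80, 3,
                 dimnames = list(sprintf("g%02d", 1:80), paste0("s", 1:3)))
  sets <- list(S1 = sprintf("g%02d", 5:20), S2 = sprintf("g%02d", 40:44))
  sc <- sample_set_score(expr, sets)
  expr_t <- expr
  expr_t[, 2] <- exp(expr[, 2] / 3)           # strictly monotone
  expr_t[, 3] <- rank(expr[, 3])
  expect_equal(sample_set_score(expr_t, sets), sc, tolerance = 1e-12)
})

test_that("a 15-pathway collection scores without missing values", {
  set.seed(16)
  expr <- matrix(rlnorm(100 * 6, 2, 1), 100, 6,
                 dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  sets <- lapply(1:15, function(i) sprintf("g%03d", sample(100, 8)))
  names(sets) <- paste0("PATHWAY_", 1:15)
  sc <- sample_set_score(expr, sets)
  expect_equal(dim(sc), c(15, 6))
  expect_false(any(is.na(sc)))
  # a set with no expressed member is flagged missing
  sc2 <- sample_set_score(expr, c(sets, list(EMPTY = "not_a_gene")))
  expect_true(all(is.na(sc2["EMPTY", ])))
})

test_that("score deltas recover planted timepoint shifts", {
  set.seed(18)
  n <- 10
  pairing <- data.frame(patient_id = sprintf("P%02d", 1:n),
                        sample_from = sprintf("P%02d_T1", 1:n),
                        sample_to = sprintf("P%02d_T2", 1:n))
  base <- rnorm(n)
  scores <- rbind(SETA = c(base, base + 0.3), SETB = c(base, base))
  colnames(scores) <- c(pairing$sample_from, pairing$sample_to)
  d <- score_delta(scores, pairing, test = "paired_t")
  expect_equal(d$delta[d$set == "SETA"], 0.3, tolerance = 1e-12)
  expect_equal(d$delta[d$set == "SETB"], 0)
  expect_equal(d$p[d$set == "SETB"], 1)       # all-zero differences

  noisy <- scores
  noisy[1, ] <- noisy[1, ] + rnorm(2 * n, 0, 0.1)
  dn <- score_delta(noisy, pairing, test = "paired_t")
  expect_lt(dn$p[dn$set == "SETA"], 0.01)

  bad <- pairing; bad$sample_to[1] <- "missing_sample"
  expect_error(score_delta(scores, bad), "unmatched pairing")
})

test_that("planted score shifts reach significance reliably", {
  n <- 10
  pairing <- data.frame(patient_id = sprintf("P%02d", 1:n),
                        sample_from = sprintf("P%02d_T1", 1:n),
                        sample_to = sprintf("P%02d_T2", 1:n))
  hits <- 0
  for (r in 1:200) {
    set.seed(1000 + r)
    base <- rnorm(n)
    scores <- rbind(SETA = c(base + rnorm(n, 0, 0.1),
                             base + 0.3 + rnorm(n, 0, 0.1)))
    colnames(scores) <- c(pairing$sample_from, pairing$sample_to)
    d <- score_delta(scores, pairing, test = "paired_t")
    hits <- hits + (d$p < 0.01)
  }
  expect_gte(hits / 200, 0.95)
})
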