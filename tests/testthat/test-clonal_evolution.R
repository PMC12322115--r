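# Helper: build a variant table from a compact spec of present variants.
# rows: list of c(patient, timepoint, gene, protein_change, ref, alt)
vt <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(patient_id = r[[1]], sample_id = paste0(r[[1]], "_T", r[[2]]),
               timepoint = as.integer(r[[2]]), gene = r[[3]],
               protein_change = r[[4]], ref_count = as.integer(r[[5]]),
               alt_count = as.integer(r[[6]]), stringsAsFactors = FALSE)
  }))
  variant_table(df)
}

test_that("partition splits truncal and private variants by presence", {
  tbl <- vt(list("P1", 1, "EGFR", "L858R", 100, 50),
            list("P1", 2, "EGFR", "L858R", 100, 60),
            list("P1", 1, "KRAS", "G12C", 100, 40),
            list("P1", 2, "TP53", "R273H", 100, 2))  # alt 2 < min_alt 3
  part <- partition_variants(tbl)
  expect_setequal(part$P1$truncal, "EGFR:L858R")
  expect_equal(part$P1$private[["1"]], "KRAS:G12C")
  expect_null(part$P1$private[["2"]])

  expect_warning(partition_variants(vt(list("P9", 1, "EGFR", "L858R", 100, 50))),
                 "single timepoint")
})

test_that("evolution classification reproduces the canonical patterns", {
  # persistence: same single variant at both timepoints -> "1>1"
  t1 <- vt(list("P1", 1, "EGFR", "L858R", 100, 50),
           list("P1", 2, "EGFR", "L858R", 100, 55))
  c1 <- classify_evolution(t1, "EGFR")
  expect_equal(c1$pattern, "1>1")
  expect_equal(c1$label, "persistence")

  # expansion: acquired secondary point mutation -> "1>2"
  t2 <- vt(list("P2", 1, "EGFR", "L858R", 100, 50),
           list("P2", 2, "EGFR", "L858R", 100, 55),
           list("P2", 2, "EGFR", "I744M", 100, 30))
  c2 <- classify_evolution(t2, "EGFR")
  expect_equal(c2$pattern, "1>2")
  expect_equal(c2$label, "expansion")

  # extinction: variant disappears -> "1>0"
  t3 <- vt(list("P3", 1, "TP53", "R273H", 100, 40),
           list("P3", 2, "KRAS", "G12C", 100, 40))
  c3 <- classify_evolution(t3, "TP53")
  expect_equal(c3$pattern, "1>0")
  expect_equal(c3$label, "extinction")

  # de novo acquisition counts as expansion -> "0>1"
  c4 <- classify_evolution(t3, "KRAS")
  expect_equal(c4$pattern, "0>1")
  expect_equal(c4$label, "expansion")

  # same count, different identity -> complex
  t5 <- vt(list("P5", 1, "EGFR", "L858R", 100, 40),
           list("P5", 2, "EGFR", "T790M", 100, 40))
  expect_equal(classify_evolution(t5, "EGFR")$label, "complex")

  # gene never mutated -> absent
  expect_equal(classify_evolution(t5, "BRAF")$label, "absent")
})

test_that("presence rule gates classification at the read level", {
  tbl <- vt(list("P1", 1, "EGFR", "L858R", 100, 50),
            list("P1", 2, "EGFR", "L858R", 198, 2))  # below min_alt
  expect_equal(classify_evolution(tbl, "EGFR")$label, "extinction")
  # lenient rule flips it back to persistence
  lenient <- presence_rule(min_alt = 1L, min_vaf = 0)
  expect_equal(classify_evolution(tbl, "EGFR", lenient)$label, "persistence")
})

test_that("classification on planted cohorts is exact", {
  b <- generate_cohort(sim_params(n_patients = 15L), seed = 8)
  calls <- classify_evolution(b$variants, b$params$focal_gene,
                              b$params$presence)
  expect_equal(nrow(calls), 15)
  expect_identical(calls$label,
                   unname(b$truth$evolution_class[calls$patient_id]))
})

test_that("MATH score matches its closed form and invariances", {
  expect_equal(math_score(c(0.5, 0.5, 0.5))$value, 0)
  # hand computation: MAD = 0.2 * 1.4826, median = 0.4
  expect_equal(math_score(c(0.2, 0.4, 0.6))$value,
               100 * 0.2 * 1.4826 / 0.4, tolerance = 1e-12)
  expect_equal(math_score(c(0.2, 0.4, 0.6))$value, 74.13, tolerance = 1e-9)

  set.seed(41)
  for (i in 1:200) {
    v <- runif(sample(3:20, 1), 0.02, 0.9)
    k <- runif(1, 0.1, 1.1)
    s1 <- math_score(v)$value
    s2 <- math_score(pmin(v * k, 1))$value
    if (all(v * k <= 1)) expect_equal(s2, s1, tolerance = 1e-9)
  }

  expect_true(is.na(math_score(0.5)$value))        # <2 variants flagged
  expect_error(math_score(c(0, 0.5)), "\\(0, 1\\]")
})

test_that("fusion dynamics satisfy the set-algebra conservation laws", {
  f <- classify_fusions(list(`1` = c("A", "B"), `2` = c("B", "C")))
  expect_equal(c(f$maintained, f$vanished, f$acquired), c(1, 1, 1))
  expect_equal(classify_fusions(list(`1` = "A", `2` = "A"))$maintained, 1)
  f0 <- classify_fusions(list(`1` = character(0), `2` = "A"))
  expect_equal(c(f0$maintained, f0$vanished, f0$acquired), c(0, 0, 1))
  expect_error(classify_fusions(list(`1` = "A"), 1, 2), "missing timepoint")

  set.seed(7)
  pool <- paste0("F", 1:12)
  for (i in 1:1000) {
    s1 <- sample(pool, sample(0:8, 1))
    s2 <- sample(pool, sample(0:8, 1))
    f <- classify_fusions(list(`1` = s1, `2` = s2))
    expect_identical(f$maintained + f$vanished, length(s1))
    expect_identical(f$maintained + f$acquired, length(s2))
  }
})

test_that("metastasis association matches the closed-form chi-square", {
  r <- metastasis_association(10, 20, 20, 10)
  expect_equal(r$odds_ratio, 0.25)
  expect_equal(r$chi2, chi2_closed_form(10, 20, 20, 10), tolerance = 1e-9)
  expect_equal(r$chi2, 20 / 3, tolerance = 1e-9)

  r2 <- metastasis_association(5, 5, 5, 5)
  expect_equal(r2$odds_ratio, 1)
  expect_equal(r2$chi2, 0)

  expect_equal(metastasis_association(5, 0, 5, 5)$odds_ratio, Inf)
  expect_true(is.na(metastasis_association(0, 0, 5, 5)$chi2))

  set.seed(13)
  for (i in 1:200) {
    cells <- rpois(4, 20) + 1
    r <- metastasis_association(cells[1], cells[2], cells[3], cells[4])
    expect_equal(r$chi2, do.call(chi2_closed_form, as.list(cells)),
                 tolerance = 1e-9)
  }
})

test_that("per-codon site counts match exhaustive substitution enumeration", {
  # TTT (Phe): of the 9 changes only TTC is silent -> 8/3 N, 1/3 S
  expect_equal(codon_sites("TTT"),
               c(n_sites = 8 / 3, s_sites = 1 / 3), tolerance = 1e-12)
  # exhaustive oracle over every sense codon
  code <- longipharm:::GENETIC_CODE_STD
  for (codon in names(code)[code != "*"]) {
    n <- 0; s <- 0
    for (pos in 1:3) for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon; substr(mut, pos, pos) <- b
      if (code[[mut]] == code[[codon]]) s <- s + 1 / 3 else n <- n + 1 / 3
    }
    expect_equal(codon_sites(codon), c(n_sites = n, s_sites = s),
                 tolerance = 1e-12)
  }
})

test_that("dN/dS estimator handles edge cases and contracts", {
  cds <- c(gene1 = "GCTGCTGCT")   # Ala x3; pos-3 changes are silent
  syn <- data.frame(cds_id = "gene1", pos = c(3, 6, 9),
                    ref = "T", alt = c("A", "C", "G"))
  r <- dnds_ratio(syn, cds)
  expect_equal(r$omega, 0)
  expect_equal(r$n_sites + r$s_sites, 9, tolerance = 1e-9)

  non <- data.frame(cds_id = "gene1", pos = 1, ref = "G", alt = "A")
  r2 <- dnds_ratio(non, cds)
  expect_false(r2$omega_defined)

  bad <- data.frame(cds_id = "gene1", pos = 1, ref = "A", alt = "C")
  expect_error(dnds_ratio(bad, cds), "mismatch")
  expect_error(longipharm:::split_codons("GCTTAA"), "stop codon")
  expect_error(longipharm:::split_codons("GCTA"), "multiple of 3")
})

test_that("dN/dS deltas compare selection between mutation sets", {
  cds <- c(g = "GCTGCTGCTGCTGCTGCT")      # Ala x6
  syn <- data.frame(cds_id = "g", pos = c(3, 6, 9), ref = "T",
                    alt = c("A", "C", "G"))
  mix <- rbind(syn, data.frame(cds_id = "g", pos = c(1, 4), ref = "G",
                               alt = c("A", "A")))
  d <- dnds_delta(syn, mix, cds)
  expect_equal(d$from$omega, 0)
  expect_gt(d$to$omega, 0)
  expect_equal(d$delta, d$to$omega - d$from$omega)
})

test_that("uniform mutations over the opportunity space are neutral", {
  cds <- neutral_test_cds()
  set.seed(17)
  muts <- draw_uniform_mutations("g", cds, 10000)
  r <- dnds_ratio(muts, c(g = cds))
  expect_gt(r$omega, 0.9)
  expect_lt(r$omega, 1.1)
  # planted 2:1 nonsynonymous excess: duplicate nonsynonymous draws
  cls <- vapply(seq_len(nrow(muts)), function(i) {
    longipharm:::classify_mutation(cds, muts$pos[i], muts$ref[i], muts$alt[i])
  }, character(1))
  muts2 <- rbind(muts, muts[cls == "N", ])
  r2 <- dnds_ratio(muts2, c(g = cds))
  expect_gt(r2$omega, 2 * 0.9)
  expect_lt(r2$omega, 2 * 1.1)
})
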