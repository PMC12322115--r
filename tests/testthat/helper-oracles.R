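# Independent brute-force oracles, written against the definitions only —
# deliberately naive O(N) loops, kept free of any package internals.

# Weighted KS running-sum enrichment score: literal loop over the ranked
# list, genes ordered by decreasing statistic (ties by name).
gsea_es_bruteforce <- function(stat, set, p = 1) {
  ord <- order(-stat, names(stat))
  genes <- names(stat)[ord]
  s <- unname(stat[ord])
  nr <- 0
  for (g in seq_along(genes)) {
    if (genes[g] %in% set) nr <- nr + abs(s[g])^p
  }
  n_miss <- sum(!(genes %in% set))
  running <- 0
  max_p <- 0; min_p <- 0
  for (g in seq_along(genes)) {
    if (genes[g] %in% set) {
      running <- running + (if (nr > 0) abs(s[g])^p / nr
                            else 1 / sum(genes %in% set))
    } else {
      running <- running - 1 / n_miss
    }
    if (running > max_p) max_p <- running
    if (running < min_p) min_p <- running
  }
  # same stated tie rule: positive peak wins near-exact magnitude ties
  if (max_p + min_p >= -1e-12) max_p else min_p
}

# ROC AUC by explicit enumeration of all positive-negative pairs.
roc_auc_pairs <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (p > n) + 0.5 * (p == n)
  }
  tot / (length(pos) * length(neg))
}

# Closed-form Pearson chi-square for a 2x2 table.
chi2_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
}

# A fixed 300-codon CDS with no stop codons, used by the dN/dS tests.
# 20 distinct sense codons repeated 15 times keeps composition mixed.
neutral_test_cds <- function() {
  codons <- c("GCT", "TGT", "GAT", "GAA", "TTT", "GGT", "CAT", "ATT",
              "AAA", "TTA", "ATG", "AAT", "CCT", "CAA", "CGT", "TCT",
              "ACT", "GTT", "TGG", "TAT")
  paste(rep(codons, 15), collapse = "")
}

# Balanced uniform draw of n single-nucleotide mutations over the full
# opportunity space of a CDS: whole permuted enumerations plus a
# without-replacement remainder (uniform marginal, reduced variance).
draw_uniform_mutations <- function(cds_id, seq, n) {
  space <- all_single_nt_changes(cds_id, seq)
  m <- nrow(space)
  full <- n %/% m
  idx <- c(rep(seq_len(m), full), sample.int(m, n - full * m))
  space[sample(idx), , drop = FALSE]
}
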