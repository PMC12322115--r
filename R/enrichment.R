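# Preranked GSEA (weighted Kolmogorov-Smirnov running sum), single-sample
# gene-set scoring (ssGSEA-style rank statistic) and timepoint score deltas.

# Signed running-sum enrichment statistic. `stat` must be sorted is NOT
# assumed; genes are ordered by decreasing statistic (ties broken by gene
# name for determinism). Hits increment |stat|^p normalized over set
# members, misses decrement 1/(N - |set|).
gsea_es <- function(stat, set, p = 1) {
  genes <- names(stat)
  ord <- order(-stat, genes)
  genes <- genes[ord]; s <- stat[ord]
  hit <- genes %in% set
  n <- length(genes); k <- sum(hit)
  if (k == 0) stop("gene set has empty intersection with the ranked list")
  if (k == n) stop("gene set covers the whole ranked list (no misses)")
  w <- abs(s)^p
  nr <- sum(w[hit])
  inc <- if (nr > 0) ifelse(hit, w / nr, 0) else ifelse(hit, 1 / k, 0)
  dec <- ifelse(hit, 0, 1 / (n - k))
  running <- cumsum(inc - dec)
  max_p <- max(running); min_p <- min(running)
  # Signed maximum deviation. A running sum can attain +M and -M exactly
  # (miss-runs at both ends); the tie is broken toward the positive peak,
  # with a small tolerance so floating-point noise cannot flip the sign.
  es <- if (max_p + min_p >= -1e-12) max_p else min_p
  peak <- if (es >= 0) which.max(running) else which.min(running)
  list(es = es, running = running, genes = genes, hit = hit, peak = peak)
}

#' Preranked gene-set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum statistic: genes are ordered by
#' decreasing statistic; set members ("hits") increment the running sum by
#' `|stat|^weight` normalized over set members, non-members decrement by
#' `1 / (N - |set|)`. The enrichment score (ES) is the signed maximum
#' deviation; when the positive and negative peaks tie in magnitude
#' (possible exactly, from miss-runs at both ends of the list) the
#' positive peak is reported. The null is gene-label permutation; the
#' p-value uses add-one
#' smoothing (minimum attainable p is `1 / (n_perm + 1)`), and
#' `NES = ES / mean(|permuted ES| of the same sign)`.
#'
#' @param stat named numeric vector (gene-level ranking statistic, e.g.
#'   model importance or a DEG statistic).
#' @param set character vector of gene symbols.
#' @param n_perm number of gene-label permutations.
#' @param weight hit-weight exponent p (1 = classic weighted GSEA; 0 =
#'   unweighted KS).
#' @param seed integer seed for the permutation null.
#' @return list classed `lp_gsea` with `es`, `nes`, `p`, `leading_edge`
#'   (set genes at or before the running-sum peak), `n_perm`.
#' @export
preranked_gsea <- function(stat, set, n_perm = 1000L, weight = 1, seed = 1L) {
  if (length(stat) < 2) stop("ranked list needs at least 2 genes")
  if (is.null(names(stat))) stop("ranking statistic must be a named vector")
  res <- gsea_es(stat, set, p = weight)
  idx <- seq_along(res$genes)
  leading <- if (res$es >= 0) {
    res$genes[res$hit & idx <= res$peak]
  } else {
    res$genes[res$hit & idx >= res$peak]
  }
  k <- sum(res$hit)
  set.seed(as.integer(seed))
  perm_es <- vapply(seq_len(n_perm), function(i) {
    gsea_es(stat, sample(names(stat), k), p = weight)$es
  }, numeric(1))
  same_sign <- if (res$es >= 0) perm_es[perm_es >= 0] else perm_es[perm_es < 0]
  p_perm <- (1 + sum(abs(same_sign) >= abs(res$es))) / (n_perm + 1)
  nes <- if (length(same_sign) > 0 && mean(abs(same_sign)) > 0) {
    res$es / mean(abs(same_sign))
  } else NA_real_
  structure(list(es = res$es, nes = nes, p = p_perm,
                 leading_edge = leading, n_perm = n_perm,
                 set_size = k), class = "lp_gsea")
}

#' @export
print.lp_gsea <- function(x, ...) {
  cat(sprintf("GSEA: ES = %.4f, NES = %s, p = %.4g (%d permutations, |set| = %d)\n",
              x$es, if (is.na(x$nes)) "NA" else sprintf("%.3f", x$nes),
              x$p, x$n_perm, x$set_size))
  invisible(x)
}

#' Single-sample gene-set scores (ssGSEA-style rank statistic)
#'
#' Per sample, genes are ranked by expression (descending; ties broken by
#' gene name). The set score is the sum over all rank positions of the
#' difference between the weighted hit CDF (normalized ranks raised to
#' `alpha` over set members) and the miss CDF — a purely rank-based
#' statistic, invariant to any strictly monotone transform of one sample's
#' expression vector.
#'
#' @param expr genes x samples numeric matrix.
#' @param sets named list of gene sets (e.g. from [read_gmt]).
#' @param alpha rank-weight exponent (default 0.25).
#' @param normalize if TRUE, min-max normalize each set's scores across
#'   samples to \[0, 1\].
#' @return sets x samples numeric matrix; a set with no expressed member
#'   in the matrix yields an `NA` row.
#' @export
sample_set_score <- function(expr, sets, alpha = 0.25, normalize = FALSE) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  genes <- rownames(expr)
  n <- length(genes)
  if (n < 2) stop("need at least 2 genes")
  out <- matrix(NA_real_, nrow = length(sets), ncol = ncol(expr),
                dimnames = list(names(sets), colnames(expr)))
  set_members <- lapply(sets, function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)
    # normalized rank weight: top gene gets weight n, bottom gets 1
    rank_w <- (n:1)^alpha
    for (si in seq_along(sets)) {
      hit <- set_members[[si]][ord]
      k <- sum(hit)
      if (k == 0 || k == n) next
      w <- rank_w * hit
      p_hit <- cumsum(w) / sum(w)
      p_miss <- cumsum(!hit) / (n - k)
      out[si, j] <- sum(p_hit - p_miss)
    }
  }
  if (normalize) {
    out <- t(apply(out, 1, function(r) {
      rng <- range(r, na.rm = TRUE)
      if (diff(rng) == 0) return(r * 0)
      (r - rng[1]) / diff(rng)
    }))
  }
  out
}

#' Timepoint delta of gene-set scores within a patient group
#'
#' For each gene set (row of `scores`), the difference between mean score
#' at the later and earlier timepoint over paired patients, with a
#' two-sided test.
#'
#' @param scores sets x samples matrix from [sample_set_score()].
#' @param pairing data.frame with columns `patient_id`, `sample_from`,
#'   `sample_to` (one row per paired patient).
#' @param test `"paired_t"` (default) or `"welch_t"`.
#' @return data.frame `set`, `n`, `delta`, `p`.
#' @export
score_delta <- function(scores, pairing, test = c("paired_t", "welch_t")) {
  test <- match.arg(test)
  stopifnot(all(c("patient_id", "sample_from", "sample_to") %in% names(pairing)))
  missing_s <- setdiff(c(pairing$sample_from, pairing$sample_to),
                       colnames(scores))
  if (length(missing_s)) stop("unmatched pairing: sample ", missing_s[1],
                              " not in score matrix")
  if (nrow(pairing) < 2) stop("need at least 2 pairs")
  rows <- lapply(rownames(scores), function(set_name) {
    x_from <- scores[set_name, pairing$sample_from]
    x_to <- scores[set_name, pairing$sample_to]
    ok <- is.finite(x_from) & is.finite(x_to)
    x_from <- x_from[ok]; x_to <- x_to[ok]
    delta <- mean(x_to) - mean(x_from)
    p <- if (length(x_from) < 2) {
      NA_real_
    } else if (test == "paired_t") {
      d <- x_to - x_from
      if (all(d == 0)) {
        1
      } else {
        # constant non-zero differences have no testable variance
        tryCatch(stats::t.test(x_to, x_from, paired = TRUE)$p.value,
                 error = function(e) NA_real_)
      }
    } else {
      if (stats::sd(x_to) == 0 && stats::sd(x_from) == 0) {
        if (delta == 0) 1 else NA_real_
      } else {
        tryCatch(stats::t.test(x_to, x_from)$p.value,
                 error = function(e) NA_real_)
      }
    }
    data.frame(set = set_name, n = length(x_from), delta = delta, p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
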