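# Single-cell QC, cluster marker signatures, NNLS bulk deconvolution,
# treatment staging and ROC AUC.

#' Single-cell QC parameters
#'
#' Cells are dropped when mitochondrial fraction is strictly above
#' `mito_max`, or the detected-feature count is strictly below `feat_min`
#' or strictly above `feat_max` (boundary cells are kept).
#'
#' @param mito_max maximum mitochondrial UMI fraction (default 0.30).
#' @param feat_min,feat_max detected-feature count bounds (defaults 200
#'   and 6000).
#' @return list classed `lp_qc_params`.
#' @export
qc_params <- function(mito_max = 0.30, feat_min = 200L, feat_max = 6000L) {
  if (mito_max <= 0 || mito_max >= 1) stop("mito_max must be in (0, 1)")
  if (feat_min <= 0 || feat_min >= feat_max) {
    stop("need 0 < feat_min < feat_max")
  }
  structure(list(mito_max = mito_max, feat_min = as.integer(feat_min),
                 feat_max = as.integer(feat_max)), class = "lp_qc_params")
}

#' QC-filter a single-cell count matrix
#'
#' Mitochondrial fraction is computed on raw UMI counts; features are
#' "detected" when their count is > 0. The per-cell report names the
#' first rule each dropped cell triggered.
#'
#' @param counts cells x genes non-negative integer matrix.
#' @param mito logical per gene (TRUE = mitochondrial), or a character
#'   vector of mitochondrial gene names.
#' @param params [qc_params()].
#' @return list `counts` (surviving cells), `report` (data.frame `cell`,
#'   `mito_frac`, `n_features`, `kept`, `rule` — `"pass"`, `"mito"`,
#'   `"low_features"` or `"high_features"`). If every cell is dropped the
#'   empty matrix is returned with a warning.
#' @export
qc_filter <- function(counts, mito, params = qc_params()) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (is.character(mito)) mito <- colnames(counts) %in% mito
  stopifnot(length(mito) == ncol(counts))
  if (all(mito)) stop("at least one non-mitochondrial gene required")
  total <- rowSums(counts)
  mito_frac <- ifelse(total > 0, rowSums(counts[, mito, drop = FALSE]) / total, 0)
  n_feat <- rowSums(counts > 0)
  rule <- rep("pass", nrow(counts))
  rule[n_feat > params$feat_max] <- "high_features"
  rule[n_feat < params$feat_min] <- "low_features"
  rule[mito_frac > params$mito_max] <- "mito"
  kept <- rule == "pass"
  report <- data.frame(cell = rownames(counts), mito_frac = mito_frac,
                       n_features = n_feat, kept = kept, rule = rule,
                       stringsAsFactors = FALSE)
  if (!any(kept)) warning("QC filter dropped every cell")
  list(counts = counts[kept, , drop = FALSE], report = report,
       mito = mito, params = params)
}

# counts-per-10k, log1p — library-size normalization before rank tests.
normalize_counts <- function(counts) {
  lib <- rowSums(counts)
  lib[lib == 0] <- 1
  log1p(counts / lib * 1e4)
}

#' Cluster marker signature by rank-sum DEG test
#'
#' Per gene, a two-sided Wilcoxon rank-sum test of the cluster's cells
#' against the rest on library-size-normalized (counts per 10k, log1p)
#' values, and log2 fold change of `(mean + 1) / (mean + 1)` on the
#' normalized scale. The top `top_n` genes are ordered by p ascending,
#' then log2FC descending.
#'
#' @param counts cells x genes count matrix.
#' @param labels cluster label per cell (named by cell or in row order).
#' @param cluster the cluster to profile.
#' @param top_n signature size.
#' @return data.frame classed `lp_cluster_signature`: `gene`, `log2fc`,
#'   `p`, restricted to the top `top_n`.
#' @export
cluster_signature <- function(counts, labels, cluster, top_n = 50L) {
  if (!is.null(names(labels))) labels <- labels[rownames(counts)]
  in_cl <- labels == cluster
  if (sum(in_cl) < 3 || sum(!in_cl) < 3) {
    stop("cluster and rest must each have at least 3 cells")
  }
  norm <- normalize_counts(counts)
  res <- lapply(colnames(counts), function(g) {
    a <- norm[in_cl, g]; b <- norm[!in_cl, g]
    p <- if (all(a == a[1]) && all(b == a[1])) 1 else {
      suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    }
    data.frame(gene = g, log2fc = log2((mean(a) + 1) / (mean(b) + 1)),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$p, -out$log2fc), ]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  class(out) <- c("lp_cluster_signature", "data.frame")
  out
}

#' Deconvolve bulk expression into cell-type fractions (NNLS)
#'
#' Per sample, solves `min || bulk - f' ref ||_2` subject to `f >= 0`
#' (non-negative least squares), then renormalizes `f` to sum to 1.
#'
#' @param bulk genes x samples expression matrix.
#' @param ref celltypes x genes reference profile matrix; reference genes
#'   must be a subset of the bulk genes and the reference rows linearly
#'   independent.
#' @return samples x celltypes fraction matrix (rows sum to 1).
#' @export
deconvolve <- function(bulk, ref) {
  stopifnot(is.matrix(bulk), is.matrix(ref), nrow(ref) >= 2)
  missing_g <- setdiff(colnames(ref), rownames(bulk))
  if (length(missing_g)) stop("reference gene absent from bulk: ", missing_g[1])
  A <- t(ref[, colnames(ref), drop = FALSE])        # genes x celltypes
  if (qr(A)$rank < ncol(A)) stop("rank-deficient reference profile matrix")
  B <- bulk[colnames(ref), , drop = FALSE]
  out <- matrix(NA_real_, ncol(bulk), nrow(ref),
                dimnames = list(colnames(bulk), rownames(ref)))
  for (j in seq_len(ncol(B))) {
    f <- pracma::lsqnonneg(A, B[, j])$x
    if (sum(f) == 0) stop("all-zero NNLS solution for sample ", colnames(B)[j])
    out[j, ] <- f / sum(f)
  }
  out
}

#' Stage patients by sequential EGFR-TKI treatment history
#'
#' BASELINE = treatment-naive; POST1 = 1st/2nd-generation TKI without
#' T790M; POST2 = T790M acquired after TKI; POST3 = osimertinib-treated.
#' Precedence POST3 > POST2 > POST1 > BASELINE.
#'
#' @param history data.frame with columns `patient_id`, `tki_generation`
#'   (0 = naive, 1 or 2), `t790m` (logical), `osimertinib` (logical).
#' @return named character vector of stages per patient.
#' @export
stage_patients <- function(history) {
  stopifnot(all(c("patient_id", "tki_generation", "t790m", "osimertinib")
                %in% names(history)))
  vapply(seq_len(nrow(history)), function(i) {
    h <- history[i, ]
    if (h$osimertinib) {
      if (h$tki_generation == 0 && !h$t790m) {
        stop("contradictory record for ", h$patient_id,
             ": osimertinib-treated but otherwise treatment-naive")
      }
      "POST3"
    } else if (h$t790m) {
      if (h$tki_generation == 0) {
        stop("contradictory record for ", h$patient_id,
             ": T790M acquired without prior TKI")
      }
      "POST2"
    } else if (h$tki_generation >= 1) {
      "POST1"
    } else "BASELINE"
  }, character(1)) |> stats::setNames(history$patient_id)
}

#' ROC AUC (Mann-Whitney statistic)
#'
#' `P(score+ > score-) + 0.5 * P(tie)`, computed in closed form from
#' midranks.
#'
#' @param scores numeric vector.
#' @param labels 0/1 (or logical) class labels, same length.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
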