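# Paired longitudinal drug-response shifts per evolution group and
# candidate-drug selection.

#' Validate a drug-response table
#'
#' @param auc numeric samples x drugs matrix of dose-response AUC values in
#'   \[0, 1\] (higher = more resistant), with sample and drug dimnames.
#' @param sample_info data.frame mapping `sample_id` to `patient_id` and
#'   `timepoint`; each patient may contribute at most one sample per
#'   timepoint.
#' @return list `auc`, `sample_info`, classed `lp_drug_response`.
#' @export
drug_response_table <- function(auc, sample_info) {
  stopifnot(is.matrix(auc), is.numeric(auc))
  if (is.null(rownames(auc)) || is.null(colnames(auc))) {
    stop("AUC matrix needs sample rownames and drug colnames")
  }
  if (any(!is.finite(auc)) || any(auc < 0 | auc > 1)) {
    stop("AUC values must be finite and in [0, 1]")
  }
  stopifnot(all(c("sample_id", "patient_id", "timepoint") %in% names(sample_info)))
  if (!all(rownames(auc) %in% sample_info$sample_id)) {
    stop("sample in AUC matrix missing from sample_info")
  }
  si <- sample_info[match(rownames(auc), sample_info$sample_id), ]
  if (anyDuplicated(paste(si$patient_id, si$timepoint))) {
    stop("a patient contributes more than one sample at one timepoint")
  }
  structure(list(auc = auc, sample_info = si), class = "lp_drug_response")
}

# Complete (T_from, T_to) AUC pairs for one drug within a patient group.
auc_pairs <- function(resp, group, drug, t_from, t_to) {
  si <- resp$sample_info
  if (!drug %in% colnames(resp$auc)) stop("unknown drug: ", drug)
  pts <- intersect(group, unique(si$patient_id))
  from <- to <- numeric(0); used <- character(0)
  for (pt in pts) {
    s1 <- si$sample_id[si$patient_id == pt & si$timepoint == t_from]
    s2 <- si$sample_id[si$patient_id == pt & si$timepoint == t_to]
    if (length(s1) == 1 && length(s2) == 1) {
      a1 <- resp$auc[s1, drug]; a2 <- resp$auc[s2, drug]
      if (is.finite(a1) && is.finite(a2)) {
        from <- c(from, a1); to <- c(to, a2); used <- c(used, pt)
      }
    }
  }
  list(from = from, to = to, patients = used)
}

#' Paired drug-sensitivity shift between two timepoints
#'
#' For each patient in `group` with complete AUC at both timepoints,
#' computes the per-patient paired log2 ratio
#' `log2(AUC[t_to] / AUC[t_from])`; `log2fc` is the mean of these ratios
#' (pairing-respecting, scale-robust) and `p` is the two-sided paired test
#' on the log2 values. Negative `log2fc` = increased sensitivity at the
#' later timepoint.
#'
#' @param resp drug-response table from [drug_response_table()].
#' @param group character vector of patient ids (an evolution group).
#' @param drug drug name (column of the AUC matrix).
#' @param method `"paired_t"` (default) or `"wilcoxon_signed_rank"`.
#' @param t_from,t_to paired timepoints.
#' @param p_cut,lfc_cut cutoffs used only to set `direction`.
#' @return list classed `lp_drug_shift` with `drug`, `n` (pairs), `log2fc`,
#'   `p`, `method`, `direction` (`"sensitive"`, `"resistant"` or `"none"`)
#'   and `testable`. With fewer than 2 pairs, or a degenerate
#'   (zero-variance) paired t, the result is flagged `testable = FALSE`
#'   with `p = NA`.
#' @export
paired_shift <- function(resp, group, drug,
                         method = c("paired_t", "wilcoxon_signed_rank"),
                         t_from = 1L, t_to = 2L,
                         p_cut = 0.1, lfc_cut = 0.2) {
  method <- match.arg(method)
  pr <- auc_pairs(resp, group, drug, t_from, t_to)
  if (any(pr$from == 0) || any(pr$to == 0)) {
    stop("zero AUC value; log fold change undefined for drug ", drug)
  }
  n <- length(pr$from)
  if (n < 2) {
    return(structure(list(drug = drug, n = n, log2fc = NA_real_,
                          p = NA_real_, method = method,
                          direction = "none", testable = FALSE),
                     class = "lp_drug_shift"))
  }
  l_from <- log2(pr$from); l_to <- log2(pr$to)
  d <- l_to - l_from
  log2fc <- mean(d)
  p <- if (method == "paired_t") {
    if (stats::sd(d) == 0) NA_real_
    else tryCatch(stats::t.test(l_to, l_from, paired = TRUE)$p.value,
                  error = function(e) NA_real_)
  } else {
    if (all(d == 0)) NA_real_
    else suppressWarnings(
      stats::wilcox.test(l_to, l_from, paired = TRUE, exact = FALSE)$p.value)
  }
  testable <- !is.na(p)
  direction <- if (testable && p < p_cut && log2fc <= -lfc_cut) {
    "sensitive"
  } else if (testable && p < p_cut && log2fc >= lfc_cut) {
    "resistant"
  } else "none"
  structure(list(drug = drug, n = n, log2fc = log2fc, p = p,
                 method = method, direction = direction, testable = testable),
            class = "lp_drug_shift")
}

#' Paired shifts for every drug in the screen
#'
#' @inheritParams paired_shift
#' @param group_label label recorded on every row (e.g.
#'   `"EGFR_extinction"`).
#' @return data.frame (one row per drug): `drug`, `group`, `n`, `log2fc`,
#'   `p`, `direction`, `testable`.
#' @export
shift_all_drugs <- function(resp, group, group_label = "group",
                            method = c("paired_t", "wilcoxon_signed_rank"),
                            t_from = 1L, t_to = 2L,
                            p_cut = 0.1, lfc_cut = 0.2) {
  method <- match.arg(method)
  rows <- lapply(colnames(resp$auc), function(drug) {
    s <- paired_shift(resp, group, drug, method, t_from, t_to, p_cut, lfc_cut)
    data.frame(drug = drug, group = group_label, n = s$n, log2fc = s$log2fc,
               p = s$p, direction = s$direction, testable = s$testable,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Select candidate drugs by p-value and fold-change cutoffs
#'
#' A drug is a sensitive candidate when `p < p_cut` and
#' `log2fc <= -lfc_cut`, a resistant candidate when `p < p_cut` and
#' `log2fc >= lfc_cut` (the magnitude rule is two-sided; the sign gives the
#' direction). Within each list drugs are sorted by p then |log2fc|
#' descending.
#'
#' @param results data.frame from [shift_all_drugs()] (or rbind of them).
#' @param p_cut p-value cutoff (default 0.1).
#' @param lfc_cut absolute log2 fold-change cutoff (default 0.2).
#' @return list `sensitive`, `resistant` (character drug vectors).
#' @export
select_candidates <- function(results, p_cut = 0.1, lfc_cut = 0.2) {
  ok <- results$testable & !is.na(results$p)
  sen <- results[ok & results$p < p_cut & results$log2fc <= -lfc_cut, ]
  res <- results[ok & results$p < p_cut & results$log2fc >= lfc_cut, ]
  ord <- function(d) d$drug[order(d$p, -abs(d$log2fc))]
  list(sensitive = ord(sen), resistant = ord(res))
}

#' @export
print.lp_drug_shift <- function(x, ...) {
  cat(sprintf("%s: n = %d pairs, log2FC = %s, p = %s (%s) -> %s\n",
              x$drug, x$n,
              if (is.na(x$log2fc)) "NA" else sprintf("%.3f", x$log2fc),
              if (is.na(x$p)) "not testable" else format.pval(x$p, digits = 3),
              x$method, x$direction))
  invisible(x)
}
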