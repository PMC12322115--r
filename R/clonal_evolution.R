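# Truncal/private partition, evolution typing, MATH, dN/dS, fusion dynamics
# and mutation-metastasis association.

#' Read-level variant presence rule
#'
#' A variant is called present in a sample iff `alt_count >= min_alt` and
#' VAF `>= min_vaf`. This deterministic rule replaces probabilistic
#' phylogeny-based presence calls and is conservative at typical targeted
#' sequencing depth (~200x).
#'
#' @param min_alt minimum supporting alt reads (default 3).
#' @param min_vaf minimum variant allele fraction (default 0.02).
#' @return list classed `lp_presence_rule`.
#' @export
presence_rule <- function(min_alt = 3L, min_vaf = 0.02) {
  if (min_alt < 1) stop("min_alt must be >= 1")
  if (min_vaf < 0 || min_vaf >= 1) stop("min_vaf must be in [0, 1)")
  structure(list(min_alt = as.integer(min_alt), min_vaf = min_vaf),
            class = "lp_presence_rule")
}

variant_present <- function(tbl, rule) {
  tbl$alt_count >= rule$min_alt & tbl$vaf >= rule$min_vaf
}

# Distinct (gene, protein_change) variants of `gene` (or all genes if NULL)
# present at a given timepoint of one patient.
present_variants_at <- function(tbl, patient, timepoint, rule, gene = NULL) {
  sel <- tbl$patient_id == patient & tbl$timepoint == timepoint &
    variant_present(tbl, rule)
  if (!is.null(gene)) sel <- sel & tbl$gene == gene
  unique(paste(tbl$gene[sel], tbl$protein_change[sel], sep = ":"))
}

#' Partition each patient's variants into truncal and private sets
#'
#' A variant (gene:protein_change) is truncal if present (per `rule`) at
#' every timepoint of the patient, private if present in a proper non-empty
#' subset of timepoints. Patients with a single timepoint are skipped with a
#' warning.
#'
#' @param tbl variant table (see [variant_table]).
#' @param rule presence rule from [presence_rule()].
#' @return Named list (per patient) of `list(truncal = character,
#'   private = list(timepoint-key -> character))`; `private` is keyed by the
#'   comma-separated timepoints at which the variant is present.
#' @export
partition_variants <- function(tbl, rule = presence_rule()) {
  out <- list()
  for (pt in unique(tbl$patient_id)) {
    tps <- sort(unique(tbl$timepoint[tbl$patient_id == pt]))
    if (length(tps) < 2) {
      warning("patient ", pt, " has a single timepoint; skipped")
      next
    }
    per_tp <- lapply(tps, function(tp) present_variants_at(tbl, pt, tp, rule))
    names(per_tp) <- as.character(tps)
    all_vars <- unique(unlist(per_tp))
    truncal <- character(0)
    private <- list()
    for (v in all_vars) {
      at <- tps[vapply(per_tp, function(s) v %in% s, logical(1))]
      if (length(at) == length(tps)) {
        truncal <- c(truncal, v)
      } else if (length(at) > 0) {
        key <- paste(at, collapse = ",")
        private[[key]] <- c(private[[key]], v)
      }
    }
    out[[pt]] <- list(truncal = truncal, private = private)
  }
  out
}

#' Classify per-patient evolution type for a focal gene
#'
#' Let A be the set of distinct protein changes of `gene` present at
#' `t_from` and B the set present at `t_to`. The pattern is `"|A|>|B|"` and
#' the label is:
#' \itemize{
#'   \item `absent`: A and B both empty;
#'   \item `persistence`: A non-empty and A = B;
#'   \item `extinction`: A non-empty and B empty;
#'   \item `expansion`: B a proper superset of A, or A empty and B non-empty;
#'   \item `complex`: anything else (e.g. same count, different identity).
#' }
#'
#' @param tbl variant table.
#' @param gene focal gene symbol (e.g. `"EGFR"`, `"TP53"`).
#' @param rule presence rule.
#' @param t_from,t_to the two timepoints compared (consecutive integers for
#'   the usual T_n vs T_n+1 comparison).
#' @param patients patients to classify; default all patients having both
#'   timepoints. A patient missing either timepoint raises an error naming
#'   the patient.
#' @return data.frame with columns `patient_id`, `gene`, `n_from`, `n_to`,
#'   `pattern`, `label`, classed `lp_evolution_calls`.
#' @export
classify_evolution <- function(tbl, gene, rule = presence_rule(),
                               t_from = 1L, t_to = 2L, patients = NULL) {
  if (is.null(patients)) {
    has_both <- vapply(unique(tbl$patient_id), function(pt) {
      tps <- tbl$timepoint[tbl$patient_id == pt]
      t_from %in% tps && t_to %in% tps
    }, logical(1))
    patients <- unique(tbl$patient_id)[has_both]
  }
  rows <- lapply(patients, function(pt) {
    tps <- tbl$timepoint[tbl$patient_id == pt]
    if (!(t_from %in% tps) || !(t_to %in% tps)) {
      stop("patient ", pt, " is missing timepoint ",
           if (t_from %in% tps) t_to else t_from)
    }
    A <- present_variants_at(tbl, pt, t_from, rule, gene)
    B <- present_variants_at(tbl, pt, t_to, rule, gene)
    label <- if (length(A) == 0 && length(B) == 0) {
      "absent"
    } else if (length(A) > 0 && setequal(A, B)) {
      "persistence"
    } else if (length(A) > 0 && length(B) == 0) {
      "extinction"
    } else if ((all(A %in% B) && length(B) > length(A))) {
      "expansion"   # covers A empty, B non-empty
    } else {
      "complex"
    }
    data.frame(patient_id = pt, gene = gene,
               n_from = length(A), n_to = length(B),
               pattern = paste0(length(A), ">", length(B)),
               label = label, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(patient_id = character(0), gene = character(0),
                      n_from = integer(0), n_to = integer(0),
                      pattern = character(0), label = character(0))
  }
  class(out) <- c("lp_evolution_calls", "data.frame")
  out
}

#' MATH intratumor-heterogeneity score
#'
#' Mutant-allele tumor heterogeneity for one sample's VAFs:
#' `100 * 1.4826 * median(|VAF_i - median(VAF)|) / median(VAF)` — i.e.
#' 100 x MAD (with the Gaussian consistency constant) over the median.
#' Zero iff all VAFs are equal; invariant to rescaling all VAFs by a
#' positive constant.
#'
#' @param vafs numeric vector of variant allele fractions in (0, 1].
#' @return list with `value`, `mad`, `median_vaf` and `n`, classed
#'   `lp_math`; `value` is `NA` (flagged not-computable) when fewer than 2
#'   VAFs are supplied.
#' @export
math_score <- function(vafs) {
  vafs <- vafs[!is.na(vafs)]
  if (any(vafs <= 0 | vafs > 1)) stop("VAFs must lie in (0, 1]")
  if (length(vafs) < 2) {
    return(structure(list(value = NA_real_, mad = NA_real_,
                          median_vaf = if (length(vafs)) median(vafs) else NA_real_,
                          n = length(vafs)), class = "lp_math"))
  }
  med <- stats::median(vafs)
  if (med == 0) stop("median VAF is zero; MATH undefined")
  m <- stats::mad(vafs, constant = 1.4826)
  structure(list(value = 100 * m / med, mad = m, median_vaf = med,
                 n = length(vafs)), class = "lp_math")
}

#' Per-sample MATH scores for a variant table
#' @param tbl variant table.
#' @return data.frame with `sample_id`, `n`, `math`.
#' @export
math_scores <- function(tbl) {
  ids <- unique(tbl$sample_id)
  res <- lapply(ids, function(s) {
    sc <- math_score(tbl$vaf[tbl$sample_id == s])
    data.frame(sample_id = s, n = sc$n, math = sc$value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' @export
print.lp_math <- function(x, ...) {
  cat(sprintf("MATH score: %s (MAD %.4f / median VAF %.4f, n = %d)\n",
              if (is.na(x$value)) "not computable (<2 variants)"
              else sprintf("%.2f", x$value),
              x$mad, x$median_vaf, x$n))
  invisible(x)
}

#' Fusion dynamics between two timepoints
#'
#' Counts maintained (present at both), vanished (lost at the late
#' timepoint) and acquired (new at the late timepoint) fusions.
#'
#' @param fusions_by_timepoint named list: timepoint (as character or
#'   integer-keyed) -> character vector of fusion names.
#' @param t_from,t_to timepoints compared.
#' @return list `maintained`, `vanished`, `acquired` (integer counts) plus
#'   the underlying name sets.
#' @export
classify_fusions <- function(fusions_by_timepoint, t_from = 1L, t_to = 2L) {
  keys <- names(fusions_by_timepoint)
  kf <- as.character(t_from); kt <- as.character(t_to)
  if (!(kf %in% keys) || !(kt %in% keys)) {
    stop("missing timepoint ", if (kf %in% keys) kt else kf)
  }
  f1 <- unique(fusions_by_timepoint[[kf]])
  f2 <- unique(fusions_by_timepoint[[kt]])
  list(maintained = length(intersect(f1, f2)),
       vanished   = length(setdiff(f1, f2)),
       acquired   = length(setdiff(f2, f1)),
       maintained_set = intersect(f1, f2),
       vanished_set = setdiff(f1, f2),
       acquired_set = setdiff(f2, f1))
}

#' Mutation-metastasis association from a 2x2 contingency table
#'
#' Odds ratio `ad/bc` and Pearson chi-squared test (no continuity
#' correction, df = 1) for a table with cells a (mut+, met+), b (mut+,
#' met-), c (mut-, met+), d (mut-, met-).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return list `odds_ratio` (`Inf` when `b*c == 0` and `a*d > 0`), `chi2`,
#'   `p`; `chi2`/`p` are `NA` (not computable) when any margin is zero.
#' @export
metastasis_association <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) stop("cell counts must be >= 0")
  n <- sum(cells)
  if (n == 0) stop("empty contingency table")
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  m <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE)
  margins_ok <- all(rowSums(m) > 0) && all(colSums(m) > 0)
  if (margins_ok) {
    ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
    chi2 <- unname(ct$statistic); p <- ct$p.value
  } else {
    chi2 <- NA_real_; p <- NA_real_
  }
  list(odds_ratio = or, chi2 = chi2, p = p, n = n)
}
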