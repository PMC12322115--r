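# Drug-combination scoring: highest-single-agent (HSA) excess and
# Chou-Talalay combination index from median-effect fits.

#' Dose-response combination grid
#'
#' @param doses_a,doses_b dose vectors including 0 (the single-agent
#'   margins).
#' @param inhibition matrix of fractional inhibition in \[0, 1\], rows
#'   indexed by `doses_a`, columns by `doses_b`; `inhibition[1, 1]` is the
#'   untreated well.
#' @return list classed `lp_dose_grid`.
#' @export
dose_response_grid <- function(doses_a, doses_b, inhibition) {
  stopifnot(is.matrix(inhibition),
            nrow(inhibition) == length(doses_a),
            ncol(inhibition) == length(doses_b))
  if (!(0 %in% doses_a) || !(0 %in% doses_b)) {
    stop("dose lattice must include the 0 margins (single agents)")
  }
  if (any(!is.finite(inhibition)) || any(inhibition < 0 | inhibition > 1)) {
    stop("inhibition must be finite and in [0, 1]")
  }
  o_a <- order(doses_a); o_b <- order(doses_b)
  structure(list(doses_a = doses_a[o_a], doses_b = doses_b[o_b],
                 inhibition = inhibition[o_a, o_b, drop = FALSE]),
            class = "lp_dose_grid")
}

#' Build a dose grid from a long-format plate table
#'
#' Viability is normalized to the untreated (0, 0) well and converted to
#' inhibition `1 - viability / viability(0, 0)`; replicates are averaged.
#'
#' @param plate data.frame with columns `dose_a`, `dose_b`, `viability`
#'   (and optionally `replicate`).
#' @return an `lp_dose_grid`.
#' @export
grid_from_plate <- function(plate) {
  stopifnot(all(c("dose_a", "dose_b", "viability") %in% names(plate)))
  agg <- stats::aggregate(viability ~ dose_a + dose_b, data = plate, FUN = mean)
  v00 <- agg$viability[agg$dose_a == 0 & agg$dose_b == 0]
  if (length(v00) != 1 || v00 <= 0) stop("missing or invalid untreated (0, 0) well")
  da <- sort(unique(agg$dose_a)); db <- sort(unique(agg$dose_b))
  inh <- matrix(NA_real_, length(da), length(db))
  for (k in seq_len(nrow(agg))) {
    inh[match(agg$dose_a[k], da), match(agg$dose_b[k], db)] <-
      1 - agg$viability[k] / v00
  }
  if (any(is.na(inh))) stop("incomplete dose lattice")
  dose_response_grid(da, db, pmin(pmax(inh, 0), 1))
}

#' Highest-single-agent (HSA) synergy score
#'
#' For every combination well (both doses > 0) the excess over the best
#' constituent single agent is
#' `inhibition(i, j) - max(inhibition(i, 0), inhibition(0, j))`; the score
#' is `100 * mean(excess)` (percent scale). Zero when every combination
#' well equals the HSA reference; positive = synergy.
#'
#' @param grid an `lp_dose_grid` with both zero-dose margins.
#' @return numeric HSA score.
#' @export
hsa_score <- function(grid) {
  stopifnot(inherits(grid, "lp_dose_grid"))
  ia <- which(grid$doses_a > 0); ib <- which(grid$doses_b > 0)
  if (length(ia) == 0 || length(ib) == 0) stop("no combination wells")
  i0 <- which(grid$doses_a == 0); j0 <- which(grid$doses_b == 0)
  if (length(i0) != 1 || length(j0) != 1) stop("missing single-agent margins")
  excess <- outer(ia, ib, Vectorize(function(i, j) {
    grid$inhibition[i, j] - max(grid$inhibition[i, j0],
                                grid$inhibition[i0, j])
  }))
  100 * mean(excess)
}

#' Median-effect (Chou-Talalay) fit
#'
#' Least-squares fit of `log10(fa / (1 - fa))` against `log10(D)`; the
#' slope is `m` and `Dm = 10^(-intercept / m)` is the median-effect dose.
#' Points with `fa` outside (0, 1) are excluded with a warning.
#'
#' @param doses positive doses.
#' @param fa fraction affected at each dose.
#' @return list classed `lp_median_effect` with `m`, `Dm`, `r2`,
#'   `n_used`.
#' @export
median_effect_fit <- function(doses, fa) {
  stopifnot(length(doses) == length(fa))
  usable <- fa > 0 & fa < 1 & doses > 0
  if (sum(!usable) > 0) {
    warning(sum(!usable), " point(s) with fa outside (0, 1) or dose <= 0 excluded")
  }
  if (sum(usable) < 2) stop("need at least 2 points with 0 < fa < 1")
  x <- log10(doses[usable])
  y <- log10(fa[usable] / (1 - fa[usable]))
  fit <- stats::lm(y ~ x)
  m <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  if (!is.finite(m) || m <= 0) stop("non-positive median-effect slope")
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - sum(stats::residuals(fit)^2) / ss_tot
  structure(list(m = m, Dm = 10^(-b / m), r2 = r2, n_used = sum(usable)),
            class = "lp_median_effect")
}

#' @export
print.lp_median_effect <- function(x, ...) {
  cat(sprintf("Median-effect fit: m = %.4f, Dm = %.4g (r2 = %.4f, n = %d)\n",
              x$m, x$Dm, x$r2, x$n_used))
  invisible(x)
}

#' Chou-Talalay combination index
#'
#' `CI = d1 / Dx1 + d2 / Dx2` where `Dx_k = Dm_k * (fa / (1 - fa))^(1 / m_k)`
#' is the dose of drug k alone producing effect `fa`. CI < 1 indicates
#' synergy, 1 additivity, > 1 antagonism.
#'
#' @param fit1,fit2 median-effect fits ([median_effect_fit]) for the two
#'   drugs.
#' @param d1,d2 doses used in combination.
#' @param fa effect level at which CI is evaluated (typically the
#'   inhibition achieved by the combination well), in (0, 1).
#' @return list `ci`, `fa`, `d1`, `d2`, `Dx1`, `Dx2`.
#' @export
combination_index <- function(fit1, fit2, d1, d2, fa) {
  stopifnot(inherits(fit1, "lp_median_effect"),
            inherits(fit2, "lp_median_effect"))
  if (fa <= 0 || fa >= 1) stop("fa must be in (0, 1)")
  if (d1 < 0 || d2 < 0) stop("doses must be >= 0")
  Dx1 <- fit1$Dm * (fa / (1 - fa))^(1 / fit1$m)
  Dx2 <- fit2$Dm * (fa / (1 - fa))^(1 / fit2$m)
  list(ci = d1 / Dx1 + d2 / Dx2, fa = fa, d1 = d1, d2 = d2,
       Dx1 = Dx1, Dx2 = Dx2)
}

#' Full synergy summary for a combination grid
#'
#' HSA score over all combination wells, plus the combination index at
#' every combination well evaluated at that well's achieved inhibition,
#' from median-effect fits of the two single-agent margins.
#'
#' @param grid an `lp_dose_grid`.
#' @return list classed `lp_synergy` with `hsa_score`, `fit_a`, `fit_b`
#'   and `ci_table` (data.frame `dose_a`, `dose_b`, `fa`, `ci`; wells with
#'   achieved fa outside (0, 1) get `NA` CI).
#' @export
synergy_summary <- function(grid) {
  stopifnot(inherits(grid, "lp_dose_grid"))
  i0 <- which(grid$doses_a == 0); j0 <- which(grid$doses_b == 0)
  ia <- which(grid$doses_a > 0); ib <- which(grid$doses_b > 0)
  fit_a <- median_effect_fit(grid$doses_a[ia], grid$inhibition[ia, j0])
  fit_b <- median_effect_fit(grid$doses_b[ib], grid$inhibition[i0, ib])
  rows <- list()
  for (i in ia) for (j in ib) {
    fa <- grid$inhibition[i, j]
    ci <- if (fa > 0 && fa < 1) {
      combination_index(fit_a, fit_b, grid$doses_a[i], grid$doses_b[j], fa)$ci
    } else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      dose_a = grid$doses_a[i], dose_b = grid$doses_b[j], fa = fa, ci = ci)
  }
  structure(list(hsa_score = hsa_score(grid), fit_a = fit_a, fit_b = fit_b,
                 ci_table = do.call(rbind, rows)), class = "lp_synergy")
}

#' @export
print.lp_synergy <- function(x, ...) {
  cat(sprintf("HSA synergy score: %.3f\n", x$hsa_score))
  cat(sprintf("Median CI over combination wells: %.3f\n",
              stats::median(x$ci_table$ci, na.rm = TRUE)))
  invisible(x)
}
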