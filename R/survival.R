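# Quartile dichotomization of drug-tolerant scores and survival comparison
# (log-rank, univariate Cox with Efron ties) with 5-year truncation.

#' Dichotomize subjects by score quartiles
#'
#' Low group = score <= Q1, high group = score >= Q3 (type-7 quantiles);
#' the middle half is excluded. All subjects tied at a quartile boundary
#' are included in the corresponding group.
#'
#' @param records data.frame with columns `patient_id` and `score`; at
#'   least 4 subjects (8+ recommended for a meaningful comparison).
#' @return list `high`, `low`, `excluded` (character id vectors) plus
#'   `q1`, `q3`.
#' @export
quartile_groups <- function(records) {
  stopifnot(all(c("patient_id", "score") %in% names(records)))
  if (nrow(records) < 4) stop("need at least 4 subjects for quartile grouping")
  s <- records$score
  if (all(s == s[1])) stop("all scores equal; no quartile separation")
  q <- stats::quantile(s, c(0.25, 0.75), type = 7, names = FALSE)
  list(low = records$patient_id[s <= q[1]],
       high = records$patient_id[s >= q[2]],
       excluded = records$patient_id[s > q[1] & s < q[2]],
       q1 = q[1], q3 = q[2])
}

#' Administratively censor follow-up at a horizon
#'
#' Times beyond `horizon` are set to `horizon` with the event indicator
#' cleared (censored). Idempotent.
#'
#' @param records data.frame with `time_months` and `event` columns.
#' @param horizon follow-up horizon in months (default 60 = 5 years).
#' @return the truncated records.
#' @export
truncate_followup <- function(records, horizon = 60) {
  if (horizon <= 0) stop("horizon must be positive")
  over <- records$time_months > horizon
  records$event[over] <- 0L
  records$time_months[over] <- horizon
  records
}

surv_group_data <- function(records, groups) {
  ids <- c(groups$high, groups$low)
  if (length(groups$high) == 0 || length(groups$low) == 0) {
    stop("both groups must be non-empty")
  }
  d <- records[match(ids, records$patient_id), ]
  if (any(is.na(d$patient_id))) stop("group member missing from records")
  d$group <- ifelse(d$patient_id %in% groups$high, "high", "low")
  d
}

#' Two-group log-rank test
#'
#' Standard log-rank statistic (df = 1) comparing the high and low score
#' groups, via [survival::survdiff].
#'
#' @param records data.frame with `patient_id`, `time_months`, `event`.
#' @param groups group assignment from [quartile_groups()] (or any list
#'   with `high` and `low` id vectors).
#' @return list `chi2`, `p`, `n` (per group), `events` (per group).
#' @export
logrank_test <- function(records, groups) {
  d <- surv_group_data(records, groups)
  if (sum(d$event) == 0) stop("no events in either group")
  sd <- survival::survdiff(survival::Surv(time_months, event) ~ group,
                           data = d)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       n = table(d$group), events = tapply(d$event, d$group, sum))
}

#' Univariate Cox proportional-hazards comparison
#'
#' Maximum partial likelihood with Efron tie handling (via
#' [survival::coxph]). With `groups` supplied the covariate is the
#' high-vs-low indicator (HR = hazard in the high group relative to low);
#' otherwise `records$score` is used as a continuous covariate.
#'
#' @param records data.frame with `patient_id`, `time_months`, `event`
#'   (and `score` for the continuous case).
#' @param groups optional group assignment from [quartile_groups()].
#' @return list classed `lp_cox`: `hr`, `ci95` (length-2), `beta`, `se`,
#'   `p` (Wald), `score_chi2`/`score_p` (score test, df = 1), `n`,
#'   `events`, `converged` (FALSE flags monotone likelihood /
#'   separation).
#' @export
cox_univariate <- function(records, groups = NULL) {
  if (!is.null(groups)) {
    d <- surv_group_data(records, groups)
    d$x <- as.integer(d$group == "high")
  } else {
    stopifnot("score" %in% names(records))
    d <- records
    d$x <- d$score
  }
  if (stats::sd(d$x) == 0) stop("covariate has no variation")
  fit <- tryCatch(
    survival::coxph(survival::Surv(time_months, event) ~ x, data = d,
                    ties = "efron",
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 50)),
    warning = function(w) {
      f <- suppressWarnings(
        survival::coxph(survival::Surv(time_months, event) ~ x, data = d,
                        ties = "efron"))
      attr(f, "lp_diverged") <- grepl("converge|infinite|beta", conditionMessage(w))
      f
    })
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  converged <- is.null(attr(fit, "lp_diverged")) || !attr(fit, "lp_diverged")
  if (!converged) warning("Cox fit diverged (monotone likelihood / separation)")
  structure(list(hr = exp(beta),
                 ci95 = exp(beta + c(-1, 1) * 1.96 * se),
                 beta = beta, se = se,
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 score_chi2 = unname(fit$score),
                 score_p = stats::pchisq(unname(fit$score), df = 1,
                                         lower.tail = FALSE),
                 n = nrow(d), events = sum(d$event), converged = converged),
            class = "lp_cox")
}

#' @export
print.lp_cox <- function(x, ...) {
  cat(sprintf("Cox PH: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g, %d events / %d subjects%s\n",
              x$hr, x$ci95[1], x$ci95[2], x$p, x$events, x$n,
              if (x$converged) "" else " [diverged]"))
  invisible(x)
}

#' Quartile-dichotomized 5-year survival analysis
#'
#' Convenience pipeline: truncate follow-up at `horizon`, split by score
#' quartiles, and compare high vs low with log-rank and Cox.
#'
#' @param records data.frame with `patient_id`, `time_months`, `event`,
#'   `score`.
#' @param horizon follow-up horizon in months.
#' @return list `groups`, `logrank`, `cox`.
#' @export
score_survival <- function(records, horizon = 60) {
  rec <- truncate_followup(records, horizon)
  grp <- quartile_groups(rec)
  list(groups = grp, logrank = logrank_test(rec, grp),
       cox = cox_univariate(rec, grp))
}
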