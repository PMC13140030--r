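# Validation statistics: Kaplan-Meier, person-time rates, Harrell's C with
# jackknife CI and subgroup analyses, Cox PH across risk groups, calibration
# intercept/slope via the Poisson representation of a Cox model, and
# head-to-head score comparison on common complete cases.

#' Shift zero follow-up times to half a day
#'
#' Same-day exits (t = 0) are shifted to 0.5/365.25 years so that log terms in
#' the calibration offsets stay finite; a message reports how many were moved.
#' @param time_years Numeric vector of follow-up times.
#' @return Adjusted vector.
#' @export
ensure_positive_time <- function(time_years) {
  zero <- !is.na(time_years) & time_years <= 0
  if (any(zero)) {
    message(sum(zero), " subject(s) with same-day exit shifted to 0.5 days")
    time_years[zero] <- 0.5 / 365.25
  }
  time_years
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate with Greenwood variance and log(-log) 95%
#' confidence limits (via [survival::survfit()]).
#'
#' @param time_years Follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @return Object of class `km_curve`: data frame of event times with
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`; the underlying `survfit`
#'   fit is kept in attribute `fit`.
#' @export
kaplan_meier <- function(time_years, event) {
  if (length(time_years) == 0L) stop("empty survival dataset")
  fit <- survival::survfit(survival::Surv(time_years, event) ~ 1,
                           conf.type = "log-log")
  keep <- fit$n.event > 0
  curve <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                      n_event = fit$n.event[keep], surv = fit$surv[keep],
                      std_err = fit$std.err[keep] * fit$surv[keep],
                      lower = fit$lower[keep], upper = fit$upper[keep])
  structure(curve, fit = fit, class = c("km_curve", "data.frame"))
}

#' Survival probability at a time point from a `km_curve`
#' @param km A `km_curve`.
#' @param t Time in years.
#' @return Estimated S(t) (1 before the first event; last value carried
#'   forward beyond the last observed time).
#' @export
km_at <- function(km, t) {
  fit <- attr(km, "fit")
  s <- summary(fit, times = t, extend = TRUE)
  as.numeric(s$surv)
}

#' Person-time mortality rate
#'
#' @param time_years Follow-up times.
#' @param event 0/1 event indicator.
#' @return List with `person_years`, `deaths`, `rate_per_100py` (rounded to 2
#'   decimals, the reporting convention) and the unrounded `rate_raw`.
#' @export
person_time_rate <- function(time_years, event) {
  if (length(time_years) == 0L) stop("empty survival dataset")
  py <- sum(time_years)
  if (py <= 0) stop("zero person-time")
  d <- sum(event)
  rate <- 100 * d / py
  list(person_years = py, deaths = d,
       rate_per_100py = round(rate, 2), rate_raw = rate)
}

#' Harrell's concordance statistic for a mortality-oriented marker
#'
#' A pair of subjects is comparable under right-censoring when the subject
#' with the shorter follow-up has the event (a pair with equal times is
#' comparable only when exactly one has the event, the death counting as the
#' earlier failure). A comparable pair is concordant when the subject failing
#' first carries the higher marker (the marker is oriented toward mortality:
#' higher score, higher risk); marker ties contribute 1/2. The confidence
#' interval uses a leave-one-subject-out jackknife standard error with a
#' normal interval, computed exactly from per-subject pair contributions.
#'
#' @param time_years Follow-up times (> 0).
#' @param event 0/1 event indicator.
#' @param marker Numeric risk marker (score total or risk-group rank).
#' @param conf_level Confidence level for the interval.
#' @return Object of class `concordance_result`: `c` plus pair counts
#'   (`comparable`, `concordant`, `discordant`, `tied_marker`), `se`,
#'   `lower`, `upper`, `n`, `events`.
#' @export
harrells_c <- function(time_years, event, marker, conf_level = 0.95) {
  n <- length(time_years)
  stopifnot(length(event) == n, length(marker) == n)
  if (n < 2L) stop("need at least two subjects")
  if (sum(event) < 1L) stop("need at least one event")
  if (any(!is.finite(marker))) stop("markers must be finite")

  conc <- disc <- tied <- 0
  conc_i <- comp_i <- numeric(n)
  for (i in which(event == 1L)) {
    later <- (time_years > time_years[i]) |
      (time_years == time_years[i] & event == 0L)
    if (!any(later)) next
    m_later <- marker[later]
    cc <- sum(m_later < marker[i])
    dd <- sum(m_later > marker[i])
    tt <- sum(m_later == marker[i])
    conc <- conc + cc; disc <- disc + dd; tied <- tied + tt
    score <- ifelse(m_later < marker[i], 1, ifelse(m_later > marker[i], 0, 0.5))
    comp_i[i] <- comp_i[i] + sum(later)
    conc_i[i] <- conc_i[i] + sum(score)
    comp_i[later] <- comp_i[later] + 1
    conc_i[later] <- conc_i[later] + score
  }
  comparable <- conc + disc + tied
  if (comparable == 0) stop("no comparable pairs")
  num <- conc + 0.5 * tied
  C <- num / comparable

  # exact leave-one-out values from per-subject contributions
  denom_k <- comparable - comp_i
  ok <- denom_k > 0
  c_k <- ifelse(ok, (num - conc_i) / denom_k, C)
  se <- sqrt((n - 1) / n * sum((c_k - mean(c_k))^2))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  structure(list(c = C, comparable = comparable, concordant = conc,
                 discordant = disc, tied_marker = tied, se = se,
                 lower = max(0, C - z * se), upper = min(1, C + z * se),
                 n = n, events = sum(event)),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("Harrell's C = %.3f (95%% CI %.3f-%.3f), %d subjects, %d events\n",
              x$c, x$lower, x$upper, x$n, x$events))
  invisible(x)
}

#' Subgroup discrimination
#'
#' Harrell's C within each level of each subgroup labelling. Subgroups that
#' cannot support the statistic (fewer than two subjects, no events or no
#' comparable pairs) are skipped with a warning.
#'
#' @param time_years,event,marker As in [harrells_c()].
#' @param subgroups Named list of vectors (factor/character/logical), each of
#'   the same length as `time_years`.
#' @return Data frame with `subgroup`, `level`, `n`, `events`, `c`, `lower`,
#'   `upper`.
#' @export
subgroup_discrimination <- function(time_years, event, marker, subgroups) {
  rows <- list()
  for (sg in names(subgroups)) {
    lab <- subgroups[[sg]]
    for (lev in unique(stats::na.omit(as.character(lab)))) {
      idx <- !is.na(lab) & as.character(lab) == lev
      res <- tryCatch(harrells_c(time_years[idx], event[idx], marker[idx]),
                      error = function(e) {
                        warning("subgroup ", sg, "=", lev, " skipped: ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        subgroup = sg, level = lev, n = res$n, events = res$events,
        c = res$c, lower = res$lower, upper = res$upper,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(subgroup = character(), level = character(),
                      n = integer(), events = integer(), c = numeric(),
                      lower = numeric(), upper = numeric()))
  do.call(rbind, rows)
}

#' Hazard ratios across pre-specified risk groups
#'
#' Cox proportional-hazards regression with risk-group indicator covariates
#' (lowest group as reference) maximised by [survival::coxph()], Efron tie
#' correction by default and Wald confidence intervals. A non-reference group
#' with no events produces a monotone partial likelihood; its coefficient is
#' flagged `unstable`.
#'
#' @param time_years,event As in [harrells_c()].
#' @param group Factor (or coercible) of risk-group labels; the first level
#'   is the reference.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return Object of class `cox_risk_fit`: data frame `coefficients`
#'   (`group`, `beta`, `se`, `hr`, `lower`, `upper`, `unstable`), `loglik`,
#'   reference level `reference`, and the `coxph` fit in attribute `fit`.
#' @export
cox_risk_groups <- function(time_years, event, group,
                            ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2L) stop("need at least two risk groups")
  ev_by_group <- tapply(event, group, sum)
  if (sum(ev_by_group > 0) < 2L)
    stop("need events in at least two groups")
  fit <- survival::coxph(survival::Surv(time_years, event) ~ group,
                         ties = ties)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  lev <- levels(group)[-1L]
  unstable <- ev_by_group[lev] == 0 | se > 100
  if (any(unstable))
    warning("monotone likelihood: group(s) ",
            paste(lev[unstable], collapse = ", "),
            " have unstable coefficients")
  coefs <- data.frame(group = lev, beta = as.numeric(beta),
                      se = as.numeric(se), hr = exp(as.numeric(beta)),
                      lower = exp(as.numeric(beta) - 1.96 * se),
                      upper = exp(as.numeric(beta) + 1.96 * se),
                      unstable = as.logical(unstable),
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(coefficients = coefs, loglik = fit$loglik[2L],
                 reference = levels(group)[1L]),
            fit = fit, class = "cox_risk_fit")
}

#' @export
print.cox_risk_fit <- function(x, ...) {
  cat("Cox PH across risk groups (reference:", x$reference, ")\n")
  print(within(x$coefficients, {
    hr <- round(hr, 2); lower <- round(lower, 2); upper <- round(upper, 2)
    beta <- round(beta, 3); se <- round(se, 3)
  }))
  invisible(x)
}

#' Calibration intercept and slope (Poisson representation of a Cox model)
#'
#' One record per subject at the (horizon-truncated) exit time. The intercept
#' model is an intercept-only Poisson likelihood for the event indicator with
#' offset `log` predicted cumulative hazard, whose MLE is the closed form
#' `log(sum(d) / sum(H))` (calibration-in-the-large on the log-hazard scale).
#' The slope model regresses the event indicator on the prognostic index with
#' offset `log` of the baseline cumulative-hazard component; the coefficient
#' on the prognostic index is the calibration slope (1 = perfect, < 1 =
#' predictions too spread out). Confidence intervals come from the expected
#' information.
#'
#' @param time_years,event As in [harrells_c()].
#' @param prognostic_index Per-subject prognostic index `pi` such that the
#'   predicted cumulative hazard is `exp(pi) * base_cumhaz` (see
#'   [predicted_cumhaz()]).
#' @param base_cumhaz Baseline cumulative hazard at each subject's exit
#'   (> 0).
#' @param conf_level Confidence level.
#' @return Object of class `calibration_result`: `intercept`,
#'   `intercept_ci`, `slope`, `slope_ci`, `n`, `events`.
#' @export
calibration_poisson <- function(time_years, event, prognostic_index,
                                base_cumhaz, conf_level = 0.95) {
  pred_cumhaz <- exp(prognostic_index) * base_cumhaz
  if (any(!is.finite(pred_cumhaz)) || any(pred_cumhaz <= 0))
    stop("predicted cumulative hazards must be positive and finite")
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  fit_a <- stats::glm(event ~ 1 + offset(log(pred_cumhaz)),
                      family = stats::poisson())
  alpha <- as.numeric(stats::coef(fit_a)[1L])
  se_a <- sqrt(diag(stats::vcov(fit_a)))[1L]

  fit_b <- stats::glm(event ~ prognostic_index + offset(log(base_cumhaz)),
                      family = stats::poisson())
  beta <- as.numeric(stats::coef(fit_b)["prognostic_index"])
  se_b <- sqrt(diag(stats::vcov(fit_b)))["prognostic_index"]

  structure(list(intercept = alpha,
                 intercept_ci = c(alpha - z * se_a, alpha + z * se_a),
                 slope = beta,
                 slope_ci = as.numeric(c(beta - z * se_b, beta + z * se_b)),
                 n = length(event), events = sum(event)),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("calibration intercept %.3f (95%% CI %.3f-%.3f)\n",
              x$intercept, x$intercept_ci[1L], x$intercept_ci[2L]))
  cat(sprintf("calibration slope     %.3f (95%% CI %.3f-%.3f)\n",
              x$slope, x$slope_ci[1L], x$slope_ci[2L]))
  invisible(x)
}

#' Predicted versus observed 5-year survival by risk group
#'
#' For each risk group, the Kaplan-Meier estimate at 5 years is compared with
#' the group-level predicted survival of the definition. Empty groups are
#' omitted with a warning; an all-censored group observes survival 1.
#'
#' @param time_years,event As in [harrells_c()].
#' @param group Risk-group labels.
#' @param def A `score_definition` with risk groups.
#' @return Data frame with `group`, `n`, `deaths`, `predicted`, `observed`,
#'   `obs_lower`, `obs_upper`, `difference` (predicted - observed) and
#'   `abs_difference`.
#' @export
calibration_by_group <- function(time_years, event, group,
                                 def = dataids_definition()) {
  labels <- unlist(def$risk_groups$labels)
  pred_map <- def$risk_groups$predicted_survival_5y
  rows <- list()
  for (g in labels) {
    idx <- !is.na(group) & as.character(group) == g
    if (!any(idx)) {
      warning("risk group '", g, "' has no subjects; omitted")
      next
    }
    km <- kaplan_meier(time_years[idx], event[idx])
    fit <- attr(km, "fit")
    s <- summary(fit, times = 5, extend = TRUE)
    obs <- as.numeric(s$surv)
    lo <- as.numeric(s$lower); up <- as.numeric(s$upper)
    pred <- as.numeric(pred_map[[g]])
    rows[[length(rows) + 1L]] <- data.frame(
      group = g, n = sum(idx), deaths = sum(event[idx]),
      predicted = pred, observed = obs,
      obs_lower = ifelse(is.na(lo), NA_real_, lo),
      obs_upper = ifelse(is.na(up), NA_real_, up),
      difference = pred - obs, abs_difference = abs(pred - obs),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Head-to-head discrimination on common complete cases
#'
#' Restricts to the subjects for whom both scores are computable, then
#' computes Harrell's C for each score on that common subset.
#'
#' @param scored Data frame from [score_cohort()] including `time_years` and
#'   `event`.
#' @param score_a,score_b Score names (columns `<name>_total` and
#'   `<name>_computable` must exist).
#' @return List with `n_common`, and `concordance_result`s `c_a` and `c_b`.
#' @export
compare_scores <- function(scored, score_a, score_b) {
  comp <- scored[[paste0(score_a, "_computable")]] &
    scored[[paste0(score_b, "_computable")]]
  if (!any(comp)) stop("no subjects with both scores computable")
  sub <- scored[comp, , drop = FALSE]
  list(n_common = nrow(sub),
       score_a = score_a, score_b = score_b,
       c_a = harrells_c(sub$time_years, sub$event,
                        sub[[paste0(score_a, "_total")]]),
       c_b = harrells_c(sub$time_years, sub$event,
                        sub[[paste0(score_b, "_total")]]))
}
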