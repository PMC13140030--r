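# Top-level external validation: one call that ingests a cohort, computes the
# scores and produces every validation statistic, returned as a classed
# object with print/summary/plot methods and CSV/JSON report writers.

#' Round half-up (reporting convention for percentages)
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values; exact halves round away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Externally validate prognostic scores on a cohort
#'
#' Runs the full pipeline: cohort ingestion, eligibility screening, windowed
#' baseline resolution, score computation, and the validation statistics —
#' person-time mortality rate, Harrell's C (overall and in the pre-specified
#' subgroups: sex, CD4 </>= 350, CD4 nadir </>= 200, CD4 </>= cohort median,
#' HIV-RNA </>= 200), Cox hazard ratios across risk groups, calibration
#' intercept and slope on the Poisson representation of a Cox model at the
#' 5-year horizon, predicted versus observed Kaplan-Meier survival per risk
#' group, completeness accounting and head-to-head comparisons on common
#' complete cases.
#'
#' @param participants_csv,measurements_csv Input CSV paths (see
#'   [load_cohort()]), or an `hiv_cohort` object as the first argument.
#' @param study_end Administrative censoring date.
#' @param horizon_years Prediction horizon (follow-up truncated here before
#'   calibration).
#' @param window_months Baseline window half-width.
#' @param bmi_mode `"unrestricted"` or `"windowed"` (see
#'   [select_bmi_inputs()]).
#' @param impute `"none"` or `"normal_values"` (VACS 2.0 albumin/ALT/AST).
#' @param scores Scores to evaluate.
#' @param definitions Optional named list of `score_definition`s.
#' @return Object of class `score_validation`.
#' @export
score_validation <- function(participants_csv, measurements_csv = NULL,
                             study_end = as.Date("2019-12-31"),
                             horizon_years = 5, window_months = 12,
                             bmi_mode = c("unrestricted", "windowed"),
                             impute = c("none", "normal_values"),
                             scores = c("dataids", "vacs1", "vacs2"),
                             definitions = NULL) {
  bmi_mode <- match.arg(bmi_mode)
  impute <- match.arg(impute)
  if (inherits(participants_csv, "hiv_cohort")) {
    cohort <- participants_csv
  } else {
    cohort <- load_cohort(participants_csv, measurements_csv)
  }
  if (is.null(definitions))
    definitions <- list(dataids = dataids_definition(),
                        vacs1 = vacs1_definition(),
                        vacs2 = vacs2_definition())
  def <- definitions$dataids

  base <- resolve_baseline(cohort, study_end = study_end,
                           horizon_years = horizon_years,
                           window_months = window_months, bmi_mode = bmi_mode)
  screening <- attr(base, "screening")
  n_screened <- nrow(screening)
  n_included <- sum(screening$included)
  reasons <- unique(screening$reason[!is.na(screening$reason)])
  flow <- data.frame(
    stage = c("screened", "included",
              paste0("excluded_", reasons, recycle0 = TRUE)),
    n = c(n_screened, n_included,
          vapply(reasons, function(r) sum(screening$reason == r, na.rm = TRUE),
                 integer(1))),
    stringsAsFactors = FALSE)
  flow$percent <- round_half_up(100 * flow$n / n_screened, 1)

  scored <- score_cohort(base, scores = scores, impute = impute,
                         definitions = definitions)
  scored$time_years <- ensure_positive_time(scored$time_years)

  rate <- person_time_rate(scored$time_years, scored$event)
  compl <- completeness_table(scored, scores)

  ok <- scored$dataids_computable
  an <- scored[ok, , drop = FALSE]
  cd4_median <- stats::median(an$cd4, na.rm = TRUE)
  subgroups <- list(
    sex = an$sex,
    cd4_350 = ifelse(is.na(an$cd4), NA, ifelse(an$cd4 < 350, "<350", ">=350")),
    nadir_200 = ifelse(is.na(an$cd4_nadir), NA,
                       ifelse(an$cd4_nadir < 200, "<200", ">=200")),
    cd4_median = ifelse(is.na(an$cd4), NA,
                        ifelse(an$cd4 < cd4_median, "<median", ">=median")),
    rna_200 = ifelse(is.na(an$hiv_rna), NA,
                     ifelse(an$hiv_rna < 200, "<200", ">=200")))

  concordance <- harrells_c(an$time_years, an$event, an$dataids_total)
  subgroup_c <- subgroup_discrimination(an$time_years, an$event,
                                        an$dataids_total, subgroups)
  cox <- tryCatch(cox_risk_groups(an$time_years, an$event, an$dataids_group),
                  error = function(e) NULL, warning = function(w)
                    suppressWarnings(cox_risk_groups(an$time_years, an$event,
                                                     an$dataids_group)))
  ph <- predicted_cumhaz(def, an$dataids_total, an$time_years)
  calibration <- calibration_poisson(an$time_years, an$event, ph$pi,
                                     ph$base_cumhaz)
  cal_groups <- calibration_by_group(an$time_years, an$event,
                                     an$dataids_group, def)

  comparisons <- list()
  if ("dataids" %in% scores)
    for (s in intersect(scores, c("vacs1", "vacs2")))
      comparisons[[s]] <- compare_scores(scored, "dataids", s)

  structure(list(
    flow = flow, screening = screening, scored = scored, rate = rate,
    completeness = compl, concordance = concordance, subgroup_c = subgroup_c,
    cox = cox, calibration = calibration, calibration_groups = cal_groups,
    comparisons = comparisons, cd4_median = cd4_median,
    settings = list(study_end = as.Date(study_end),
                    horizon_years = horizon_years,
                    window_months = window_months, bmi_mode = bmi_mode,
                    impute = impute, scores = scores)),
    class = "score_validation")
}

#' @export
print.score_validation <- function(x, ...) {
  incl <- x$flow[x$flow$stage == "included", ]
  scr <- x$flow[x$flow$stage == "screened", ]
  cat(sprintf("External validation: %d screened, %d (%.1f%%) included\n",
              scr$n, incl$n, incl$percent))
  cat(sprintf("Deaths: %d over %.0f person-years (%.2f per 100 PY)\n",
              x$rate$deaths, x$rate$person_years, x$rate$rate_per_100py))
  print(x$concordance)
  print(x$calibration)
  cat("\nPredicted vs observed 5-year survival by risk group:\n")
  cg <- x$calibration_groups
  cg$predicted <- round(cg$predicted, 2); cg$observed <- round(cg$observed, 2)
  cg$difference <- round(cg$difference, 2)
  print(cg[, c("group", "n", "deaths", "predicted", "observed", "difference")])
  invisible(x)
}

#' @export
summary.score_validation <- function(object, ...) {
  print(object)
  cat("\nSubgroup discrimination:\n")
  sc <- object$subgroup_c
  sc$c <- round(sc$c, 3); sc$lower <- round(sc$lower, 3)
  sc$upper <- round(sc$upper, 3)
  print(sc)
  if (!is.null(object$cox)) { cat("\n"); print(object$cox) }
  if (length(object$comparisons)) {
    cat("\nHead-to-head comparisons (common complete cases):\n")
    for (s in names(object$comparisons)) {
      cmp <- object$comparisons[[s]]
      cat(sprintf("  dataids C=%.3f vs %s C=%.3f on n=%d\n",
                  cmp$c_a$c, s, cmp$c_b$c, cmp$n_common))
    }
  }
  cat("\nCompleteness:\n")
  print(object$completeness)
  invisible(object)
}

#' @export
plot.score_validation <- function(x, ...) {
  cg <- x$calibration_groups
  idx <- seq_len(nrow(cg))
  graphics::plot(idx, cg$observed, ylim = c(0, 1), xaxt = "n", pch = 16,
                 xlab = "risk group", ylab = "5-year survival probability",
                 main = "Predicted vs observed 5-year survival", ...)
  graphics::axis(1, at = idx, labels = cg$group)
  graphics::segments(idx, cg$obs_lower, idx, cg$obs_upper)
  graphics::points(idx + 0.1, cg$predicted, pch = 4, col = 2)
  graphics::legend("bottomleft", pch = c(16, 4), col = c(1, 2),
                   legend = c("observed (KM)", "predicted"), bty = "n")
  invisible(x)
}

#' Write validation report tables
#'
#' Emits the report as plain data tables: the risk-group table (predicted vs
#' observed survival), the subgroup concordance table, the head-to-head
#' comparison table, the completeness table, the eligibility flow, the
#' person-time rate, and a `validation.json` summary. Deterministic given the
#' same validation object.
#'
#' @param x A `score_validation`.
#' @param dir Output directory (created when needed).
#' @return Invisibly, the vector of files written.
#' @export
write_validation_report <- function(x, dir) {
  stopifnot(inherits(x, "score_validation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(dir, name)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    path
  }
  files <- c(
    w(x$flow, "flow.csv"),
    w(x$calibration_groups, "risk_groups.csv"),
    w(x$subgroup_c, "subgroup_concordance.csv"),
    w(x$completeness, "completeness.csv"))
  if (!is.null(x$cox)) files <- c(files, w(x$cox$coefficients, "hazard_ratios.csv"))
  if (length(x$comparisons)) {
    cmp <- do.call(rbind, lapply(names(x$comparisons), function(s) {
      k <- x$comparisons[[s]]
      data.frame(comparison = paste0("dataids_vs_", s), n_common = k$n_common,
                 c_dataids = k$c_a$c, c_dataids_lower = k$c_a$lower,
                 c_dataids_upper = k$c_a$upper, c_other = k$c_b$c,
                 c_other_lower = k$c_b$lower, c_other_upper = k$c_b$upper,
                 stringsAsFactors = FALSE)
    }))
    files <- c(files, w(cmp, "comparisons.csv"))
  }
  js <- file.path(dir, "validation.json")
  jsonlite::write_json(list(
    n_screened = x$flow$n[x$flow$stage == "screened"],
    n_included = x$flow$n[x$flow$stage == "included"],
    included_percent = x$flow$percent[x$flow$stage == "included"],
    deaths = x$rate$deaths, person_years = x$rate$person_years,
    rate_per_100py = x$rate$rate_per_100py,
    c_statistic = x$concordance$c,
    c_ci = c(x$concordance$lower, x$concordance$upper),
    calibration_intercept = x$calibration$intercept,
    calibration_slope = x$calibration$slope,
    settings = lapply(x$settings, as.character)),
    js, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(files, js))
}
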