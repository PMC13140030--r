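# Synthetic cohort generator: draws baseline covariates from the marginal
# distributions of a French cohort of people living with HIV aged >= 70,
# simulates exponential survival under a proportional-hazards model on the
# true Dat'AIDS score, applies administrative censoring, loss to follow-up
# and missingness masks, and writes the CSV schemas the ingestion layer
# consumes.

#' Configuration for the synthetic cohort
#'
#' Defaults emulate the validation study population: n = 1330 people living
#' with HIV aged 70 or older entering between 2014-06-01 and 2017-12-31
#' (mostly prevalent patients entering soon after the window opens),
#' administratively censored at 5 years or 2019-12-31, with 11% lost to
#' follow-up. Covariate marginals follow the published baseline table (sex,
#' age bands, CD4, comorbidity prevalences, lab medians/IQRs); missingness is
#' MCAR with albumin present in 34.1% and within-window weight in 68.3% of
#' subjects. The hazard model `h(t) = h0 * exp(lambda_true * score)` uses
#' `lambda_true` = 0.105 per point and `h0` = 0.0092 per year, solved once so
#' the four risk groups' 5-year survival matches the published group-level
#' predictions (0.95/0.90/0.80/0.53 at group median scores 1/8/16/25).
#' `hazard_model = "group_bridge"` instead simulates events exactly from the
#' packaged group-level predictions, for calibration self-consistency checks.
#'
#' @param n Number of eligible subjects.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param ... Named overrides of any default listed above (see
#'   `str(synthetic_config())`).
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n = 1330, seed = 1, ...) {
  cfg <- list(
    n = n, seed = seed,
    entry_start = "2014-06-01", entry_end = "2017-12-31",
    study_end = "2019-12-31", horizon_years = 5,
    prevalent_fraction = 0.75,
    male_fraction = 0.758,
    age_band_probs = c("70-74" = 0.608, "75-84" = 0.365, ">=85" = 0.026),
    cd4_meanlog = log(553), cd4_sdlog = 0.457,
    cd4_nadir_meanlog = log(174), cd4_nadir_sdlog = 0.94,
    rna_suppressed_fraction = 0.884, rna_undetectable_value = 20,
    rna_meanlog = log(1556), rna_sdlog = 4.67, rna_max = 1e7,
    hemoglobin_mean_male = 14.2, hemoglobin_mean_female = 13.2,
    hemoglobin_sd = 1.5,
    creatinine_meanlog_male = 4.48, creatinine_meanlog_female = 4.24,
    creatinine_sdlog = 0.41,
    alt_meanlog = log(23), alt_sdlog = 0.448,
    ast_meanlog = log(25), ast_sdlog = 0.325,
    platelets_meanlog = log(200), platelets_sdlog = 0.275,
    wbc_meanlog = log(6), wbc_sdlog = 0.27,
    albumin_mean = 42, albumin_sd = 4.7,
    bmi_meanlog = log(24.2), bmi_sdlog = 0.17,
    height_mean_male = 1.75, height_mean_female = 1.62, height_sd = 0.065,
    prev_cancer = 0.112, prev_cvd = 0.133, prev_cirrhosis = 0.030,
    prev_hcv = 0.047, prev_hbv = 0.013, prev_aids = 0.25,
    lambda_true = 0.105, h0 = 0.0092,
    hazard_model = "score",
    ltfu_fraction = 0.11,
    albumin_missing = 0.659, bmi_window_missing = 0.317,
    lab_missing = 0.005, cd4_nadir_missing = 0.05, rna_missing = 0.003,
    n_ineligible = 0)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

#' @rdname synthetic_config
#' @param cfg A configuration list.
#' @export
validate_synthetic_config <- function(cfg) {
  bad <- character(0)
  if (!isTRUE(cfg$n > 0)) bad <- c(bad, "n")
  probs <- c("prevalent_fraction", "male_fraction", "rna_suppressed_fraction",
             "prev_cancer", "prev_cvd", "prev_cirrhosis", "prev_hcv",
             "prev_hbv", "prev_aids", "ltfu_fraction", "albumin_missing",
             "bmi_window_missing", "lab_missing", "cd4_nadir_missing",
             "rna_missing")
  for (p in probs)
    if (!isTRUE(cfg[[p]] >= 0 && cfg[[p]] <= 1)) bad <- c(bad, p)
  if (abs(sum(cfg$age_band_probs) - 1) > 0.01) bad <- c(bad, "age_band_probs")
  if (!isTRUE(cfg$h0 > 0)) bad <- c(bad, "h0")
  if (!isTRUE(cfg$hazard_model %in% c("score", "group_bridge")))
    bad <- c(bad, "hazard_model")
  if (length(bad))
    stop("invalid synthetic config field(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

.rtrunc_unif_bands <- function(n, probs) {
  band <- sample(names(probs), n, replace = TRUE, prob = probs)
  lo <- c("70-74" = 70, "75-84" = 75, ">=85" = 85)[band]
  hi <- c("70-74" = 75, "75-84" = 85, ">=85" = 95)[band]
  stats::runif(n, lo, hi)
}

#' Generate a synthetic cohort
#'
#' Draws covariates independently from the configured marginals (the
#' published source reports only marginals; no copula is imposed), computes
#' each subject's true Dat'AIDS score with the packaged definition, simulates
#' an exponential event time with hazard `h0 * exp(lambda_true * score)`,
#' applies administrative censoring (5-year horizon / study end) and uniform
#' loss to follow-up, scatters dated measurements around the entry date,
#' applies the MCAR missingness masks, and (optionally) writes
#' `participants.csv`, `measurements.csv` and a `meta.json` with the seed.
#'
#' @param cfg A `synthetic_config`.
#' @param dir Output directory; when `NULL` nothing is written.
#' @return Invisibly, a list with `participants`, `measurements` (data
#'   frames), `truth` (per-subject true score, risk group and realized
#'   censoring cap) and `paths` (when written).
#' @export
generate_cohort <- function(cfg = synthetic_config(), dir = NULL) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  n <- cfg$n
  id <- sprintf("S%05d", seq_len(n))
  entry_start <- as.Date(cfg$entry_start)
  entry_end <- as.Date(cfg$entry_end)
  study_end <- as.Date(cfg$study_end)
  window_days <- as.numeric(entry_end - entry_start)

  prevalent <- stats::runif(n) < cfg$prevalent_fraction
  entry_off <- ifelse(prevalent,
                      floor(stats::runif(n, 0, 183)),
                      floor(stats::runif(n, 0, window_days + 1)))
  entry <- entry_start + entry_off

  sex <- ifelse(stats::runif(n) < cfg$male_fraction, "male", "female")
  age <- .rtrunc_unif_bands(n, cfg$age_band_probs)
  birth <- entry - round(age * DAYS_PER_YEAR)

  cd4 <- round(stats::rlnorm(n, cfg$cd4_meanlog, cfg$cd4_sdlog))
  cd4_nadir <- round(pmin(stats::rlnorm(n, cfg$cd4_nadir_meanlog,
                                        cfg$cd4_nadir_sdlog), cd4))
  suppressed <- stats::runif(n) < cfg$rna_suppressed_fraction
  rna <- ifelse(suppressed, cfg$rna_undetectable_value,
                round(pmin(stats::rlnorm(n, cfg$rna_meanlog, cfg$rna_sdlog) + 50,
                           cfg$rna_max)))
  hgb <- round(stats::rnorm(n, ifelse(sex == "male", cfg$hemoglobin_mean_male,
                                      cfg$hemoglobin_mean_female),
                            cfg$hemoglobin_sd), 1)
  hgb <- pmax(hgb, 5)
  creat <- round(stats::rlnorm(n, ifelse(sex == "male",
                                         cfg$creatinine_meanlog_male,
                                         cfg$creatinine_meanlog_female),
                               cfg$creatinine_sdlog), 1)
  alt <- pmax(round(stats::rlnorm(n, cfg$alt_meanlog, cfg$alt_sdlog)), 5)
  ast <- pmax(round(stats::rlnorm(n, cfg$ast_meanlog, cfg$ast_sdlog)), 5)
  plt <- pmax(round(stats::rlnorm(n, cfg$platelets_meanlog, cfg$platelets_sdlog)), 20)
  wbc <- round(stats::rlnorm(n, cfg$wbc_meanlog, cfg$wbc_sdlog), 1)
  alb <- round(pmax(stats::rnorm(n, cfg$albumin_mean, cfg$albumin_sd), 20), 1)
  bmi <- stats::rlnorm(n, cfg$bmi_meanlog, cfg$bmi_sdlog)
  height <- round(stats::rnorm(n, ifelse(sex == "male", cfg$height_mean_male,
                                         cfg$height_mean_female),
                               cfg$height_sd), 2)
  weight <- round(bmi * height^2, 1)

  cancer <- stats::runif(n) < cfg$prev_cancer
  cvd <- stats::runif(n) < cfg$prev_cvd
  cirr <- stats::runif(n) < cfg$prev_cirrhosis
  hcv <- stats::runif(n) < cfg$prev_hcv
  hbv <- stats::runif(n) < cfg$prev_hbv
  aids <- stats::runif(n) < cfg$prev_aids

  # true score from the full (pre-missingness) covariates
  truth_base <- derive_covariates(data.frame(
    participant_id = id, sex = sex, age = age,
    non_hiv_cancer = cancer, cvd = cvd, cirrhosis = cirr, aids = aids,
    hbv = hbv, hcv = hcv, cd4 = cd4, cd4_nadir = cd4_nadir, hiv_rna = rna,
    hemoglobin = hgb, creatinine = creat, ast = ast, alt = alt,
    platelets = plt, wbc = wbc, albumin = alb, weight = weight,
    height = height, stringsAsFactors = FALSE))
  def <- dataids_definition()
  scored <- score_cohort(truth_base, scores = "dataids",
                         definitions = list(dataids = def))
  true_score <- scored$dataids_total

  if (cfg$hazard_model == "group_bridge") {
    # simulate exactly from the packaged group-level predictions (constant
    # hazard -log(S_g(5))/5), so downstream calibration should recover
    # intercept 0 and slope 1
    rate <- -log(assign_risk_group(true_score, def)$predicted_survival_5y) / 5
  } else {
    rate <- cfg$h0 * exp(cfg$lambda_true * true_score)
  }
  t_death <- stats::rexp(n, rate)
  admin_cap <- pmin(cfg$horizon_years,
                    as.numeric(study_end - entry) / DAYS_PER_YEAR)
  ltfu <- stats::runif(n) < cfg$ltfu_fraction
  ltfu_time <- ifelse(ltfu, stats::runif(n, 0, cfg$horizon_years), Inf)
  cens <- pmin(admin_cap, ltfu_time)
  died <- t_death <= cens
  time <- pmin(t_death, cens)
  exit <- entry + pmax(1, round(time * DAYS_PER_YEAR))

  participants <- data.frame(
    participant_id = id, sex = sex,
    birth_date = birth, entry_date = entry, exit_date = exit,
    event = ifelse(died, "death", "censored"),
    hiv2_flag = FALSE, non_hiv_cancer = cancer, cvd = cvd,
    cirrhosis = cirr, aids = aids, hbsag_pos = hbv, hcv_ab_pos = hcv,
    stringsAsFactors = FALSE)

  # MCAR missingness masks (independent of event status)
  m_alb <- stats::runif(n) < cfg$albumin_missing
  m_bmi <- stats::runif(n) < cfg$bmi_window_missing
  m_lab <- matrix(stats::runif(n * 6) < cfg$lab_missing, n, 6)
  colnames(m_lab) <- c("hemoglobin", "creatinine", "ast", "alt",
                       "platelets", "wbc")
  m_nadir <- stats::runif(n) < cfg$cd4_nadir_missing
  m_rna <- stats::runif(n) < cfg$rna_missing

  off <- function() floor(stats::runif(n, -365, 366))
  add <- function(acc, analyte, values, present, offsets) {
    if (!any(present)) return(acc)
    acc[[length(acc) + 1L]] <- data.frame(
      participant_id = id[present], analyte = analyte,
      date = entry[present] + offsets[present],
      value = values[present], unit = .analyte_units[[analyte]],
      stringsAsFactors = FALSE)
    acc
  }
  all_on <- rep(TRUE, n)
  meas <- list()
  meas <- add(meas, "cd4", cd4, all_on, off())
  meas <- add(meas, "cd4_nadir", cd4_nadir, !m_nadir, off())
  meas <- add(meas, "hiv_rna", rna, !m_rna, off())
  meas <- add(meas, "hemoglobin", hgb, !m_lab[, "hemoglobin"], off())
  meas <- add(meas, "creatinine", creat, !m_lab[, "creatinine"], off())
  meas <- add(meas, "ast", ast, !m_lab[, "ast"], off())
  meas <- add(meas, "alt", alt, !m_lab[, "alt"], off())
  meas <- add(meas, "platelets", plt, !m_lab[, "platelets"], off())
  meas <- add(meas, "wbc", wbc, !m_lab[, "wbc"], off())
  meas <- add(meas, "albumin", alb, !m_alb, off())
  # weight outside the +/-12-month window for the masked fraction
  w_off <- ifelse(m_bmi, -floor(stats::runif(n, 400, 1460)), floor(stats::runif(n, -365, 366)))
  meas <- add(meas, "weight", weight, all_on, w_off)
  meas <- add(meas, "height", height, all_on, -floor(stats::runif(n, 0, 731)))

  if (cfg$n_ineligible > 0) {
    k <- cfg$n_ineligible
    iid <- sprintf("X%05d", seq_len(k))
    reason <- rep_len(c("age", "no_cd4", "hiv2"), k)
    ientry <- entry_start + floor(stats::runif(k, 0, window_days + 1))
    iage <- ifelse(reason == "age", stats::runif(k, 60, 69.5),
                   stats::runif(k, 70, 85))
    participants <- rbind(participants, data.frame(
      participant_id = iid, sex = "male",
      birth_date = ientry - round(iage * DAYS_PER_YEAR),
      entry_date = ientry, exit_date = ientry + 400,
      event = "censored", hiv2_flag = reason == "hiv2",
      non_hiv_cancer = FALSE, cvd = FALSE, cirrhosis = FALSE, aids = FALSE,
      hbsag_pos = FALSE, hcv_ab_pos = FALSE, stringsAsFactors = FALSE))
    cd4_off <- ifelse(reason == "no_cd4", 430L, 10L)
    meas[[length(meas) + 1L]] <- data.frame(
      participant_id = iid, analyte = "cd4", date = ientry + cd4_off,
      value = round(stats::rlnorm(k, cfg$cd4_meanlog, cfg$cd4_sdlog)),
      unit = .analyte_units[["cd4"]], stringsAsFactors = FALSE)
  }

  measurements <- do.call(rbind, meas)
  measurements <- measurements[order(measurements$participant_id,
                                     measurements$analyte,
                                     measurements$date), ]
  rownames(measurements) <- NULL

  truth <- data.frame(participant_id = id, true_score = true_score,
                      true_group = as.character(scored$dataids_group),
                      admin_cap_years = admin_cap, ltfu = ltfu,
                      stringsAsFactors = FALSE)

  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    ppath <- file.path(dir, "participants.csv")
    mpath <- file.path(dir, "measurements.csv")
    cohort <- structure(list(participants = participants,
                             measurements = measurements),
                        class = "hiv_cohort")
    write_cohort(cohort, ppath, mpath)
    meta <- file.path(dir, "meta.json")
    jsonlite::write_json(list(seed = cfg$seed, n = cfg$n,
                              config = unclass(cfg)),
                         meta, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(participants = ppath, measurements = mpath, meta = meta)
  }
  invisible(list(participants = participants, measurements = measurements,
                 truth = truth, paths = paths))
}

#' Small hand-checkable fixtures
#'
#' Writes (or returns) the worked fixtures used throughout the tests: a
#' 5-subject Kaplan-Meier set whose product-limit estimate steps through
#' 0.8, 0.5333 and 0.2667; a 3-subject concordance set with C = 1; and a
#' 3-subject calibration set whose closed-form intercept is 0.
#'
#' @param dir Output directory; when `NULL` nothing is written.
#' @return List of data frames `km`, `concordance`, `calibration` (and
#'   `paths` when written).
#' @export
generate_worked_fixtures <- function(dir = NULL) {
  km <- data.frame(time = c(2, 3, 4, 5, 6), event = c(1, 0, 1, 1, 0))
  cc <- data.frame(marker = c(3, 2, 1), time = c(1, 2, 3), event = c(1, 1, 1))
  cal <- data.frame(event = c(1, 0, 1), cumhaz = c(0.5, 0.5, 1.0))
  out <- list(km = km, concordance = cc, calibration = cal)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- c(km = file.path(dir, "km_fixture.csv"),
               concordance = file.path(dir, "concordance_fixture.csv"),
               calibration = file.path(dir, "calibration_fixture.csv"))
    utils::write.csv(km, paths["km"], row.names = FALSE, quote = FALSE)
    utils::write.csv(cc, paths["concordance"], row.names = FALSE, quote = FALSE)
    utils::write.csv(cal, paths["calibration"], row.names = FALSE, quote = FALSE)
    out$paths <- paths
  }
  out
}
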