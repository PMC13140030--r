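# Cohort ingestion, eligibility screening, follow-up computation and windowed
# baseline-value selection.
#
# Time conventions used throughout (fixed for reproducibility): one month in
# window rules is 30.4375 days, one year is 365.25 days; ages are exact
# fractional years at the entry date.

DAYS_PER_MONTH <- 30.4375
DAYS_PER_YEAR <- 365.25

.analyte_units <- c(
  cd4 = "cells/mm3", cd4_nadir = "cells/mm3", hiv_rna = "copies/mL",
  hemoglobin = "g/dL", creatinine = "umol/L", ast = "U/L", alt = "U/L",
  platelets = "10^3/uL", wbc = "10^3/uL", albumin = "g/L",
  weight = "kg", height = "m")

# unit spellings accepted on input, normalised to the canonical name above
.unit_aliases <- list(
  "umol/L" = c("umol/L", "μmol/L", "µmol/L"),
  "10^3/uL" = c("10^3/uL", "10^3/μL", "1e3/uL"),
  "cells/mm3" = c("cells/mm3", "cells/µL", "cells/uL"),
  "copies/mL" = "copies/mL", "g/dL" = "g/dL", "U/L" = c("U/L", "IU/L"),
  "g/L" = "g/L", "kg" = "kg", "m" = "m")

.participant_cols <- c(
  "participant_id", "sex", "birth_date", "entry_date", "exit_date", "event",
  "hiv2_flag", "non_hiv_cancer", "cvd", "cirrhosis", "aids",
  "hbsag_pos", "hcv_ab_pos")

.parse_iso_date <- function(x) {
  d <- as.Date(rep(NA_character_, length(x)))
  ok <- grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  d[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  d
}

#' Load a cohort from CSV files
#'
#' Reads the participant table (static flags, entry/exit dates, vital status)
#' and the long-format dated measurement table. Every row is either parsed or
#' rejected with a row-level diagnostic (line number and message); rejected
#' rows are dropped from the returned tables and reported in `$problems`.
#' Dates must be ISO-8601 (`YYYY-MM-DD`), booleans 0/1, and measurement units
#' must match the documented unit per analyte (creatinine umol/L, haemoglobin
#' g/dL, CD4 cells/mm3, HIV-RNA copies/mL, albumin g/L, AST/ALT U/L,
#' platelets and white cells 10^3/uL, weight kg, height m).
#'
#' @param participants_csv Path to the participant CSV.
#' @param measurements_csv Path to the measurement CSV.
#' @return An object of class `hiv_cohort`: a list with data frames
#'   `participants`, `measurements` and `problems`.
#' @export
load_cohort <- function(participants_csv, measurements_csv) {
  if (!file.exists(participants_csv)) stop("file not found: ", participants_csv)
  if (!file.exists(measurements_csv)) stop("file not found: ", measurements_csv)

  problems <- list()
  note <- function(file, line, msg)
    problems[[length(problems) + 1L]] <<- data.frame(
      file = file, line = line, message = msg, stringsAsFactors = FALSE)

  pp <- utils::read.csv(participants_csv, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(.participant_cols, names(pp))
  if (length(missing_cols))
    stop("participants file lacks columns: ", paste(missing_cols, collapse = ", "))

  keep <- rep(TRUE, nrow(pp))
  for (col in c("birth_date", "entry_date", "exit_date")) {
    d <- .parse_iso_date(pp[[col]])
    bad <- which(is.na(d) & !(col == "birth_date" & pp[[col]] == ""))
    for (i in bad) note("participants", i + 1L, paste0("malformed date in ", col))
    keep[bad] <- FALSE
    pp[[col]] <- d
  }
  bad_event <- which(!pp$event %in% c("death", "censored"))
  for (i in bad_event) note("participants", i + 1L,
                            "event must be 'death' or 'censored'")
  keep[bad_event] <- FALSE
  neg <- which(keep & !is.na(pp$exit_date) & !is.na(pp$entry_date) &
                 pp$exit_date < pp$entry_date)
  for (i in neg) note("participants", i + 1L, "exit_date before entry_date")
  keep[neg] <- FALSE
  pp <- pp[keep, , drop = FALSE]

  for (col in c("hiv2_flag", "non_hiv_cancer", "cvd", "cirrhosis", "aids",
                "hbsag_pos", "hcv_ab_pos"))
    pp[[col]] <- pp[[col]] %in% c("1", "TRUE", "true")
  pp$sex <- tolower(pp$sex)
  if (nrow(pp) && any(!pp$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  rownames(pp) <- NULL

  mm <- utils::read.csv(measurements_csv, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("participant_id", "analyte", "date", "value", "unit")
  if (nrow(mm) == 0L && !all(need %in% names(mm))) {
    mm <- data.frame(participant_id = character(), analyte = character(),
                     date = as.Date(character()), value = numeric(),
                     unit = character(), stringsAsFactors = FALSE)
  } else {
    missing_cols <- setdiff(need, names(mm))
    if (length(missing_cols))
      stop("measurements file lacks columns: ", paste(missing_cols, collapse = ", "))
    keep <- rep(TRUE, nrow(mm))
    unknown <- which(!mm$analyte %in% names(.analyte_units))
    for (i in unknown) note("measurements", i + 1L,
                            paste0("unknown analyte '", mm$analyte[i], "'"))
    keep[unknown] <- FALSE

    expected <- .analyte_units[mm$analyte]
    ok_unit <- mapply(function(u, e) {
      if (is.na(e)) TRUE else u %in% .unit_aliases[[e]]
    }, mm$unit, expected)
    bad_unit <- which(keep & !ok_unit)
    for (i in bad_unit) note("measurements", i + 1L,
      paste0("unit '", mm$unit[i], "' for ", mm$analyte[i],
             ": expected \"", expected[i], "\""))
    keep[bad_unit] <- FALSE

    d <- .parse_iso_date(mm$date)
    bad_date <- which(keep & is.na(d))
    for (i in bad_date) note("measurements", i + 1L, "malformed date")
    keep[bad_date] <- FALSE

    v <- suppressWarnings(as.numeric(mm$value))
    bad_val <- which(keep & (is.na(v) | v <= 0))
    for (i in bad_val) note("measurements", i + 1L,
                            "value must be a positive number")
    keep[bad_val] <- FALSE

    mm$date <- d
    mm$value <- v
    mm$unit <- ifelse(is.na(expected), mm$unit, as.character(expected))
    mm <- mm[keep, need, drop = FALSE]
    rownames(mm) <- NULL
  }

  problems <- if (length(problems)) do.call(rbind, problems) else
    data.frame(file = character(), line = integer(), message = character(),
               stringsAsFactors = FALSE)
  if (nrow(problems))
    warning(sprintf("%d row(s) rejected during cohort load; see $problems",
                    nrow(problems)))

  structure(list(participants = pp, measurements = mm, problems = problems),
            class = "hiv_cohort")
}

#' Write a cohort back to CSV files
#'
#' Inverse of [load_cohort()] on the documented schema: ISO dates, 0/1
#' booleans, canonical units. `load_cohort(write_cohort(x))` is the identity.
#'
#' @param cohort An `hiv_cohort`.
#' @param participants_csv,measurements_csv Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, participants_csv, measurements_csv) {
  stopifnot(inherits(cohort, "hiv_cohort"))
  pp <- cohort$participants
  out <- data.frame(
    participant_id = pp$participant_id, sex = pp$sex,
    birth_date = format(pp$birth_date, "%Y-%m-%d"),
    entry_date = format(pp$entry_date, "%Y-%m-%d"),
    exit_date = format(pp$exit_date, "%Y-%m-%d"),
    event = pp$event,
    hiv2_flag = as.integer(pp$hiv2_flag),
    non_hiv_cancer = as.integer(pp$non_hiv_cancer),
    cvd = as.integer(pp$cvd), cirrhosis = as.integer(pp$cirrhosis),
    aids = as.integer(pp$aids), hbsag_pos = as.integer(pp$hbsag_pos),
    hcv_ab_pos = as.integer(pp$hcv_ab_pos), stringsAsFactors = FALSE)
  utils::write.csv(out, participants_csv, row.names = FALSE, quote = FALSE)
  mm <- cohort$measurements
  mm$date <- format(mm$date, "%Y-%m-%d")
  utils::write.csv(mm, measurements_csv, row.names = FALSE, quote = FALSE)
  invisible(c(participants_csv, measurements_csv))
}

#' Exact fractional age at a date
#' @param birth_date,at Date vectors.
#' @return Age in years (365.25-day years).
#' @export
age_at <- function(birth_date, at) {
  as.numeric(at - birth_date) / DAYS_PER_YEAR
}

#' Screen participants for study eligibility
#'
#' A participant is included when aged 70 or older at entry, infected with
#' HIV-1 (no HIV-2 flag) and with at least one CD4 cell count within the
#' 12-month window before or after the entry date. The first failing rule is
#' recorded as the exclusion reason (`age`, `hiv2`, `no_cd4_in_window`).
#'
#' @param cohort An `hiv_cohort`.
#' @param window_months Width of the CD4 window on each side of entry.
#' @return Data frame with `participant_id`, `included`, `reason`.
#' @export
screen_eligibility <- function(cohort, window_months = 12) {
  stopifnot(inherits(cohort, "hiv_cohort"))
  pp <- cohort$participants
  mm <- cohort$measurements
  window_days <- window_months * DAYS_PER_MONTH
  cd4 <- mm[mm$analyte == "cd4", c("participant_id", "date")]
  cd4_by_id <- split(cd4$date, cd4$participant_id)

  age <- age_at(pp$birth_date, pp$entry_date)
  has_cd4 <- vapply(seq_len(nrow(pp)), function(i) {
    d <- cd4_by_id[[pp$participant_id[i]]]
    !is.null(d) && any(abs(as.numeric(d - pp$entry_date[i])) <= window_days)
  }, logical(1))

  reason <- rep(NA_character_, nrow(pp))
  reason[!has_cd4] <- "no_cd4_in_window"
  reason[pp$hiv2_flag] <- "hiv2"
  reason[age < 70] <- "age"
  data.frame(participant_id = pp$participant_id,
             included = is.na(reason), reason = reason,
             stringsAsFactors = FALSE)
}

#' Compute truncated follow-up time and event indicator
#'
#' Follow-up runs from entry to the earliest of exit, completion of the
#' horizon (default 5 years) and the administrative study end. Deaths
#' occurring after the truncation point are recoded as censored at the
#' truncation point.
#'
#' @param entry_date,exit_date Date vectors.
#' @param event Character vector, `"death"` or `"censored"`.
#' @param study_end Administrative censoring date.
#' @param horizon_years Follow-up horizon in years.
#' @return Data frame with `time_years` (>= 0) and `event` (0/1).
#' @export
compute_followup <- function(entry_date, exit_date, event,
                             study_end = as.Date("2019-12-31"),
                             horizon_years = 5) {
  study_end <- as.Date(study_end)
  dur <- as.numeric(exit_date - entry_date)
  if (any(dur < 0, na.rm = TRUE)) stop("negative follow-up duration")
  cap <- pmin(horizon_years * DAYS_PER_YEAR,
              as.numeric(study_end - entry_date))
  time <- pmin(dur, cap)
  ev <- as.integer(event == "death" & dur <= cap + 1e-9)
  data.frame(time_years = time / DAYS_PER_YEAR, event = ev)
}

#' Select the baseline value of an analyte
#'
#' Among measurements within `window_months` before or after the entry date,
#' returns the one closest to entry. When a before-entry and an after-entry
#' measurement are exactly equidistant, the after-entry value is preferred
#' (`prefer_after = TRUE`), reflecting that post-entry values better represent
#' the state at entry. Two same-day measurements resolve to the last listed,
#' with a warning.
#'
#' @param dates Date vector of measurements.
#' @param values Numeric vector of the same length.
#' @param entry Entry date.
#' @param window_months Window half-width in months (30.4375-day months);
#'   `Inf` disables the window.
#' @param prefer_after Break exact distance ties toward the after-entry value.
#' @return List with `value`, `date` and `side` (`"before"`, `"after"`,
#'   `"none"`); `value` is `NA` when no measurement falls in the window.
#' @export
select_baseline_value <- function(dates, values, entry, window_months = 12,
                                  prefer_after = TRUE) {
  stopifnot(length(dates) == length(values))
  empty <- list(value = NA_real_, date = as.Date(NA), side = "none")
  if (length(dates) == 0L) return(empty)
  offset <- as.numeric(dates - entry)
  window_days <- window_months * DAYS_PER_MONTH
  in_win <- abs(offset) <= window_days
  if (!any(in_win)) return(empty)
  dates <- dates[in_win]; values <- values[in_win]; offset <- offset[in_win]
  dist <- abs(offset)
  best <- dist == min(dist)
  idx <- which(best)
  if (length(idx) > 1L) {
    after <- offset[idx] >= 0
    if (prefer_after && any(after)) idx <- idx[after]
    if (length(idx) > 1L) {
      warning("multiple same-distance measurements; taking the last listed")
      idx <- idx[length(idx)]
    }
  }
  list(value = values[idx], date = dates[idx],
       side = if (offset[idx] >= 0) "after" else "before")
}

#' Select weight and height for BMI
#'
#' In `windowed` mode the weight obeys the same +/-12-month rule as other
#' analytes; in `unrestricted` mode the globally closest dated weight is used,
#' with no time limit (BMI is the one covariate exempted from the window, to
#' avoid excluding stable patients who rarely have their weight re-measured).
#' Height is always the closest available measurement regardless of mode.
#'
#' @param weight_dates,weight_values,height_dates,height_values Measurement
#'   series.
#' @param entry Entry date.
#' @param mode `"windowed"` or `"unrestricted"`.
#' @param window_months Window half-width for `windowed` mode.
#' @return List with `weight` and `height` (`NA` when unresolvable).
#' @export
select_bmi_inputs <- function(weight_dates, weight_values,
                              height_dates, height_values, entry,
                              mode = c("unrestricted", "windowed"),
                              window_months = 12) {
  mode <- match.arg(mode)
  w <- select_baseline_value(weight_dates, weight_values, entry,
                             window_months = if (mode == "windowed")
                               window_months else Inf)
  h <- select_baseline_value(height_dates, height_values, entry,
                             window_months = Inf)
  list(weight = w$value, height = h$value)
}

#' Resolve baseline covariates for every included participant
#'
#' Applies [screen_eligibility()], then resolves one baseline value per
#' analyte per participant with [select_baseline_value()] (BMI inputs with
#' [select_bmi_inputs()]), computes truncated follow-up, and attaches the
#' derived clinical quantities ([derive_covariates()]).
#'
#' @param cohort An `hiv_cohort`.
#' @param study_end Administrative censoring date.
#' @param horizon_years Follow-up horizon in years.
#' @param window_months Baseline window half-width in months.
#' @param bmi_mode `"unrestricted"` (default, no time limit on weight) or
#'   `"windowed"`.
#' @return Data frame, one row per included participant, with resolved
#'   analytes, comorbidity flags, follow-up (`time_years`, `event`) and
#'   derived covariates. Attribute `screening` carries the eligibility table.
#' @export
resolve_baseline <- function(cohort, study_end = as.Date("2019-12-31"),
                             horizon_years = 5, window_months = 12,
                             bmi_mode = c("unrestricted", "windowed")) {
  stopifnot(inherits(cohort, "hiv_cohort"))
  bmi_mode <- match.arg(bmi_mode)
  elig <- screen_eligibility(cohort, window_months)
  pp <- cohort$participants[elig$included, , drop = FALSE]
  mm <- cohort$measurements
  mm_by_id <- split(mm, mm$participant_id)

  analytes <- c("cd4", "cd4_nadir", "hiv_rna", "hemoglobin", "creatinine",
                "ast", "alt", "platelets", "wbc", "albumin")
  rows <- lapply(seq_len(nrow(pp)), function(i) {
    id <- pp$participant_id[i]
    entry <- pp$entry_date[i]
    sub <- mm_by_id[[id]]
    vals <- vapply(analytes, function(a) {
      s <- sub[sub$analyte == a, , drop = FALSE]
      if (is.null(sub) || nrow(s) == 0L) return(NA_real_)
      select_baseline_value(s$date, s$value, entry, window_months)$value
    }, numeric(1))
    wsub <- sub[sub$analyte == "weight", , drop = FALSE]
    hsub <- sub[sub$analyte == "height", , drop = FALSE]
    bi <- select_bmi_inputs(
      if (is.null(sub)) as.Date(character()) else wsub$date,
      if (is.null(sub)) numeric() else wsub$value,
      if (is.null(sub)) as.Date(character()) else hsub$date,
      if (is.null(sub)) numeric() else hsub$value,
      entry, mode = bmi_mode, window_months = window_months)
    c(vals, weight = bi$weight, height = bi$height)
  })
  vals <- do.call(rbind, rows)

  fu <- compute_followup(pp$entry_date, pp$exit_date, pp$event,
                         study_end, horizon_years)
  base <- data.frame(
    participant_id = pp$participant_id, sex = pp$sex,
    age = age_at(pp$birth_date, pp$entry_date),
    non_hiv_cancer = pp$non_hiv_cancer, cvd = pp$cvd,
    cirrhosis = pp$cirrhosis, aids = pp$aids,
    hbv = pp$hbsag_pos, hcv = pp$hcv_ab_pos,
    vals, time_years = fu$time_years, event = fu$event,
    stringsAsFactors = FALSE)
  rownames(base) <- NULL
  base <- derive_covariates(base)
  attr(base, "screening") <- elig
  base
}
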