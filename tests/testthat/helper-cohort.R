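# Builders for small in-code cohort fixtures.

participant_row <- function(id = "P1", sex = "male",
                            birth = "1946-01-01", entry = "2015-01-01",
                            exit = "2019-01-01", event = "censored",
                            hiv2 = 0, cancer = 0, cvd = 0, cirrhosis = 0,
                            aids = 0, hbsag = 0, hcv = 0) {
  data.frame(participant_id = id, sex = sex, birth_date = birth,
             entry_date = entry, exit_date = exit, event = event,
             hiv2_flag = hiv2, non_hiv_cancer = cancer, cvd = cvd,
             cirrhosis = cirrhosis, aids = aids, hbsag_pos = hbsag,
             hcv_ab_pos = hcv, stringsAsFactors = FALSE)
}

measurement_row <- function(id = "P1", analyte = "cd4", date = "2015-01-15",
                            value = 550, unit = NULL) {
  units <- c(cd4 = "cells/mm3", cd4_nadir = "cells/mm3",
             hiv_rna = "copies/mL", hemoglobin = "g/dL",
             creatinine = "umol/L", ast = "U/L", alt = "U/L",
             platelets = "10^3/uL", wbc = "10^3/uL", albumin = "g/L",
             weight = "kg", height = "m")
  if (is.null(unit)) unit <- unname(units[analyte])
  data.frame(participant_id = id, analyte = analyte, date = date,
             value = value, unit = unit, stringsAsFactors = FALSE)
}

write_cohort_files <- function(participants, measurements,
                               dir = withr::local_tempdir(.local_envir = parent.frame())) {
  pp <- file.path(dir, "participants.csv")
  mp <- file.path(dir, "measurements.csv")
  utils::write.csv(participants, pp, row.names = FALSE, quote = FALSE)
  utils::write.csv(measurements, mp, row.names = FALSE, quote = FALSE)
  list(participants = pp, measurements = mp, dir = dir)
}

empty_measurements <- function() {
  data.frame(participant_id = character(), analyte = character(),
             date = character(), value = numeric(), unit = character(),
             stringsAsFactors = FALSE)
}

# Brute-force O(n^2) pair-enumeration oracle for Harrell's C; implements the
# comparability and orientation rules directly, one pair at a time.
concordance_oracle <- function(time, event, marker) {
  n <- length(time)
  conc <- comp <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      a <- i; b <- j
      if (time[b] < time[a] || (time[b] == time[a] && event[b] == 1 && event[a] == 0)) {
        a <- j; b <- i
      }
      # a now has the shorter time (or is the death in a death/censored tie)
      comparable <- (event[a] == 1) &&
        (time[a] < time[b] || (time[a] == time[b] && event[b] == 0))
      if (!comparable) next
      comp <- comp + 1
      if (marker[a] > marker[b]) conc <- conc + 1
      else if (marker[a] == marker[b]) conc <- conc + 0.5
    }
  }
  if (comp == 0) return(NA_real_)
  conc / comp
}

# Exact Cox partial log-likelihood for untied event times (Efron = Breslow
# when there are no ties), used as a grid-search oracle.
cox_loglik_untied <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
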