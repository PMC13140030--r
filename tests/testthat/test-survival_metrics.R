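test_that("Kaplan-Meier reproduces the hand-computed product-limit steps", {
  fx <- generate_worked_fixtures()$km
  km <- kaplan_meier(fx$time, fx$event)
  expect_equal(km$surv, c(0.8, 0.8 * 2/3, 0.8 * 2/3 * 1/2), tolerance = 1e-6)
  expect_equal(km$surv, c(0.8, 0.5333, 0.2667), tolerance = 1e-3)
  # step heights are d_j / n_j exactly
  expect_equal(km$n_event / km$n_risk, c(1/5, 1/3, 1/2))
  # no events: survival stays at 1
  km0 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_equal(km_at(km0, 3), 1)
  # all distinct deaths: empirical survival function
  km1 <- kaplan_meier(1:4, rep(1, 4))
  expect_equal(km1$surv, c(0.75, 0.5, 0.25, 0))
  expect_error(kaplan_meier(numeric(0), integer(0)), "empty")
})

test_that("KM tracks the true exponential survival within Greenwood tolerance", {
  set.seed(21)
  lambda <- 0.3
  t <- rexp(1500, lambda)
  cens <- runif(1500, 0, 8)
  time <- pmin(t, cens); event <- as.integer(t <= cens)
  km <- kaplan_meier(time, event)
  fit <- attr(km, "fit")
  s <- summary(fit, times = c(1, 2, 3))
  expect_true(all(abs(s$surv - exp(-lambda * c(1, 2, 3))) < 3.5 * s$std.err))
  # confidence bounds stay inside [0, 1]
  expect_true(all(km$lower >= 0 & km$upper <= 1, na.rm = TRUE))
})

test_that("person-time rate arithmetic and scaling", {
  # 221 deaths over exactly 5598 person-years
  time <- rep(5598 / 400, 400)
  event <- c(rep(1, 221), rep(0, 179))
  r <- person_time_rate(time, event)
  expect_equal(r$person_years, 5598)
  expect_equal(r$deaths, 221)
  expect_equal(r$rate_per_100py, 3.95)
  expect_equal(person_time_rate(c(1, 2), c(0, 0))$rate_per_100py, 0)
  # doubling every follow-up time halves the rate
  r2 <- person_time_rate(2 * time, event)
  expect_equal(r2$rate_raw, r$rate_raw / 2)
  expect_error(person_time_rate(numeric(0), integer(0)), "empty")
})

test_that("Harrell's C on worked fixtures", {
  fx <- generate_worked_fixtures()$concordance
  res <- harrells_c(fx$time, fx$event, fx$marker)
  expect_equal(res$c, 1)
  expect_equal(res$comparable, 3)
  expect_equal(res$concordant, 3)
  # identical markers: all ties, C = 1/2
  expect_equal(harrells_c(c(1, 2, 3), c(1, 1, 1), c(2, 2, 2))$c, 0.5)
  # pair counts are consistent
  set.seed(31)
  t <- rexp(40); e <- rbinom(40, 1, 0.6); m <- sample(0:5, 40, replace = TRUE)
  res <- harrells_c(t, e, m)
  expect_equal(res$concordant + res$discordant + res$tied_marker,
               res$comparable)
  expect_error(harrells_c(1, 1, 1), "two subjects")
  expect_error(harrells_c(c(1, 2), c(0, 0), c(1, 2)), "event")
})

test_that("Harrell's C equals the brute-force pair-enumeration oracle", {
  set.seed(42)
  for (k in 1:60) {
    n <- sample(5:50, 1)
    time <- round(rexp(n, 0.3), sample(c(0, 1, 3), 1))  # induce some ties
    time <- pmax(time, 0.01)
    event <- rbinom(n, 1, runif(1, 0.3, 1))
    if (sum(event) == 0) event[1] <- 1L
    marker <- sample(0:8, n, replace = TRUE)
    oracle <- concordance_oracle(time, event, marker)
    if (is.na(oracle)) next
    expect_equal(harrells_c(time, event, marker)$c, oracle, tolerance = 1e-12)
  }
})

test_that("C agrees with survival::concordance and reverses under orientation flip", {
  set.seed(17)
  n <- 200
  time <- rexp(n, 0.2); event <- rbinom(n, 1, 0.7)
  marker <- time * -0.5 + rnorm(n)  # continuous, no marker ties
  res <- harrells_c(time, event, marker)
  ref <- survival::concordance(survival::Surv(time, event) ~ marker,
                               reverse = TRUE)
  expect_equal(res$c, as.numeric(ref$concordance), tolerance = 1e-10)
  flipped <- harrells_c(time, event, -marker)
  expect_equal(flipped$c, 1 - res$c, tolerance = 1e-12)
  # jackknife CI spans the estimate
  expect_lt(res$lower, res$c); expect_gt(res$upper, res$c)
})

test_that("subgroup discrimination restricts exactly and skips degenerate groups", {
  set.seed(13)
  n <- 120
  time <- rexp(n, 0.2); event <- rbinom(n, 1, 0.6)
  marker <- sample(0:30, n, replace = TRUE)
  whole <- harrells_c(time, event, marker)
  g <- rep(c("a", "b"), length.out = n)
  tab <- subgroup_discrimination(time, event, marker,
                                 list(all = rep("cohort", n), half = g))
  expect_equal(tab$c[tab$level == "cohort"], whole$c)
  for (lev in c("a", "b")) {
    idx <- g == lev
    expect_equal(tab$c[tab$level == lev],
                 concordance_oracle(time[idx], event[idx], marker[idx]),
                 tolerance = 1e-12)
  }
  # degenerate subgroup (no events) is skipped with a warning
  g2 <- ifelse(event == 1, "ev", "noev")
  expect_warning(
    tab2 <- subgroup_discrimination(time, event, marker, list(s = g2)),
    "skipped")
  expect_false("noev" %in% tab2$level)
})

test_that("Cox risk-group fit matches a grid-search partial-likelihood oracle", {
  # two groups, untied event times: Efron = Breslow = plain partial likelihood
  time <- c(1, 2, 3, 4, 5, 6, 7, 8)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  group <- factor(c("low", "high", "low", "high", "low", "high", "high", "low"),
                  levels = c("low", "high"))
  fit <- cox_risk_groups(time, event, group)
  x <- as.integer(group == "high")
  grid <- seq(-3, 3, by = 0.001)
  ll <- vapply(grid, cox_loglik_untied, numeric(1), time = time,
               event = event, x = x)
  expect_equal(fit$coefficients$beta, grid[which.max(ll)], tolerance = 2e-3)
  # the returned maximum is at least as good as any grid point
  expect_gte(cox_loglik_untied(fit$coefficients$beta, time, event, x) + 1e-9,
             max(ll))
  expect_equal(fit$coefficients$hr, exp(fit$coefficients$beta))
})

test_that("Cox HR is 1 under symmetry and recovers a tripled hazard", {
  # identical event/censoring patterns in both groups
  time <- rep(c(1, 2, 3, 4), 2)
  event <- rep(c(1, 0, 1, 1), 2)
  group <- rep(c("low", "high"), each = 4)
  fit <- cox_risk_groups(time, event, group)
  expect_equal(fit$coefficients$hr, 1, tolerance = 1e-8)
  # n = 2000 exponential simulation with hazard ratio 3
  set.seed(77)
  g <- rep(c("ref", "exp"), each = 1000)
  rate <- ifelse(g == "exp", 0.3, 0.1)
  t <- rexp(2000, rate); cens <- pmin(runif(2000, 0, 10), 5)
  fit <- cox_risk_groups(pmin(t, cens), as.integer(t <= cens),
                         factor(g, levels = c("ref", "exp")))
  expect_gt(fit$coefficients$upper, 3)
  expect_lt(fit$coefficients$lower, 3)
  expect_equal(fit$coefficients$hr, 3, tolerance = 0.15)
  # a group with no events is flagged unstable
  expect_error(cox_risk_groups(c(1, 2, 3, 4), c(0, 0, 0, 0),
                               c("a", "a", "b", "b")), "events")
})

test_that("calibration intercept has the closed-form MLE and errors on bad hazards", {
  # sum(d) = sum(H): alpha-hat = log(2/2) = 0
  fx <- generate_worked_fixtures()$calibration
  res <- calibration_poisson(time_years = rep(1, 3), event = fx$event,
                             prognostic_index = rep(0, 3),
                             base_cumhaz = fx$cumhaz)
  expect_equal(res$intercept, 0, tolerance = 1e-8)
  # general closed form log(sum d / sum H)
  set.seed(3)
  d <- rbinom(50, 1, 0.3); H <- runif(50, 0.05, 0.8); pi <- rnorm(50, 0, 0.3)
  res <- calibration_poisson(rep(1, 50), d, pi, H)
  expect_equal(res$intercept, log(sum(d) / sum(exp(pi) * H)), tolerance = 1e-7)
  expect_error(calibration_poisson(1, 1, 0, -0.1), "positive")
})

test_that("calibration recovers (0, 1) from self-generated data and -log 2 under mis-scaling", {
  set.seed(55)
  n <- 4000
  pi <- rnorm(n, -2.5, 0.8)
  t_death <- rexp(n, exp(pi) / 5)      # cumulative hazard exp(pi) * t/5
  time <- pmin(t_death, 5)
  event <- as.integer(t_death <= 5)
  base <- time / 5
  res <- calibration_poisson(time, event, pi, base)
  expect_equal(res$intercept, 0, tolerance = 0.1)
  expect_equal(res$slope, 1, tolerance = 0.1)
  expect_true(res$slope_ci[1] < 1 && res$slope_ci[2] > 1)
  # doubling the predicted hazards shifts the intercept to -log 2
  res2 <- calibration_poisson(time, event, pi + log(2), base)
  expect_equal(res2$intercept, -log(2), tolerance = 0.1)
  expect_equal(res2$slope, res$slope, tolerance = 1e-6)
})

test_that("per-group calibration compares KM at 5 years with the mapping", {
  def <- dataids_definition()
  # moderate group built so KM(5) is exactly 0.85: 15/100 die, rest censored at 5
  time <- c(runif(15, 0.5, 4.5), rep(5, 85))
  event <- c(rep(1, 15), rep(0, 85))
  group <- rep("moderate", 100)
  w <- capture_warnings(tab <- calibration_by_group(time, event, group, def))
  expect_length(w, 3)  # the three absent groups are each reported
  expect_true(all(grepl("no subjects", w)))
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$predicted, 0.90)
  expect_equal(tab$observed, 0.85, tolerance = 1e-9)
  expect_equal(tab$difference, 0.05, tolerance = 1e-9)
  # an all-censored group observes survival 1
  t2 <- suppressWarnings(
    calibration_by_group(rep(c(2, 5), 10), rep(0, 20), rep("low", 20), def))
  expect_equal(t2$observed[t2$group == "low"], 1)
})

test_that("group-level calibration differences vanish when simulating from predictions", {
  res <- generate_cohort(synthetic_config(n = 3000, seed = 23,
                                          hazard_model = "group_bridge",
                                          ltfu_fraction = 0))
  f <- write_cohort_files(res$participants, res$measurements)
  scored <- score_cohort(resolve_baseline(load_cohort(f$participants,
                                                      f$measurements)),
                         scores = "dataids")
  scored$time_years <- ensure_positive_time(scored$time_years)
  ok <- scored$dataids_computable
  tab <- calibration_by_group(scored$time_years[ok], scored$event[ok],
                              scored$dataids_group[ok])
  # within ~3 standard errors of the observed KM estimate (from its CI width)
  se <- (tab$obs_upper - tab$obs_lower) / (2 * qnorm(0.975))
  expect_true(all(tab$abs_difference < 3 * se + 0.005))
})

test_that("score comparison restricts to common complete cases", {
  res <- generate_cohort(synthetic_config(n = 300, seed = 15))
  f <- write_cohort_files(res$participants, res$measurements)
  scored <- score_cohort(resolve_baseline(load_cohort(f$participants,
                                                      f$measurements)))
  scored$time_years <- ensure_positive_time(scored$time_years)
  cmp <- compare_scores(scored, "dataids", "vacs2")
  common <- scored$dataids_computable & scored$vacs2_computable
  expect_equal(cmp$n_common, sum(common))
  # the C values equal the oracle on the restricted set
  sub <- scored[common, ]
  expect_equal(cmp$c_a$c, concordance_oracle(sub$time_years, sub$event,
                                             sub$dataids_total),
               tolerance = 1e-12)
  expect_equal(cmp$c_b$c, concordance_oracle(sub$time_years, sub$event,
                                             sub$vacs2_total),
               tolerance = 1e-12)
  # comparing a score with itself yields identical C
  cmp2 <- compare_scores(scored, "dataids", "dataids")
  expect_equal(cmp2$c_a$c, cmp2$c_b$c)
})
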