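# Score engines: evaluate categorical points tables (Dat'AIDS, VACS 1.0) and
# continuous scores (VACS 2.0) from resolved + derived baseline covariates,
# with risk grouping, group-level survival prediction, the normal-value
# imputation policy and completeness accounting.

.category_points <- function(comp, value) {
  if (is.na(value)) return(NA_real_)
  cats <- comp$categories
  if (!is.null(cats[[1L]]$value)) {
    for (k in cats) if (identical(k$value, as.logical(value)))
      return(as.numeric(k$points))
    stop("value outside definition domain for component '", comp$covariate, "'")
  }
  for (k in cats) {
    lo <- if (is.null(k$min)) -Inf else as.numeric(k$min)
    hi <- if (is.null(k$max)) Inf else as.numeric(k$max)
    if (value >= lo && value < hi) return(as.numeric(k$points))
  }
  stop("value ", value, " outside definition domain for component '",
       comp$covariate, "'")
}

#' Evaluate a score for one subject
#'
#' For a categorical definition, sums the per-component category points; for a
#' continuous definition, sums clamped linear contributions
#' `slope * (clamp(x) - ref)` (inputs range-clamped to the asset's stated
#' domain before evaluation). A subject is `computable` only when no required
#' covariate is missing; missing components are listed by name.
#'
#' @param def A `score_definition`.
#' @param covariates Named list or one-row data frame holding the covariates
#'   the definition names (e.g. `age`, `cd4`, `egfr`, `anemia`, ...).
#' @return List of class `score_result`: `total`, `breakdown` (named numeric),
#'   `missing_components`, `computable`, plus `risk_group` and
#'   `predicted_survival_5y` when the definition defines risk groups.
#' @export
evaluate_score <- function(def, covariates) {
  stopifnot(inherits(def, "score_definition"))
  covariates <- as.list(covariates)
  breakdown <- numeric(0)
  missing_components <- character(0)
  for (comp in def$components) {
    x <- covariates[[comp$covariate]]
    x <- if (is.null(x)) NA else x
    if (def$type == "categorical") {
      pts <- .category_points(comp, x)
    } else {
      if (is.na(x)) pts <- NA_real_ else {
        x <- as.numeric(x)
        lo <- as.numeric(comp$clamp[[1L]]); hi <- as.numeric(comp$clamp[[2L]])
        pts <- as.numeric(comp$slope) * (min(max(x, lo), hi) - as.numeric(comp$ref))
      }
    }
    if (is.na(pts)) missing_components <- c(missing_components, comp$covariate)
    breakdown[comp$covariate] <- pts
  }
  computable <- length(missing_components) == 0L
  res <- list(total = if (computable) sum(breakdown) else NA_real_,
              breakdown = breakdown,
              missing_components = missing_components,
              computable = computable)
  if (computable && !is.null(def$risk_groups)) {
    rg <- assign_risk_group(res$total, def)
    res$risk_group <- rg$risk_group
    res$predicted_survival_5y <- rg$predicted_survival_5y
  }
  class(res) <- "score_result"
  res
}

#' @export
print.score_result <- function(x, ...) {
  if (x$computable) {
    cat(sprintf("score total: %g\n", x$total))
    if (!is.null(x$risk_group))
      cat(sprintf("risk group: %s (predicted 5-year survival %.2f)\n",
                  x$risk_group, x$predicted_survival_5y))
  } else {
    cat("score not computable; missing:",
        paste(x$missing_components, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Map score totals to risk groups and predicted 5-year survival
#'
#' Risk groups are defined by ordered integer cut-points (scores `0-3` low,
#' `4-13` moderate, `14-19` high, `>=20` very high for the packaged Dat'AIDS
#' definition) and each group carries a published 5-year predicted survival
#' probability (0.95 / 0.90 / 0.80 / 0.53).
#'
#' @param total Numeric vector of score totals (>= 0).
#' @param def A `score_definition` with a `risk_groups` block.
#' @return Data-frame-like list with `risk_group` (character) and
#'   `predicted_survival_5y`; vectorised over `total`.
#' @export
assign_risk_group <- function(total, def = dataids_definition()) {
  rg <- def$risk_groups
  if (is.null(rg)) stop("definition '", def$name, "' has no risk groups")
  cut <- as.numeric(unlist(rg$cutpoints))
  labels <- unlist(rg$labels)
  idx <- findInterval(total, cut) + 1L
  grp <- labels[idx]
  pred <- as.numeric(unlist(rg$predicted_survival_5y[grp]))
  pred[is.na(grp)] <- NA_real_
  list(risk_group = grp, predicted_survival_5y = pred)
}

#' Predicted survival at intermediate times
#'
#' When the definition carries the derivation baseline survival
#' (`baseline_survival$s0_5y` and coefficient `lambda`), the continuous
#' prediction `S(t) = S0(5)^(exp(lambda * total) * t/5)` is used. Otherwise
#' the group-level mapping is bridged with a constant-hazard interpolation
#' `S_g(t) = S_g(5)^(t/5)`, which is exact at t = 5 and reproducible from the
#' published group-level predictions alone.
#'
#' @param def A `score_definition` with risk groups.
#' @param total Score total(s).
#' @param t Time in years, in (0, 5].
#' @return Predicted survival probability, vectorised over `total` and `t`.
#' @export
predicted_survival_curve <- function(def, total, t) {
  if (any(t <= 0)) stop("t must be positive")
  if (any(t > 5 + 1e-9)) stop("t must not exceed the 5-year horizon")
  exp(-predicted_cumhaz(def, total, t)$cumhaz)
}

#' Predicted cumulative hazard decomposition
#'
#' Returns the components the Poisson calibration model consumes: the
#' predicted cumulative hazard `cumhaz` at time `t`, its baseline part
#' `base_cumhaz` (t/5 under the constant-hazard bridge) and the prognostic
#' index `pi` such that `cumhaz = exp(pi) * base_cumhaz`.
#'
#' @inheritParams predicted_survival_curve
#' @return List with `cumhaz`, `base_cumhaz`, `pi`.
#' @export
predicted_cumhaz <- function(def, total, t) {
  bs <- def$baseline_survival
  base_cumhaz <- t / 5
  if (!is.null(bs)) {
    pi <- log(-log(as.numeric(bs$s0_5y))) + as.numeric(bs$lambda) * total
  } else {
    rg <- assign_risk_group(total, def)
    pi <- log(-log(rg$predicted_survival_5y))
  }
  list(cumhaz = exp(pi) * base_cumhaz, base_cumhaz = base_cumhaz, pi = pi)
}

#' Normal-value imputation for missing albumin, ALT and AST
#'
#' Sets missing albumin to 4 g/dL (40 g/L), missing ALT to 25 IU/L and
#' missing AST to 20 IU/L, leaving every other field untouched, and records
#' provenance flags (`albumin_imputed`, `alt_imputed`, `ast_imputed`).
#' Derived quantities that depend on the three analytes (FIB-4, albumin in
#' g/dL) are recomputed where they were previously missing. Idempotent.
#'
#' @param base Baseline data frame (see [resolve_baseline()]).
#' @return `base` with imputed values and provenance flags.
#' @export
impute_normal_values <- function(base) {
  base$albumin_imputed <- is.na(base$albumin)
  base$alt_imputed <- is.na(base$alt)
  base$ast_imputed <- is.na(base$ast)
  base$albumin[base$albumin_imputed] <- 40
  base$alt[base$alt_imputed] <- 25
  base$ast[base$ast_imputed] <- 20
  base$albumin_gdl <- base$albumin / 10
  redo <- is.na(base$fib4)
  base$fib4[redo] <- fib4(base$age[redo], base$ast[redo], base$alt[redo],
                          base$platelets[redo])
  base
}

#' Score a cohort
#'
#' Evaluates the requested scores for every row of a resolved baseline table.
#' The Dat'AIDS score uses the banded/flagged covariates (age, CD4, non-HIV
#' cancer, CVD, eGFR, cirrhosis, low BMI, anaemia, HCV); VACS 1.0 the
#' categorical index over age, CD4, HIV-RNA, haemoglobin, FIB-4, eGFR and
#' HCV; VACS 2.0 the continuous score additionally using albumin, white
#' cells, platelets and BMI. With `impute = "normal_values"` the VACS 2.0
#' inputs albumin/ALT/AST are imputed to normal values first (the other
#' scores are unaffected).
#'
#' @param base Baseline data frame from [resolve_baseline()] (or the
#'   generator).
#' @param scores Character subset of `c("dataids", "vacs1", "vacs2")`.
#' @param impute `"none"` or `"normal_values"` (applies to VACS 2.0 only).
#' @param definitions Named list of `score_definition` objects; defaults to
#'   the packaged assets.
#' @return `base` with, per score `s`, columns `<s>_total` and
#'   `<s>_computable`, plus `dataids_group` and `dataids_pred5` when the
#'   Dat'AIDS score is requested.
#' @export
score_cohort <- function(base, scores = c("dataids", "vacs1", "vacs2"),
                         impute = c("none", "normal_values"),
                         definitions = NULL) {
  impute <- match.arg(impute)
  scores <- match.arg(scores, several.ok = TRUE)
  if (is.null(definitions))
    definitions <- list(dataids = dataids_definition(),
                        vacs1 = vacs1_definition(),
                        vacs2 = vacs2_definition())
  vacs2_base <- if (impute == "normal_values") impute_normal_values(base) else base

  for (s in scores) {
    def <- definitions[[s]]
    src <- if (s == "vacs2") vacs2_base else base
    res <- lapply(seq_len(nrow(src)), function(i)
      evaluate_score(def, src[i, , drop = FALSE]))
    base[[paste0(s, "_total")]] <- vapply(res, `[[`, numeric(1), "total")
    base[[paste0(s, "_computable")]] <- vapply(res, `[[`, logical(1), "computable")
    if (s == "dataids" && !is.null(def$risk_groups)) {
      rg <- assign_risk_group(base$dataids_total, def)
      base$dataids_group <- factor(rg$risk_group,
                                   levels = unlist(def$risk_groups$labels))
      base$dataids_pred5 <- rg$predicted_survival_5y
    }
  }
  base
}

#' Completeness accounting for computed scores
#'
#' Counts, per score, the subjects for whom the score is computable, and the
#' pairwise common-complete counts against the first score listed (the
#' head-to-head comparisons are conducted on subjects for whom both scores
#' can be calculated simultaneously).
#'
#' @param scored Data frame from [score_cohort()].
#' @param scores Scores to tabulate (must have `<s>_computable` columns).
#' @return Data frame with `item`, `n_computable`, `fraction`.
#' @export
completeness_table <- function(scored, scores = c("dataids", "vacs1", "vacs2")) {
  n <- nrow(scored)
  comp <- lapply(scores, function(s) scored[[paste0(s, "_computable")]])
  names(comp) <- scores
  rows <- data.frame(item = scores,
                     n_computable = vapply(comp, sum, integer(1)),
                     stringsAsFactors = FALSE)
  if (length(scores) > 1L) {
    ref <- scores[1L]
    for (s in scores[-1L]) {
      rows <- rbind(rows, data.frame(
        item = paste0("both_", ref, "_", s),
        n_computable = sum(comp[[ref]] & comp[[s]]),
        stringsAsFactors = FALSE))
    }
  }
  rows$fraction <- rows$n_computable / n
  rownames(rows) <- NULL
  rows
}
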