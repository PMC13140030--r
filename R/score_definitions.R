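#' Load a score definition asset
#'
#' Score definitions are structured JSON files describing either a categorical
#' points table (a list of components, each with disjoint category intervals
#' and non-negative points) or a continuous score (clamped linear
#' contributions). Categorical definitions may additionally carry risk-group
#' cut-points, a group-level mapping to 5-year predicted survival, and an
#' optional derivation baseline-survival slot (`baseline_survival`, with
#' elements `s0_5y` and `lambda`) used for continuous survival prediction when
#' available.
#'
#' The packaged definitions are available through [dataids_definition()],
#' [vacs1_definition()] and [vacs2_definition()].
#'
#' @param path Path to a JSON score definition.
#' @return An object of class `score_definition`.
#' @seealso [score_cohort()], [assign_risk_group()]
#' @export
load_score_definition <- function(path) {
  if (!file.exists(path)) stop("score definition not found: ", path)
  def <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_score_definition(def)
  class(def) <- "score_definition"
  def
}

#' Validate the structure of a score definition
#'
#' Checks the schema invariants: known type, components with either interval
#' categories (disjoint, covering, with explicit open ends) or boolean
#' categories, non-negative points, strictly increasing risk cut-points and
#' predicted survival probabilities in (0, 1].
#'
#' @param def A list parsed from a score definition JSON file.
#' @return Invisibly `TRUE`; stops with a descriptive error otherwise.
#' @export
validate_score_definition <- function(def) {
  stopifnot(is.list(def))
  if (is.null(def$name) || is.null(def$type))
    stop("score definition must have 'name' and 'type'")
  if (!def$type %in% c("categorical", "continuous"))
    stop("unknown score definition type: ", def$type)
  if (length(def$components) == 0L) stop("score definition has no components")

  for (comp in def$components) {
    if (is.null(comp$covariate)) stop("component without covariate name")
    if (def$type == "continuous") {
      if (is.null(comp$slope) || is.null(comp$ref) || length(comp$clamp) != 2L)
        stop("continuous component '", comp$covariate,
             "' needs slope, ref and a length-2 clamp")
      next
    }
    cats <- comp$categories
    if (length(cats) == 0L)
      stop("component '", comp$covariate, "' has no categories")
    pts <- vapply(cats, function(k) as.numeric(k$points), numeric(1))
    if (any(!is.finite(pts)) || any(pts < 0))
      stop("component '", comp$covariate, "' has invalid points")
    if (!is.null(cats[[1L]]$value)) {
      vals <- vapply(cats, function(k) isTRUE(k$value), logical(1))
      if (length(cats) != 2L || sum(vals) != 1L)
        stop("boolean component '", comp$covariate,
             "' must have exactly one TRUE and one FALSE category")
    } else {
      lo <- vapply(cats, function(k) if (is.null(k$min)) -Inf else as.numeric(k$min), numeric(1))
      hi <- vapply(cats, function(k) if (is.null(k$max)) Inf else as.numeric(k$max), numeric(1))
      o <- order(lo)
      if (any(hi[o] <= lo[o]))
        stop("component '", comp$covariate, "' has an empty interval")
      # intervals are [min, max): they must tile the covariate domain
      if (any(abs(lo[o][-1L] - hi[o][-length(hi)]) > 1e-9))
        stop("component '", comp$covariate,
             "' categories do not partition the domain")
    }
  }

  rg <- def$risk_groups
  if (!is.null(rg)) {
    cut <- as.numeric(unlist(rg$cutpoints))
    if (any(diff(cut) <= 0)) stop("risk cut-points must be strictly increasing")
    if (length(rg$labels) != length(cut) + 1L)
      stop("risk groups need one more label than cut-points")
    ps <- as.numeric(unlist(rg$predicted_survival_5y[unlist(rg$labels)]))
    if (length(ps) != length(rg$labels) || any(ps <= 0) || any(ps > 1))
      stop("predicted 5-year survival must be in (0, 1] for every group")
  }
  invisible(TRUE)
}

#' @rdname load_score_definition
#' @export
dataids_definition <- function() {
  load_score_definition(system.file("extdata", "dataids_points_synthetic.json",
                                    package = "hivprognosis", mustWork = TRUE))
}

#' @rdname load_score_definition
#' @export
vacs1_definition <- function() {
  load_score_definition(system.file("extdata", "vacs1_points.json",
                                    package = "hivprognosis", mustWork = TRUE))
}

#' @rdname load_score_definition
#' @export
vacs2_definition <- function() {
  load_score_definition(system.file("extdata", "vacs2_coefficients_synthetic.json",
                                    package = "hivprognosis", mustWork = TRUE))
}

#' Maximum and minimum achievable totals of a categorical definition
#'
#' Used for asset-integrity checks: the Dat'AIDS score ranges from 0 to 73.
#'
#' @param def A `score_definition`.
#' @return Named numeric vector with elements `min` and `max`.
#' @export
score_range <- function(def) {
  stopifnot(inherits(def, "score_definition"), def$type == "categorical")
  per_max <- vapply(def$components, function(comp)
    max(vapply(comp$categories, function(k) as.numeric(k$points), numeric(1))),
    numeric(1))
  per_min <- vapply(def$components, function(comp)
    min(vapply(comp$categories, function(k) as.numeric(k$points), numeric(1))),
    numeric(1))
  c(min = sum(per_min), max = sum(per_max))
}

#' @export
print.score_definition <- function(x, ...) {
  cat(sprintf("Score definition '%s' (%s)\n", x$name, x$type))
  cat(sprintf("  components: %s\n",
              paste(vapply(x$components, `[[`, "", "covariate"), collapse = ", ")))
  if (x$type == "categorical") {
    r <- score_range(x)
    cat(sprintf("  total range: %g to %g\n", r["min"], r["max"]))
  }
  if (!is.null(x$risk_groups))
    cat(sprintf("  risk groups: %s at cut-points %s\n",
                paste(unlist(x$risk_groups$labels), collapse = "/"),
                paste(unlist(x$risk_groups$cutpoints), collapse = ", ")))
  invisible(x)
}
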