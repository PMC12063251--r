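THRESHOLD_TOL <- 1e-9  # tie-point re-verification tolerance

#' Parameter specification for sensitivity analysis
#'
#' @param name Parameter name: `"prevalence"`, `"<test>.sensitivity"`,
#'   `"<test>.specificity"`, `"<test>.unit_cost"`, `"<test>.provider_cost"`
#'   or `"transport_per_trip"`.
#' @param base Base-case value.
#' @param low,high Uncertainty range bounds with `low <= base <= high`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, base, low, high) {
  if (low > base || high < base) {
    stop("range (low, high) must bracket the base value", call. = FALSE)
  }
  structure(list(name = name, base = base, low = low, high = high),
            class = "param_spec")
}

# ICER (or dominance flag) between the two cheapest-frontier strategies of a
# two-strategy comparison table.
frontier_icer <- function(cmp) {
  if (any(cmp$status %in% c("absolutely-dominated", "extended-dominated"))) {
    return(list(icer = NA_real_, status = "dominance"))
  }
  v <- cmp$icer[!is.na(cmp$icer)]
  if (length(v) == 0) return(list(icer = NA_real_, status = "tie"))
  list(icer = v[length(v)], status = "trade-off")
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full pipeline (tree rollback, ICER, dominance) at each
#' point of a grid across one parameter's uncertainty range, all other
#' parameters held at base. When the incremental effectiveness or cost
#' changes sign inside the range the dominance status flips; those crossing
#' points are located by root-finding rather than reported as a meaningless
#' ICER interval across the singularity.
#'
#' @param model A [cea_model()] with exactly two strategies.
#' @param spec A [param_spec()].
#' @param grid_points Number of grid values (endpoints included), >= 2.
#' @return A list of class `tornado_row`: `parameter`, `grid`, `icer`
#'   (vector, `NA` where a strategy is dominated or tied), `status` (per
#'   grid point), `icer_at_low`, `icer_at_high`, `icer_min`, `icer_max`
#'   (over defined values), `crossings` (parameter values where dominance
#'   status changes).
#' @export
one_way_dsa <- function(model, spec, grid_points = 101) {
  stopifnot(inherits(model, "cea_model"), inherits(spec, "param_spec"))
  if (grid_points < 2) stop("grid_points must be at least 2", call. = FALSE)
  if (length(model$tests) != 2) {
    stop("one_way_dsa is defined for two-strategy comparisons", call. = FALSE)
  }
  grid <- seq(spec$low, spec$high, length.out = grid_points)
  if (spec$low == spec$high) grid <- rep(spec$base, grid_points)

  eval_at <- function(value) frontier_icer(evaluate_cea(set_parameter(model, spec$name, value)))
  evals <- lapply(grid, eval_at)
  icers <- vapply(evals, `[[`, numeric(1), "icer")
  status <- vapply(evals, `[[`, "", "status")

  # locate dominance crossings: sign changes of incremental effectiveness or cost
  nm <- names(model$tests)
  diff_fun <- function(field) function(v) {
    m <- set_parameter(model, spec$name, v)
    r <- rollback(build_screening_tree(unname(m$tests), m$cohort))
    r[[field]][r$strategy == nm[2]] - r[[field]][r$strategy == nm[1]]
  }
  crossings <- c()
  for (field in c("effectiveness", "cost")) {
    f <- diff_fun(field)
    vals <- vapply(grid, f, numeric(1))
    flips <- which(sign(vals[-1]) * sign(vals[-length(vals)]) < 0)
    for (k in flips) {
      root <- stats::uniroot(f, lower = grid[k], upper = grid[k + 1],
                             tol = THRESHOLD_TOL)$root
      crossings <- c(crossings, root)
    }
  }
  defined <- icers[!is.na(icers)]
  structure(
    list(parameter = spec$name, grid = grid, icer = icers, status = status,
         icer_at_low = icers[1], icer_at_high = icers[grid_points],
         icer_min = if (length(defined)) min(defined) else NA_real_,
         icer_max = if (length(defined)) max(defined) else NA_real_,
         crossings = sort(unique(crossings))),
    class = "tornado_row"
  )
}

#' @export
print.tornado_row <- function(x, ...) {
  cat(sprintf("<tornado_row> %s over [%g, %g]\n", x$parameter,
              min(x$grid), max(x$grid)))
  cat(sprintf("  ICER at low %.2f, at high %.2f; range [%.2f, %.2f]\n",
              x$icer_at_low, x$icer_at_high, x$icer_min, x$icer_max))
  if (length(x$crossings)) {
    cat("  dominance crossings at:", paste(signif(x$crossings, 6), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate one-way sensitivity analyses
#'
#' Runs [one_way_dsa()] for several parameters and stacks the endpoint and
#' extreme ICERs into a data frame ready for a tornado diagram.
#'
#' @param model A [cea_model()].
#' @param specs List of [param_spec()]s.
#' @param grid_points Grid size per parameter.
#' @return A data.frame with one row per parameter: `parameter`, `low`,
#'   `high`, `icer_low`, `icer_high`, `icer_min`, `icer_max`, `n_crossings`.
#' @export
dsa_table <- function(model, specs, grid_points = 101) {
  rows <- lapply(specs, function(s) {
    r <- one_way_dsa(model, s, grid_points)
    data.frame(parameter = s$name, low = s$low, high = s$high,
               icer_low = r$icer_at_low, icer_high = r$icer_at_high,
               icer_min = r$icer_min, icer_max = r$icer_max,
               n_crossings = length(r$crossings), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Threshold (tie-point) analysis on effectiveness
#'
#' Solves for the value of one accuracy parameter (or the prevalence) at
#' which the two strategies have equal expected effectiveness, i.e. equal
#' proportions correctly diagnosed. Because effectiveness is linear in each
#' of prevalence, sensitivity and specificity, the tie-point has a closed
#' form; a bisection fallback (tolerance 1e-9) handles any parameter
#' without one and doubles as an independent cross-check.
#'
#' @param model A [cea_model()] with two strategies.
#' @param parameter One of `"prevalence"`, `"<test>.sensitivity"`,
#'   `"<test>.specificity"`.
#' @param method `"closed_form"` (default) or `"bisection"`.
#' @return A list of class `threshold_result`: `parameter`, `tie_value`
#'   (`NA` when no tie exists in the feasible domain),
#'   `within_uncertainty_range`, `quantity_tied = "effectiveness"`.
#' @export
threshold_equal_effectiveness <- function(model, parameter,
                                          method = c("closed_form", "bisection")) {
  stopifnot(inherits(model, "cea_model"))
  method <- match.arg(method)
  if (length(model$tests) != 2) {
    stop("threshold analysis is defined for two-strategy comparisons", call. = FALSE)
  }
  nm <- names(model$tests)
  p <- model$cohort$prevalence
  eff <- function(t) expected_effectiveness(p, t$sensitivity, t$specificity)
  e1 <- eff(model$tests[[1]]); e2 <- eff(model$tests[[2]])

  if (abs(e1 - e2) <= EFFECT_TIE_EPS) {
    tie <- get_parameter(model, parameter)
    return(threshold_result(parameter, tie, model, "effectiveness"))
  }

  diff_at <- function(v) {
    m <- set_parameter(model, parameter, v)
    pp <- m$cohort$prevalence
    t1 <- m$tests[[1]]; t2 <- m$tests[[2]]
    expected_effectiveness(pp, t1$sensitivity, t1$specificity) -
      expected_effectiveness(pp, t2$sensitivity, t2$specificity)
  }

  if (method == "bisection") {
    lo <- .Machine$double.eps; hi <- 1 - .Machine$double.eps
    if (sign(diff_at(lo)) * sign(diff_at(hi)) > 0) {
      return(threshold_result(parameter, NA_real_, model, "effectiveness"))
    }
    tie <- stats::uniroot(diff_at, lower = lo, upper = hi, tol = THRESHOLD_TOL)$root
    return(threshold_result(parameter, tie, model, "effectiveness"))
  }

  if (parameter == "prevalence") {
    # E1 - E2 = p * [(se1 - sp1) - (se2 - sp2)] + (sp1 - sp2)
    t1 <- model$tests[[1]]; t2 <- model$tests[[2]]
    slope <- (t1$sensitivity - t1$specificity) - (t2$sensitivity - t2$specificity)
    if (slope == 0) return(threshold_result(parameter, NA_real_, model, "effectiveness"))
    tie <- (t2$specificity - t1$specificity) / slope
    if (tie <= 0 || tie >= 1) tie <- NA_real_
    return(threshold_result(parameter, tie, model, "effectiveness"))
  }

  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% nm ||
      !parts[2] %in% c("sensitivity", "specificity")) {
    stop("no effectiveness tie-point for parameter '", parameter, "'", call. = FALSE)
  }
  this <- model$tests[[parts[1]]]
  other_eff <- if (parts[1] == nm[1]) e2 else e1
  tie <- if (parts[2] == "sensitivity") {
    (other_eff - (1 - p) * this$specificity) / p
  } else {
    (other_eff - p * this$sensitivity) / (1 - p)
  }
  if (tie < 0 || tie > 1) tie <- NA_real_
  threshold_result(parameter, tie, model, "effectiveness")
}

threshold_result <- function(parameter, tie_value, model, quantity_tied) {
  within <- NA
  if (!is.na(tie_value)) {
    rng <- uncertainty_range(model, parameter)
    if (!is.null(rng)) within <- tie_value >= rng[1] && tie_value <= rng[2]
  }
  structure(list(parameter = parameter, tie_value = tie_value,
                 within_uncertainty_range = within, quantity_tied = quantity_tied),
            class = "threshold_result")
}

uncertainty_range <- function(model, parameter) {
  if (parameter == "prevalence") return(model$cohort$prevalence_range)
  parts <- strsplit(parameter, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% names(model$tests)) {
    t <- model$tests[[parts[1]]]
    if (parts[2] == "sensitivity") return(t$sens_range)
    if (parts[2] == "specificity") return(t$spec_range)
  }
  NULL
}

#' @export
print.threshold_result <- function(x, ...) {
  if (is.na(x$tie_value)) {
    cat(sprintf("<threshold_result> %s: no tie-point in the feasible domain\n",
                x$parameter))
  } else {
    cat(sprintf("<threshold_result> %s ties %s at %.4f%s\n", x$parameter,
                x$quantity_tied, x$tie_value,
                if (isTRUE(x$within_uncertainty_range)) " (within uncertainty range)"
                else if (isFALSE(x$within_uncertainty_range)) " (outside uncertainty range)"
                else ""))
  }
  invisible(x)
}

#' Provider-cost scenario
#'
#' Replaces one strategy's provider per-test cost while keeping its patient
#' costs and every accuracy parameter at base, then recomputes the full
#' comparison. This answers questions such as "what if a cheaper analyser
#' brought this test's provider cost down to its comparator's?".
#'
#' @param model A [cea_model()] whose `profiles` include the target strategy
#'   (the patient share of the unit cost comes from its profile).
#' @param strategy Strategy name.
#' @param new_provider_unit_cost Replacement provider cost per test.
#' @return A [comparison_table][rank_and_compare()].
#' @export
scenario_provider_cost <- function(model, strategy, new_provider_unit_cost) {
  stopifnot(inherits(model, "cea_model"))
  if (!strategy %in% names(model$tests)) {
    stop("unknown strategy '", strategy, "'", call. = FALSE)
  }
  if (new_provider_unit_cost < 0) {
    stop("provider cost must be non-negative", call. = FALSE)
  }
  evaluate_cea(set_parameter(model, paste0(strategy, ".provider_cost"),
                             new_provider_unit_cost))
}
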