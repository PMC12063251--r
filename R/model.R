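#' Cost-effectiveness model
#'
#' Bundles the screened cohort, the competing screening strategies and
#' (optionally) their ingredient cost profiles into one object that the
#' evaluation, sensitivity and scenario functions operate on.
#'
#' @param cohort_obj A [cohort()].
#' @param tests List of [screening_test()]s.
#' @param profiles Optional named list of [test_cost_profile()]s keyed by
#'   strategy name; required for provider-cost scenarios and transport
#'   tie-point analyses, which need the provider/patient decomposition.
#' @return An object of class `cea_model`.
#' @export
cea_model <- function(cohort_obj, tests, profiles = NULL) {
  stopifnot(inherits(cohort_obj, "cohort"))
  nms <- vapply(tests, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate strategy names", call. = FALSE)
  names(tests) <- nms
  if (!is.null(profiles)) {
    for (p in profiles) stopifnot(inherits(p, "test_cost_profile"))
    missing_p <- setdiff(nms, names(profiles))
    if (length(missing_p) > 0 && length(profiles) > 0) {
      # profiles are optional per strategy; keep whatever is provided
    }
  }
  structure(list(cohort = cohort_obj, tests = tests, profiles = profiles),
            class = "cea_model")
}

#' @export
print.cea_model <- function(x, ...) {
  cat(sprintf("<cea_model> prevalence %.1f%%, %d strategies: %s\n",
              100 * x$cohort$prevalence, length(x$tests),
              paste(names(x$tests), collapse = ", ")))
  invisible(x)
}

#' Evaluate a model: tree, rollback, ranking
#'
#' Builds the screening decision tree, rolls it back to expected cost and
#' effectiveness per strategy, and ranks the strategies with dominance
#' classification.
#'
#' @param model A [cea_model()].
#' @return A [comparison_table][rank_and_compare()].
#' @export
evaluate_cea <- function(model) {
  stopifnot(inherits(model, "cea_model"))
  res <- rollback(build_screening_tree(unname(model$tests), model$cohort))
  rank_and_compare(res)
}

# Patient (and provider) per-test unit costs from a strategy's profile.
profile_breakdown <- function(model, strategy) {
  if (is.null(model$profiles) || is.null(model$profiles[[strategy]])) {
    stop("no cost profile available for strategy '", strategy, "'", call. = FALSE)
  }
  societal_unit_cost(model$profiles[[strategy]])
}

# Resolve a parameter name into a setter acting on the model. Names:
#   prevalence | <test>.sensitivity | <test>.specificity | <test>.unit_cost |
#   <test>.provider_cost | transport_per_trip
set_parameter <- function(model, name, value) {
  stopifnot(inherits(model, "cea_model"))
  if (name == "prevalence") {
    if (value <= 0 || value >= 1) stop("prevalence must be in (0, 1)", call. = FALSE)
    model$cohort$prevalence <- value
    return(model)
  }
  if (name == "transport_per_trip") {
    for (nm in names(model$tests)) {
      prof <- model$profiles[[nm]]
      if (is.null(prof)) {
        stop("transport_per_trip requires a cost profile for every strategy",
             call. = FALSE)
      }
      base_transport <- transport_unit_of(prof)
      model$tests[[nm]]$unit_cost <-
        model$tests[[nm]]$unit_cost - base_transport + value * prof$n_visits
    }
    return(model)
  }
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% names(model$tests)) {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  test_name <- parts[1]; field <- parts[2]
  if (field %in% c("sensitivity", "specificity")) {
    if (value < 0 || value > 1) stop(field, " must be in [0, 1]", call. = FALSE)
    model$tests[[test_name]][[field]] <- value
    # the stored uncertainty range describes the base model, drop it when moved outside
    rng_field <- if (field == "sensitivity") "sens_range" else "spec_range"
    rng <- model$tests[[test_name]][[rng_field]]
    if (!is.null(rng) && (value < rng[1] || value > rng[2])) {
      model$tests[[test_name]][[rng_field]] <- NULL
    }
  } else if (field == "unit_cost") {
    if (value < 0) stop("unit_cost must be non-negative", call. = FALSE)
    model$tests[[test_name]]$unit_cost <- value
  } else if (field == "provider_cost") {
    if (value < 0) stop("provider_cost must be non-negative", call. = FALSE)
    patient_unit <- profile_breakdown(model, test_name)$patient_unit
    model$tests[[test_name]]$unit_cost <- value + patient_unit
  } else {
    stop("unknown parameter '", name, "'", call. = FALSE)
  }
  model
}

transport_unit_of <- function(profile, transport_label = "transport") {
  lab <- tolower(vapply(profile$patient_components, `[[`, "", "label"))
  idx <- which(startsWith(lab, transport_label))
  if (length(idx) != 1) {
    stop("profile '", profile$test_id, "' must have exactly one transport component",
         call. = FALSE)
  }
  per_test_unit_cost(profile$patient_components[[idx]], profile$n_tests)
}

# Current value of a settable parameter.
get_parameter <- function(model, name) {
  if (name == "prevalence") return(model$cohort$prevalence)
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  if (length(parts) == 2 && parts[1] %in% names(model$tests)) {
    t <- model$tests[[parts[1]]]
    return(switch(parts[2],
                  sensitivity = t$sensitivity,
                  specificity = t$specificity,
                  unit_cost = t$unit_cost,
                  provider_cost = t$unit_cost - profile_breakdown(model, parts[1])$patient_unit,
                  stop("unknown parameter '", name, "'", call. = FALSE)))
  }
  stop("unknown parameter '", name, "'", call. = FALSE)
}
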