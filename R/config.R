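#' Load and validate an analysis configuration
#'
#' Reads a YAML (or JSON) configuration describing the currency context,
#' costing settings, cohort, screening tests and analysis directives, and
#' validates it before any computation runs. Every validation failure is
#' reported, each naming the offending field, not only the first.
#'
#' Schema (YAML):
#' \preformatted{
#' currency:  {exchange_rate, inflation_factor}
#' costing:   {n_tests, discount_rate, ingredient_table}   # CSV path,
#'                                             # relative to the config file
#' cohort:    {prevalence, range: [low, high]}
#' tests:     [{name, sensitivity, sens_range, specificity, spec_range,
#'              unit_cost, n_visits}]
#' analysis:  {dsa: {parameters, grid_points}, thresholds, scenarios,
#'             transport_tie: {a, b}, simulation: {n, seed}}
#' }
#'
#' @param path Path to the configuration file.
#' @return An object of class `analysis_config`: the parsed configuration
#'   plus `dir` (for resolving relative paths).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (length(cfg) == 0) stop("config file is empty: ", path, call. = FALSE)
  errors <- character()
  fail <- function(field, msg) errors <<- c(errors, paste0(field, ": ", msg))
  num_in <- function(x, field, lo = -Inf, hi = Inf, strict = FALSE) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1 || is.na(x)) {
      fail(field, "must be a single number"); return(FALSE)
    }
    ok <- if (strict) x > lo && x < hi else x >= lo && x <= hi
    if (!ok) fail(field, sprintf("must be in %s%g, %g%s",
                                 if (strict) "(" else "[", lo, hi,
                                 if (strict) ")" else "]"))
    ok
  }

  if (!is.null(cfg$currency)) {
    num_in(cfg$currency$exchange_rate, "currency.exchange_rate", 0, Inf, strict = TRUE)
    num_in(cfg$currency$inflation_factor, "currency.inflation_factor", 0, Inf, strict = TRUE)
  }
  if (is.null(cfg$costing)) {
    fail("costing", "section is required")
  } else {
    num_in(cfg$costing$n_tests, "costing.n_tests", 0, Inf, strict = TRUE)
    if (!is.null(cfg$costing$discount_rate)) {
      num_in(cfg$costing$discount_rate, "costing.discount_rate", 0, Inf)
    }
  }
  if (is.null(cfg$cohort)) {
    fail("cohort", "section is required")
  } else {
    if (num_in(cfg$cohort$prevalence, "cohort.prevalence", 0, 1, strict = TRUE) &&
        !is.null(cfg$cohort$range)) {
      rng <- unlist(cfg$cohort$range)
      if (length(rng) != 2 || rng[1] > cfg$cohort$prevalence ||
          rng[2] < cfg$cohort$prevalence) {
        fail("cohort.range", "must be [low, high] bracketing the prevalence")
      }
    }
  }
  if (is.null(cfg$tests) || length(cfg$tests) < 1) {
    fail("tests", "at least one test must be given")
  } else {
    for (i in seq_along(cfg$tests)) {
      t <- cfg$tests[[i]]
      pre <- sprintf("tests[%d]", i)
      if (is.null(t$name) || !nzchar(t$name)) fail(paste0(pre, ".name"), "is required")
      num_in(t$sensitivity, paste0(pre, ".sensitivity"), 0, 1)
      num_in(t$specificity, paste0(pre, ".specificity"), 0, 1)
      for (rng_field in c("sens_range", "spec_range")) {
        rng <- unlist(t[[rng_field]])
        base <- if (rng_field == "sens_range") t$sensitivity else t$specificity
        if (!is.null(rng) && (length(rng) != 2 || any(rng < 0) || any(rng > 1) ||
                              (is.numeric(base) && (rng[1] > base || rng[2] < base)))) {
          fail(paste0(pre, ".", rng_field), "must be [low, high] in [0,1] bracketing the base")
        }
      }
      if (!is.null(t$unit_cost)) num_in(t$unit_cost, paste0(pre, ".unit_cost"), 0, Inf)
      if (!is.null(t$n_visits)) num_in(t$n_visits, paste0(pre, ".n_visits"), 1, Inf)
    }
    nms <- vapply(cfg$tests, function(t) t$name %||% "", "")
    if (anyDuplicated(nms)) fail("tests", "duplicate test names")
  }
  if (!is.null(cfg$costing$ingredient_table)) {
    tab <- file.path(dirname(path), cfg$costing$ingredient_table)
    if (!file.exists(tab)) fail("costing.ingredient_table", paste("file not found:", tab))
  }
  if (length(errors) > 0) {
    stop("invalid configuration:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$dir <- dirname(normalizePath(path))
  structure(cfg, class = "analysis_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the model objects described by a configuration
#'
#' @param config An [analysis_config][load_config()].
#' @return A list with `model` (a [cea_model()]), `profiles` (named list of
#'   [test_cost_profile()]s, possibly empty) and `currency`
#'   (a [currency_context()] or `NULL`).
#' @export
config_to_model <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  profiles <- NULL
  if (!is.null(config$costing$ingredient_table)) {
    visits <- vapply(config$tests, function(t) t$n_visits %||% 1, numeric(1))
    names(visits) <- vapply(config$tests, `[[`, "", "name")
    profiles <- read_ingredient_table(
      file.path(config$dir, config$costing$ingredient_table),
      n_tests = config$costing$n_tests, n_visits = visits
    )
  }
  tests <- lapply(config$tests, function(t) {
    unit_cost <- t$unit_cost
    if (is.null(unit_cost)) {
      if (is.null(profiles[[t$name]])) {
        stop("test '", t$name, "' has neither unit_cost nor a cost profile",
             call. = FALSE)
      }
      unit_cost <- societal_unit_cost(profiles[[t$name]])$total_unit
    }
    screening_test(t$name, t$sensitivity, t$specificity, unit_cost,
                   sens_range = unlist(t$sens_range),
                   spec_range = unlist(t$spec_range))
  })
  cohort_obj <- cohort(config$cohort$prevalence,
                       prevalence_range = unlist(config$cohort$range))
  currency <- if (!is.null(config$currency)) {
    currency_context(config$currency$exchange_rate,
                     config$currency$inflation_factor %||% 1)
  }
  list(model = cea_model(cohort_obj, tests, profiles), profiles = profiles,
       currency = currency)
}

# Range of a DSA parameter: explicit in the directive, else the stored
# uncertainty range of the named parameter.
dsa_spec_from_config <- function(model, entry) {
  if (is.character(entry)) entry <- list(name = entry)
  base <- get_parameter(model, entry$name)
  lo <- entry$low; hi <- entry$high
  if (is.null(lo) || is.null(hi)) {
    rng <- uncertainty_range(model, entry$name)
    if (is.null(rng)) {
      stop("dsa parameter '", entry$name, "' has no stored uncertainty range; ",
           "give explicit low/high", call. = FALSE)
    }
    lo <- rng[1]; hi <- rng[2]
  }
  param_spec(entry$name, base, lo, hi)
}

#' Run the full analysis pipeline
#'
#' Executes costing, the decision model, the incremental comparison, any
#' requested sensitivity/threshold/scenario analyses and an optional
#' Monte-Carlo simulation, writing CSV (display-rounded) and JSON
#' (full-precision) reports to `out_dir`. Any stage failure aborts with a
#' stage-named error and removes partial outputs. With a single strategy
#' the incremental comparison is skipped with a logged notice.
#'
#' @param config An [analysis_config][load_config()] or a path to one.
#' @param out_dir Output directory (created if needed).
#' @param seed Overrides `analysis.simulation.seed` when given.
#' @return Invisibly, a list with the in-memory results (`costing`,
#'   `cea`, `dsa`, `thresholds`, `scenarios`, `simulation`, `log`) and
#'   `files` (paths written).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "analysis_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(name) {
    p <- file.path(out_dir, name)
    written <<- c(written, p)
    p
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  results <- list()
  notices <- character()

  built <- stage("costing", {
    b <- config_to_model(config)
    if (!is.null(b$profiles)) {
      results$costing <- lapply(b$profiles, cost_table)
      for (nm in names(b$profiles)) {
        tab <- results$costing[[nm]]
        tab$total <- round(tab$total, 3)
        tab$unit <- round(tab$unit, 3)
        tab$share_pct <- round(tab$share_pct, 1)
        utils::write.csv(tab, emit(paste0("cost_", nm, ".csv")), row.names = FALSE)
      }
    }
    b
  })
  model <- built$model

  results$cea <- stage("cea", {
    if (length(model$tests) < 2) {
      notices <- c(notices, "single strategy: incremental comparison skipped")
      r <- rollback(build_screening_tree(unname(model$tests), model$cohort))
      jsonlite::write_json(as.data.frame(r), emit("effectiveness.json"),
                           auto_unbox = TRUE, digits = NA)
      NULL
    } else {
      cmp <- evaluate_cea(model)
      write_comparison_csv(cmp, emit("cea.csv"))
      jsonlite::write_json(as.data.frame(cmp), emit("cea.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      cmp
    }
  })

  an <- config$analysis
  if (!is.null(an$dsa) && length(model$tests) == 2) {
    results$dsa <- stage("dsa", {
      specs <- lapply(an$dsa$parameters, dsa_spec_from_config, model = model)
      tab <- dsa_table(model, specs, grid_points = an$dsa$grid_points %||% 101)
      out <- tab
      for (col in c("icer_low", "icer_high", "icer_min", "icer_max")) {
        out[[col]] <- round(out[[col]], 2)
      }
      utils::write.csv(out, emit("dsa.csv"), row.names = FALSE, na = "")
      tab
    })
  }
  if (!is.null(an$thresholds) && length(model$tests) == 2) {
    results$thresholds <- stage("threshold", {
      th <- lapply(an$thresholds, threshold_equal_effectiveness, model = model)
      df <- do.call(rbind, lapply(th, function(x) {
        data.frame(parameter = x$parameter, tie_value = x$tie_value,
                   within_uncertainty_range = x$within_uncertainty_range,
                   quantity_tied = x$quantity_tied, stringsAsFactors = FALSE)
      }))
      jsonlite::write_json(df, emit("thresholds.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      th
    })
  }
  if (!is.null(an$transport_tie)) {
    results$transport_tie <- stage("threshold", {
      pa <- built$profiles[[an$transport_tie$a]]
      pb <- built$profiles[[an$transport_tie$b]]
      if (is.null(pa) || is.null(pb)) {
        stop("transport_tie strategies need cost profiles", call. = FALSE)
      }
      tie <- transport_tie_point(pa, pb,
                                 unit_cost_a = model$tests[[an$transport_tie$a]]$unit_cost,
                                 unit_cost_b = model$tests[[an$transport_tie$b]]$unit_cost)
      jsonlite::write_json(tie, emit("transport_tie.json"), auto_unbox = TRUE,
                           digits = NA)
      tie
    })
  }
  if (!is.null(an$scenarios) && length(model$tests) >= 2) {
    results$scenarios <- stage("scenario", {
      lapply(seq_along(an$scenarios), function(i) {
        sc <- an$scenarios[[i]]
        cmp <- scenario_provider_cost(model, sc$strategy, sc$provider_cost)
        write_comparison_csv(cmp, emit(sprintf("scenario_%d.csv", i)))
        cmp
      })
    })
  }
  if (!is.null(an$simulation)) {
    results$simulation <- stage("simulation", {
      sim_seed <- seed %||% an$simulation$seed %||% 1L
      n <- an$simulation$n %||% 1e5
      if (length(model$tests) >= 2) {
        sim <- empirical_comparison(n, model$cohort, model$tests[[1]],
                                    model$tests[[2]], seed = sim_seed)
        report <- list(n = n, seed = sim_seed,
                       strategies = names(model$tests)[1:2],
                       proportion_correct = c(sim$a$proportion_correct,
                                              sim$b$proportion_correct),
                       delta_cost = sim$delta_cost,
                       delta_effectiveness = sim$delta_effectiveness,
                       icer = sim$icer)
      } else {
        s <- simulate_cohort(n, model$cohort, model$tests[[1]], seed = sim_seed)
        report <- list(n = n, seed = sim_seed, strategies = names(model$tests),
                       proportion_correct = s$proportion_correct)
        sim <- s
      }
      jsonlite::write_json(report, emit("simulation.json"), auto_unbox = TRUE,
                           digits = NA, na = "null")
      sim
    })
  }

  inputs <- c(ingredient_table = if (!is.null(config$costing$ingredient_table)) {
    file.path(config$dir, config$costing$ingredient_table)
  })
  results$log <- list(
    package_version = as.character(utils::packageVersion("screencea")),
    seed = seed %||% an$simulation$seed,
    notices = notices,
    input_checksums = if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  )
  jsonlite::write_json(results$log, emit("log.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  results$files <- written
  invisible(results)
}
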