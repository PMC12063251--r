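#' Cost ingredient
#'
#' One provider- or patient-borne cost component of a testing strategy, as
#' used in ingredient-based (bottom-up) microcosting. A component is valued
#' either as a study-period total (to be spread over the number of tests
#' performed) or as a unit price times a quantity consumed per test.
#'
#' @param label Component name, e.g. `"Test kits"`.
#' @param category One of `"capital"`, `"recurrent"`, `"patient"`.
#' @param total_cost Study-period total cost (currency units). Mutually
#'   exclusive with `unit_price`/`quantity_per_test`.
#' @param unit_price Price per unit consumed (currency units).
#' @param quantity_per_test Units consumed per test.
#' @param useful_life_years Useful life in years; capital items only.
#' @param trips_multiplier Factor applied to a patient component when a
#'   strategy requires additional facility visits (e.g. 2 for a test that
#'   needs a return trip in a fasted state); patient items only.
#' @return An object of class `cost_ingredient`.
#' @seealso [per_test_unit_cost()], [test_cost_profile()]
#' @export
#' @examples
#' cost_ingredient("Test kits", "recurrent", total_cost = 972.234)
#' cost_ingredient("Lancets", "recurrent", unit_price = 0.05, quantity_per_test = 1)
cost_ingredient <- function(label, category = c("capital", "recurrent", "patient"),
                            total_cost = NULL, unit_price = NULL,
                            quantity_per_test = NULL, useful_life_years = NULL,
                            trips_multiplier = NULL) {
  category <- match.arg(category)
  has_total <- !is.null(total_cost) && !is.na(total_cost)
  has_pq <- !is.null(unit_price) && !is.na(unit_price) &&
    !is.null(quantity_per_test) && !is.na(quantity_per_test)
  if (has_total == has_pq) {
    stop("exactly one of `total_cost` or (`unit_price`, `quantity_per_test`) ",
         "must be given for ingredient '", label, "'", call. = FALSE)
  }
  if (has_total && total_cost < 0) {
    stop("total_cost must be non-negative for ingredient '", label, "'", call. = FALSE)
  }
  if (has_pq && (unit_price < 0 || quantity_per_test < 0)) {
    stop("unit_price and quantity_per_test must be non-negative", call. = FALSE)
  }
  if (!is.null(useful_life_years) && !is.na(useful_life_years)) {
    if (category != "capital") {
      stop("useful_life_years applies to capital items only", call. = FALSE)
    }
    if (useful_life_years <= 0) stop("useful_life_years must be positive", call. = FALSE)
  } else {
    useful_life_years <- NULL
  }
  if (!is.null(trips_multiplier) && !is.na(trips_multiplier)) {
    if (category != "patient") {
      stop("trips_multiplier applies to patient items only", call. = FALSE)
    }
    if (trips_multiplier < 1) stop("trips_multiplier must be >= 1", call. = FALSE)
  } else {
    trips_multiplier <- NULL
  }
  structure(
    list(label = as.character(label), category = category,
         total_cost = if (has_total) as.numeric(total_cost) else NULL,
         unit_price = if (has_pq) as.numeric(unit_price) else NULL,
         quantity_per_test = if (has_pq) as.numeric(quantity_per_test) else NULL,
         useful_life_years = useful_life_years,
         trips_multiplier = trips_multiplier),
    class = "cost_ingredient"
  )
}

#' @export
print.cost_ingredient <- function(x, ...) {
  val <- if (!is.null(x$total_cost)) {
    sprintf("total %.3f", x$total_cost)
  } else {
    sprintf("%.3f x %g per test", x$unit_price, x$quantity_per_test)
  }
  cat(sprintf("<cost_ingredient> %s [%s] %s\n", x$label, x$category, val))
  invisible(x)
}

#' Annualize a capital acquisition cost
#'
#' Converts the acquisition cost of a capital item (e.g. an analyser or
#' glucometer) into an equivalent annual cost over its useful life using the
#' standard annuity factor \eqn{a = (1 - (1+r)^{-L}) / r}. At a zero discount
#' rate the factor reduces to its limit \eqn{a = L}, i.e. straight-line
#' spreading.
#'
#' @param acquisition_cost Purchase cost (currency units), non-negative.
#' @param life_years Useful life span in years, positive.
#' @param discount_rate Annual discount rate as a fraction (default 0: a
#'   single short testing cycle gives no reason to discount).
#' @return Equivalent annual cost (currency units per year).
#' @export
#' @examples
#' annualize_capital(1000, 5)        # 200 per year
#' annualize_capital(1000, 5, 0.03)  # 218.35 per year
annualize_capital <- function(acquisition_cost, life_years, discount_rate = 0) {
  if (life_years <= 0) stop("life_years must be positive", call. = FALSE)
  if (acquisition_cost < 0) stop("acquisition_cost must be non-negative", call. = FALSE)
  if (discount_rate < 0) stop("discount_rate must be non-negative", call. = FALSE)
  annuity <- if (discount_rate == 0) {
    life_years
  } else {
    (1 - (1 + discount_rate)^(-life_years)) / discount_rate
  }
  acquisition_cost / annuity
}

#' Per-test unit cost of one ingredient
#'
#' Spreads a study-period total over the number of tests performed, or
#' multiplies unit price by per-test quantity when the ingredient is valued
#' that way.
#'
#' @param ingredient A [cost_ingredient()].
#' @param n_tests Number of tests over which study-period totals are spread.
#' @return Cost per test (currency units).
#' @export
#' @examples
#' kits <- cost_ingredient("Test kits", "recurrent", total_cost = 972.234)
#' per_test_unit_cost(kits, 1659)  # 0.586
per_test_unit_cost <- function(ingredient, n_tests) {
  stopifnot(inherits(ingredient, "cost_ingredient"))
  if (is.null(ingredient$total_cost)) {
    return(ingredient$unit_price * ingredient$quantity_per_test)
  }
  if (n_tests <= 0) stop("n_tests must be positive", call. = FALSE)
  ingredient$total_cost / n_tests
}

#' Per-test cost profile of a screening strategy
#'
#' Bundles the provider and patient cost components of one testing strategy
#' with the costing denominator (tests performed) and the number of facility
#' visits the strategy requires.
#'
#' @param test_id Strategy name.
#' @param provider_components List of [cost_ingredient()]s with category
#'   `"capital"` or `"recurrent"`.
#' @param patient_components List of [cost_ingredient()]s with category
#'   `"patient"` (transport, meals, lost productivity, ...).
#' @param n_tests Tests over which study-period totals are spread.
#' @param n_visits Facility visits required per screened patient (2 for a
#'   fasting test that requires a return trip, else 1).
#' @return An object of class `test_cost_profile`.
#' @export
test_cost_profile <- function(test_id, provider_components, patient_components,
                              n_tests, n_visits = 1) {
  if (n_tests <= 0) stop("n_tests must be positive", call. = FALSE)
  if (n_visits < 1) stop("n_visits must be at least 1", call. = FALSE)
  chk <- function(lst, who, cats) {
    for (ing in lst) {
      stopifnot(inherits(ing, "cost_ingredient"))
      if (!ing$category %in% cats) {
        stop(who, " component '", ing$label, "' has category '", ing$category, "'",
             call. = FALSE)
      }
    }
  }
  chk(provider_components, "provider", c("capital", "recurrent"))
  chk(patient_components, "patient", "patient")
  structure(
    list(test_id = as.character(test_id),
         provider_components = provider_components,
         patient_components = patient_components,
         n_tests = as.numeric(n_tests), n_visits = as.numeric(n_visits)),
    class = "test_cost_profile"
  )
}

#' @export
print.test_cost_profile <- function(x, ...) {
  u <- societal_unit_cost(x)
  cat(sprintf("<test_cost_profile> %s: %d provider + %d patient components, n_tests = %g, visits = %g\n",
              x$test_id, length(x$provider_components), length(x$patient_components),
              x$n_tests, x$n_visits))
  cat(sprintf("  unit cost %.3f (provider %.3f [%.1f%%] + patient %.3f [%.1f%%])\n",
              u$total_unit, u$provider_unit, u$provider_share,
              u$patient_unit, u$patient_share))
  invisible(x)
}

#' Societal per-test unit cost of a strategy
#'
#' Sums the per-test cost of every provider and patient component and reports
#' the provider/patient split. The societal perspective counts patient-borne
#' costs (transport, meals, lost productivity) alongside provider costs.
#'
#' @param profile A [test_cost_profile()].
#' @return A list with `provider_unit`, `patient_unit`, `total_unit`
#'   (currency per test) and `provider_share`, `patient_share` (percent of
#'   the societal unit cost; they sum to 100).
#' @export
societal_unit_cost <- function(profile) {
  stopifnot(inherits(profile, "test_cost_profile"))
  if (length(profile$provider_components) + length(profile$patient_components) == 0) {
    stop("profile has no cost components", call. = FALSE)
  }
  unit_sum <- function(lst) {
    if (length(lst) == 0) return(0)
    sum(vapply(lst, per_test_unit_cost, numeric(1), n_tests = profile$n_tests))
  }
  provider_unit <- unit_sum(profile$provider_components)
  patient_unit <- unit_sum(profile$patient_components)
  total_unit <- provider_unit + patient_unit
  if (total_unit > 0) {
    provider_share <- 100 * provider_unit / total_unit
  } else {
    provider_share <- 0
  }
  list(provider_unit = provider_unit, patient_unit = patient_unit,
       total_unit = total_unit, provider_share = provider_share,
       patient_share = if (total_unit > 0) 100 - provider_share else 0)
}

#' Currency conversion context
#'
#' @param exchange_rate Local currency units per USD (e.g. 3789.58 UGX per
#'   USD on 1 June 2019).
#' @param inflation_factor Multiplicative adjustment from the costing base
#'   year to the reporting year (1 for no adjustment).
#' @return An object of class `currency_context`.
#' @export
currency_context <- function(exchange_rate, inflation_factor = 1) {
  if (exchange_rate <= 0) stop("exchange_rate must be positive", call. = FALSE)
  if (inflation_factor <= 0) stop("inflation_factor must be positive", call. = FALSE)
  structure(list(exchange_rate = as.numeric(exchange_rate),
                 inflation_factor = as.numeric(inflation_factor)),
            class = "currency_context")
}

#' Convert a local-currency amount to report-year USD
#'
#' @param amount Amount in local currency units.
#' @param ctx A [currency_context()].
#' @return Amount in USD, inflation-adjusted to the report year.
#' @export
#' @examples
#' convert_currency(3789.58, currency_context(3789.58))  # 1 USD
convert_currency <- function(amount, ctx) {
  stopifnot(inherits(ctx, "currency_context"))
  amount / ctx$exchange_rate * ctx$inflation_factor
}

#' Transport cost tie-point between two strategies
#'
#' Solves for the per-trip transport cost at which the societal unit costs of
#' two strategies are equal, when transport is modelled as (per-trip cost x
#' number of visits) and all non-transport components are held fixed at their
#' profile values. A strategy demanding an extra fasted-state visit doubles
#' its transport exposure, so below the tie-point the cheaper-per-trip
#' strategy's cost advantage flips.
#'
#' @param profile_a,profile_b [test_cost_profile()]s differing in `n_visits`.
#' @param unit_cost_a,unit_cost_b Optional canonical societal unit costs for
#'   the two strategies; defaults to [societal_unit_cost()] of each profile.
#' @param transport_label Label identifying the transport component
#'   (case-insensitive prefix match, default `"transport"`).
#' @return A list with `tie_point` (currency per trip; negative values are
#'   flagged), `feasible` (logical: a non-negative tie-point exists) and the
#'   per-strategy non-transport unit costs used.
#' @export
transport_tie_point <- function(profile_a, profile_b,
                                unit_cost_a = NULL, unit_cost_b = NULL,
                                transport_label = "transport") {
  stopifnot(inherits(profile_a, "test_cost_profile"),
            inherits(profile_b, "test_cost_profile"))
  if (profile_a$n_visits == profile_b$n_visits) {
    stop("profiles have equal visit counts: no per-trip transport cost can ",
         "equalize totals", call. = FALSE)
  }
  transport_unit <- function(profile) {
    lab <- tolower(vapply(profile$patient_components, `[[`, "", "label"))
    idx <- which(startsWith(lab, tolower(transport_label)))
    if (length(idx) != 1) {
      stop("profile '", profile$test_id, "' must have exactly one transport ",
           "component", call. = FALSE)
    }
    per_test_unit_cost(profile$patient_components[[idx]], profile$n_tests)
  }
  total_a <- if (is.null(unit_cost_a)) societal_unit_cost(profile_a)$total_unit else unit_cost_a
  total_b <- if (is.null(unit_cost_b)) societal_unit_cost(profile_b)$total_unit else unit_cost_b
  nontransport_a <- total_a - transport_unit(profile_a)
  nontransport_b <- total_b - transport_unit(profile_b)
  tie <- (nontransport_b - nontransport_a) / (profile_a$n_visits - profile_b$n_visits)
  list(tie_point = tie, feasible = tie >= 0,
       nontransport_a = nontransport_a, nontransport_b = nontransport_b,
       visits_a = profile_a$n_visits, visits_b = profile_b$n_visits)
}

#' Read an ingredient cost table
#'
#' Reads a CSV with columns `test_id,label,category,total_cost,unit_price,`
#' `quantity_per_test,useful_life_years,trips_multiplier` (empty cells where
#' a field is inapplicable) and builds one [test_cost_profile()] per strategy.
#'
#' @param path Path to the CSV file.
#' @param n_tests Costing denominator shared by all strategies.
#' @param n_visits Named numeric vector of visits per strategy (default 1 for
#'   any strategy not named).
#' @return A named list of [test_cost_profile()]s.
#' @export
read_ingredient_table <- function(path, n_tests, n_visits = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("test_id", "label", "category", "total_cost", "unit_price",
                "quantity_per_test", "useful_life_years", "trips_multiplier")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("ingredient table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  profiles <- list()
  for (id in unique(df$test_id)) {
    rows <- df[df$test_id == id, , drop = FALSE]
    prov <- list(); pat <- list()
    for (i in seq_len(nrow(rows))) {
      r <- rows[i, ]
      ing <- cost_ingredient(
        r$label, r$category,
        total_cost = num(r$total_cost), unit_price = num(r$unit_price),
        quantity_per_test = num(r$quantity_per_test),
        useful_life_years = num(r$useful_life_years),
        trips_multiplier = num(r$trips_multiplier)
      )
      if (ing$category == "patient") pat <- c(pat, list(ing)) else prov <- c(prov, list(ing))
    }
    visits <- if (!is.null(n_visits) && id %in% names(n_visits)) n_visits[[id]] else 1
    profiles[[id]] <- test_cost_profile(id, prov, pat, n_tests = n_tests,
                                        n_visits = visits)
  }
  profiles
}

#' Tabulate a cost profile
#'
#' Expands a [test_cost_profile()] into a data frame mirroring a published
#' costing table: one row per component plus provider, patient and total
#' rows, with study-period total, per-test unit cost and percentage share of
#' the societal unit cost.
#'
#' @param profile A [test_cost_profile()].
#' @return A data.frame with columns `component`, `category`, `total`,
#'   `unit`, `share_pct`.
#' @export
cost_table <- function(profile) {
  stopifnot(inherits(profile, "test_cost_profile"))
  u <- societal_unit_cost(profile)
  row1 <- function(ing) {
    unit <- per_test_unit_cost(ing, profile$n_tests)
    total <- if (!is.null(ing$total_cost)) ing$total_cost else unit * profile$n_tests
    data.frame(component = ing$label, category = ing$category, total = total,
               unit = unit, share_pct = 100 * unit / u$total_unit,
               stringsAsFactors = FALSE)
  }
  comp <- do.call(rbind, lapply(c(profile$provider_components,
                                  profile$patient_components), row1))
  subtot <- data.frame(
    component = c("Subtotal, provider costs", "Subtotal, patient costs",
                  "Total unit cost (societal)"),
    category = c("provider", "patient", "total"),
    total = c(u$provider_unit, u$patient_unit, u$total_unit) * profile$n_tests,
    unit = c(u$provider_unit, u$patient_unit, u$total_unit),
    share_pct = c(u$provider_share, u$patient_share, 100),
    stringsAsFactors = FALSE
  )
  rbind(comp, subtot)
}
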