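test_that("capital annualization matches the annuity factor and its limits", {
  # straight-line limits at zero discount
  expect_equal(annualize_capital(1000, 5, 0), 200)
  expect_equal(annualize_capital(1000, 1, 0), 1000)
  # independent oracle: annuity factor as an explicit sum of discount factors
  r <- 0.03
  factor <- sum((1 + r)^-(1:5))
  expect_equal(factor, 4.5797072, tolerance = 1e-7)
  expect_equal(annualize_capital(1000, 5, r), 1000 / factor, tolerance = 1e-12)
  expect_equal(annualize_capital(1000, 5, r), 218.35, tolerance = 1e-4)
  # continuity: r -> 0 approaches the straight-line value
  expect_lt(abs(annualize_capital(1000, 5, 1e-9) / annualize_capital(1000, 5, 0) - 1),
            1e-6)
  # annualized value stays below the acquisition cost once the life span
  # exceeds one year (at exactly one year the payment carries the interest)
  for (L in c(2, 5, 10)) {
    expect_lte(annualize_capital(500, L, 0.05), 500)
  }
  expect_equal(annualize_capital(500, 1, 0.05), 500 * 1.05, tolerance = 1e-12)
  expect_error(annualize_capital(1000, 0, 0), "life_years")
  expect_error(annualize_capital(1000, -1, 0.03), "life_years")
})

test_that("per-test unit costs reproduce the published component costs", {
  cases <- list(
    list(label = "Test kits", total = 972.234, unit = 0.586),
    list(label = "Transport costs", total = 4422.894, unit = 2.666),
    list(label = "Meals", total = 5290.551, unit = 3.189)
  )
  for (cs in cases) {
    ing <- cost_ingredient(cs$label, if (cs$label == "Test kits") "recurrent" else "patient",
                           total_cost = cs$total)
    expect_equal(per_test_unit_cost(ing, 1659), cs$unit, tolerance = 1e-3)
  }
  zero <- cost_ingredient("nothing", "recurrent", total_cost = 0)
  expect_equal(per_test_unit_cost(zero, 1659), 0)
  priced <- cost_ingredient("Lancets", "recurrent", unit_price = 0.05,
                            quantity_per_test = 2)
  expect_equal(per_test_unit_cost(priced, 10), 0.1)
  expect_error(per_test_unit_cost(zero, 0), "n_tests")
})

test_that("ingredient validation enforces the one-of-two valuation rule", {
  expect_error(cost_ingredient("x", "recurrent"), "exactly one")
  expect_error(cost_ingredient("x", "recurrent", total_cost = 1, unit_price = 1,
                               quantity_per_test = 1), "exactly one")
  expect_error(cost_ingredient("x", "recurrent", total_cost = -1), "non-negative")
  expect_error(cost_ingredient("x", "recurrent", total_cost = 1,
                               useful_life_years = 5), "capital")
  expect_error(cost_ingredient("x", "capital", total_cost = 1,
                               useful_life_years = 0), "positive")
  expect_error(cost_ingredient("x", "capital", total_cost = 1,
                               trips_multiplier = 2), "patient")
  expect_error(cost_ingredient("x", "patient", total_cost = 1,
                               trips_multiplier = 0.5), ">= 1")
})

test_that("societal unit cost decomposes additively with shares summing to 100", {
  profiles <- read_ingredient_table(example_path("ingredients"), n_tests = 1659,
                                    n_visits = c(FPG = 2, HBA1c = 1))
  for (nm in c("FPG", "HBA1c")) {
    prof <- profiles[[nm]]
    u <- societal_unit_cost(prof)
    comps <- c(prof$provider_components, prof$patient_components)
    unit_sum <- sum(vapply(comps, per_test_unit_cost, numeric(1), n_tests = 1659))
    expect_equal(u$total_unit, unit_sum, tolerance = 1e-3)
    expect_equal(u$provider_share + u$patient_share, 100, tolerance = 1e-12)
    expect_equal(u$total_unit, u$provider_unit + u$patient_unit, tolerance = 1e-12)
  }
  # published unit costs and cost shares
  fpg <- societal_unit_cost(profiles$FPG)
  hba <- societal_unit_cost(profiles$HBA1c)
  expect_equal(fpg$total_unit, 8.188, tolerance = 1e-3)
  expect_equal(hba$total_unit, 6.922, tolerance = 1e-3)
  expect_lt(abs(fpg$patient_share - 90.4), 0.1)
  expect_lt(abs(hba$patient_share - 64.9), 0.1)
  expect_equal(fpg$provider_unit, 0.781, tolerance = 1e-3)
  expect_equal(hba$provider_unit, 2.429, tolerance = 1e-3)
  expect_equal(hba$patient_unit, 4.493, tolerance = 1e-3)
})

test_that("zero patient components give a zero patient share", {
  prof <- test_cost_profile(
    "provider-only",
    provider_components = list(cost_ingredient("kits", "recurrent", total_cost = 10)),
    patient_components = list(), n_tests = 10
  )
  u <- societal_unit_cost(prof)
  expect_equal(u$patient_share, 0)
  expect_equal(u$provider_share, 100)
  empty <- test_cost_profile("empty", list(), list(), n_tests = 5)
  expect_error(societal_unit_cost(empty), "no cost components")
})

test_that("currency conversion divides by the exchange rate and applies inflation", {
  ctx <- currency_context(3789.58, 1)
  expect_equal(convert_currency(3789.58, ctx), 1)
  expect_equal(convert_currency(0, ctx), 0)
  ctx2 <- currency_context(3789.58, 1.1)
  expect_equal(convert_currency(7579.16, ctx2), 2.2, tolerance = 1e-12)
  expect_error(currency_context(0), "exchange_rate")
  expect_error(currency_context(100, 0), "inflation_factor")
})

test_that("transport tie-point equalizes totals and is symmetric", {
  profiles <- read_ingredient_table(example_path("ingredients"), n_tests = 1659,
                                    n_visits = c(FPG = 2, HBA1c = 1))
  tie <- transport_tie_point(profiles$FPG, profiles$HBA1c,
                             unit_cost_a = 8.188, unit_cost_b = 6.922)
  expect_equal(tie$tie_point, 0.067, tolerance = 1e-9)
  expect_true(tie$feasible)
  # symmetry: swapping the two profiles gives the same tie-point
  swapped <- transport_tie_point(profiles$HBA1c, profiles$FPG,
                                 unit_cost_a = 6.922, unit_cost_b = 8.188)
  expect_equal(swapped$tie_point, tie$tie_point, tolerance = 1e-12)
  # back-substitution: at the tie-point both totals are equal
  total_at <- function(nontransport, visits) nontransport + tie$tie_point * visits
  expect_lt(abs(total_at(tie$nontransport_a, tie$visits_a) -
                total_at(tie$nontransport_b, tie$visits_b)), 1e-9)
  # identical non-transport costs tie at zero
  mk <- function(id, visits) test_cost_profile(
    id,
    provider_components = list(cost_ingredient("kits", "recurrent", total_cost = 50)),
    patient_components = list(cost_ingredient("Transport", "patient", total_cost = 30,
                                              trips_multiplier = visits)),
    n_tests = 10, n_visits = visits
  )
  expect_equal(transport_tie_point(mk("a", 2), mk("b", 1))$tie_point, 0)
  expect_error(transport_tie_point(mk("a", 2), mk("b", 2)), "equal visit counts")
})

test_that("cost tables mirror the component / subtotal / total layout", {
  profiles <- read_ingredient_table(example_path("ingredients"), n_tests = 1659,
                                    n_visits = c(FPG = 2, HBA1c = 1))
  tab <- cost_table(profiles$FPG)
  expect_equal(nrow(tab), 8 + 3)
  expect_equal(tab$unit[tab$component == "Test kits"], 0.586, tolerance = 1e-3)
  total_row <- tab[tab$category == "total", ]
  expect_equal(total_row$share_pct, 100)
  comp_rows <- tab[!tab$component %in% c("Subtotal, provider costs",
                                         "Subtotal, patient costs",
                                         "Total unit cost (societal)"), ]
  expect_equal(sum(comp_rows$unit), total_row$unit, tolerance = 1e-12)
})
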