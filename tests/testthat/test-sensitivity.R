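test_that("a degenerate range reproduces the base-case ICER at every grid point", {
  model <- base_model(with_profiles = FALSE)
  spec <- param_spec("HBA1c.sensitivity", 0.698, 0.698, 0.698)
  row <- one_way_dsa(model, spec, grid_points = 5)
  expect_equal(row$icer_min, 989.0625, tolerance = 1e-9)
  expect_equal(row$icer_max, 989.0625, tolerance = 1e-9)
  expect_length(row$crossings, 0)
})

test_that("the prevalence DSA keeps a positive trade-off across its range", {
  model <- base_model(with_profiles = FALSE)
  spec <- param_spec("prevalence", 0.084, 0.0709, 0.0982)
  row <- one_way_dsa(model, spec, grid_points = 101)
  expect_true(all(row$status == "trade-off"))
  expect_true(all(row$icer > 0))
  expect_length(row$crossings, 0)
  # closed-form endpoint oracle: ICER = dC / [p (se_F - se_H) + (1-p)(sp_F - sp_H)]
  dE <- function(p) p * (0.626 - 0.698) + (1 - p) * (0.994 - 0.986)
  expect_equal(row$icer_at_low, 1.266 / dE(0.0709), tolerance = 1e-9)
  expect_equal(row$icer_at_high, 1.266 / dE(0.0982), tolerance = 1e-9)
  # ICER increases with prevalence (the less sensitive FPG test loses ground)
  expect_true(all(diff(row$icer) > 0))
})

test_that("FPG specificity DSA crosses into dominance at the published tie-point", {
  model <- base_model(with_profiles = FALSE)
  spec <- param_spec("FPG.specificity", 0.994, 0.989, 0.997)
  row <- one_way_dsa(model, spec, grid_points = 101)
  expect_length(row$crossings, 1)
  expect_equal(row$crossings, 0.992603, tolerance = 1e-5)
  expect_equal(round(100 * row$crossings, 1), 99.3)
  # below the tie FPG is less effective and more costly: absolutely dominated
  expect_equal(row$status[1], "dominance")
  expect_equal(row$status[101], "trade-off")
})

test_that("DSA ICER is monotone when no dominance crossing occurs", {
  model <- base_model(with_profiles = FALSE)
  # sign of d(ICER)/d(theta) from the analytic derivative of dC / dE(theta):
  # dE rises with FPG accuracy (ICER falls) and falls with HBA1c accuracy
  cases <- list(
    list(spec = param_spec("FPG.sensitivity", 0.626, 0.615, 0.798), sign = -1),
    list(spec = param_spec("HBA1c.sensitivity", 0.698, 0.463, 0.705), sign = +1),
    list(spec = param_spec("HBA1c.specificity", 0.986, 0.954, 0.987), sign = +1)
  )
  for (cs in cases) {
    row <- one_way_dsa(model, cs$spec, grid_points = 41)
    expect_length(row$crossings, 0)
    expect_true(all(sign(diff(row$icer)) == cs$sign),
                label = paste("monotone ICER for", cs$spec$name))
  }
})

test_that("effectiveness tie-points match the published threshold analysis", {
  model <- base_model(with_profiles = FALSE)
  published <- c("HBA1c.sensitivity" = 71.3, "HBA1c.specificity" = 98.7,
                 "FPG.sensitivity" = 61.1, "FPG.specificity" = 99.3)
  for (param in names(published)) {
    th <- threshold_equal_effectiveness(model, param)
    expect_equal(round(100 * th$tie_value, 1), published[[param]],
                 label = param)
    expect_true(th$within_uncertainty_range, label = param)
    expect_equal(th$quantity_tied, "effectiveness")
    # re-verification: both strategies tie to < 1e-9 at the solved value
    m2 <- screencea:::set_parameter(model, param, th$tie_value)
    res <- rollback(build_screening_tree(unname(m2$tests), m2$cohort))
    expect_lt(abs(diff(res$effectiveness)), 1e-9)
    # closed form and bisection agree
    bi <- threshold_equal_effectiveness(model, param, method = "bisection")
    expect_lt(abs(bi$tie_value - th$tie_value), 1e-8)
  }
  # prevalence tie-point lies outside its uncertainty range (robust result)
  prev <- threshold_equal_effectiveness(model, "prevalence")
  expect_equal(prev$tie_value, 0.1, tolerance = 1e-9)
  expect_false(prev$within_uncertainty_range)
})

test_that("already-tied strategies return the base value as the tie-point", {
  tied <- cea_model(cohort(0.1),
                    list(screening_test("A", 0.7, 0.9, 3),
                         screening_test("B", 0.7, 0.9, 5)))
  th <- threshold_equal_effectiveness(tied, "A.sensitivity")
  expect_equal(th$tie_value, 0.7)
})

test_that("a parameter with no bracketing tie returns a no-threshold result", {
  # strategy A beats B in both sensitivity and specificity: varying B's
  # sensitivity alone cannot close the specificity gap at this prevalence
  model <- cea_model(cohort(0.05),
                     list(screening_test("A", 0.99, 0.99, 3),
                          screening_test("B", 0.5, 0.5, 5)))
  th <- threshold_equal_effectiveness(model, "B.sensitivity")
  expect_true(is.na(th$tie_value))
  bi <- threshold_equal_effectiveness(model, "B.sensitivity", method = "bisection")
  expect_true(is.na(bi$tie_value))
})

test_that("the provider-cost scenario reproduces the published what-ifs", {
  model <- base_model(with_profiles = TRUE)
  # cheaper analyser: HBA1c provider cost down to the FPG level
  cmp <- scenario_provider_cost(model, "HBA1c", 0.781)
  expect_equal(round(cmp$icer[2], 2), 2276.56)
  expect_equal(cmp$cost[cmp$strategy == "HBA1c"], 0.781 + 4.493, tolerance = 1e-9)
  # unchanged provider cost recovers the base case
  base <- scenario_provider_cost(model, "HBA1c", 2.429)
  expect_equal(round(base$icer[2], 2), 989.06)
  # provider cost pushing HBA1c above cost parity while staying less
  # effective flips FPG... HBA1c to absolute dominance
  parity_provider <- 8.188 - 4.493  # provider cost at which unit costs tie
  cmp2 <- scenario_provider_cost(model, "HBA1c", parity_provider + 0.5)
  expect_equal(cmp2$status[cmp2$strategy == "HBA1c"], "absolutely-dominated")
  expect_error(scenario_provider_cost(model, "OGTT", 1), "unknown strategy")
  expect_error(scenario_provider_cost(model, "HBA1c", -1), "non-negative")
})

test_that("dsa_table stacks endpoint and extreme ICERs per parameter", {
  model <- base_model(with_profiles = FALSE)
  tab <- dsa_table(model, list(
    param_spec("prevalence", 0.084, 0.0709, 0.0982),
    param_spec("FPG.specificity", 0.994, 0.989, 0.997)
  ), grid_points = 21)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$parameter, c("prevalence", "FPG.specificity"))
  expect_true(all(tab$icer_min <= tab$icer_max, na.rm = TRUE))
  expect_equal(tab$n_crossings, c(0, 1))
})
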