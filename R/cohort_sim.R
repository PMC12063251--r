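# Expand one user seed into independent substream seeds (status, then one
# per strategy) so adding a strategy never perturbs earlier draws.
substream_seeds <- function(seed, n_streams) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_streams)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  phat <- x / n
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  c(low = centre - half, high = centre + half)
}

#' Simulate an individual-level screening cohort
#'
#' Monte-Carlo twin of the decision tree: disease status is drawn
#' Bernoulli(prevalence); given disease the test result is
#' Bernoulli(sensitivity), given no disease a positive result occurs with
#' probability 1 - specificity. Individuals are cross-classified into
#' TP/FP/TN/FN and each accrues the strategy's unit cost. Identical inputs
#' and seed give identical output.
#'
#' @param n Cohort size, >= 1.
#' @param cohort_obj A [cohort()].
#' @param test A [screening_test()].
#' @param seed Integer seed.
#' @param keep_individuals Return the per-individual classification table.
#' @return A list of class `simulation_summary`: `n`, `counts` (named TP,
#'   FP, TN, FN), `proportion_correct`, `wilson_ci_95`, `mean_cost`, `seed`,
#'   and optionally `individuals` (data.frame `id`, `true_status`,
#'   `test_result`, `classification`, `accrued_cost`).
#' @export
#' @examples
#' s <- simulate_cohort(10000, cohort(0.084),
#'                      screening_test("FPG", 0.626, 0.994, 8.188), seed = 1)
#' s$proportion_correct
simulate_cohort <- function(n, cohort_obj, test, seed, keep_individuals = FALSE) {
  stopifnot(inherits(cohort_obj, "cohort"), inherits(test, "screening_test"))
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  seeds <- substream_seeds(seed, 2L)
  set.seed(seeds[1])
  diseased <- stats::runif(n) < cohort_obj$prevalence
  set.seed(seeds[2])
  u <- stats::runif(n)
  positive <- ifelse(diseased, u < test$sensitivity, u >= test$specificity)
  summarize_cohort(diseased, positive, test, seed, keep_individuals)
}

classify_outcomes <- function(diseased, positive) {
  ifelse(diseased,
         ifelse(positive, "TP", "FN"),
         ifelse(positive, "FP", "TN"))
}

summarize_cohort <- function(diseased, positive, test, seed, keep_individuals) {
  n <- length(diseased)
  cls <- classify_outcomes(diseased, positive)
  counts <- vapply(c(TP = "TP", FP = "FP", TN = "TN", FN = "FN"),
                   function(k) sum(cls == k), integer(1))
  correct <- counts[["TP"]] + counts[["TN"]]
  out <- list(n = n, counts = counts,
              proportion_correct = correct / n,
              wilson_ci_95 = wilson_ci(correct, n),
              mean_cost = test$unit_cost, seed = seed)
  if (keep_individuals) {
    out$individuals <- data.frame(
      id = seq_len(n),
      true_status = ifelse(diseased, "diseased", "non-diseased"),
      test_result = ifelse(positive, "positive", "negative"),
      classification = cls,
      accrued_cost = test$unit_cost,
      stringsAsFactors = FALSE
    )
  }
  structure(out, class = "simulation_summary")
}

#' @export
print.simulation_summary <- function(x, ...) {
  cat(sprintf("<simulation_summary> n = %d (seed %s)\n", x$n, format(x$seed)))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$counts[["TP"]],
              x$counts[["FP"]], x$counts[["TN"]], x$counts[["FN"]]))
  cat(sprintf("  proportion correct %.4f (95%% CI %.4f-%.4f), mean cost %.3f\n",
              x$proportion_correct, x$wilson_ci_95[["low"]],
              x$wilson_ci_95[["high"]], x$mean_cost))
  invisible(x)
}

#' Empirical two-strategy comparison by simulation
#'
#' Simulates both strategies on the *same* drawn disease statuses (common
#' random numbers) with independent test-result draws per strategy, and
#' returns empirical incremental cost, incremental effectiveness and the
#' resulting ICER estimate. Sharing statuses removes the prevalence
#' component of the variance of the effectiveness difference.
#'
#' @param n Cohort size.
#' @param cohort_obj A [cohort()].
#' @param test_a,test_b [screening_test()]s.
#' @param seed Integer seed.
#' @return A list: per-strategy `simulation_summary`s (`a`, `b`),
#'   `delta_cost`, `delta_effectiveness`, `icer` (`NA` with a tie signal
#'   when the empirical effectiveness difference is zero).
#' @export
empirical_comparison <- function(n, cohort_obj, test_a, test_b, seed) {
  stopifnot(inherits(cohort_obj, "cohort"))
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  seeds <- substream_seeds(seed, 3L)
  set.seed(seeds[1])
  diseased <- stats::runif(n) < cohort_obj$prevalence
  result_for <- function(test, s) {
    set.seed(s)
    u <- stats::runif(n)
    positive <- ifelse(diseased, u < test$sensitivity, u >= test$specificity)
    summarize_cohort(diseased, positive, test, seed, keep_individuals = FALSE)
  }
  a <- result_for(test_a, seeds[2])
  b <- result_for(test_b, seeds[3])
  d_eff <- b$proportion_correct - a$proportion_correct
  d_cost <- b$mean_cost - a$mean_cost
  est <- icer(list(cost = a$mean_cost, effectiveness = a$proportion_correct),
              list(cost = b$mean_cost, effectiveness = b$proportion_correct))
  list(a = a, b = b, delta_cost = d_cost, delta_effectiveness = d_eff,
       icer = as.numeric(est), tie = isTRUE(attr(est, "tie")))
}

#' Random two-strategy model for property testing
#'
#' Draws a valid random cohort and two random screening tests: prevalence
#' uniform on \[0.01, 0.30\], sensitivity and specificity uniform on
#' \[0.4, 0.999\], unit costs uniform on \[1, 20\]. Reproducible by seed.
#'
#' @param seed Integer seed.
#' @return A list with `cohort` (a [cohort()]) and `tests` (two
#'   [screening_test()]s named `"A"` and `"B"`).
#' @export
random_model <- function(seed) {
  set.seed(seed)
  prev <- stats::runif(1, 0.01, 0.30)
  draw_test <- function(name) {
    screening_test(name,
                   sensitivity = stats::runif(1, 0.4, 0.999),
                   specificity = stats::runif(1, 0.4, 0.999),
                   unit_cost = stats::runif(1, 1, 20))
  }
  list(cohort = cohort(prev), tests = list(A = draw_test("A"), B = draw_test("B")))
}
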