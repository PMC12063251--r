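PROB_TOL <- 1e-9  # absolute tolerance for chance-node probability sums

#' Screening test strategy
#'
#' A diagnostic strategy defined by its accuracy against the reference
#' standard and its societal unit cost.
#'
#' @param name Strategy name.
#' @param sensitivity Probability a diseased person tests positive, in
#'   \[0, 1\].
#' @param specificity Probability a non-diseased person tests negative, in
#'   \[0, 1\].
#' @param unit_cost Societal cost per test (currency units).
#' @param sens_range,spec_range Optional `(low, high)` uncertainty ranges
#'   (95\% CI bounds) bracketing the base values.
#' @return An object of class `screening_test`.
#' @export
#' @examples
#' screening_test("HBA1c", 0.698, 0.986, 6.922,
#'                sens_range = c(0.463, 0.861), spec_range = c(0.954, 0.996))
screening_test <- function(name, sensitivity, specificity, unit_cost,
                           sens_range = NULL, spec_range = NULL) {
  chk_frac <- function(x, what) {
    if (!is.numeric(x) || any(x < 0) || any(x > 1)) {
      stop(what, " must be in [0, 1]", call. = FALSE)
    }
  }
  chk_frac(sensitivity, "sensitivity")
  chk_frac(specificity, "specificity")
  if (unit_cost < 0) stop("unit_cost must be non-negative", call. = FALSE)
  chk_range <- function(rng, base, what) {
    if (is.null(rng)) return(NULL)
    chk_frac(rng, paste(what, "range"))
    if (length(rng) != 2 || rng[1] > base || rng[2] < base) {
      stop(what, " range must be (low, high) bracketing the base value",
           call. = FALSE)
    }
    as.numeric(rng)
  }
  structure(
    list(name = as.character(name), sensitivity = as.numeric(sensitivity),
         specificity = as.numeric(specificity), unit_cost = as.numeric(unit_cost),
         sens_range = chk_range(sens_range, sensitivity, "sensitivity"),
         spec_range = chk_range(spec_range, specificity, "specificity")),
    class = "screening_test"
  )
}

#' @export
print.screening_test <- function(x, ...) {
  cat(sprintf("<screening_test> %s: Se %.1f%%, Sp %.1f%%, unit cost %.3f\n",
              x$name, 100 * x$sensitivity, 100 * x$specificity, x$unit_cost))
  invisible(x)
}

#' Screened cohort
#'
#' @param prevalence Disease prevalence in the screened population, in
#'   (0, 1).
#' @param prevalence_range Optional `(low, high)` uncertainty range.
#' @param n Cohort size (used by the Monte-Carlo simulator; the analytic
#'   model needs only the prevalence).
#' @return An object of class `cohort`.
#' @export
cohort <- function(prevalence, prevalence_range = NULL, n = NULL) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("prevalence must be strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(prevalence_range)) {
    if (length(prevalence_range) != 2 || prevalence_range[1] > prevalence ||
        prevalence_range[2] < prevalence) {
      stop("prevalence_range must bracket the base prevalence", call. = FALSE)
    }
  }
  structure(list(prevalence = as.numeric(prevalence),
                 prevalence_range = prevalence_range,
                 n = n),
            class = "cohort")
}

#' Joint outcome probabilities of a screening test
#'
#' Classifies the screened population into the four diagnostic outcomes. A
#' diseased individual (probability `p`) is a true positive with probability
#' `se`, else a false negative; a non-diseased individual is a true negative
#' with probability `sp`, else a false positive.
#'
#' @param p Disease prevalence.
#' @param se Test sensitivity.
#' @param sp Test specificity.
#' @return A named list `tp`, `fn`, `tn`, `fp` summing to 1.
#' @export
#' @examples
#' outcome_probabilities(0.084, 0.698, 0.986)
outcome_probabilities <- function(p, se, sp) {
  for (x in list(p = p, se = se, sp = sp)) {
    if (!is.numeric(x) || x < 0 || x > 1) {
      stop("p, se and sp must all be in [0, 1]", call. = FALSE)
    }
  }
  list(tp = p * se, fn = p * (1 - se), tn = (1 - p) * sp, fp = (1 - p) * (1 - sp))
}

#' Expected effectiveness: proportion correctly diagnosed
#'
#' The decision model's effectiveness payoff is 1 for a correct diagnosis
#' (true positive or true negative) and 0 otherwise, so the expected
#' effectiveness is \eqn{E = p \cdot Se + (1 - p) \cdot Sp}.
#'
#' @inheritParams outcome_probabilities
#' @return Expected proportion correctly diagnosed, in \[0, 1\].
#' @export
#' @examples
#' expected_effectiveness(0.084, 0.626, 0.994)  # 0.963088
expected_effectiveness <- function(p, se, sp) {
  o <- outcome_probabilities(p, se, sp)
  o$tp + o$tn
}

#' Decision-tree node constructors
#'
#' Low-level building blocks for custom trees: a decision node chooses among
#' strategy branches, a chance node carries `(label, probability, child)`
#' branches whose probabilities must sum to 1 (absolute tolerance `1e-9`),
#' and a terminal node carries the `(cost, effectiveness)` payoff pair.
#' Payoffs are kept as a pair so outcome-specific costs or other effect
#' measures can be attached.
#'
#' @param branches For `decision_node()`, a list of `list(label, child)`;
#'   for `chance_node()`, a list of `list(label, probability, child)`.
#' @param cost,effectiveness Terminal payoffs.
#' @return A `decision_tree_node`.
#' @name tree_nodes
NULL

#' @rdname tree_nodes
#' @export
decision_node <- function(branches) {
  structure(list(type = "decision", branches = branches), class = "decision_tree_node")
}

#' @rdname tree_nodes
#' @export
chance_node <- function(branches) {
  probs <- vapply(branches, `[[`, numeric(1), "probability")
  if (abs(sum(probs) - 1) > PROB_TOL) {
    stop("chance-node probabilities must sum to 1 (got ", sum(probs), ")",
         call. = FALSE)
  }
  if (any(probs < -PROB_TOL)) stop("negative branch probability", call. = FALSE)
  structure(list(type = "chance", branches = branches), class = "decision_tree_node")
}

#' @rdname tree_nodes
#' @export
terminal_node <- function(cost, effectiveness) {
  structure(list(type = "terminal",
                 payoffs = list(cost = cost, effectiveness = effectiveness)),
            class = "decision_tree_node")
}

#' Build the screening decision tree
#'
#' Constructs the decision tree for one screening cycle: a decision node
#' over strategies; under each strategy a chance node on disease status
#' (prevalence); under each status a chance node on the test result driven
#' by sensitivity (if diseased) or specificity (if not). Terminals carry the
#' strategy's unit cost and an effectiveness payoff of 1 for correct
#' diagnoses (TP, TN) and 0 for errors (FP, FN). The reference standard is
#' implicit: it defines which branch is correct and is not costed.
#'
#' @param tests List of [screening_test()]s (at least one; two or more for a
#'   comparison).
#' @param cohort_obj A [cohort()].
#' @return An object of class `decision_tree`.
#' @export
build_screening_tree <- function(tests, cohort_obj) {
  stopifnot(inherits(cohort_obj, "cohort"))
  if (length(tests) < 1) stop("at least one strategy is required", call. = FALSE)
  nms <- vapply(tests, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate strategy names", call. = FALSE)
  p <- cohort_obj$prevalence
  strat_branch <- function(test) {
    stopifnot(inherits(test, "screening_test"))
    se <- test$sensitivity; sp <- test$specificity; c0 <- test$unit_cost
    diseased <- chance_node(list(
      list(label = "test positive (TP)", probability = se,
           child = terminal_node(c0, 1)),
      list(label = "test negative (FN)", probability = 1 - se,
           child = terminal_node(c0, 0))
    ))
    healthy <- chance_node(list(
      list(label = "test negative (TN)", probability = sp,
           child = terminal_node(c0, 1)),
      list(label = "test positive (FP)", probability = 1 - sp,
           child = terminal_node(c0, 0))
    ))
    list(label = test$name, child = chance_node(list(
      list(label = "diabetes", probability = p, child = diseased),
      list(label = "no diabetes", probability = 1 - p, child = healthy)
    )))
  }
  root <- decision_node(lapply(tests, strat_branch))
  structure(list(root = root, strategies = nms), class = "decision_tree")
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree> %d strategies: %s\n", length(x$strategies),
              paste(x$strategies, collapse = ", ")))
  invisible(x)
}

# Probability-weighted expectation of (cost, effectiveness) below a node.
rollback_node <- function(node) {
  switch(node$type,
    terminal = c(cost = node$payoffs$cost, effectiveness = node$payoffs$effectiveness),
    chance = {
      probs <- vapply(node$branches, `[[`, numeric(1), "probability")
      if (abs(sum(probs) - 1) > PROB_TOL) {
        stop("invalid tree: chance-node probabilities sum to ", sum(probs),
             call. = FALSE)
      }
      vals <- vapply(node$branches, function(b) rollback_node(b$child), numeric(2))
      c(cost = sum(probs * vals["cost", ]),
        effectiveness = sum(probs * vals["effectiveness", ]))
    },
    stop("rollback_node reached a decision node; roll back per strategy",
         call. = FALSE)
  )
}

#' Roll back a decision tree
#'
#' Computes each strategy's expected cost and expected effectiveness by
#' probability-weighted averaging from the leaves to the root. For the
#' screening tree this equals the closed forms: cost = unit cost and
#' effectiveness = `p * se + (1 - p) * sp`.
#'
#' @param tree A [decision_tree][build_screening_tree()].
#' @return A data.frame of class `strategy_results` with one row per
#'   strategy: `strategy`, `cost`, `effectiveness`.
#' @export
rollback <- function(tree) {
  stopifnot(inherits(tree, "decision_tree"))
  rows <- lapply(tree$root$branches, function(b) {
    v <- rollback_node(b$child)
    data.frame(strategy = b$label, cost = v[["cost"]],
               effectiveness = v[["effectiveness"]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("strategy_results", "data.frame")
  out
}

#' Serialize a decision tree to JSON
#'
#' Writes the node structure (`type`, `branches` with `label`/`probability`,
#' terminal `payoffs`) for inspection and golden-file comparison.
#'
#' @param tree A decision tree.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when writing to a file).
#' @export
tree_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "decision_tree"))
  strip <- function(node) {
    n <- unclass(node)
    if (!is.null(n$branches)) {
      n$branches <- lapply(n$branches, function(b) {
        b$child <- strip(b$child)
        b
      })
    }
    n
  }
  json <- jsonlite::toJSON(list(strategies = tree$strategies,
                                root = strip(tree$root)),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}
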