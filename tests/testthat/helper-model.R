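# Base two-strategy diabetes screening model (the bundled worked example)
# built directly in code so tests do not depend on YAML parsing, plus
# independent brute-force oracles kept deliberately separate from the
# package's own algorithms.

base_tests <- function() {
  list(
    HBA1c = screening_test("HBA1c", 0.698, 0.986, 6.922,
                           sens_range = c(0.463, 0.861),
                           spec_range = c(0.954, 0.996)),
    FPG = screening_test("FPG", 0.626, 0.994, 8.188,
                         sens_range = c(0.415, 0.798),
                         spec_range = c(0.989, 0.997))
  )
}

base_cohort <- function() cohort(0.084, prevalence_range = c(0.0709, 0.0982))

base_model <- function(with_profiles = TRUE) {
  profiles <- NULL
  if (with_profiles) {
    profiles <- read_ingredient_table(
      system.file("extdata", "iganga_2019_costs.csv", package = "screencea"),
      n_tests = 1659, n_visits = c(FPG = 2, HBA1c = 1)
    )
  }
  cea_model(base_cohort(), unname(base_tests()), profiles = profiles)
}

# Oracle 1: expected payoffs by exhaustive root-to-leaf path enumeration.
enumerate_expectation <- function(node, prob = 1) {
  if (node$type == "terminal") {
    return(data.frame(prob = prob, cost = node$payoffs$cost,
                      effectiveness = node$payoffs$effectiveness))
  }
  do.call(rbind, lapply(node$branches, function(b) {
    enumerate_expectation(b$child, prob * b$probability)
  }))
}

brute_force_rollback <- function(tree) {
  rows <- lapply(tree$root$branches, function(b) {
    paths <- enumerate_expectation(b$child)
    data.frame(strategy = b$label,
               cost = sum(paths$prob * paths$cost),
               effectiveness = sum(paths$prob * paths$effectiveness),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Oracle 2: dominance classification from first principles. A strategy is
# absolutely dominated by any cheaper-or-equal, more effective rival;
# extended-dominated when the blend of two surviving rivals matching its
# effectiveness is strictly cheaper.
brute_force_dominance <- function(df) {
  n <- nrow(df)
  status <- rep("efficient", n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if ((df$cost[j] <= df$cost[i] && df$effectiveness[j] > df$effectiveness[i]) ||
          (df$cost[j] < df$cost[i] && df$effectiveness[j] >= df$effectiveness[i])) {
        status[i] <- "absolutely-dominated"
      }
    }
  }
  repeat {
    changed <- FALSE
    alive <- which(status == "efficient")
    for (s in alive) {
      for (i in alive) {
        for (j in alive) {
          if (length(unique(c(s, i, j))) < 3) next
          ei <- df$effectiveness[i]; ej <- df$effectiveness[j]
          es <- df$effectiveness[s]
          if (ei < es && es < ej) {
            lam <- (ej - es) / (ej - ei)
            blend_cost <- lam * df$cost[i] + (1 - lam) * df$cost[j]
            if (blend_cost < df$cost[s] - 1e-12) {
              status[s] <- "extended-dominated"
              changed <- TRUE
            }
          }
        }
      }
    }
    if (!changed) break
  }
  status
}
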