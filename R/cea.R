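EFFECT_TIE_EPS <- 1e-12  # effectiveness differences below this are ties

#' Incremental cost-effectiveness ratio
#'
#' The change in expected cost divided by the change in expected
#' effectiveness between two strategies. The ratio is invariant under
#' swapping the two arguments (both differences change sign).
#'
#' @param reference,comparator Lists or one-row data frames with `cost` and
#'   `effectiveness`.
#' @return ICER (currency per additional unit of effectiveness), or `NA`
#'   with a `"tie"` attribute when the effectiveness difference is below
#'   `1e-12` (no ICER is defined; only the cost difference is meaningful).
#' @export
#' @examples
#' icer(list(cost = 6.922, effectiveness = 0.961808),
#'      list(cost = 8.188, effectiveness = 0.963088))  # 989.0625
icer <- function(reference, comparator) {
  d_cost <- comparator$cost - reference$cost
  d_eff <- comparator$effectiveness - reference$effectiveness
  if (abs(d_eff) <= EFFECT_TIE_EPS) {
    out <- NA_real_
    attr(out, "tie") <- TRUE
    attr(out, "incremental_cost") <- d_cost
    return(out)
  }
  d_cost / d_eff
}

#' Cost-effectiveness ratio of a single strategy
#'
#' @param result A list or one-row data frame with `cost` and
#'   `effectiveness`.
#' @return Expected cost divided by expected effectiveness.
#' @export
cer <- function(result) {
  if (result$effectiveness <= 0) {
    stop("cost-effectiveness ratio undefined at zero effectiveness", call. = FALSE)
  }
  result$cost / result$effectiveness
}

#' Rank strategies and classify dominance
#'
#' Sorts strategies by ascending expected cost and walks the
#' cost-effectiveness frontier. A strategy is *absolutely dominated* when
#' another strategy is cheaper-or-equal and strictly more effective, or
#' equally effective and strictly cheaper. *Extended dominance* is then
#' applied iteratively: a strategy is removed when the ICER of reaching it
#' from the previous surviving strategy exceeds the ICER of moving past it,
#' i.e. a blend of its neighbours is more efficient. ICERs are reported
#' between successive surviving strategies; the cheapest surviving strategy
#' is the baseline.
#'
#' @param results A `strategy_results` data frame (see [rollback()]) or any
#'   data.frame with `strategy`, `cost`, `effectiveness`.
#' @return A data.frame of class `comparison_table`: `strategy`, `cost`,
#'   `effectiveness`, `incremental_cost`, `incremental_effectiveness`,
#'   `icer`, `status` (one of `"baseline"`, `"non-dominated"`,
#'   `"absolutely-dominated"`, `"extended-dominated"`). Incremental values
#'   refer to the previous non-dominated row.
#' @export
rank_and_compare <- function(results) {
  df <- as.data.frame(results)
  stopifnot(all(c("strategy", "cost", "effectiveness") %in% names(df)))
  if (nrow(df) < 2) stop("at least two strategies are required", call. = FALSE)
  if (anyDuplicated(df$strategy)) stop("duplicate strategy names", call. = FALSE)

  df <- df[order(df$cost, df$effectiveness), , drop = FALSE]
  rownames(df) <- NULL
  n <- nrow(df)
  status <- rep("non-dominated", n)

  # absolute dominance: pairwise check
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      ci <- df$cost[i]; ei <- df$effectiveness[i]
      cj <- df$cost[j]; ej <- df$effectiveness[j]
      if ((cj <= ci && ej > ei) || (cj < ci && ej >= ei)) {
        status[i] <- "absolutely-dominated"
        break
      }
    }
  }

  # extended dominance: prune until the surviving ICER sequence is increasing
  repeat {
    alive <- which(status == "non-dominated")
    if (length(alive) < 3) break
    icers <- vapply(seq_along(alive)[-1], function(k) {
      icer(df[alive[k - 1], ], df[alive[k], ])
    }, numeric(1))
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    # the strategy whose incoming ICER exceeds its outgoing ICER is removed
    status[alive[bad[1] + 1]] <- "extended-dominated"
  }

  df$incremental_cost <- NA_real_
  df$incremental_effectiveness <- NA_real_
  df$icer <- NA_real_
  alive <- which(status == "non-dominated")
  if (length(alive) > 0) {
    status[alive[1]] <- "baseline"
    for (k in seq_along(alive)[-1]) {
      i <- alive[k]; prev <- alive[k - 1]
      df$incremental_cost[i] <- df$cost[i] - df$cost[prev]
      df$incremental_effectiveness[i] <- df$effectiveness[i] - df$effectiveness[prev]
      df$icer[i] <- icer(df[prev, ], df[i, ])
    }
  }
  df$status <- status
  class(df) <- c("comparison_table", "data.frame")
  df
}

#' @export
print.comparison_table <- function(x, digits = 2, ...) {
  cat("Cost-effectiveness ranking (ascending cost)\n")
  shown <- as.data.frame(x)
  shown$cost <- round(shown$cost, digits)
  shown$effectiveness <- round(shown$effectiveness, 3)
  shown$incremental_cost <- round(shown$incremental_cost, digits)
  shown$incremental_effectiveness <- round(shown$incremental_effectiveness, 3)
  shown$icer <- round(shown$icer, digits)
  print(shown, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table to CSV
#'
#' Writes the ranking with currency and ratios rounded to 2 decimals and
#' effectiveness to 3 decimals; use [jsonlite::write_json()] on the table
#' itself for full precision.
#'
#' @param table A [rank_and_compare()] result.
#' @param path Output CSV path.
#' @return The rounded data.frame, invisibly.
#' @export
write_comparison_csv <- function(table, path) {
  out <- as.data.frame(table)
  for (col in c("cost", "incremental_cost", "icer")) out[[col]] <- round(out[[col]], 2)
  for (col in c("effectiveness", "incremental_effectiveness")) {
    out[[col]] <- round(out[[col]], 3)
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(out)
}
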