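#' Net monetary benefit
#'
#' `wtp * QALYs - cost`: the monetary value of a strategy at a given
#' willingness to pay.
#'
#' @param result A `strategy_result`.
#' @param wtp Willingness to pay, USD per QALY, >= 0.
#' @return NMB in USD.
#' @export
nmb <- function(result, wtp) {
  stopifnot(inherits(result, "strategy_result"), wtp >= 0)
  wtp * result$qalys - result$cost
}

#' Compare two strategies
#'
#' Computes incremental cost and effectiveness of `new` relative to
#' `reference`, classifies dominance, and reports the incremental net
#' monetary benefit (`INMB = wtp * dE - dC`; positive favors `new`). The
#' ICER is reported as a ratio only when both increments share a sign and are
#' nonzero; dominance categories replace negative ratios, matching standard
#' reporting practice.
#'
#' @param new,reference `strategy_result`s with distinct names.
#' @param wtp Willingness to pay, USD per QALY.
#' @return A `cea_comparison`: list with `new`, `reference`, `delta_cost`,
#'   `delta_qalys`, `icer` (`NA` unless category is `"icer"`), `category`
#'   (`"dominant"`, `"dominated"`, `"equal"` or `"icer"`), `inmb`, `wtp`.
#' @export
compare <- function(new, reference, wtp) {
  stopifnot(inherits(new, "strategy_result"),
            inherits(reference, "strategy_result"), wtp >= 0)
  if (identical(new$strategy, reference$strategy)) {
    stop("compared strategies must have distinct names", call. = FALSE)
  }
  dc <- new$cost - reference$cost
  de <- new$qalys - reference$qalys
  category <- if (dc == 0 && de == 0) {
    "equal"
  } else if ((dc < 0 && de >= 0) || (dc <= 0 && de > 0)) {
    "dominant"
  } else if ((dc > 0 && de <= 0) || (dc >= 0 && de < 0)) {
    "dominated"
  } else {
    "icer"
  }
  icer <- if (category == "icer") dc / de else NA_real_
  structure(list(new = new$strategy, reference = reference$strategy,
                 delta_cost = dc, delta_qalys = de, icer = icer,
                 category = category, inmb = wtp * de - dc, wtp = wtp),
            class = "cea_comparison")
}

#' @export
print.cea_comparison <- function(x, ...) {
  icer_txt <- if (x$category == "icer") sprintf("$%.2f/QALY", x$icer)
              else x$category
  cat(sprintf("%s vs %s: dCost $%.2f, dQALYs %.4f -> %s; INMB $%.2f at WTP $%s\n",
              x$new, x$reference, x$delta_cost, x$delta_qalys, icer_txt,
              x$inmb, format(x$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Cost-effectiveness efficiency frontier
#'
#' Sorts strategies by effectiveness, breaks effectiveness ties by lower
#' cost, removes strongly dominated strategies (another strategy costs no
#' more and is at least as effective, better on one margin), then removes
#' extendedly dominated strategies by the standard sweep: successive
#' pairwise ICERs along the frontier must be increasing.
#'
#' @param results List of `strategy_result`s (>= 1).
#' @return The non-dominated subset, ordered by increasing effectiveness.
#' @export
frontier <- function(results) {
  stopifnot(length(results) >= 1)
  df <- results_table(results)
  ord <- order(df$qalys, df$cost)
  df <- df[ord, ]
  results <- results[ord]
  # effectiveness ties: keep the cheaper (first after ordering)
  keep <- !duplicated(df$qalys)
  df <- df[keep, ]; results <- results[keep]
  # strong dominance: any other strategy with cost <= and qalys >= (one strict)
  dominated <- vapply(seq_len(nrow(df)), function(i) {
    any(df$cost <= df$cost[i] & df$qalys >= df$qalys[i] &
          (df$cost < df$cost[i] | df$qalys > df$qalys[i]))
  }, logical(1))
  df <- df[!dominated, ]; results <- results[!dominated]
  # extended dominance: ICERs along the frontier must increase
  repeat {
    if (nrow(df) < 3) break
    icers <- diff(df$cost) / diff(df$qalys)
    bad <- which(diff(icers) < 0)
    if (length(bad) == 0) break
    drop <- bad[1] + 1  # middle strategy of the first decreasing pair
    df <- df[-drop, ]; results <- results[-drop]
  }
  results
}
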