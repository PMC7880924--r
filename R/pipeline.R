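#' Run the full pipeline for one strategy
#'
#' Decision tree (diagnostic branches, acute time-0 cost, entry state
#' distribution) followed by the Markov cohort model.
#'
#' @param strategy A `strategy_spec`.
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param trace Keep the per-cycle trace (see [run_cohort()]).
#' @return A `strategy_result`: list with `strategy`, `cost` (acute +
#'   discounted long-term, USD), `qalys`, plus the `branches`, `acute_cost`
#'   and `markov` pieces.
#' @export
run_strategy <- function(strategy, params, conventions = cea_conventions(),
                         trace = FALSE) {
  stopifnot(inherits(strategy, "strategy_spec"))
  b <- classify(params$pretest_probability, strategy$sensitivity,
                strategy$specificity)
  ac <- acute_cost(b, strategy, params)
  init <- initial_state_distribution(b, conventions$entry)
  mk <- run_cohort(init, params, conventions, trace = trace)
  structure(list(strategy = strategy$name,
                 cost = ac + mk$total_cost,
                 qalys = mk$total_qalys,
                 acute_cost = ac, branches = b, markov = mk),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("%s: $%.2f, %.4f QALYs (acute $%.2f)\n",
              x$strategy, x$cost, x$qalys, x$acute_cost))
  invisible(x)
}

#' Bare strategy result from totals
#'
#' Convenience constructor used when totals come from elsewhere (for example
#' the microsimulation oracle or published figures).
#'
#' @param name Strategy label.
#' @param cost Total discounted cost, USD, >= 0.
#' @param qalys Total discounted effectiveness, QALYs, >= 0.
#' @return A `strategy_result`.
#' @export
strategy_result <- function(name, cost, qalys) {
  stopifnot(cost >= 0, qalys >= 0)
  structure(list(strategy = name, cost = cost, qalys = qalys),
            class = "strategy_result")
}

#' Deterministic base case for all strategies
#'
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param strategies Named list of `strategy_spec`s; defaults to the three
#'   compared strategies.
#' @return Named list of `strategy_result`s.
#' @export
run_base_case <- function(params = cea_parameters(),
                          conventions = cea_conventions(),
                          strategies = default_strategies(params)) {
  lapply(strategies, run_strategy, params = params, conventions = conventions)
}

#' Tabulate strategy results
#'
#' @param results List of `strategy_result`s.
#' @return data.frame with columns `strategy`, `cost`, `qalys`.
#' @export
results_table <- function(results) {
  data.frame(
    strategy = vapply(results, `[[`, "", "strategy"),
    cost = vapply(results, `[[`, 0, "cost"),
    qalys = vapply(results, `[[`, 0, "qalys"),
    row.names = NULL
  )
}
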