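#' Patient-level microsimulation
#'
#' Independent brute-force oracle for the cohort engine: each simulated
#' patient draws a disease truth from the pre-test probability, a test
#' result from the strategy's sensitivity or specificity, incurs the
#' branch's acute cost, enters the Markov state given by the entry
#' convention, and then walks the yearly state chain under the same
#' transition matrix, accruing discounted rewards with exactly the same
#' accrual timing as [run_cohort()] (state occupied in year t rewarded at
#' discount exponent t, or t - 0.5 under the half-cycle correction; incident
#' stenosis PTCA charges per the same flag). By the law of large numbers the
#' mean cost and QALYs converge to the cohort-model totals.
#'
#' @param n Number of patients, >= 1.
#' @param strategy A `strategy_spec`.
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param seed Integer seed; a fixed seed reproduces the trajectory list
#'   exactly.
#' @return A `microsim_result`: list with `trajectories` (data.frame:
#'   patient, truth, test_result, acute_cost, years_alive, disc_cost,
#'   disc_qalys), `mean_cost`, `mean_qalys`, `se_cost`, `se_qalys` (the
#'   means include acute costs, matching `acute + markov` totals).
#' @export
simulate_patients <- function(n, strategy, params,
                              conventions = cea_conventions(), seed = 1) {
  stopifnot(n >= 1, inherits(strategy, "strategy_spec"),
            inherits(params, "cea_parameters"),
            inherits(conventions, "cea_conventions"))
  set.seed(seed)
  truth <- stats::runif(n) < params$pretest_probability
  positive <- ifelse(truth,
                     stats::runif(n) < strategy$sensitivity,
                     stats::runif(n) >= strategy$specificity)
  acute <- strategy$imaging_cost +
    ifelse(truth & positive, params$cost_ptca,
    ifelse(truth & !positive, params$cost_ptca_delayed,
    ifelse(!truth & positive, params$cost_ica, 0)))

  # entry state per convention, patient-wise
  state <- rep(1L, n)  # 1 NoStenosis, 2 Stenosis, 3 Dead
  if (conventions$entry == "fn-diseased") {
    state[truth & !positive] <- 2L
  } else if (conventions$entry == "positives-decrement") {
    state[positive] <- 2L
  }

  lt <- if (conventions$mortality == "life-table") load_life_table() else NULL
  yearly_cost <- c(params$yearly_cost_no_stenosis,
                   params$yearly_cost_stenosis, 0)
  utility <- c(params$utility_no_stenosis, params$utility_stenosis,
               params$utility_dead)
  horizon <- params$horizon_cycles
  disc_cost <- numeric(n)
  disc_qalys <- numeric(n)
  years_alive <- numeric(n)
  m <- transition_matrix(params, conventions, params$start_age, lt)
  prev_state <- rep(1L, n)
  for (t in seq_len(horizon)) {
    age <- params$start_age + t - 1
    if (conventions$mortality == "life-table") {
      m <- transition_matrix(params, conventions, age, lt)
    }
    d <- discount_factor(if (conventions$half_cycle) t - 0.5 else t,
                         params$discount_rate)
    cost_t <- yearly_cost[state]
    if (conventions$charge_incident_ptca && t > 1) {
      cost_t <- cost_t +
        ifelse(state == 2L & prev_state == 1L, params$cost_ptca, 0)
    }
    disc_cost <- disc_cost + d * cost_t
    disc_qalys <- disc_qalys + d * utility[state]
    years_alive <- years_alive + (state != 3L)
    prev_state <- state
    # one categorical transition per alive patient, cycle-major draws
    u <- stats::runif(n)
    cum <- t(apply(m, 1, cumsum))
    nxt <- state
    for (s in 1:2) {
      idx <- state == s
      if (any(idx)) {
        nxt[idx] <- 1L + findInterval(u[idx], cum[s, ], left.open = TRUE)
      }
    }
    state <- nxt
  }
  traj <- data.frame(
    patient = seq_len(n),
    truth = as.integer(truth),
    test_result = as.integer(positive),
    acute_cost = acute,
    years_alive = years_alive,
    disc_cost = disc_cost,
    disc_qalys = disc_qalys
  )
  total <- acute + disc_cost
  structure(list(trajectories = traj,
                 mean_cost = mean(total),
                 mean_qalys = mean(disc_qalys),
                 se_cost = stats::sd(total) / sqrt(n),
                 se_qalys = stats::sd(disc_qalys) / sqrt(n),
                 strategy = strategy$name, n = n, seed = seed),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("microsimulation %s (n=%d): mean $%.2f (SE %.2f), %.4f QALYs (SE %.5f)\n",
              x$strategy, x$n, x$mean_cost, x$se_cost, x$mean_qalys,
              x$se_qalys))
  invisible(x)
}

#' Export microsimulation trajectories to CSV
#'
#' @param sim A `microsim_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trajectories <- function(sim, path) {
  stopifnot(inherits(sim, "microsim_result"))
  df <- sim$trajectories
  df$acute_cost <- sprintf("%.2f", df$acute_cost)
  df$disc_cost <- sprintf("%.2f", df$disc_cost)
  df$disc_qalys <- sprintf("%.4f", df$disc_qalys)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Generate a synthetic diagnostic-accuracy study
#'
#' Emulates the statistical structure of a prospective accuracy study: the
#' diseased count is binomial at the prevalence, true positives binomial at
#' the sensitivity among the diseased, and true negatives binomial at the
#' specificity among the non-diseased.
#'
#' @param n Cohort size, >= 1.
#' @param prevalence,sensitivity,specificity Generating rates in \[0, 1\].
#' @param seed Integer seed.
#' @return A `study_table`: list of integer counts `tp`, `fn`, `fp`, `tn`
#'   summing to `n`, with `n` and the generating rates as attributes.
#' @export
generate_study <- function(n, prevalence, sensitivity, specificity, seed = 1) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  set.seed(seed)
  diseased <- stats::rbinom(1, n, prevalence)
  tp <- stats::rbinom(1, diseased, sensitivity)
  tn <- stats::rbinom(1, n - diseased, specificity)
  structure(list(tp = tp, fn = diseased - tp, fp = n - diseased - tn,
                 tn = tn),
            n = n, prevalence = prevalence, sensitivity = sensitivity,
            specificity = specificity, class = "study_table")
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("2x2 study (n=%d): TP %d  FN %d  FP %d  TN %d\n",
              attr(x, "n"), x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Accuracy estimates from a 2x2 study table
#'
#' @param table A `study_table`.
#' @return Named numeric: `prevalence`, `sensitivity`, `specificity`
#'   (`NaN` where a margin is empty).
#' @export
estimate_accuracy <- function(table) {
  stopifnot(inherits(table, "study_table"))
  n <- attr(table, "n")
  c(prevalence = (table$tp + table$fn) / n,
    sensitivity = table$tp / (table$tp + table$fn),
    specificity = table$tn / (table$fp + table$tn))
}
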