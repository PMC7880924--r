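#' Model convention flags
#'
#' The published analysis leaves several structural choices open; each is a
#' named flag here so every result can state exactly which conventions
#' produced it.
#'
#' @param entry How diagnostic branches map to the entry state; see
#'   [initial_state_distribution()].
#' @param resolution `"tunnel"`: a newly stenosed patient spends one cycle in
#'   `Stenosis` (with its yearly cost and utility) and, surviving, returns to
#'   `NoStenosis` — the annual new-stenosis risk is a yearly revascularization
#'   rate, so the state is transient. `"persistent"`: once stenosed, a
#'   survivor remains in `Stenosis`.
#' @param risk_rule How per-cause annual risks combine within a row:
#'   `"multiplicative"` (default) treats them as independent,
#'   `1 - prod(1 - p_i)`, which always yields valid probabilities;
#'   `"additive"` sums them (errors if the sum exceeds 1).
#' @param half_cycle Half-cycle correction: discount exponent `t - 0.5`
#'   instead of `t`. Off by default.
#' @param mortality `"constant"` uses the flat other-cause death risk;
#'   `"life-table"` replaces it with the packaged age-specific schedule
#'   (synthetic; see [load_life_table()]), recomputing the transition matrix
#'   each cycle.
#' @param charge_incident_ptca If `TRUE`, patients newly transitioning into
#'   `Stenosis` during the simulation are charged one PTCA event cost in that
#'   cycle. Off by default: the yearly with-stenosis cost premium already
#'   represents revascularization-year expenses.
#' @return A `cea_conventions` object.
#' @export
cea_conventions <- function(entry = "all-treated",
                            resolution = "tunnel",
                            risk_rule = "multiplicative",
                            half_cycle = FALSE,
                            mortality = "constant",
                            charge_incident_ptca = FALSE) {
  entry <- match.arg(entry,
                     c("all-treated", "fn-diseased", "positives-decrement"))
  resolution <- match.arg(resolution, c("tunnel", "persistent"))
  risk_rule <- match.arg(risk_rule, c("multiplicative", "additive"))
  mortality <- match.arg(mortality, c("constant", "life-table"))
  structure(list(entry = entry, resolution = resolution,
                 risk_rule = risk_rule, half_cycle = isTRUE(half_cycle),
                 mortality = mortality,
                 charge_incident_ptca = isTRUE(charge_incident_ptca)),
            class = "cea_conventions")
}

#' @export
print.cea_conventions <- function(x, ...) {
  cat("model conventions:",
      sprintf("entry=%s, resolution=%s, risks=%s, half-cycle=%s, mortality=%s, incident-PTCA-charge=%s\n",
              x$entry, x$resolution, x$risk_rule,
              if (x$half_cycle) "on" else "off", x$mortality,
              if (x$charge_incident_ptca) "on" else "off"))
  invisible(x)
}

#' Discount factor
#'
#' @param t Time in years since model entry, >= 0.
#' @param rate Annual discount rate, >= 0.
#' @return `(1 + rate)^(-t)`.
#' @export
discount_factor <- function(t, rate) {
  stopifnot(all(t >= 0), rate >= 0)
  (1 + rate)^(-t)
}

#' Packaged age-specific mortality schedule
#'
#' Loads the synthetic annual other-cause death-probability schedule shipped
#' with the package: a Gompertz-Makeham curve anchored to the base-case
#' other-cause risk at age 65 (it is a constructed stand-in, not national
#' life-table data). Used when the `mortality = "life-table"` convention is
#' selected.
#'
#' @return A data.frame with columns `age` and `qx`.
#' @export
load_life_table <- function() {
  path <- system.file("extdata", "synthetic_life_table.csv",
                      package = "ctpcea")
  utils::read.csv(path)
}

.other_cause_risk <- function(age, params, conventions, life_table = NULL) {
  if (conventions$mortality == "constant") return(params$p_death_other)
  if (is.null(life_table)) life_table <- load_life_table()
  i <- findInterval(age, life_table$age)
  i <- pmin(pmax(i, 1L), nrow(life_table))
  life_table$qx[i]
}

.combine_risks <- function(risks, risk_rule) {
  if (risk_rule == "multiplicative") 1 - prod(1 - risks) else sum(risks)
}

#' Annual transition matrix
#'
#' Rows and columns are indexed `NoStenosis`, `Stenosis`, `Dead`; `Dead` is
#' absorbing. The `NoStenosis` row combines the annual risk of a new
#' relevant stenosis with disease and other-cause death under the configured
#' risk rule (under the multiplicative rule the stenosis risk applies to the
#' survivors of the combined death risk); the `Stenosis` row combines its
#' own death risks, with the surviving mass returning to `NoStenosis` under
#' the `"tunnel"` resolution or remaining under `"persistent"`.
#'
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param age Attained age at the start of the cycle (used by the
#'   life-table mortality option); defaults to `params$start_age`.
#' @param life_table Optional preloaded schedule from [load_life_table()].
#' @return 3x3 numeric matrix with rows summing to 1.
#' @export
transition_matrix <- function(params, conventions = cea_conventions(),
                              age = params$start_age, life_table = NULL) {
  stopifnot(inherits(params, "cea_parameters"),
            inherits(conventions, "cea_conventions"))
  if (age < params$start_age || age > 110) {
    stop("age must lie in [start_age, 110]", call. = FALSE)
  }
  q_other <- .other_cause_risk(age, params, conventions, life_table)
  d_no <- .combine_risks(c(params$p_death_no_stenosis, q_other),
                         conventions$risk_rule)
  d_st <- .combine_risks(c(params$p_death_stenosis, q_other),
                         conventions$risk_rule)
  if (conventions$risk_rule == "additive") {
    if (d_no + params$p_new_stenosis > 1 || d_st > 1) {
      stop("additive risks exceed 1; use risk_rule = 'multiplicative'",
           call. = FALSE)
    }
    to_sten <- params$p_new_stenosis
  } else {
    to_sten <- (1 - d_no) * params$p_new_stenosis
  }
  m <- matrix(0, 3, 3, dimnames = list(.states, .states))
  m["NoStenosis", ] <- c(1 - d_no - to_sten, to_sten, d_no)
  if (conventions$resolution == "tunnel") {
    m["Stenosis", ] <- c(1 - d_st, 0, d_st)
  } else {
    m["Stenosis", ] <- c(0, 1 - d_st, d_st)
  }
  m["Dead", "Dead"] <- 1
  m
}

#' Run the Markov cohort model
#'
#' Propagates a cohort through the three-state model for
#' `params$horizon_cycles` annual cycles. The state occupied during cycle
#' `t` is the occupancy after `t - 1` transitions (entry distribution for
#' cycle 1); each cycle accrues `occupancy . yearly costs` and
#' `occupancy . utilities`, discounted at exponent `t` (or `t - 0.5` with
#' the half-cycle correction). When `charge_incident_ptca` is on, the mass
#' newly flowing `NoStenosis -> Stenosis` is additionally charged one PTCA
#' in its stenosis cycle; the entry cohort is never charged (its procedures
#' are acute, time-0 costs handled by the decision tree).
#'
#' @param initial Named or positional probability vector over
#'   (`NoStenosis`, `Stenosis`, `Dead`), summing to 1.
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param trace If `FALSE`, skip building the per-cycle data.frame and
#'   return totals only (fast path for sensitivity analyses).
#' @return A `markov_trace`: list with `trace` (data.frame: cycle, age,
#'   occupancy per state during the cycle, discounted cost and QALY
#'   increments, cumulative totals), `total_cost`, `total_qalys`.
#' @export
run_cohort <- function(initial, params, conventions = cea_conventions(),
                       trace = TRUE) {
  stopifnot(inherits(params, "cea_parameters"),
            inherits(conventions, "cea_conventions"))
  initial <- as.numeric(initial)
  if (length(initial) != 3 || any(initial < 0) ||
      abs(sum(initial) - 1) > 1e-9) {
    stop("initial must be a 3-state probability distribution summing to 1",
         call. = FALSE)
  }
  n <- params$horizon_cycles
  lt <- if (conventions$mortality == "life-table") load_life_table() else NULL
  age_varying <- conventions$mortality == "life-table"
  m <- transition_matrix(params, conventions, params$start_age, lt)

  yearly_cost <- c(params$yearly_cost_no_stenosis,
                   params$yearly_cost_stenosis, 0)
  utility <- c(params$utility_no_stenosis, params$utility_stenosis,
               params$utility_dead)

  v <- initial
  total_cost <- 0
  total_qalys <- 0
  rows <- if (trace && n > 0) vector("list", n) else NULL
  incident <- 0
  for (t in seq_len(n)) {
    age <- params$start_age + t - 1
    if (age_varying) m <- transition_matrix(params, conventions, age, lt)
    d <- discount_factor(if (conventions$half_cycle) t - 0.5 else t,
                         params$discount_rate)
    cost_t <- sum(v * yearly_cost) +
      if (conventions$charge_incident_ptca) incident * params$cost_ptca else 0
    qaly_t <- sum(v * utility)
    total_cost <- total_cost + d * cost_t
    total_qalys <- total_qalys + d * qaly_t
    if (trace) {
      rows[[t]] <- data.frame(cycle = t, age = age,
                              NoStenosis = v[1], Stenosis = v[2], Dead = v[3],
                              disc_cost = d * cost_t, disc_qaly = d * qaly_t)
    }
    incident <- v[1] * m["NoStenosis", "Stenosis"]
    v <- as.numeric(v %*% m)
  }
  tr <- if (trace) {
    out <- if (n > 0) do.call(rbind, rows) else
      data.frame(cycle = integer(), age = numeric(), NoStenosis = numeric(),
                 Stenosis = numeric(), Dead = numeric(),
                 disc_cost = numeric(), disc_qaly = numeric())
    out$cum_cost <- cumsum(out$disc_cost)
    out$cum_qalys <- cumsum(out$disc_qaly)
    out
  } else NULL
  structure(list(trace = tr, total_cost = total_cost,
                 total_qalys = total_qalys, conventions = conventions),
            class = "markov_trace")
}

#' @export
print.markov_trace <- function(x, ...) {
  n <- if (is.null(x$trace)) NA_integer_ else nrow(x$trace)
  cat(sprintf("Markov cohort trace: %s cycles, discounted totals $%.2f / %.4f QALYs\n",
              n, x$total_cost, x$total_qalys))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param trace A `markov_trace` from [run_cohort()] (with `trace = TRUE`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path) {
  stopifnot(inherits(trace, "markov_trace"), !is.null(trace$trace))
  df <- trace$trace
  df$disc_cost <- sprintf("%.2f", df$disc_cost)
  df$cum_cost <- sprintf("%.2f", df$cum_cost)
  df$disc_qaly <- sprintf("%.4f", df$disc_qaly)
  df$cum_qalys <- sprintf("%.4f", df$cum_qalys)
  for (s in .states) df[[s]] <- sprintf("%.6f", df[[s]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
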