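#' Joint diagnostic-outcome probabilities
#'
#' Crosses disease prevalence with a test's sensitivity and specificity to
#' obtain the joint probabilities of the four diagnostic outcomes:
#' true positive, false negative, false positive, true negative.
#'
#' @param prevalence Pre-test probability of treatment-requiring stenosis.
#' @param sensitivity,specificity Test operating characteristics in \[0, 1\].
#' @return A `branch_probabilities` object: named list with elements `tp`,
#'   `fn`, `fp`, `tn` summing to 1, with the prevalence kept as an attribute.
#' @examples
#' classify(0.6267, 1.000, 0.429)$fp  # 0.2132, the combined strategy's
#'                                    # false-positive rate of ~21.3%
#' @export
classify <- function(prevalence, sensitivity, specificity) {
  for (v in c(prevalence, sensitivity, specificity)) {
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("classify() inputs must be probabilities in [0, 1]", call. = FALSE)
    }
  }
  b <- list(
    tp = prevalence * sensitivity,
    fn = prevalence * (1 - sensitivity),
    fp = (1 - prevalence) * (1 - specificity),
    tn = (1 - prevalence) * specificity
  )
  structure(b, prevalence = prevalence, class = "branch_probabilities")
}

#' @export
print.branch_probabilities <- function(x, ...) {
  cat(sprintf("branches (prevalence %.4f): TP %.6f  FN %.6f  FP %.6f  TN %.6f\n",
              attr(x, "prevalence"), x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Strategy definition
#'
#' @param name Strategy label (`"CTA"`, `"CTP"`, `"CTA_CTP"`, or any unique
#'   name).
#' @param sensitivity,specificity Operating characteristics in \[0, 1\].
#' @param imaging_cost Acute imaging cost in USD.
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name, sensitivity, specificity, imaging_cost) {
  stopifnot(is.character(name), length(name) == 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            imaging_cost >= 0)
  structure(list(name = name, sensitivity = sensitivity,
                 specificity = specificity, imaging_cost = imaging_cost),
            class = "strategy_spec")
}

#' The three compared strategies at current parameter values
#'
#' CTA, CTP and the combined CTA+CTP strategy. The combined strategy uses
#' the empirical accuracies of the source diagnostic study (sensitivity
#' 1.000, specificity 0.429 at base values) rather than the discordant-
#' positive composition rule; see [combine_tests_or_rule()] for the
#' analytic cross-check.
#'
#' @param params A `cea_parameters` object.
#' @return Named list of three `strategy_spec`s.
#' @export
default_strategies <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  list(
    CTA = strategy_spec("CTA", params$sens_cta, params$spec_cta,
                        params$cost_cta),
    CTP = strategy_spec("CTP", params$sens_ctp, params$spec_ctp,
                        params$cost_ctp),
    CTA_CTP = strategy_spec("CTA_CTP", params$sens_combo, params$spec_combo,
                            params$cost_combo)
  )
}

#' Expected acute (time-0) cost of a strategy
#'
#' True positives incur a timely PTCA, false negatives a delayed PTCA
#' (1.3x as expensive by assumption), false positives an unnecessary ICA
#' without revascularization, and true negatives no acute treatment cost.
#' The imaging cost is always incurred. Acute costs are charged at model
#' entry, undiscounted.
#'
#' @param branches A `branch_probabilities` object.
#' @param strategy A `strategy_spec` (its `imaging_cost` is used).
#' @param params A `cea_parameters` object.
#' @return Expected acute cost in USD.
#' @export
acute_cost <- function(branches, strategy, params) {
  stopifnot(inherits(branches, "branch_probabilities"),
            inherits(strategy, "strategy_spec"),
            inherits(params, "cea_parameters"))
  strategy$imaging_cost +
    branches$tp * params$cost_ptca +
    branches$fn * params$cost_ptca_delayed +
    branches$fp * params$cost_ica
}

#' Compose two tests under the discordant-positive rule
#'
#' If any positive result from either test is called positive, the composite
#' sensitivity is `1 - (1 - sensA) (1 - sensB)` and the composite specificity
#' `specA * specB` (assuming conditional independence). Provided as a
#' diagnostic cross-check: the pipeline's combined strategy defaults to the
#' source study's empirical accuracies, which this rule does not reproduce
#' (0.305 vs the empirical 0.429 specificity at base values).
#'
#' @param sens_a,spec_a,sens_b,spec_b Marginal accuracies in \[0, 1\].
#' @return Named numeric: `sensitivity`, `specificity`.
#' @export
combine_tests_or_rule <- function(sens_a, spec_a, sens_b, spec_b) {
  for (v in c(sens_a, spec_a, sens_b, spec_b)) {
    stopifnot(is.numeric(v), length(v) == 1, v >= 0, v <= 1)
  }
  c(sensitivity = 1 - (1 - sens_a) * (1 - sens_b),
    specificity = spec_a * spec_b)
}

.states <- c("NoStenosis", "Stenosis", "Dead")

#' Initial Markov state distribution for a diagnosed cohort
#'
#' Maps the four diagnostic branches onto the three health states under a
#' named entry convention; nobody enters dead.
#'
#' \describe{
#'   \item{`all-treated`}{Everyone enters `NoStenosis`: positives are treated
#'     at entry (timely or, for false negatives, delayed PTCA whose cost is
#'     already charged acutely) and negatives without disease are well. The
#'     package default.}
#'   \item{`fn-diseased`}{False negatives spend their first cycle in
#'     `Stenosis` (disease initially missed); everyone else enters
#'     `NoStenosis`.}
#'   \item{`positives-decrement`}{All test positives (TP + FP) spend their
#'     first cycle in `Stenosis`, carrying its utility decrement and cost
#'     premium through the peri-procedural year.}
#' }
#'
#' @param branches A `branch_probabilities` object.
#' @param convention One of `"all-treated"`, `"fn-diseased"`,
#'   `"positives-decrement"`.
#' @return Named probability vector over `NoStenosis`, `Stenosis`, `Dead`.
#' @export
initial_state_distribution <- function(branches,
                                       convention = "all-treated") {
  stopifnot(inherits(branches, "branch_probabilities"))
  stenosis <- switch(convention,
    "all-treated" = 0,
    "fn-diseased" = branches$fn,
    "positives-decrement" = branches$tp + branches$fp,
    stop("unknown entry convention: '", convention, "'", call. = FALSE)
  )
  stats::setNames(c(1 - stenosis, stenosis, 0), .states)
}
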