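#' Distribution specifications for probabilistic sensitivity analysis
#'
#' A distribution spec carries a family (`beta`, `gamma` or `fixed`), its
#' hyperparameters, and a provenance tag. Probabilities and utilities are
#' given beta distributions, costs gamma distributions; parameters without
#' sampling uncertainty (or with a degenerate mean of 0 or 1) are `fixed`.
#'
#' @param value The constant returned by every draw.
#' @return An object of class `dist_spec`.
#' @export
fixed_spec <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1, !is.na(value))
  value <- unname(value)
  structure(list(family = "fixed", hyperparameters = c(value = value),
                 provenance = "from_table"),
            class = "dist_spec")
}

#' Fit a beta distribution by moment matching
#'
#' Parameterizes a beta distribution from a mean and an effective sample
#' size: `alpha = mean * n_eff`, `beta = (1 - mean) * n_eff`, so the analytic
#' mean equals the input mean. A degenerate mean of exactly 0 or 1 cannot be
#' represented by a proper beta; a `fixed` spec is returned with a warning.
#'
#' @param mean Target mean in (0, 1); 0 or 1 degenerates to a fixed spec.
#' @param n_eff Effective sample size, > 0.
#' @return A `dist_spec`.
#' @examples
#' fit_beta_moments(0.914, 150)  # alpha 137.1, beta 12.9
#' @export
fit_beta_moments <- function(mean, n_eff) {
  stopifnot(is.numeric(mean), length(mean) == 1, mean >= 0, mean <= 1)
  mean <- unname(mean); n_eff <- unname(n_eff)
  if (!is.numeric(n_eff) || length(n_eff) != 1 || n_eff <= 0) {
    stop("n_eff must be a positive real", call. = FALSE)
  }
  if (mean == 0 || mean == 1) {
    warning("degenerate mean ", mean,
            ": returning a fixed spec instead of a beta")
    return(fixed_spec(mean))
  }
  structure(list(family = "beta",
                 hyperparameters = c(alpha = mean * n_eff,
                                     beta = (1 - mean) * n_eff),
                 provenance = "fitted"),
            class = "dist_spec")
}

#' Fit a gamma distribution by moment matching
#'
#' Parameterizes a gamma distribution from a mean and standard error:
#' `shape = (mean/se)^2`, `scale = se^2/mean`, so the analytic mean and
#' standard deviation equal the inputs.
#'
#' @param mean Target mean, > 0.
#' @param se Target standard deviation, > 0.
#' @return A `dist_spec`.
#' @examples
#' fit_gamma_moments(100, 10)  # shape 100, scale 1
#' @export
fit_gamma_moments <- function(mean, se) {
  if (!is.numeric(mean) || length(mean) != 1 || mean <= 0) {
    stop("mean must be a positive real", call. = FALSE)
  }
  if (!is.numeric(se) || length(se) != 1 || se <= 0) {
    stop("se must be a positive real", call. = FALSE)
  }
  mean <- unname(mean); se <- unname(se)
  structure(list(family = "gamma",
                 hyperparameters = c(shape = (mean / se)^2,
                                     scale = se^2 / mean),
                 provenance = "fitted"),
            class = "dist_spec")
}

#' Draw from a distribution spec
#'
#' @param spec A `dist_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Fixed specs return the stored value
#'   exactly and consume no random numbers.
#' @export
draw_spec <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyperparameters
  switch(spec$family,
    fixed = rep(unname(h["value"]), n),
    beta  = stats::rbeta(n, h["alpha"], h["beta"]),
    gamma = stats::rgamma(n, shape = h["shape"], scale = h["scale"]),
    stop("unknown distribution family: ", spec$family, call. = FALSE)
  )
}

#' Analytic mean of a distribution spec
#' @param spec A `dist_spec`.
#' @return The distribution's mean.
#' @export
spec_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  h <- spec$hyperparameters
  switch(spec$family,
    fixed = unname(h["value"]),
    beta  = unname(h["alpha"] / (h["alpha"] + h["beta"])),
    gamma = unname(h["shape"] * h["scale"])
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(x$family, "spec:",
      paste(names(x$hyperparameters), signif(x$hyperparameters, 6),
            sep = "=", collapse = ", "),
      sprintf("(%s)\n", x$provenance))
  invisible(x)
}

#' Default sampling distributions for the PSA
#'
#' Attaches a distribution spec to every input the base-case table marks as
#' distributed: beta for the pre-test probability and diagnostic accuracies
#' (effective sample size `n_eff_accuracy`, the source diagnostic-accuracy
#' cohort size), beta for utilities and annual transition probabilities
#' (`n_eff_rates`), and gamma for costs with a standard error of
#' `cost_cv` times the mean. No dispersion is published for any input, so
#' these are modelling assumptions and fully configurable.
#'
#' Accuracies with a base value of exactly 1 (CTA and combined sensitivity)
#' become fixed specs. When `params$linked_assumption` is on, the delayed
#' PTCA cost, the yearly with-stenosis cost and the combined imaging cost
#' carry no spec of their own: they are recomputed from their sampled
#' partners each iteration. With the link off they receive independent gamma
#' specs. Analysis settings (WTP, discount rate, horizon, start age) and the
#' dead-state utility are never sampled.
#'
#' @param params A `cea_parameters` object.
#' @param n_eff_accuracy Effective sample size for prevalence and accuracies.
#' @param n_eff_rates Effective sample size for utilities and transition
#'   probabilities.
#' @param cost_cv Coefficient of variation for all cost distributions.
#' @return Named list of `dist_spec`, keyed by parameter field.
#' @export
default_distributions <- function(params, n_eff_accuracy = 150,
                                  n_eff_rates = 100, cost_cv = 0.2) {
  stopifnot(inherits(params, "cea_parameters"))
  beta_of <- function(f, ne) suppressWarnings(fit_beta_moments(params[[f]], ne))
  gamma_of <- function(f) fit_gamma_moments(params[[f]], cost_cv * params[[f]])
  acc <- c("pretest_probability", "sens_cta", "spec_cta", "sens_ctp",
           "spec_ctp", "sens_combo", "spec_combo")
  rates <- c("utility_no_stenosis", "utility_stenosis", "p_new_stenosis",
             "p_death_stenosis", "p_death_no_stenosis", "p_death_other")
  costs <- c("cost_cta", "cost_ctp", "cost_ica", "cost_ptca",
             "yearly_cost_no_stenosis")
  specs <- c(
    stats::setNames(lapply(acc, beta_of, ne = n_eff_accuracy), acc),
    stats::setNames(lapply(rates, beta_of, ne = n_eff_rates), rates),
    stats::setNames(lapply(costs, gamma_of), costs)
  )
  if (!isTRUE(params$linked_assumption)) {
    specs$cost_ptca_delayed <- gamma_of("cost_ptca_delayed")
    specs$yearly_cost_stenosis <- gamma_of("yearly_cost_stenosis")
  }
  specs
}
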