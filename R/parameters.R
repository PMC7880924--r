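#' Base-case model inputs
#'
#' Returns the full set of base-case model inputs: pre-test probability of a
#' stenosis requiring PTCA, per-test diagnostic accuracies, acute procedure
#' costs, yearly state costs, health-state utilities, annual transition
#' probabilities, and the analysis settings (willingness to pay, discount
#' rate, horizon, start age). All costs are 2019 USD.
#'
#' Two inputs are linked by assumption to others: the delayed-PTCA cost is
#' 1.3 times the timely PTCA cost, and the yearly cost with relevant stenosis
#' is 1.3 times the yearly cost without. While `linked_assumption` is `TRUE`
#' (the default) these two fields are recomputed from their partners whenever
#' a parameter set is built.
#'
#' @return A named list of base values (not yet validated; see
#'   [cea_parameters()]).
#' @export
default_parameters <- function() {
  list(
    pretest_probability = 0.6267,
    start_age = 65,
    wtp = 100000,
    discount_rate = 0.03,
    horizon_cycles = 10L,
    sens_cta = 1.000, spec_cta = 0.386,
    sens_ctp = 0.914, spec_ctp = 0.789,
    sens_combo = 1.000, spec_combo = 0.429,
    cost_cta = 397.87,
    cost_ctp = 470.31,
    cost_combo = 397.87 + 470.31,
    cost_ica = 2810.00,
    cost_ptca = 4678.00,
    cost_ptca_delayed = 6081.40,
    yearly_cost_no_stenosis = 5837.27,
    yearly_cost_stenosis = 7588.45,
    utility_no_stenosis = 0.75,
    utility_stenosis = 0.70,
    utility_dead = 0,
    p_new_stenosis = 0.0264,
    p_death_stenosis = 0.0230,
    p_death_no_stenosis = 0.0232,
    p_death_other = 0.0126,
    linked_assumption = TRUE
  )
}

.prob_fields <- c(
  "pretest_probability",
  "sens_cta", "spec_cta", "sens_ctp", "spec_ctp", "sens_combo", "spec_combo",
  "utility_no_stenosis", "utility_stenosis", "utility_dead",
  "p_new_stenosis", "p_death_stenosis", "p_death_no_stenosis", "p_death_other"
)

.cost_fields <- c(
  "cost_cta", "cost_ctp", "cost_combo", "cost_ica", "cost_ptca",
  "cost_ptca_delayed", "yearly_cost_no_stenosis", "yearly_cost_stenosis"
)

#' Construct a validated parameter set
#'
#' Builds a parameter set from the base-case values, overriding any field
#' supplied as a named argument, then validates ranges. When
#' `linked_assumption` is `TRUE`, `cost_ptca_delayed` and
#' `yearly_cost_stenosis` are recomputed as 1.3 times `cost_ptca` and
#' `yearly_cost_no_stenosis` respectively (unless the dependent field itself
#' is explicitly overridden, which decouples it for that call), and
#' `cost_combo` defaults to `cost_cta + cost_ctp` unless overridden.
#'
#' @param ... Named fields overriding base values; unknown names are an error.
#' @return An object of class `cea_parameters`.
#' @examples
#' p <- cea_parameters()
#' p$pretest_probability
#' cea_parameters(cost_ptca = 5000)$cost_ptca_delayed  # 6500
#' @export
cea_parameters <- function(...) {
  over <- list(...)
  base <- default_parameters()
  unknown <- setdiff(names(over), names(base))
  if (length(unknown) > 0) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  params <- utils::modifyList(base, over)
  params <- .apply_links(params, explicit = names(over))
  validate_parameters(params)
}

# Recompute linked 1.3x fields and the combined imaging cost. Fields the
# caller set explicitly stay as given (explicit override decouples them).
.apply_links <- function(params, explicit = character()) {
  if (isTRUE(params$linked_assumption)) {
    if (!"cost_ptca_delayed" %in% explicit) {
      params$cost_ptca_delayed <- 1.3 * params$cost_ptca
    }
    if (!"yearly_cost_stenosis" %in% explicit) {
      params$yearly_cost_stenosis <- 1.3 * params$yearly_cost_no_stenosis
    }
  }
  if (!"cost_combo" %in% explicit) {
    params$cost_combo <- params$cost_cta + params$cost_ctp
  }
  params
}

#' Validate a parameter set
#'
#' Checks that all probabilities and utilities lie in \[0, 1\], costs are
#' nonnegative, the discount rate is nonnegative, the horizon is a
#' nonnegative integer count of cycles, and the utility of the dead state
#' is zero.
#'
#' @param params A named list of model inputs.
#' @return The validated object, classed `cea_parameters`.
#' @export
validate_parameters <- function(params) {
  required <- names(default_parameters())
  missing <- setdiff(required, names(params))
  if (length(missing) > 0) {
    stop("missing required parameter field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  # canonical storage types: doubles for all numeric fields (JSON readers
  # may deliver integers), logical for the link flag
  for (f in setdiff(required, "linked_assumption")) {
    if (is.numeric(params[[f]])) params[[f]] <- as.numeric(params[[f]])
  }
  params$linked_assumption <- isTRUE(params$linked_assumption)
  for (f in .prob_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop("field '", f, "' must be a probability in [0, 1], got ",
           format(v), call. = FALSE)
    }
  }
  for (f in .cost_fields) {
    v <- params[[f]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0) {
      stop("field '", f, "' must be a nonnegative cost, got ",
           format(v), call. = FALSE)
    }
  }
  if (params$discount_rate < 0) {
    stop("field 'discount_rate' must be >= 0", call. = FALSE)
  }
  if (params$horizon_cycles < 0 || params$horizon_cycles %% 1 != 0) {
    stop("field 'horizon_cycles' must be a nonnegative integer", call. = FALSE)
  }
  if (params$start_age < 0 || params$start_age > 110) {
    stop("field 'start_age' must be in [0, 110]", call. = FALSE)
  }
  if (params$wtp < 0) {
    stop("field 'wtp' must be >= 0", call. = FALSE)
  }
  if (params$utility_dead != 0) {
    stop("field 'utility_dead' must be 0", call. = FALSE)
  }
  structure(params, class = "cea_parameters")
}

#' Load a parameter set from a JSON configuration
#'
#' Keys are named exactly as the parameter-set fields; unknown keys are
#' rejected; omitted keys fall back to the base-case values. The linked
#' 1.3x fields are recomputed when `linked_assumption` is on and the field
#' is not set explicitly in the file.
#'
#' @param path Path to a JSON file.
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(cfg)) stop("configuration must be a JSON object", call. = FALSE)
  do.call(cea_parameters, cfg)
}

#' Save a parameter set to JSON
#'
#' Written at full precision so that a save/load round trip reproduces every
#' field exactly.
#'
#' @param params A `cea_parameters` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  stopifnot(inherits(params, "cea_parameters"))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                       digits = I(17))
  invisible(path)
}

#' @export
print.cea_parameters <- function(x, ...) {
  cat("Model parameter set (", length(x), " fields)\n", sep = "")
  cat(sprintf("  pre-test probability %.4f | WTP $%s/QALY | discount %.1f%% | %d annual cycles from age %g\n",
              x$pretest_probability, format(x$wtp, big.mark = ",", scientific = FALSE),
              100 * x$discount_rate, x$horizon_cycles, x$start_age))
  cat(sprintf("  CTA sens/spec %.3f/%.3f  CTP %.3f/%.3f  CTA+CTP %.3f/%.3f\n",
              x$sens_cta, x$spec_cta, x$sens_ctp, x$spec_ctp,
              x$sens_combo, x$spec_combo))
  cat(sprintf("  linked 1.3x assumption: %s\n",
              if (isTRUE(x$linked_assumption)) "on" else "off"))
  invisible(x)
}

#' Extend the horizon to a lifetime run
#'
#' Sets the number of annual cycles so the cohort is followed to age 100.
#'
#' @param params A `cea_parameters` object.
#' @return The parameter set with `horizon_cycles = 100 - start_age`.
#' @export
lifetime_horizon <- function(params) {
  stopifnot(inherits(params, "cea_parameters"))
  params$horizon_cycles <- as.integer(max(0, 100 - params$start_age))
  validate_parameters(params)
}
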