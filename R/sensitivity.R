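#' Replace one field of a parameter set
#'
#' Sets `name` to `value` and re-derives dependent fields: with the linked
#' assumption on, varying `cost_ptca` or `yearly_cost_no_stenosis` moves its
#' 1.3x partner, and varying `cost_cta` or `cost_ctp` moves the combined
#' imaging cost; setting a linked dependent field explicitly decouples it for
#' that call.
#'
#' @param params A `cea_parameters` object.
#' @param name Field name.
#' @param value New value.
#' @return A validated `cea_parameters` object.
#' @export
set_parameter <- function(params, name, value) {
  stopifnot(inherits(params, "cea_parameters"))
  if (!name %in% names(params)) {
    stop("unknown parameter name: '", name, "'", call. = FALSE)
  }
  p <- unclass(params)
  p[[name]] <- value
  p <- .apply_links(p, explicit = name)
  validate_parameters(p)
}

#' One-way sensitivity range
#'
#' @param parameter Field name in the parameter set.
#' @param low,high Range bounds in the parameter's units.
#' @param n_points Number of evenly spaced evaluation points, >= 2 (a
#'   zero-width range is permitted and evaluates identical points).
#' @param must_bracket If `TRUE` (default), [one_way_dsa()] checks that the
#'   base value lies inside `[low, high]`.
#' @return A `dsa_range` object.
#' @export
dsa_range <- function(parameter, low, high, n_points = 11,
                      must_bracket = TRUE) {
  stopifnot(is.character(parameter), length(parameter) == 1,
            low <= high, n_points >= 2)
  structure(list(parameter = parameter, low = low, high = high,
                 n_points = as.integer(n_points),
                 must_bracket = isTRUE(must_bracket)),
            class = "dsa_range")
}

#' The published one-way sensitivity ranges
#'
#' The five ranges examined in the source analysis, expanded to one row per
#' parameter: CTP imaging cost $370-570, each diagnostic accuracy +/- 5
#' percentage points (clipped to \[0, 1\], so CTA sensitivity at base 1.00
#' varies only downward), ICA cost +/- $500, PTCA cost +/- $1000, and
#' pre-test probability 40-80%.
#'
#' @param params A `cea_parameters` object (for the base accuracies).
#' @return List of `dsa_range`s.
#' @export
default_dsa_ranges <- function(params = cea_parameters()) {
  pm5 <- function(f) dsa_range(f, max(0, params[[f]] - 0.05),
                               min(1, params[[f]] + 0.05))
  list(
    dsa_range("cost_ctp", 370, 570),
    pm5("sens_cta"), pm5("spec_cta"), pm5("sens_ctp"), pm5("spec_ctp"),
    dsa_range("cost_ica", params$cost_ica - 500, params$cost_ica + 500),
    dsa_range("cost_ptca", params$cost_ptca - 1000, params$cost_ptca + 1000),
    dsa_range("pretest_probability", 0.40, 0.80)
  )
}

.inmb_at <- function(params, conventions, wtp,
                     new = "CTP", reference = "CTA") {
  strategies <- default_strategies(params)
  rn <- run_strategy(strategies[[new]], params, conventions, trace = FALSE)
  rr <- run_strategy(strategies[[reference]], params, conventions,
                     trace = FALSE)
  compare(rn, rr, wtp)$inmb
}

#' One-way deterministic sensitivity analysis
#'
#' Re-runs the full pipeline at each grid point of one parameter's range,
#' holding everything else at base values (linked 1.3x partners move per the
#' link flag), and returns the incremental net monetary benefit of CTP
#' versus CTA at each point.
#'
#' @param range A `dsa_range`.
#' @param params A `cea_parameters` object.
#' @param wtp Willingness to pay; defaults to `params$wtp`.
#' @param conventions A `cea_conventions` object.
#' @return data.frame with columns `value` and `inmb`, with attributes
#'   `parameter` and `span` (`max(inmb) - min(inmb)`).
#' @export
one_way_dsa <- function(range, params, wtp = params$wtp,
                        conventions = cea_conventions()) {
  stopifnot(inherits(range, "dsa_range"))
  if (!range$parameter %in% names(params)) {
    stop("unknown parameter name: '", range$parameter, "'", call. = FALSE)
  }
  base <- params[[range$parameter]]
  if (range$must_bracket && (base < range$low || base > range$high)) {
    stop("base value ", base, " of '", range$parameter,
         "' outside range [", range$low, ", ", range$high, "]",
         call. = FALSE)
  }
  grid <- seq(range$low, range$high, length.out = range$n_points)
  inmb <- vapply(grid, function(v) {
    .inmb_at(set_parameter(params, range$parameter, v), conventions, wtp)
  }, numeric(1))
  out <- data.frame(value = grid, inmb = inmb)
  attr(out, "parameter") <- range$parameter
  attr(out, "span") <- max(inmb) - min(inmb)
  out
}

#' Tornado table
#'
#' One row per parameter range: INMB of CTP versus CTA at the low and high
#' bound and the absolute span, sorted by descending span with the parameter
#' name as tie-break.
#'
#' @param ranges List of `dsa_range`s (>= 1).
#' @param params A `cea_parameters` object.
#' @param wtp Willingness to pay; defaults to `params$wtp`.
#' @param conventions A `cea_conventions` object.
#' @return data.frame with columns `parameter`, `low`, `high`, `inmb_low`,
#'   `inmb_high`, `span`.
#' @export
tornado <- function(ranges, params, wtp = params$wtp,
                    conventions = cea_conventions()) {
  stopifnot(length(ranges) >= 1)
  rows <- lapply(ranges, function(r) {
    d <- one_way_dsa(dsa_range(r$parameter, r$low, r$high, n_points = 2,
                               must_bracket = r$must_bracket),
                     params, wtp, conventions)
    data.frame(parameter = r$parameter, low = r$low, high = r$high,
               inmb_low = d$inmb[1], inmb_high = d$inmb[2],
               span = abs(d$inmb[2] - d$inmb[1]))
  })
  out <- do.call(rbind, rows)
  out[order(-out$span, out$parameter), , drop = FALSE]
}

# Independent substream seeds below 2^31, derived from one master seed.
.substream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2147483646L, n, replace = FALSE)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo over parameter uncertainty: each iteration draws one value
#' per distributed parameter (independent draws, one RNG substream per
#' iteration keyed by the iteration index under the master seed), rebuilds
#' the parameter set (linked 1.3x fields follow their sampled partners when
#' the link is on), runs all strategies on the identical draw, and records
#' the incremental quantities of CTP versus CTA.
#'
#' @param n_iterations Number of Monte Carlo iterations, >= 1.
#' @param seed Master seed (integer).
#' @param params Base `cea_parameters`.
#' @param dists Named list of `dist_spec`s, keyed by parameter field;
#'   defaults to [default_distributions()]. Parameters without a spec stay
#'   at base values.
#' @param wtp Analysis willingness to pay; defaults to `params$wtp`.
#' @param conventions A `cea_conventions` object.
#' @param wtp_grid WTP grid for the acceptability curve.
#' @return A `psa_result`: list with `samples` (data.frame: iteration,
#'   per-strategy cost and qalys, `delta_cost`, `delta_qalys`, `inmb`),
#'   `fraction_ce` (share of iterations with INMB > 0 at `wtp`), and `ceac`
#'   (data.frame: wtp, probability_cost_effective).
#' @export
run_psa <- function(n_iterations, seed, params = cea_parameters(),
                    dists = default_distributions(params),
                    wtp = params$wtp, conventions = cea_conventions(),
                    wtp_grid = seq(0, 200000, by = 10000)) {
  stopifnot(n_iterations >= 1)
  for (nm in names(dists)) {
    if (!inherits(dists[[nm]], "dist_spec")) {
      stop("invalid distribution spec for '", nm, "'", call. = FALSE)
    }
    if (!nm %in% names(params)) {
      stop("distribution given for unknown parameter '", nm, "'",
           call. = FALSE)
    }
  }
  subseeds <- .substream_seeds(seed, n_iterations)
  fields <- names(dists)
  nstrat <- c("CTA", "CTP", "CTA_CTP")
  cols <- as.vector(outer(c("cost", "qalys"), tolower(nstrat), paste, sep = "_"))
  samples <- matrix(NA_real_, n_iterations, 6 + 3,
                    dimnames = list(NULL, c(cols, "delta_cost",
                                            "delta_qalys", "inmb")))
  for (i in seq_len(n_iterations)) {
    set.seed(subseeds[i])
    p <- unclass(params)
    for (f in fields) p[[f]] <- draw_spec(dists[[f]], 1)
    p <- .apply_links(p, explicit = character())
    p <- validate_parameters(p)
    strategies <- default_strategies(p)
    res <- lapply(strategies, run_strategy, params = p,
                  conventions = conventions, trace = FALSE)
    dc <- res$CTP$cost - res$CTA$cost
    de <- res$CTP$qalys - res$CTA$qalys
    samples[i, ] <- c(res$CTA$cost, res$CTP$cost, res$CTA_CTP$cost,
                      res$CTA$qalys, res$CTP$qalys, res$CTA_CTP$qalys,
                      dc, de, wtp * de - dc)[c(1, 4, 2, 5, 3, 6, 7, 8, 9)]
  }
  samples <- data.frame(iteration = seq_len(n_iterations), samples)
  ceac <- data.frame(
    wtp = wtp_grid,
    probability_cost_effective = vapply(wtp_grid, function(w) {
      mean(w * samples$delta_qalys - samples$delta_cost > 0)
    }, numeric(1))
  )
  structure(list(samples = samples,
                 fraction_ce = mean(samples$inmb > 0),
                 wtp = wtp, ceac = ceac, seed = seed),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat(sprintf("PSA: %d iterations (seed %s); CTP cost-effective vs CTA in %.1f%% of iterations at WTP $%s\n",
              nrow(x$samples), format(x$seed), 100 * x$fraction_ce,
              format(x$wtp, big.mark = ",", scientific = FALSE)))
  invisible(x)
}
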