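#' @keywords internal
# FNV-1a 32-bit hash of a string; stable configuration digest without
# external dependencies.
.fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Run manifest
#'
#' Records what produced a set of outputs: the command, a digest of the
#' resolved configuration (it changes iff any configuration value changes),
#' the seed, the convention flags, the package version, the output paths,
#' and a timestamp.
#'
#' @param command Command name.
#' @param params A `cea_parameters` object.
#' @param conventions A `cea_conventions` object.
#' @param outputs Character vector of output file paths.
#' @param seed Seed used, or `NA` for deterministic commands.
#' @return A list of class `run_manifest`.
#' @export
run_manifest <- function(command, params, conventions, outputs, seed = NA) {
  cfg_json <- jsonlite::toJSON(
    list(params = unclass(params), conventions = unclass(conventions)),
    auto_unbox = TRUE, digits = NA)
  structure(list(
    command = command,
    config_digest = .fnv1a(as.character(cfg_json)),
    seed = seed,
    conventions = unclass(conventions),
    artifact_version = as.character(utils::packageVersion("ctpcea")),
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ), class = "run_manifest")
}

.write_manifest <- function(manifest, out_dir) {
  path <- file.path(out_dir, paste0(manifest$command, "_manifest.json"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# Fixed number formatting so repeated runs produce byte-identical CSV bodies:
# costs to 2 decimals, QALYs to 4, probabilities to 6.
.fmt_cost <- function(x) sprintf("%.2f", x)
.fmt_qaly <- function(x) sprintf("%.4f", x)
.fmt_prob <- function(x) sprintf("%.6f", x)

.resolve_config <- function(config) {
  if (inherits(config, "cea_parameters")) config else load_parameters(config)
}

#' Base-case command
#'
#' Runs all three strategies under the given conventions, writes a results
#' table (strategy, cost, qalys, nmb) and a comparison table (CTP and
#' CTA+CTP each against CTA, and CTA+CTP against CTP) as CSV, plus a JSON
#' manifest naming the convention flags.
#'
#' @param config Path to a JSON configuration, or a `cea_parameters` object.
#' @param out_dir Output directory (created if needed).
#' @param conventions A `cea_conventions` object.
#' @return Invisibly, a list with `results` (list of `strategy_result`),
#'   `comparisons` (list of `cea_comparison`) and the manifest.
#' @export
cmd_base_case <- function(config, out_dir,
                          conventions = cea_conventions()) {
  params <- .resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  message(sprintf("base case conventions: entry=%s, resolution=%s, risks=%s",
                  conventions$entry, conventions$resolution,
                  conventions$risk_rule))
  results <- run_base_case(params, conventions)
  tab <- results_table(results)
  tab$nmb <- vapply(results, nmb, 0, wtp = params$wtp)
  tab$cost <- .fmt_cost(tab$cost)
  tab$qalys <- .fmt_qaly(tab$qalys)
  tab$nmb <- .fmt_cost(tab$nmb)
  results_path <- file.path(out_dir, "base_case_results.csv")
  utils::write.csv(tab, results_path, row.names = FALSE, quote = FALSE)

  pairs <- list(c("CTP", "CTA"), c("CTA_CTP", "CTA"), c("CTA_CTP", "CTP"))
  comparisons <- lapply(pairs, function(pr) {
    compare(results[[pr[1]]], results[[pr[2]]], params$wtp)
  })
  ctab <- do.call(rbind, lapply(comparisons, function(cp) {
    data.frame(strategy = cp$new, comparator = cp$reference,
               delta_cost = .fmt_cost(cp$delta_cost),
               delta_qalys = .fmt_qaly(cp$delta_qalys),
               icer_or_category = if (cp$category == "icer")
                 .fmt_cost(cp$icer) else cp$category,
               inmb = .fmt_cost(cp$inmb))
  }))
  comp_path <- file.path(out_dir, "base_case_comparisons.csv")
  utils::write.csv(ctab, comp_path, row.names = FALSE, quote = FALSE)

  manifest <- run_manifest("base_case", params, conventions,
                           c(results_path, comp_path))
  .write_manifest(manifest, out_dir)
  invisible(list(results = results, comparisons = comparisons,
                 manifest = manifest))
}

#' One-way DSA command
#'
#' @param config Path to a JSON configuration, or a `cea_parameters` object.
#' @param out_dir Output directory.
#' @param ranges List of `dsa_range`s, or a path to a CSV with columns
#'   `parameter`, `low`, `high` (optional `n_points`); defaults to the
#'   published ranges.
#' @param conventions A `cea_conventions` object.
#' @return Invisibly, the tornado data.frame.
#' @export
cmd_dsa <- function(config, out_dir, ranges = NULL,
                    conventions = cea_conventions()) {
  params <- .resolve_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(ranges)) {
    ranges <- default_dsa_ranges(params)
  } else if (is.character(ranges)) {
    df <- utils::read.csv(ranges)
    ranges <- lapply(seq_len(nrow(df)), function(i) {
      dsa_range(df$parameter[i], df$low[i], df$high[i],
                n_points = if ("n_points" %in% names(df)) df$n_points[i] else 11)
    })
  }
  tor <- tornado(ranges, params, params$wtp, conventions)
  out <- tor
  for (col in c("inmb_low", "inmb_high", "span")) {
    out[[col]] <- .fmt_cost(out[[col]])
  }
  path <- file.path(out_dir, "tornado.csv")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  manifest <- run_manifest("dsa", params, conventions, path)
  .write_manifest(manifest, out_dir)
  invisible(tor)
}

#' PSA command
#'
#' @param config Path to a JSON configuration, or a `cea_parameters` object.
#' @param out_dir Output directory.
#' @param iterations Monte Carlo iterations.
#' @param seed Master seed.
#' @param wtp Willingness to pay; defaults to the configured value.
#' @param conventions A `cea_conventions` object.
#' @return Invisibly, the `psa_result`.
#' @export
cmd_psa <- function(config, out_dir, iterations = 30000, seed = 1,
                    wtp = NULL, conventions = cea_conventions()) {
  params <- .resolve_config(config)
  if (is.null(wtp)) wtp <- params$wtp
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(iterations, seed, params, wtp = wtp,
                 conventions = conventions)
  s <- psa$samples
  for (col in grep("^cost|^delta_cost|^inmb$", names(s), value = TRUE)) {
    s[[col]] <- .fmt_cost(s[[col]])
  }
  for (col in grep("^qalys|^delta_qalys", names(s), value = TRUE)) {
    s[[col]] <- .fmt_qaly(s[[col]])
  }
  samples_path <- file.path(out_dir, "psa_samples.csv")
  utils::write.csv(s, samples_path, row.names = FALSE, quote = FALSE)
  ceac <- psa$ceac
  ceac$probability_cost_effective <- .fmt_prob(ceac$probability_cost_effective)
  ceac_path <- file.path(out_dir, "ceac.csv")
  utils::write.csv(ceac, ceac_path, row.names = FALSE, quote = FALSE)
  manifest <- run_manifest("psa", params, conventions,
                           c(samples_path, ceac_path), seed = seed)
  .write_manifest(manifest, out_dir)
  invisible(psa)
}

#' Oracle-equivalence command
#'
#' Runs the patient-level microsimulation for each strategy and checks that
#' the cohort-model totals lie within 3 Monte Carlo standard errors of the
#' microsimulation means.
#'
#' @param config Path to a JSON configuration, or a `cea_parameters` object.
#' @param patients Number of simulated patients per strategy.
#' @param seed Integer seed.
#' @param conventions A `cea_conventions` object.
#' @param out_dir Optional output directory for the equivalence report CSV.
#' @return Invisibly, a data.frame with one row per strategy and a logical
#'   `pass` column; the command stops with an error if any check fails.
#' @export
cmd_oracle <- function(config, patients = 100000, seed = 1,
                       conventions = cea_conventions(), out_dir = NULL) {
  params <- .resolve_config(config)
  strategies <- default_strategies(params)
  rows <- lapply(names(strategies), function(nm) {
    st <- strategies[[nm]]
    cohort <- run_strategy(st, params, conventions, trace = FALSE)
    sim <- simulate_patients(patients, st, params, conventions, seed)
    data.frame(strategy = nm,
               cohort_cost = cohort$cost, sim_cost = sim$mean_cost,
               se_cost = sim$se_cost,
               cohort_qalys = cohort$qalys, sim_qalys = sim$mean_qalys,
               se_qalys = sim$se_qalys,
               pass = abs(cohort$cost - sim$mean_cost) <= 3 * sim$se_cost &
                 abs(cohort$qalys - sim$mean_qalys) <= 3 * sim$se_qalys)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    out <- report
    for (col in c("cohort_cost", "sim_cost", "se_cost")) {
      out[[col]] <- .fmt_cost(out[[col]])
    }
    for (col in c("cohort_qalys", "sim_qalys", "se_qalys")) {
      out[[col]] <- .fmt_qaly(out[[col]])
    }
    path <- file.path(out_dir, "oracle_equivalence.csv")
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    .write_manifest(run_manifest("oracle", params, conventions, path,
                                 seed = seed), out_dir)
  }
  if (!all(report$pass)) {
    stop("oracle equivalence failed for: ",
         paste(report$strategy[!report$pass], collapse = ", "),
         call. = FALSE)
  }
  invisible(report)
}
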