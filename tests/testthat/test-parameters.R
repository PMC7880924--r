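test_that("defaults carry the base-case values and the 1.3x links hold", {
  p <- base_params()
  expect_equal(p$pretest_probability, 0.6267)
  expect_equal(p$wtp, 100000)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$horizon_cycles, 10)
  expect_equal(p$cost_ptca_delayed, 1.3 * p$cost_ptca)
  expect_equal(p$yearly_cost_stenosis, 1.3 * p$yearly_cost_no_stenosis)
  expect_equal(p$cost_combo, p$cost_cta + p$cost_ctp)
})

test_that("linked fields follow their partners and can be decoupled", {
  p <- cea_parameters(cost_ptca = 4678)
  expect_equal(p$cost_ptca_delayed, 6081.40)
  p2 <- cea_parameters(cost_ptca = 5000)
  expect_equal(p2$cost_ptca_delayed, 6500)
  # explicit dependent override decouples it
  p3 <- cea_parameters(cost_ptca = 5000, cost_ptca_delayed = 7000)
  expect_equal(p3$cost_ptca_delayed, 7000)
  # link off: dependent stays at its base-table value
  p4 <- cea_parameters(cost_ptca = 5000, linked_assumption = FALSE)
  expect_equal(p4$cost_ptca_delayed, 6081.40)
  # set_parameter moves partners the same way
  p5 <- set_parameter(base_params(), "yearly_cost_no_stenosis", 6000)
  expect_equal(p5$yearly_cost_stenosis, 7800)
})

test_that("validation rejects out-of-range and unknown fields", {
  expect_error(cea_parameters(spec_cta = 1.5), "probability")
  expect_error(cea_parameters(cost_ica = -1), "cost")
  expect_error(cea_parameters(discount_rate = -0.01), "discount_rate")
  expect_error(cea_parameters(horizon_cycles = 2.5), "integer")
  expect_error(cea_parameters(utility_dead = 0.1), "utility_dead")
  expect_error(cea_parameters(nonsense = 1), "unknown parameter")
  expect_error(validate_parameters(list(wtp = 1)), "missing required")
})

test_that("JSON save/load round trip reproduces every field exactly", {
  p <- cea_parameters(cost_ptca = 4999.99, spec_ctp = 0.7891234,
                      pretest_probability = 1 / 3)
  path <- tempfile(fileext = ".json")
  save_parameters(p, path)
  q <- load_parameters(path)
  expect_identical(unclass(q)[names(p)], unclass(p))
})

test_that("loading rejects unknown keys and missing files, fills omissions", {
  path <- tempfile(fileext = ".json")
  writeLines('{"cost_ptca": 4678, "bogus_key": 1}', path)
  expect_error(load_parameters(path), "unknown parameter")
  writeLines('{"cost_ptca": 4678}', path)
  p <- load_parameters(path)
  expect_equal(p$pretest_probability, 0.6267)
  expect_equal(p$cost_ptca_delayed, 6081.40)
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("packaged example configuration loads to the base case", {
  cfg <- system.file("extdata", "base_case_config.json", package = "ctpcea")
  expect_identical(unclass(load_parameters(cfg)), unclass(base_params()))
})

test_that("beta moment matching: alpha = mean * n_eff, degenerate means fix", {
  spec <- fit_beta_moments(0.914, 150)
  expect_equal(unname(spec$hyperparameters["alpha"]), 137.1)
  expect_equal(unname(spec$hyperparameters["beta"]), 12.9)
  expect_equal(spec_mean(spec), 0.914)
  sym <- fit_beta_moments(0.5, 77)
  expect_equal(unname(sym$hyperparameters["alpha"]),
               unname(sym$hyperparameters["beta"]))
  expect_equal(spec_mean(fit_beta_moments(0.6267, 150)), 0.6267)
  expect_warning(d1 <- fit_beta_moments(1, 150), "degenerate")
  expect_identical(d1$family, "fixed")
  expect_equal(draw_spec(d1, 3), c(1, 1, 1))
  expect_error(fit_beta_moments(0.5, 0), "positive")
})

test_that("gamma moment matching recovers mean and sd analytically", {
  spec <- fit_gamma_moments(100, 10)
  expect_equal(unname(spec$hyperparameters["shape"]), 100)
  expect_equal(unname(spec$hyperparameters["scale"]), 1)
  s2 <- fit_gamma_moments(4678, 935.6)
  expect_equal(unname(s2$hyperparameters["shape"]), 25)
  expect_equal(unname(s2$hyperparameters["scale"]), 187.12)
  for (m in c(3, 450.7)) {
    expect_equal(spec_mean(fit_gamma_moments(m, m / 5)), m)
  }
  expect_error(fit_gamma_moments(-1, 1), "positive")
  expect_error(fit_gamma_moments(100, 0), "positive")
})

test_that("fitted specs recover their target mean in large samples", {
  set.seed(901)
  cases <- list(
    list(spec = fit_beta_moments(0.6267, 150), mean = 0.6267),
    list(spec = fit_beta_moments(0.0264, 100), mean = 0.0264),
    list(spec = fit_gamma_moments(4678, 935.6), mean = 4678, sd = 935.6)
  )
  n <- 1e6
  for (cs in cases) {
    x <- draw_spec(cs$spec, n)
    expect_lt(abs(mean(x) - cs$mean), 3 * sd(x) / sqrt(n))
    if (!is.null(cs$sd)) expect_lt(abs(sd(x) - cs$sd) / cs$sd, 0.01)
  }
})

test_that("default PSA distributions cover the distributed inputs only", {
  p <- base_params()
  d <- default_distributions(p)
  expect_true(all(c("pretest_probability", "spec_cta", "utility_stenosis",
                    "cost_ptca", "yearly_cost_no_stenosis") %in% names(d)))
  # analysis settings and linked dependents are never sampled under the link
  expect_false(any(c("wtp", "discount_rate", "horizon_cycles", "start_age",
                     "utility_dead", "cost_ptca_delayed",
                     "yearly_cost_stenosis", "cost_combo") %in% names(d)))
  expect_identical(d$sens_cta$family, "fixed")    # base 1.0 is degenerate
  expect_identical(d$spec_ctp$family, "beta")
  expect_identical(d$cost_ica$family, "gamma")
  expect_equal(spec_mean(d$cost_ptca), p$cost_ptca)
  # decoupled: dependents get their own gamma specs
  d2 <- default_distributions(cea_parameters(linked_assumption = FALSE))
  expect_identical(d2$cost_ptca_delayed$family, "gamma")
})
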