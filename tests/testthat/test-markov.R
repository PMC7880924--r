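test_that("discount factor", {
  expect_equal(discount_factor(0, 0.03), 1)
  expect_equal(discount_factor(1, 0.03), 1 / 1.03)
  expect_equal(discount_factor(c(0, 5, 40), 0), c(1, 1, 1))
  expect_error(discount_factor(-1, 0.03))
})

test_that("transition matrix rows sum to 1 and Dead is absorbing", {
  p <- base_params()
  for (conv in convention_grid()) {
    m <- transition_matrix(p, conv)
    expect_equal(unname(rowSums(m)), c(1, 1, 1), tolerance = 1e-12)
    expect_equal(unname(m["Dead", ]), c(0, 0, 1))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("additive rule reproduces the hand-computed NoStenosis row", {
  p <- base_params()
  m <- transition_matrix(p, cea_conventions(risk_rule = "additive"))
  expect_equal(unname(m["NoStenosis", ]), c(0.9378, 0.0264, 0.0358),
               tolerance = 1e-12)
  # additive rule refuses invalid rows, pointing at the multiplicative one
  bad <- cea_parameters(p_death_no_stenosis = 0.6, p_death_other = 0.5)
  expect_error(transition_matrix(bad, cea_conventions(risk_rule = "additive")),
               "multiplicative")
  m2 <- transition_matrix(bad, cea_conventions())
  expect_equal(unname(rowSums(m2)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("tunnel vs persistent stenosis resolution", {
  p <- base_params()
  mt <- transition_matrix(p, cea_conventions(resolution = "tunnel"))
  expect_equal(unname(mt["Stenosis", "Stenosis"]), 0)
  expect_gt(mt["Stenosis", "NoStenosis"], 0.9)
  mp <- transition_matrix(p, cea_conventions(resolution = "persistent"))
  expect_equal(unname(mp["Stenosis", "NoStenosis"]), 0)
})

test_that("degenerate model matches the geometric-series closed form", {
  p <- cea_parameters(p_new_stenosis = 0, p_death_no_stenosis = 0,
                      p_death_stenosis = 0, p_death_other = 0,
                      horizon_cycles = 25)
  r <- run_cohort(c(1, 0, 0), p)
  closed_q <- p$utility_no_stenosis * sum((1 + p$discount_rate)^-(1:25))
  closed_c <- p$yearly_cost_no_stenosis * sum((1 + p$discount_rate)^-(1:25))
  expect_equal(r$total_qalys, closed_q, tolerance = 1e-10)
  expect_equal(r$total_cost, closed_c, tolerance = 1e-10)
})

test_that("trivial cohorts: zero horizon and all-dead entry", {
  p0 <- cea_parameters(horizon_cycles = 0)
  r0 <- run_cohort(c(1, 0, 0), p0)
  expect_equal(r0$total_cost, 0)
  expect_equal(r0$total_qalys, 0)
  expect_equal(nrow(r0$trace), 0)
  rd <- run_cohort(c(0, 0, 1), base_params())
  expect_equal(rd$total_cost, 0)
  expect_equal(rd$total_qalys, 0)
  expect_error(run_cohort(c(0.5, 0.2, 0.1), base_params()), "summing to 1")
})

test_that("trace invariants: occupancy sums to 1, Dead nondecreasing, cumulative totals nondecreasing", {
  p <- base_params()
  for (conv in convention_grid()) {
    tr <- run_cohort(c(0.8, 0.2, 0), p, conv)$trace
    occ <- tr$NoStenosis + tr$Stenosis + tr$Dead
    expect_equal(occ, rep(1, nrow(tr)), tolerance = 1e-12)
    expect_true(all(diff(tr$Dead) >= -1e-15))
    expect_true(all(diff(tr$cum_cost) >= 0))
    expect_true(all(diff(tr$cum_qalys) >= 0))
    # all-positive death risks: survival strictly decreasing
    expect_true(all(diff(1 - tr$Dead) < 0))
  }
})

test_that("discounted totals never exceed undiscounted; QALYs bounded by horizon", {
  p <- base_params()
  p0 <- cea_parameters(discount_rate = 0)
  for (init in list(c(1, 0, 0), c(0.6, 0.4, 0))) {
    rd <- run_cohort(init, p)
    ru <- run_cohort(init, p0)
    expect_lte(rd$total_cost, ru$total_cost)
    expect_lte(rd$total_qalys, ru$total_qalys)
    expect_lte(rd$total_qalys, p$horizon_cycles * p$utility_no_stenosis)
  }
})

test_that("raising utilities or yearly costs weakly raises totals", {
  base <- run_cohort(c(0.9, 0.1, 0), base_params())
  for (f in c("utility_no_stenosis", "utility_stenosis")) {
    lo <- set_parameter(base_params(), f, base_params()[[f]] - 0.1)
    expect_lte(run_cohort(c(0.9, 0.1, 0), lo)$total_qalys, base$total_qalys)
  }
  for (f in c("yearly_cost_no_stenosis", "yearly_cost_stenosis")) {
    hi <- set_parameter(base_params(), f, base_params()[[f]] * 1.5)
    expect_gte(run_cohort(c(0.9, 0.1, 0), hi)$total_cost, base$total_cost)
  }
})

test_that("occupancy at cycle k equals initial . M^k for a constant matrix", {
  p <- base_params()
  conv <- cea_conventions(entry = "positives-decrement")
  m <- transition_matrix(p, conv)
  init <- c(0.3, 0.7, 0)
  tr <- run_cohort(init, p, conv)$trace
  mk <- diag(3)
  for (k in 1:9) {
    mk <- mk %*% m
    # trace row k+1 holds the occupancy during cycle k+1 = initial . M^k
    expect_equal(unname(unlist(tr[k + 1, c("NoStenosis", "Stenosis", "Dead")])),
                 as.numeric(init %*% mk), tolerance = 1e-12)
  }
})

test_that("incident-PTCA charging adds exactly the incident flow cost", {
  p <- base_params()
  off <- run_cohort(c(1, 0, 0), p, cea_conventions())
  on <- run_cohort(c(1, 0, 0), p, cea_conventions(charge_incident_ptca = TRUE))
  expect_gt(on$total_cost, off$total_cost)
  expect_equal(on$total_qalys, off$total_qalys)
  # hand accounting over the trace: charged mass = Stenosis occupancy fed by
  # NoStenosis (entry cohort contributes none here since it starts well)
  m <- transition_matrix(p, cea_conventions())
  extra <- sum(on$trace$Stenosis * p$cost_ptca *
                 discount_factor(on$trace$cycle, p$discount_rate))
  expect_equal(on$total_cost - off$total_cost, extra, tolerance = 1e-9)
})

test_that("half-cycle correction shifts discounting by half a year", {
  p <- base_params()
  plain <- run_cohort(c(1, 0, 0), p, cea_conventions())
  hcc <- run_cohort(c(1, 0, 0), p, cea_conventions(half_cycle = TRUE))
  expect_equal(hcc$total_qalys, plain$total_qalys * 1.03^0.5,
               tolerance = 1e-12)
})

test_that("life-table mortality raises late-age deaths above the constant risk", {
  lt <- load_life_table()
  expect_true(all(diff(lt$qx) > 0))
  p <- cea_parameters(start_age = 80)
  const <- run_cohort(c(1, 0, 0), p, cea_conventions())
  aged <- run_cohort(c(1, 0, 0), p, cea_conventions(mortality = "life-table"))
  expect_lt(aged$total_qalys, const$total_qalys)
  # at the anchor age the schedule equals the constant risk
  expect_equal(lt$qx[lt$age == 65], 0.0126)
})

test_that("trace export is stable and readable", {
  p <- base_params()
  tr <- run_cohort(c(1, 0, 0), p)
  path <- tempfile(fileext = ".csv")
  export_trace(tr, path)
  back <- read.csv(path)
  expect_equal(nrow(back), p$horizon_cycles)
  expect_named(back, c("cycle", "age", "NoStenosis", "Stenosis", "Dead",
                       "disc_cost", "disc_qaly", "cum_cost", "cum_qalys"))
})
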