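test_that("treatment effect duration follows the scenario", {
  p <- ss_params()
  expect_equal(treatment_hr_at(p, "BASE_60M", c(1, 60)), c(0.48, 0.48))
  expect_equal(treatment_hr_at(p, "BASE_60M", 61), 1)
  expect_equal(treatment_hr_at(p, "LIFETIME", c(1, 61, 400)), rep(0.48, 3))
  # declining effect: full through the 18-month trial follow-up, then linear
  expect_equal(treatment_hr_at(p, "DECLINE_18_TO_60", 18), 0.48)
  expect_equal(treatment_hr_at(p, "DECLINE_18_TO_60", 39), 0.74)
  expect_equal(treatment_hr_at(p, "DECLINE_18_TO_60", c(60, 61)), c(1, 1))
  expect_error(treatment_hr_at(p, "BASE_60M", 0), "cycle")
})

test_that("utility trajectories hit the published anchors and converge", {
  p <- ss_params()
  expect_equal(utility_at(p, "CONTROL", 0), 0.711)
  expect_equal(utility_at(p, "TREATMENT", 0), 0.711)
  expect_equal(utility_at(p, "CONTROL", 6), 0.711 - 6 * 0.005)   # 0.681
  expect_equal(utility_at(p, "CONTROL", 12), 0.681 - 6 * 0.003)  # 0.663
  expect_equal(utility_at(p, "TREATMENT", 12), 0.711 + 0.006 + 0.018)
  # carry-forward: month-12 value held through month 60
  expect_equal(utility_at(p, "TREATMENT", 60), utility_at(p, "TREATMENT", 12))
  # after month 60 the arms coincide (except under a lifetime effect)
  expect_equal(utility_at(p, "TREATMENT", 61), utility_at(p, "CONTROL", 61))
  expect_gt(utility_at(p, "TREATMENT", 61, scenario = "LIFETIME"),
            utility_at(p, "CONTROL", 61, scenario = "LIFETIME"))
  # drift mode keeps applying the 7-60 change
  p$utility_mode <- "drift_to_60"
  expect_equal(utility_at(p, "CONTROL", 60), 0.711 - 0.03 - 54 * 0.003)
})

test_that("transition matrices are row-stochastic with absorbing death", {
  p <- ss_params()
  mm <- calibrated_mm()
  for (cyc in c(1, 30, 61, 300)) {
    m <- build_transition_probabilities(p, "TREATMENT", "BASE_60M", cyc,
                                        66 + (cyc - 1) / 12, mm)
    expect_equal(rowSums(m), setNames(rep(1, 4), rownames(m)),
                 tolerance = 1e-12)
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(m["DEATH", ]), c(0, 0, 0, 1))
    expect_equal(m["ADMISSION", "STABLE"], 0)  # admitted month ends in POST
  }
  # no hazards at all: nobody moves except the structural ADMISSION -> POST
  # hand-off (an admission month always ends, alive, in post-admission)
  p0 <- ss_params()
  p0$baseline_hosp_rate <- 0
  m0 <- mortality_model(flat_life_table(0), 1)
  mz <- build_transition_probabilities(p0, "CONTROL", "BASE_60M", 1, 66, m0)
  expect_equal(unname(mz["STABLE", ]), c(1, 0, 0, 0))
  expect_equal(unname(mz["POST_ADMISSION", ]), c(1, 0, 0, 0))
  expect_equal(unname(mz["ADMISSION", ]), c(0, 0, 1, 0))
  expect_equal(unname(mz["DEATH", ]), c(0, 0, 0, 1))
  # control arm admission probability is the rate-converted closed form
  m1 <- build_transition_probabilities(ss_params(), "CONTROL",
                                       "BASE_60M", 1, 66, m0)
  expect_equal(m1["STABLE", "ADMISSION"], 0.0898689389108, tolerance = 1e-10)
})

test_that("cohort traces conserve occupancy with monotone death", {
  mm <- calibrated_mm()
  for (arm in c("TREATMENT", "CONTROL")) {
    tr <- run_cohort(ss_params(), arm, "BASE_60M", mm)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, nrow(tr$occupancy)),
                 tolerance = 1e-12)
    expect_true(all(diff(tr$occupancy[, "DEATH"]) >= -1e-15))
    expect_true(all(tr$occupancy >= -1e-12 & tr$occupancy <= 1 + 1e-12))
  }
  # procedural mortality enters at cycle 0 in the device arm only
  tr_t <- run_cohort(ss_params(), "TREATMENT", "BASE_60M", mm, horizon = 1)
  expect_equal(tr_t$occupancy[1, "DEATH"], 0.004)
  tr_c <- run_cohort(ss_params(), "CONTROL", "BASE_60M", mm, horizon = 1)
  expect_equal(tr_c$occupancy[1, "DEATH"], 0)
  # zero mortality, zero admissions: everyone stays stable
  p0 <- ss_params(); p0$baseline_hosp_rate <- 0; p0$p_procedural_death <- 0
  tr0 <- run_cohort(p0, "TREATMENT", "BASE_60M",
                    mortality_model(flat_life_table(0), 1), horizon = 24)
  expect_equal(tr0$occupancy[, "STABLE"], rep(1, 25), ignore_attr = TRUE)
})

test_that("upfront implantation cost equals the priced components", {
  bc <- base_case_ss()
  expect_equal(bc$treatment$upfront_cost,
               1392182 + 100878 + 0.03 * 144482)  # 1,497,394.46
  expect_equal(bc$control$upfront_cost, 0)
})

test_that("discounting never increases totals and vanishes at rate zero", {
  bc <- base_case_ss()
  for (r in list(bc$treatment, bc$control)) {
    expect_lte(r$cost_discounted, r$cost_undiscounted)
    expect_lte(r$qaly_discounted, r$qaly_undiscounted)
    expect_gte(r$qaly_discounted, 0)
    # QALYs cannot exceed perfect-health life expectancy
    expect_lte(r$qaly_undiscounted, r$life_months / 12)
  }
  p0 <- ss_params()
  p0$discount_rate_annual <- 0
  bc0 <- run_base_case(p0, "BASE_60M", calibrated_mm())
  expect_equal(bc0$treatment$cost_discounted, bc0$treatment$cost_undiscounted)
  expect_equal(bc0$control$qaly_discounted, bc0$control$qaly_undiscounted)
})

test_that("arms are identical when device-specific inputs are neutralised", {
  p <- neutralised_params()
  bc <- run_base_case(p, "BASE_60M", calibrated_mm())
  expect_equal(bc$icer_discounted$delta_cost, 0, tolerance = 1e-9)
  expect_equal(bc$icer_discounted$delta_qaly, 0, tolerance = 1e-12)
  expect_true(is.na(bc$icer_discounted$icer))
})

test_that("ICER arithmetic and dominance flags", {
  mk <- function(cost, qaly) {
    structure(list(cost_discounted = cost, qaly_discounted = qaly,
                   cost_undiscounted = cost, qaly_undiscounted = qaly),
              class = "cohort_result")
  }
  r <- compute_icer(mk(1100, 2.5), mk(1000, 2.0))
  expect_equal(r$icer, 200)
  expect_equal(r$dominance_flag, "none")
  expect_equal(compute_icer(mk(990, 2.1), mk(1000, 2.0))$dominance_flag,
               "dominant")
  expect_equal(compute_icer(mk(1100, 1.9), mk(1000, 2.0))$dominance_flag,
               "dominated")
  expect_true(is.na(compute_icer(mk(1100, 2), mk(1000, 2))$icer))
})

test_that("device-arm mortality at 12 months is near the trial-reported risk", {
  tr <- run_cohort(ss_params(), "TREATMENT", "BASE_60M", calibrated_mm(),
                   horizon = 12)
  expect_equal(tr$occupancy[13, "DEATH"], 0.16, tolerance = 0.04 / 0.16)
})

test_that("lower device prices lower the ICER", {
  mm <- calibrated_mm()
  base <- base_case_ss()$icer_discounted$icer
  p_cheap <- ss_params(); p_cheap$cost_device <- 0.75 * p_cheap$cost_device
  expect_lt(run_base_case(p_cheap, "BASE_60M", mm)$icer_discounted$icer, base)
})

test_that("microsimulation oracle agrees with the deterministic trace", {
  p <- ss_params()
  mm <- calibrated_mm()
  n <- 200000
  horizon <- 240
  sim <- simulate_individuals(p, "TREATMENT", "BASE_60M", mm, n = n,
                              seed = 4242, horizon = horizon,
                              report_cycles = c(12, 60, 240))
  tr <- run_cohort(p, "TREATMENT", "BASE_60M", mm, horizon = horizon)
  for (cyc in c(12, 60, 240)) {
    det <- tr$occupancy[cyc + 1, ]
    obs <- sim$occupancy[as.character(cyc), ]
    se <- sqrt(pmax(det * (1 - det), 1e-12) / n)
    expect_true(all(abs(obs - det) <= 3 * se + 1e-9),
                info = paste("cycle", cyc))
  }
  acc <- accrue_outcomes(tr, p)
  for (f in c("cost_discounted", "qaly_discounted", "life_months",
              "admissions_per_patient")) {
    expect_lt(abs(sim[[f]] - acc[[f]]), 3 * sim$se[[f]] + 1e-9)
  }
})

test_that("microsimulation is deterministic under a fixed seed and exact without hazards", {
  p0 <- neutralised_params()
  p0$baseline_hosp_rate <- 0
  m0 <- mortality_model(flat_life_table(0), 1)
  sim <- simulate_individuals(p0, "CONTROL", "BASE_60M", m0, n = 50,
                              seed = 1, horizon = 24)
  tr <- accrue_outcomes(run_cohort(p0, "CONTROL", "BASE_60M", m0,
                                   horizon = 24), p0)
  expect_equal(sim$qaly_undiscounted, tr$qaly_undiscounted, tolerance = 1e-12)
  expect_equal(sim$cost_discounted, tr$cost_discounted, tolerance = 1e-12)

  a <- simulate_individuals(ss_params(), "TREATMENT", "BASE_60M",
                            calibrated_mm(), n = 500, seed = 9, horizon = 36)
  b <- simulate_individuals(ss_params(), "TREATMENT", "BASE_60M",
                            calibrated_mm(), n = 500, seed = 9, horizon = 36)
  expect_identical(a, b)
})

test_that("per-cycle accrual export writes a complete trace", {
  bc <- base_case_ss()
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_trace(bc$treatment, tmp)
  x <- utils::read.csv(tmp)
  expect_equal(nrow(x), nrow(bc$treatment$per_cycle))
  expect_true(all(c("cycle", "age", "STABLE", "ADMISSION", "POST_ADMISSION",
                    "DEATH", "cost_inc", "qaly_inc") %in% names(x)))
})
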