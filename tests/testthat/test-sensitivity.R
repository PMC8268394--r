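test_that("one-way DSA at the base value on both ends is the identity", {
  mm <- calibrated_mm()
  base_icer <- base_case_ss()$icer_discounted$icer
  d <- one_way_dsa(ss_params(), "cost_device", low = 1392182, high = 1392182,
                   mortality_model = mm)
  expect_equal(d$icer_at_low, base_icer, tolerance = 1e-12)
  expect_equal(d$icer_at_high, base_icer, tolerance = 1e-12)
  expect_false(d$recalibrated)
})

test_that("tornado entries equal independently rerun one-way analyses", {
  mm <- calibrated_mm()
  spec <- data.frame(parameter = c("hr_hosp_treatment", "cost_admission"),
                     low = c(0.38, 272091), high = c(0.67, 453485))
  td <- run_tornado(ss_params(), spec, mortality_model = mm)
  expect_true(all(diff(td$span) <= 0))  # sorted by descending span
  for (i in seq_len(nrow(td))) {
    solo <- one_way_dsa(ss_params(), td$parameter[i], td$low_value[i],
                        td$high_value[i], mortality_model = mm)
    expect_equal(td$icer_at_low[i], solo$icer_at_low, tolerance = 1e-12)
    expect_equal(td$icer_at_high[i], solo$icer_at_high, tolerance = 1e-12)
  }
  empty <- run_tornado(ss_params(), spec[0, ], mortality_model = mm)
  expect_identical(nrow(empty), 0L)
})

test_that("the admission HR and device price are among the most influential parameters", {
  mm <- calibrated_mm()
  td <- run_tornado(ss_params(), mortality_model = mm)
  top3 <- td$parameter[1:3]
  expect_true("hr_hosp_treatment" %in% top3)
  expect_true("cost_device" %in% top3)
  # mortality-linked parameters are re-calibrated, the rest are not
  expect_true(all(td$recalibrated[td$parameter %in%
                                    c("entry_age", "hr_mortality_admission",
                                      "baseline_hosp_rate")]))
  expect_false(any(td$recalibrated[td$parameter == "cost_device"]))
})

test_that("parameter sampling recovers the specified distributions", {
  p <- ss_params()
  set.seed(77)
  n <- 5000
  draws <- replicate(n, sample_parameters(p)$sampled)
  # lognormal admission HR: geometric mean recovers the base case
  lhr <- log(draws["hr_hosp_treatment", ])
  expect_lt(abs(mean(lhr) - log(0.48)), 3 * sd(lhr) / sqrt(n))
  # symmetric (normal) cost: arithmetic mean recovers the base case
  cd <- draws["cost_device", ]
  expect_lt(abs(mean(cd) - 1392182), 3 * sd(cd) / sqrt(n))
  # beta utility: mean matches and support respected
  ub <- draws["utility_baseline", ]
  expect_lt(abs(mean(ub) - 0.711), 3 * sd(ub) / sqrt(n))
  expect_true(all(ub >= 0 & ub <= 1))
  # entry age is an integer year within the valid range
  ea <- draws["entry_age", ]
  expect_true(all(ea == round(ea) & ea >= 18 & ea <= 100))
  # the validation-only mortality input is never sampled
  expect_false("baseline_mortality_12m_treatment" %in% rownames(draws))
})

test_that("all-fixed specs reproduce the base case and seeds freeze draws", {
  p <- ss_params()
  for (id in names(p$uncertainty)) {
    p$uncertainty[[id]]$distribution <- "fixed"
  }
  set.seed(5)
  s <- sample_parameters(p)
  for (id in names(s$sampled)) expect_equal(s$sampled[[id]], p[[id]])

  mm <- calibrated_mm()
  psa1 <- run_psa(p, "BASE_60M", mm, n_draws = 1, seed = 3)
  bc <- run_base_case(p, "BASE_60M", calibrated_mortality_model(p, default_lt()))
  expect_equal(psa1$delta_cost, bc$icer_discounted$delta_cost, tolerance = 1e-9)
  expect_equal(psa1$delta_qaly, bc$icer_discounted$delta_qaly, tolerance = 1e-12)

  a <- run_psa(ss_params(), "BASE_60M", mm, n_draws = 25, seed = 42)
  b <- run_psa(ss_params(), "BASE_60M", mm, n_draws = 25, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("PSA draws fall in the upper-right quadrant and recalibrate per draw", {
  mm <- calibrated_mm()
  psa <- run_psa(ss_params(), "BASE_60M", mm, n_draws = 150, seed = 8)
  expect_gte(mean(psa$delta_cost > 0 & psa$delta_qaly > 0), 0.95)
  # recalibration tracked the sampled mortality parameters
  expect_gt(stats::sd(psa$correction_factor), 0)
  # every draw's correction factor stays in the admissible band
  expect_true(all(psa$correction_factor >= 1 & psa$correction_factor <= 100))
})

test_that("CEAC follows net-monetary-benefit logic", {
  mm <- calibrated_mm()
  psa <- run_psa(ss_params(), "BASE_60M", mm, n_draws = 100, seed = 13)
  grid <- seq(0, 6, by = 0.1) * 700473
  cc <- ceac(psa, grid)
  expect_equal(cc$probability_cost_effective[1], 0)  # lambda = 0, all dC > 0
  if (all(psa$delta_qaly > 0)) {
    expect_true(all(diff(cc$probability_cost_effective) >= 0))
  }
  huge <- ceac(psa, 1e15)$probability_cost_effective
  expect_equal(huge, mean(psa$delta_qaly > 0))
  expect_error(ceac(psa[0, ], grid), "at least one")
})

test_that("longer treatment effects dominate shorter ones, both perspectives", {
  sc <- run_scenarios(list(ss_params(), ps_params()), calibrated_mm())
  for (persp in c("SS", "PS")) {
    s <- sc[sc$perspective == persp, ]
    icer <- setNames(s$icer_discounted, s$scenario)
    expect_lt(icer["LIFETIME"], icer["BASE_60M"])
    expect_lt(icer["BASE_60M"], icer["DECLINE_18_TO_60"])
  }
})
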