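test_that("log-HR standard error back-calculation matches the formula", {
  expect_equal(se_from_ci(0.5, 0.5, 0.5), 0)
  # published pooled admission HR row: 0.48 (0.38-0.67)
  expect_equal(se_from_ci(0.48, 0.38, 0.67), 0.144672673615,
               tolerance = 1e-10)
  # scale invariance of the log-width
  expect_equal(se_from_ci(0.96, 0.76, 1.34), se_from_ci(0.48, 0.38, 0.67))
  expect_error(se_from_ci(0.5, -1, 1), "> 0")
  expect_error(se_from_ci(0.3, 0.4, 0.5), "ci_low <= hr")
})

test_that("single-study pooling is the identity", {
  s <- data.frame(label = "only", hr = 0.48, ci_low = 0.38, ci_high = 0.67)
  for (m in c("fixed", "random")) {
    pe <- pool_hazard_ratios(s, m)
    expect_equal(pe$hr, 0.48)
    expect_equal(pe$ci_low, 0.38)
    expect_equal(pe$ci_high, 0.67)
    expect_equal(pe$tau2, 0)
  }
  expect_error(pool_hazard_ratios(s[0, ]), "at least one")
})

test_that("two identical studies keep the estimate and shrink the SE by sqrt(2)", {
  s1 <- data.frame(label = "a", hr = 0.48, ci_low = 0.38, ci_high = 0.67)
  s <- rbind(s1, transform(s1, label = "b"))
  pe <- pool_hazard_ratios(s, "fixed")
  expect_equal(pe$hr, 0.48, tolerance = 1e-12)
  se1 <- se_from_ci(0.48, 0.38, 0.67)
  se_pool <- (log(pe$ci_high) - log(pe$ci_low)) / (2 * qnorm(0.975))
  expect_equal(se_pool, se1 / sqrt(2), tolerance = 1e-10)
})

test_that("pooling agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  s <- make_study_effects(0.48, 4, se_range = c(0.1, 0.4), seed = 7)
  sei <- se_from_ci(s$hr, s$ci_low, s$ci_high)

  fe <- pool_hazard_ratios(s, "fixed")
  ref_fe <- metafor::rma(yi = log(s$hr), sei = sei, method = "FE")
  expect_equal(log(fe$hr), as.numeric(ref_fe$beta), tolerance = 1e-8)
  expect_equal(log(fe$ci_high), as.numeric(ref_fe$ci.ub), tolerance = 1e-8)

  re <- pool_hazard_ratios(s, "random")
  ref_re <- metafor::rma(yi = log(s$hr), sei = sei, method = "DL")
  expect_equal(log(re$hr), as.numeric(ref_re$beta), tolerance = 1e-8)
  expect_equal(re$tau2, as.numeric(ref_re$tau2), tolerance = 1e-8)
})

test_that("pooled estimate stays inside the study range; random CI is no narrower", {
  set.seed(42)
  for (i in 1:20) {
    s <- make_study_effects(exp(rnorm(1, log(0.5), 0.3)),
                            n_studies = sample(2:6, 1))
    fe <- pool_hazard_ratios(s, "fixed")
    expect_gte(log(fe$hr), min(log(s$hr)) - 1e-12)
    expect_lte(log(fe$hr), max(log(s$hr)) + 1e-12)
    re <- pool_hazard_ratios(s, "random")
    expect_gte(log(re$ci_high) - log(re$ci_low),
               log(fe$ci_high) - log(fe$ci_low) - 1e-12)
  }
})

test_that("pooling recovers a known hazard ratio across simulated trios", {
  set.seed(20210709)
  true_hr <- 0.48
  covered <- logical(500)
  for (i in seq_along(covered)) {
    s <- make_study_effects(true_hr, 3, se_range = c(0.1, 0.3))
    pe <- pool_hazard_ratios(s, "fixed")
    covered[i] <- pe$ci_low <= true_hr && true_hr <= pe$ci_high
  }
  expect_gte(mean(covered), 0.93)
})

test_that("study-effect generation is deterministic and degenerate-safe", {
  a <- make_study_effects(0.48, 3, seed = 11)
  b <- make_study_effects(0.48, 3, seed = 11)
  expect_identical(a, b)
  z <- make_study_effects(0.48, 5, se_range = c(0, 0), seed = 1)
  expect_equal(z$hr, rep(0.48, 5))
  expect_equal(z$ci_low, z$ci_high)
})

test_that("study CSV IO validates ordering", {
  s <- make_study_effects(0.5, 3, seed = 3)
  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(s, tmp, row.names = FALSE)
  expect_equal(read_study_effects(tmp)$hr, s$hr, tolerance = 1e-12)

  bad <- transform(s, ci_low = ci_high + 1)
  utils::write.csv(bad, tmp, row.names = FALSE)
  expect_error(read_study_effects(tmp), "ci_low <= hr")
})
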