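# Shared fixtures, memoised so the correction factor is calibrated once per
# test run rather than once per test.
.memo <- new.env(parent = emptyenv())

memoised <- function(key, maker) {
  if (!exists(key, envir = .memo)) assign(key, maker(), envir = .memo)
  get(key, envir = .memo)
}

default_lt <- function() memoised("lt", make_gompertz_life_table)
ss_params <- function() memoised("ss", function() reference_parameter_fixture("SS"))
ps_params <- function() memoised("ps", function() reference_parameter_fixture("PS"))
calibrated_mm <- function() memoised("mm", function() {
  calibrated_mortality_model(ss_params(), default_lt())
})
base_case_ss <- function() memoised("bc_ss", function() {
  run_base_case(ss_params(), "BASE_60M", calibrated_mm())
})
base_case_ps <- function() memoised("bc_ps", function() {
  run_base_case(ps_params(), "BASE_60M", calibrated_mm())
})

# flat constant-mortality life table for closed-form checks
flat_life_table <- function(q = 0.12, min_age = 0, max_age = 110) {
  df <- data.frame(age = min_age:max_age, q_annual = q)
  df$q_annual[nrow(df)] <- 1
  life_table(df)
}

# parameters with all device-specific inputs neutralised: the two arms must
# then be indistinguishable
neutralised_params <- function(p = ss_params()) {
  p$hr_hosp_treatment <- 1
  p$du_treat_1_6 <- p$du_ctrl_1_6
  p$du_treat_7_60 <- p$du_ctrl_7_60
  p$p_complication <- 0
  p$p_procedural_death <- 0
  p$cost_device <- 0
  p$cost_implant <- 0
  p$cost_complication_weighted <- 0
  p$cost_monitoring_monthly <- 0
  p
}
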