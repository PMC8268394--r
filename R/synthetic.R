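# Synthetic inputs: parametric life table, simulated study-level hazard
# ratios, and the built-in reference parameter fixture.

#' Generate a Gompertz life table
#'
#' Builds an age-indexed table of annual death probabilities from a Gompertz
#' hazard, `q(age) = 1 - exp(-alpha * exp(beta * age))`, with the terminal age
#' forced to `q = 1`. This stands in for a national (Argentine-like) life
#' table: the defaults give adult mortality of the right order for a South
#' American population (q at age 66 of about 0.016) with the usual
#' log-linear increase of adult mortality with age.
#'
#' @param alpha Baseline annual hazard at age 0 (default `2.0e-5`).
#' @param beta Log-hazard slope per year of age (default `0.101`, i.e. the
#'   death hazard doubles roughly every 7 years).
#' @param max_age Terminal age of the table (default 110; must be >= 100).
#' @param min_age First age in the table (default 0).
#' @return A `life_table` data.frame with columns `age` and `q_annual`.
#' @examples
#' lt <- make_gompertz_life_table()
#' lt$q_annual[lt$age == 66]
#' @export
make_gompertz_life_table <- function(alpha = 2.0e-5, beta = 0.101,
                                     max_age = 110, min_age = 0) {
  if (!(alpha > 0)) stop("alpha must be > 0", call. = FALSE)
  if (!(beta > 0)) stop("beta must be > 0", call. = FALSE)
  if (max_age < 100) stop("max_age must be >= 100", call. = FALSE)
  age <- seq.int(min_age, max_age)
  q <- 1 - exp(-alpha * exp(beta * age))
  q[length(q)] <- 1
  life_table(data.frame(age = age, q_annual = q))
}

#' Simulate study-level hazard-ratio summaries
#'
#' Draws `n_studies` log hazard ratios around a common true value, each with
#' its own standard error, and reports them as point estimates with 95%
#' confidence intervals -- the input format of [pool_hazard_ratios()]. Used to
#' exercise and validate the pooling module.
#'
#' @param true_hr True common hazard ratio (> 0).
#' @param n_studies Number of studies (>= 1).
#' @param se_range Length-2 numeric; each study's SE of the log-HR is drawn
#'   uniformly from this range.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame with columns `label`, `hr`, `ci_low`, `ci_high`.
#' @export
make_study_effects <- function(true_hr, n_studies, se_range = c(0.1, 0.3),
                               seed = NULL) {
  if (!(true_hr > 0)) stop("true_hr must be > 0", call. = FALSE)
  if (n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  se <- stats::runif(n_studies, se_range[1], se_range[2])
  loghr <- stats::rnorm(n_studies, log(true_hr), se)
  z <- stats::qnorm(0.975)
  data.frame(
    label = sprintf("study_%02d", seq_len(n_studies)),
    hr = exp(loghr),
    ci_low = exp(loghr - z * se),
    ci_high = exp(loghr + z * se),
    stringsAsFactors = FALSE
  )
}

# Base-case inputs, uncertainty ranges and distribution families for the
# published model. Clinical/efficacy ranges are 95% CIs, utility ranges are
# SDs, cost ranges are min--max (about +/- 25% of base). Distribution
# remappings relative to the published table: the admission rate (1.13 > 1)
# is sampled as gamma, and the signed monthly utility changes as normal,
# since a beta variate can do neither.
.reference_fixture <- list(
  clinical = list(
    entry_age = list(base = 66, low = 61, high = 69,
                     dist = "normal", kind = "ci95"),
    baseline_hosp_rate = list(base = 1.13, low = 0.68, high = 1.55,
                              dist = "gamma", kind = "ci95"),
    hr_hosp_treatment = list(base = 0.48, low = 0.38, high = 0.67,
                             dist = "lognormal", kind = "ci95"),
    baseline_mortality_12m_treatment = list(base = 0.16, low = 0.14, high = 0.18,
                                            dist = "beta", kind = "ci95"),
    hr_mortality_admission = list(base = 3.32, low = 1.00, high = 5.00,
                                  dist = "lognormal", kind = "ci95"),
    p_complication = list(base = 0.03, low = 0.02, high = 0.04,
                          dist = "beta", kind = "ci95"),
    p_procedural_death = list(base = 0.004, low = 0.003, high = 0.005,
                              dist = "beta", kind = "ci95")
  ),
  utility = list(
    utility_baseline = list(base = 0.711, sd = 0.027, dist = "beta", kind = "sd"),
    du_treat_1_6 = list(base = 0.001, sd = 0.001, dist = "normal", kind = "sd"),
    du_treat_7_60 = list(base = 0.003, sd = 0.003, dist = "normal", kind = "sd"),
    du_ctrl_1_6 = list(base = -0.005, sd = 0.004, dist = "normal", kind = "sd"),
    du_ctrl_7_60 = list(base = -0.003, sd = 0.003, dist = "normal", kind = "sd"),
    disutility_admission = list(base = 0.045, sd = 0.012, dist = "beta", kind = "sd")
  ),
  costs = list(
    cost_device = list(base = 1392182, low = 1044137, high = 1740228,
                       dist = "normal", kind = "minmax"),
    cost_implant = list(
      ss = list(base = 100878, low = 75659, high = 126098,
                dist = "normal", kind = "minmax"),
      ps = list(base = 137090, low = 102818, high = 171363,
                dist = "normal", kind = "minmax")),
    cost_complication_weighted = list(
      ss = list(base = 144482, low = 108362, high = 180603,
                dist = "normal", kind = "minmax"),
      ps = list(base = 193445, low = 145084, high = 227954,
                dist = "normal", kind = "minmax")),
    cost_monitoring_monthly = list(
      ss = list(base = 973, low = 730, high = 1217,
                dist = "normal", kind = "minmax"),
      ps = list(base = 1502, low = 1126, high = 1877,
                dist = "normal", kind = "minmax")),
    cost_standard_care_monthly = list(
      ss = list(base = 4512, low = 3384, high = 5641,
                dist = "normal", kind = "minmax"),
      ps = list(base = 5440, low = 4080, high = 6800,
                dist = "normal", kind = "minmax")),
    cost_admission = list(
      ss = list(base = 362788, low = 272091, high = 453485,
                dist = "normal", kind = "minmax"),
      ps = list(base = 534983, low = 401237, high = 655753,
                dist = "normal", kind = "minmax"))
  ),
  structural = list(
    discount_rate_annual = 0.05,
    effect_duration_months = 60,
    calibration_target_mortality = 0.23,
    calibration_horizon_months = 18,
    gdp_per_capita = 700473,
    exchange_rate_ars_per_usd = 76.95,
    utility_mode = "carry_forward",
    monitoring_duration_months = Inf
  )
)

#' Built-in reference parameter set
#'
#' Returns the complete published base case for the requested payer
#' perspective: clinical and efficacy parameters, the utility trajectory,
#' per-perspective unit costs in ARS, and per-parameter uncertainty
#' descriptors for the sensitivity analyses. A plain-text copy of the same
#' values ships in `inst/extdata/reference_parameters.yaml`.
#'
#' @param perspective `"SS"` (Social Security) or `"PS"` (Private Sector).
#' @return A `pamcea_params` object (see [load_parameters()]).
#' @examples
#' p <- reference_parameter_fixture("SS")
#' p$cost_admission
#' @export
reference_parameter_fixture <- function(perspective = c("SS", "PS")) {
  load_parameters(.reference_fixture, perspective)
}
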