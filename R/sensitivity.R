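# Uncertainty analyses: one-way deterministic sensitivity (tornado),
# probabilistic sensitivity analysis over the published parameter
# distributions, cost-effectiveness acceptability curves, and the
# treatment-effect-duration scenarios.

# Parameters whose variation changes the control arm's observable mortality;
# varying one of these re-runs the correction-factor calibration so the
# control arm keeps matching the trial-observed 23% mortality at 18 months.
.recalibrate_ids <- c("entry_age", "hr_mortality_admission",
                      "baseline_hosp_rate")

# Parameters excluded from sampling/DSA: carried for validation only.
.validation_only_ids <- "baseline_mortality_12m_treatment"

#' One-way deterministic sensitivity analysis for a single parameter
#'
#' Reruns the full base case twice with one parameter set to its low and
#' high value, all else held at base case. The calibrated mortality model is
#' held fixed, except when the varied parameter itself drives control-arm
#' mortality (`entry_age`, `hr_mortality_admission`, `baseline_hosp_rate`),
#' in which case the correction factor is recalibrated for each endpoint.
#'
#' @param p A `pamcea_params` parameter set.
#' @param parameter_id Name of the parameter to vary.
#' @param low,high Endpoint values; default to the parameter's DSA range
#'   (95% CI, +/- 1 SD for utilities, min--max for costs).
#' @param scenario Treatment-effect scenario (default `"BASE_60M"`).
#' @param mortality_model The calibrated [mortality_model()] of the base case.
#' @return A one-row data.frame: `parameter`, `low_value`, `high_value`,
#'   `icer_at_low`, `icer_at_high`, `span`, `recalibrated`.
#' @export
one_way_dsa <- function(p, parameter_id, low = NULL, high = NULL,
                        scenario = "BASE_60M", mortality_model) {
  u <- p$uncertainty[[parameter_id]]
  if (!parameter_id %in% names(p) || (is.null(u) && is.null(low))) {
    stop("unknown or range-less parameter: ", parameter_id, call. = FALSE)
  }
  if (is.null(low)) low <- u$dsa_low
  if (is.null(high)) high <- u$dsa_high
  if (low > high) stop("low must be <= high", call. = FALSE)
  recal <- parameter_id %in% .recalibrate_ids
  icer_with <- function(value) {
    pv <- set_param(p, parameter_id, value)
    viol <- validate_parameters(pv)
    # only the parameter's own range rules matter here; the stored DSA span
    # no longer brackets a deliberately displaced base value
    viol <- viol[viol$field == parameter_id &
                   !grepl("DSA range", viol$rule), , drop = FALSE]
    if (nrow(viol) > 0) {
      stop("invalid DSA value for ", parameter_id, ": ", viol$rule[1],
           call. = FALSE)
    }
    mm <- if (recal) {
      calibrated_mortality_model(pv, mortality_model$life_table)
    } else {
      mortality_model
    }
    run_base_case(pv, scenario, mm)$icer_discounted$icer
  }
  il <- icer_with(low); ih <- icer_with(high)
  data.frame(parameter = parameter_id, low_value = low, high_value = high,
             icer_at_low = il, icer_at_high = ih,
             span = abs(ih - il), recalibrated = recal,
             stringsAsFactors = FALSE)
}

#' Tornado analysis: one-way DSA over all uncertain parameters
#'
#' @param p A `pamcea_params` parameter set.
#' @param dsa_spec Optional data.frame with columns `parameter`, `low`,
#'   `high`; defaults to every non-fixed parameter's DSA range from the
#'   uncertainty map (validation-only parameters excluded).
#' @param scenario Treatment-effect scenario.
#' @param mortality_model The calibrated base-case [mortality_model()].
#' @return A data.frame of [one_way_dsa()] rows sorted by descending ICER
#'   span, class `pamcea_tornado`.
#' @export
run_tornado <- function(p, dsa_spec = NULL, scenario = "BASE_60M",
                        mortality_model) {
  if (is.null(dsa_spec)) {
    ids <- setdiff(names(p$uncertainty), .validation_only_ids)
    ids <- ids[vapply(ids, function(i)
      p$uncertainty[[i]]$distribution != "fixed", logical(1))]
    dsa_spec <- data.frame(
      parameter = ids,
      low = vapply(ids, function(i) p$uncertainty[[i]]$dsa_low, numeric(1)),
      high = vapply(ids, function(i) p$uncertainty[[i]]$dsa_high, numeric(1)),
      stringsAsFactors = FALSE)
  }
  if (nrow(dsa_spec) == 0) {
    out <- data.frame(parameter = character(), low_value = numeric(),
                      high_value = numeric(), icer_at_low = numeric(),
                      icer_at_high = numeric(), span = numeric(),
                      recalibrated = logical(), stringsAsFactors = FALSE)
    class(out) <- c("pamcea_tornado", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(dsa_spec)), function(i) {
    one_way_dsa(p, dsa_spec$parameter[i], dsa_spec$low[i], dsa_spec$high[i],
                scenario, mortality_model)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  class(out) <- c("pamcea_tornado", "data.frame")
  out
}

# internal: SD implied by an uncertainty spec (CI and min-max ranges are
# both read as 95% intervals)
.uspec_sd <- function(u) {
  switch(u$bounds_kind,
         sd = u$bounds_low,
         (u$bounds_high - u$bounds_low) / (2 * .z975))
}

# internal: draw one value for a parameter, rejecting draws that violate the
# parameter's own validity range
.sample_one <- function(id, base, u) {
  sdv <- .uspec_sd(u)
  draw <- switch(u$distribution,
    fixed = function() base,
    normal = function() stats::rnorm(1, base, sdv),
    lognormal = function() {
      sdlog <- (log(u$bounds_high) - log(u$bounds_low)) / (2 * .z975)
      stats::rlnorm(1, log(base), sdlog)
    },
    gamma = function() {
      stats::rgamma(1, shape = (base / sdv)^2, rate = base / sdv^2)
    },
    beta = function() {
      v <- sdv^2
      k <- base * (1 - base) / v - 1
      if (k <= 0) {
        stop("beta moments unmatchable for parameter '", id, "'",
             call. = FALSE)
      }
      stats::rbeta(1, base * k, (1 - base) * k)
    })
  ok <- function(x) {
    if (!is.finite(x)) return(FALSE)
    if (id == "entry_age") return(x >= 18 && x <= 100)
    if (startsWith(id, "cost_")) return(x >= 0)
    if (startsWith(id, "hr_")) return(x > 0)
    if (id %in% c("p_complication", "p_procedural_death",
                  "utility_baseline", "disutility_admission")) {
      return(x >= 0 && x <= 1)
    }
    if (id == "baseline_hosp_rate") return(x >= 0)
    TRUE
  }
  for (i in seq_len(100)) {
    x <- draw()
    if (ok(x)) {
      return(list(value = x, resampled = i - 1L))
    }
  }
  stop("could not draw a valid value for '", id, "' in 100 attempts",
       call. = FALSE)
}

#' Draw one parameter set from the uncertainty distributions
#'
#' Samples every non-fixed parameter from its (remapped) distribution: beta
#' parameters are moment-matched to base + 95% CI (or the stated SD),
#' lognormal hazard ratios take their log-SE from the CI, costs are normal
#' with SD derived from the min--max range read as a 95% interval, and the
#' admission rate is gamma. The sampled entry age is rounded to the nearest
#' integer year for life-table lookup. Draws violating a parameter's validity
#' range are rejected and redrawn. Uses the current RNG state (fix with
#' `set.seed()` for reproducibility).
#'
#' @param p A `pamcea_params` parameter set with uncertainty descriptors.
#' @return A list: `params` (the sampled `pamcea_params`), `sampled` (named
#'   vector of sampled values) and `n_resampled` (rejected draws).
#' @export
sample_parameters <- function(p) {
  sampled <- numeric(0)
  n_res <- 0L
  ids <- setdiff(names(p$uncertainty), .validation_only_ids)
  for (id in ids) {
    s <- .sample_one(id, p[[id]], p$uncertainty[[id]])
    val <- if (id == "entry_age") round(s$value) else s$value
    sampled[id] <- val
    n_res <- n_res + s$resampled
    p[[id]] <- val
  }
  list(params = p, sampled = sampled, n_resampled = n_res)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of joint parameter uncertainty: per draw, samples
#' every uncertain parameter ([sample_parameters()]), optionally recalibrates
#' the mortality correction factor so each draw's control arm still matches
#' the trial mortality target, reruns both arms over a lifetime horizon, and
#' records the incremental discounted cost and QALY.
#'
#' @param p A `pamcea_params` parameter set.
#' @param scenario Treatment-effect scenario (default `"BASE_60M"`).
#' @param mortality_model Base-case [mortality_model()]; supplies the life
#'   table, and the fallback correction factor when `recalibrate = FALSE`.
#' @param n_draws Number of Monte Carlo draws (published analysis: 1000).
#' @param seed Integer seed; fixing it makes the draw list bit-reproducible.
#' @param recalibrate Recalibrate the correction factor within each draw
#'   (default `TRUE`).
#' @return A data.frame of class `pamcea_psa`: one row per draw with the
#'   sampled parameter values, `correction_factor`, `delta_cost` and
#'   `delta_qaly` (discounted). Attributes: `n_failed` (draws that failed and
#'   were replaced), `n_resampled` (single-parameter rejections), `seed`.
#' @export
run_psa <- function(p, scenario = "BASE_60M", mortality_model,
                    n_draws = 1000, seed = NULL, recalibrate = TRUE) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lt <- mortality_model$life_table
  rows <- vector("list", n_draws)
  n_failed <- 0L; n_resampled <- 0L
  for (i in seq_len(n_draws)) {
    for (attempt in seq_len(50)) {
      res <- tryCatch({
        s <- sample_parameters(p)
        mm <- if (recalibrate) {
          calibrated_mortality_model(s$params, lt)
        } else {
          mortality_model
        }
        bc <- run_base_case(s$params, scenario, mm)
        c(s$sampled, correction_factor = mm$correction_factor,
          delta_cost = bc$icer_discounted$delta_cost,
          delta_qaly = bc$icer_discounted$delta_qaly,
          n_resampled = s$n_resampled)
      }, error = function(e) NULL)
      if (!is.null(res)) break
      n_failed <- n_failed + 1L
    }
    if (is.null(res)) {
      stop("PSA draw ", i, " failed repeatedly; check parameter specs",
           call. = FALSE)
    }
    n_resampled <- n_resampled + res[["n_resampled"]]
    rows[[i]] <- res[setdiff(names(res), "n_resampled")]
  }
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(draw = seq_len(n_draws), out)
  attr(out, "n_failed") <- n_failed
  attr(out, "n_resampled") <- n_resampled
  attr(out, "seed") <- seed
  attr(out, "perspective") <- p$perspective
  class(out) <- c("pamcea_psa", "data.frame")
  out
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA draws with
#' positive net monetary benefit, `lambda * delta_qaly - delta_cost > 0`.
#'
#' @param draws A `pamcea_psa` data.frame (needs `delta_cost`, `delta_qaly`).
#' @param wtp_grid Thresholds in ARS per QALY; default 0 to 6 GDP per capita
#'   in steps of 0.1 GDP.
#' @param gdp_per_capita GDP per capita used for the default grid.
#' @return A data.frame with columns `wtp` and `probability_cost_effective`.
#' @export
ceac <- function(draws, wtp_grid = NULL, gdp_per_capita = 700473) {
  if (is.null(draws) || nrow(draws) < 1) {
    stop("at least one PSA draw is required", call. = FALSE)
  }
  if (is.null(wtp_grid)) {
    wtp_grid <- seq(0, 6, by = 0.1) * gdp_per_capita
  }
  prob <- vapply(wtp_grid, function(lambda) {
    mean(lambda * draws$delta_qaly - draws$delta_cost > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability_cost_effective = prob)
}

#' Treatment-effect-duration scenario analysis
#'
#' Runs the three effect-duration scenarios (base-case 60 months, lifetime,
#' and decline from month 18 to month 60) for one or more perspectives.
#'
#' @param params A `pamcea_params` object, or a (possibly named) list of
#'   them, one per perspective.
#' @param mortality_model The calibrated [mortality_model()] (shared across
#'   scenarios; the scenarios change only the treatment effect).
#' @return A data.frame with one row per perspective x scenario:
#'   incremental discounted cost/QALY, and discounted and undiscounted ICERs.
#' @export
run_scenarios <- function(params, mortality_model) {
  if (inherits(params, "pamcea_params")) params <- list(params)
  rows <- list()
  for (p in params) {
    for (s in .scenarios) {
      bc <- run_base_case(p, s, mortality_model)
      rows[[length(rows) + 1]] <- data.frame(
        perspective = p$perspective, scenario = s,
        delta_cost = bc$icer_discounted$delta_cost,
        delta_qaly = bc$icer_discounted$delta_qaly,
        icer_discounted = bc$icer_discounted$icer,
        icer_undiscounted = bc$icer_undiscounted$icer,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
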