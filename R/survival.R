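# Background mortality: rate/probability conversions, life tables, and the
# heart-failure excess-hazard correction factor calibrated so the control
# arm's cumulative mortality matches the trial-observed risk.

#' Convert an event rate to a probability (and back)
#'
#' Standard exponential conversions between a constant event rate and the
#' probability of at least one event over a duration:
#' `p = 1 - exp(-rate * duration)` and `rate = -log(1 - p) / duration`.
#'
#' @param rate Event rate (events per unit time, >= 0).
#' @param prob Probability in \[0, 1).
#' @param duration Exposure duration, in the rate's time unit (> 0).
#' @return A probability (`prob_from_rate`) or a rate (`rate_from_prob`).
#' @examples
#' prob_from_rate(1.13, 1 / 12)  # monthly admission risk from 1.13/pt-yr
#' @export
prob_from_rate <- function(rate, duration = 1) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  1 - exp(-rate * duration)
}

#' @rdname prob_from_rate
#' @export
rate_from_prob <- function(prob, duration = 1) {
  if (any(prob < 0 | prob >= 1)) stop("prob must be in [0, 1)", call. = FALSE)
  if (any(duration <= 0)) stop("duration must be > 0", call. = FALSE)
  -log(1 - prob) / duration
}

#' Construct and validate a life table
#'
#' @param x A data.frame with columns `age` (integer years, strictly
#'   increasing and contiguous) and `q_annual` (annual death probability in
#'   \[0, 1\], equal to 1 at the terminal age).
#' @return `x` with class `life_table` prepended.
#' @export
life_table <- function(x) {
  if (!all(c("age", "q_annual") %in% names(x))) {
    stop("life table needs columns 'age' and 'q_annual'", call. = FALSE)
  }
  x <- as.data.frame(x)[c("age", "q_annual")]
  if (nrow(x) < 2 || any(diff(x$age) != 1)) {
    stop("life-table ages must be contiguous integers", call. = FALSE)
  }
  if (any(x$q_annual < 0 | x$q_annual > 1)) {
    stop("q_annual must lie in [0, 1]", call. = FALSE)
  }
  if (x$q_annual[nrow(x)] != 1) {
    stop("q_annual must equal 1 at the terminal age", call. = FALSE)
  }
  class(x) <- c("life_table", "data.frame")
  x
}

#' Read / write a life table as two-column CSV
#'
#' @param path CSV file with header `age,q_annual`.
#' @param lt A `life_table`.
#' @return `read_life_table()` returns a `life_table`; `write_life_table()`
#'   returns `path` invisibly.
#' @export
read_life_table <- function(path) {
  life_table(utils::read.csv(path))
}

#' @rdname read_life_table
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE)
  invisible(path)
}

#' Background-mortality model with an excess-hazard correction factor
#'
#' Couples a life table with a dimensionless hazard multiplier representing
#' the excess death risk of NYHA class III heart failure relative to the
#' general population. The multiplier acts on the hazard scale, so derived
#' probabilities stay in \[0, 1\] for any factor.
#'
#' @param life_table A `life_table`.
#' @param correction_factor Hazard multiplier (>= 1); the published base case
#'   calibrates to about 7.7.
#' @return An object of class `mortality_model`.
#' @export
mortality_model <- function(life_table, correction_factor = 1) {
  stopifnot(inherits(life_table, "life_table"))
  if (correction_factor < 1) {
    stop("correction_factor must be >= 1", call. = FALSE)
  }
  structure(list(life_table = life_table,
                 correction_factor = correction_factor),
            class = "mortality_model")
}

# internal: annual q at floor(age), vectorised; errors outside the table
.q_annual_at <- function(lt, age) {
  a <- floor(age)
  idx <- a - lt$age[1] + 1
  if (any(idx < 1 | idx > nrow(lt))) {
    stop("age ", paste(unique(a[idx < 1 | idx > nrow(lt)]), collapse = ", "),
         " outside the life-table range [", lt$age[1], ", ",
         lt$age[nrow(lt)], "]", call. = FALSE)
  }
  lt$q_annual[idx]
}

#' Monthly background death probability at a given age
#'
#' Converts the life table's annual death probability at `floor(age)` to a
#' hazard, scales it by the model's correction factor (and an optional extra
#' multiplier, e.g. the in-admission mortality hazard ratio), and converts
#' back to a one-month probability.
#'
#' @param m A [mortality_model()].
#' @param age Age in years (may be fractional; the annual probability of the
#'   integer year applies).
#' @param extra_hazard_multiplier Additional hazard multiplier (default 1).
#' @return Monthly death probability in \[0, 1\] (vectorised over `age`).
#' @export
monthly_background_mortality <- function(m, age, extra_hazard_multiplier = 1) {
  q <- .q_annual_at(m$life_table, age)
  h_month <- -log(1 - pmin(q, 1 - 1e-15)) / 12
  p <- 1 - exp(-h_month * m$correction_factor * extra_hazard_multiplier)
  p[q >= 1] <- 1
  p
}

#' Cumulative background mortality over a number of months
#'
#' Product-limit cumulative death probability starting from `entry_age`, with
#' the cohort aging in exact monthly increments and the annual probability of
#' each integer year applying throughout that year.
#'
#' @param m A [mortality_model()].
#' @param entry_age Starting age in years.
#' @param months Number of monthly cycles (>= 0).
#' @param extra_hazard_multiplier Additional hazard multiplier applied every
#'   month (default 1).
#' @return Cumulative death probability in \[0, 1\].
#' @export
cumulative_mortality <- function(m, entry_age, months,
                                 extra_hazard_multiplier = 1) {
  if (months < 0) stop("months must be >= 0", call. = FALSE)
  if (months == 0) return(0)
  ages <- entry_age + (seq_len(months) - 1) / 12
  qm <- monthly_background_mortality(m, ages, extra_hazard_multiplier)
  1 - prod(1 - qm)
}

#' Calibrate the heart-failure excess-mortality correction factor
#'
#' Finds the hazard multiplier that makes the control-arm model's cumulative
#' mortality at the calibration horizon equal the externally observed risk
#' (base case: 23% at 18 months, the control-arm mortality of the pivotal
#' trial). Calibration runs the full control-arm cohort model -- including the
#' elevated mortality of the admission and post-admission states -- so the
#' factor matches the model's observable mortality, not the stable state
#' alone. Root finding is bracketed bisection on \[1, 100\], deterministic,
#' with tolerance `1e-6` on the target probability.
#'
#' @param p A `pamcea_params` parameter set (admission rate and in-admission
#'   mortality hazard ratio enter the calibration).
#' @param life_table A `life_table`.
#' @param target Cumulative mortality to hit (default
#'   `p$calibration_target_mortality`).
#' @param horizon_months Calibration horizon in months (default
#'   `p$calibration_horizon_months`).
#' @return The correction factor (a single number >= 1).
#' @seealso [mortality_model()], [run_cohort()].
#' @export
calibrate_correction_factor <- function(p, life_table,
                                        target = p$calibration_target_mortality,
                                        horizon_months = p$calibration_horizon_months) {
  stopifnot(inherits(p, "pamcea_params"), inherits(life_table, "life_table"))
  if (!(target > 0 && target < 1)) {
    stop("calibration target must be in (0, 1)", call. = FALSE)
  }
  mort_at <- function(f) {
    mm <- mortality_model(life_table, f)
    tr <- run_cohort(p, arm = "CONTROL", scenario = "BASE_60M",
                     mortality_model = mm, horizon = horizon_months)
    tr$occupancy[horizon_months + 1, "DEATH"]
  }
  lo <- 1; hi <- 100
  m_lo <- mort_at(lo)
  if (abs(m_lo - target) <= 1e-6) return(1)
  m_hi <- mort_at(hi)
  if (m_lo > target || m_hi < target) {
    stop(sprintf(paste0("calibration target %.4f not achievable: model ",
                        "mortality at %d months spans [%.4f, %.4f] for ",
                        "factors in [1, 100]"),
                 target, horizon_months, m_lo, m_hi), call. = FALSE)
  }
  for (i in seq_len(200)) {
    mid <- (lo + hi) / 2
    m_mid <- mort_at(mid)
    if (abs(m_mid - target) <= 1e-6) return(mid)
    if (m_mid < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Calibrated background-mortality model
#'
#' Convenience wrapper: calibrates the correction factor with
#' [calibrate_correction_factor()] and returns the resulting
#' [mortality_model()].
#'
#' @inheritParams calibrate_correction_factor
#' @return A `mortality_model` with the calibrated factor.
#' @export
calibrated_mortality_model <- function(p, life_table,
                                       target = p$calibration_target_mortality,
                                       horizon_months = p$calibration_horizon_months) {
  f <- calibrate_correction_factor(p, life_table, target, horizon_months)
  mortality_model(life_table, f)
}
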