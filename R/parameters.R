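#' @keywords internal
"_PACKAGE"

# Parameter ids that feed the cohort engine, by block. Everything else in a
# config is structural. `baseline_mortality_12m_treatment` is carried for
# external validation only and never enters a transition probability.
.clinical_ids <- c(
  "entry_age", "baseline_hosp_rate", "hr_hosp_treatment",
  "baseline_mortality_12m_treatment", "hr_mortality_admission",
  "p_complication", "p_procedural_death"
)
.utility_ids <- c(
  "utility_baseline", "du_treat_1_6", "du_treat_7_60",
  "du_ctrl_1_6", "du_ctrl_7_60", "disutility_admission"
)
.cost_ids <- c(
  "cost_device", "cost_implant", "cost_complication_weighted",
  "cost_monitoring_monthly", "cost_standard_care_monthly", "cost_admission"
)
.structural_defaults <- list(
  discount_rate_annual = 0.05,
  effect_duration_months = 60,
  calibration_target_mortality = 0.23,
  calibration_horizon_months = 18,
  gdp_per_capita = 700473,
  exchange_rate_ars_per_usd = 76.95,
  utility_mode = "carry_forward",
  monitoring_duration_months = Inf
)

#' Uncertainty descriptor for one parameter
#'
#' Describes how a parameter's uncertainty is expressed (95% CI, standard
#' deviation, or min--max range), which distribution family the probabilistic
#' sensitivity analysis samples from, and the range used by the one-way
#' deterministic sensitivity analysis.
#'
#' @param distribution One of `"beta"`, `"lognormal"`, `"normal"`, `"gamma"`,
#'   `"fixed"`.
#' @param bounds_kind One of `"ci95"`, `"sd"`, `"minmax"`.
#' @param bounds_low,bounds_high Interval bounds (for `bounds_kind = "sd"` both
#'   hold the standard deviation).
#' @param base Base-case value, used to derive the default DSA range.
#' @param dsa_low,dsa_high One-way sensitivity range; defaults to the interval
#'   bounds (or base +/- 1 SD when `bounds_kind = "sd"`).
#' @return A list of class `pamcea_uspec`.
#' @export
uncertainty_spec <- function(distribution, bounds_kind, bounds_low, bounds_high,
                             base = NA_real_, dsa_low = NULL, dsa_high = NULL) {
  distribution <- match.arg(distribution,
                            c("beta", "lognormal", "normal", "gamma", "fixed"))
  bounds_kind <- match.arg(bounds_kind, c("ci95", "sd", "minmax"))
  if (bounds_kind != "sd" && !is.na(bounds_low) && !is.na(bounds_high) &&
      bounds_low > bounds_high) {
    stop("uncertainty_spec: bounds_low > bounds_high", call. = FALSE)
  }
  if (is.null(dsa_low)) {
    dsa_low <- if (bounds_kind == "sd") base - bounds_low else bounds_low
  }
  if (is.null(dsa_high)) {
    dsa_high <- if (bounds_kind == "sd") base + bounds_high else bounds_high
  }
  structure(
    list(distribution = distribution, bounds_kind = bounds_kind,
         bounds_low = bounds_low, bounds_high = bounds_high,
         dsa_low = dsa_low, dsa_high = dsa_high),
    class = "pamcea_uspec"
  )
}

#' Load and validate a model parameter set
#'
#' Reads a structured configuration (YAML/JSON file or an equivalent R list)
#' holding the clinical, utility and per-perspective cost inputs together with
#' their uncertainty descriptors, selects the cost column for the requested
#' payer perspective, fills missing structural settings with base-case
#' defaults, and validates every invariant.
#'
#' @param source Path to a YAML or JSON configuration file, or a list with
#'   blocks `clinical`, `utility`, `costs` and optionally `structural`. Cost
#'   entries may carry a single `base`/`low`/`high` or per-perspective `ss`/`ps`
#'   sub-blocks.
#' @param perspective `"SS"` (Social Security) or `"PS"` (Private Sector).
#' @return An object of class `pamcea_params`: a named list of base-case
#'   values, structural settings, the active `perspective`, and an
#'   `uncertainty` map of [uncertainty_spec()] entries.
#' @seealso [reference_parameter_fixture()] for the built-in base case,
#'   [validate_parameters()], [write_config()].
#' @export
load_parameters <- function(source, perspective = c("SS", "PS")) {
  perspective <- match.arg(toupper(perspective), c("SS", "PS"))
  cfg <- if (is.character(source)) {
    if (!file.exists(source)) stop("config file not found: ", source, call. = FALSE)
    if (grepl("\\.json$", source, ignore.case = TRUE)) {
      jsonlite::read_json(source, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(source)
    }
  } else if (is.list(source)) {
    source
  } else {
    stop("source must be a file path or a list", call. = FALSE)
  }

  for (block in c("clinical", "utility", "costs")) {
    if (is.null(cfg[[block]])) {
      stop("config is missing the '", block, "' block", call. = FALSE)
    }
  }

  p <- list(perspective = perspective)
  unc <- list()

  pull_entry <- function(entry, id, block) {
    if (is.null(entry)) {
      stop("config is missing required parameter '", id, "' in block '",
           block, "'", call. = FALSE)
    }
    entry
  }
  entry_to_uspec <- function(e, base) {
    dist <- if (is.null(e$dist)) "fixed" else e$dist
    kind <- if (is.null(e$kind)) "ci95" else e$kind
    if (kind == "sd") {
      sdv <- if (!is.null(e$sd)) e$sd else e$low
      uncertainty_spec(dist, "sd", sdv, sdv, base = base)
    } else {
      uncertainty_spec(dist, kind, e$low, e$high, base = base)
    }
  }

  for (id in .clinical_ids) {
    e <- pull_entry(cfg$clinical[[id]], id, "clinical")
    p[[id]] <- as.numeric(e$base)
    unc[[id]] <- entry_to_uspec(e, p[[id]])
  }
  for (id in .utility_ids) {
    e <- pull_entry(cfg$utility[[id]], id, "utility")
    p[[id]] <- as.numeric(e$base)
    unc[[id]] <- entry_to_uspec(e, p[[id]])
  }
  side <- tolower(perspective)
  for (id in .cost_ids) {
    e <- pull_entry(cfg$costs[[id]], id, "costs")
    if (!is.null(e[[side]])) e <- e[[side]]
    if (is.null(e$base)) {
      stop("cost parameter '", id, "' has no value for perspective ",
           perspective, call. = FALSE)
    }
    p[[id]] <- as.numeric(e$base)
    unc[[id]] <- entry_to_uspec(e, p[[id]])
  }

  st <- cfg$structural
  for (id in names(.structural_defaults)) {
    p[[id]] <- if (!is.null(st[[id]])) st[[id]] else .structural_defaults[[id]]
  }
  if (is.character(p$monitoring_duration_months)) {
    # ".inf" sentinel: YAML/JSON carry no native infinity
    p$monitoring_duration_months <- Inf
  }
  p$monitoring_duration_months <- as.numeric(p$monitoring_duration_months)
  p$uncertainty <- unc
  class(p) <- "pamcea_params"

  viol <- validate_parameters(p)
  if (nrow(viol) > 0) {
    stop("invalid parameter set:\n",
         paste(sprintf("  %s = %s: %s", viol$field, viol$value, viol$rule),
               collapse = "\n"),
         call. = FALSE)
  }
  p
}

#' Validate a parameter set, reporting violations
#'
#' Checks every invariant of the parameter set (probabilities and utilities in
#' \[0, 1\], non-negative rates/hazard ratios/costs, entry age in \[18, 100\],
#' well-ordered uncertainty bounds, DSA ranges spanning the base case) and
#' returns a report instead of throwing, for interactive inspection.
#'
#' @param p A `pamcea_params` object (possibly hand-edited).
#' @return A data.frame with columns `field`, `value`, `rule`; zero rows iff
#'   the parameter set is valid.
#' @export
validate_parameters <- function(p) {
  out <- list()
  bad <- function(field, value, rule) {
    out[[length(out) + 1]] <<- data.frame(
      field = field, value = as.character(value), rule = rule,
      stringsAsFactors = FALSE)
  }
  chk <- function(field, ok, rule) {
    v <- p[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) {
      bad(field, v %||% "NULL", "must be a single non-missing number")
    } else if (!ok(v)) {
      bad(field, v, rule)
    }
  }
  in01 <- function(x) x >= 0 && x <= 1
  nonneg <- function(x) x >= 0

  chk("entry_age", function(x) x >= 18 && x <= 100, "must be in [18, 100]")
  chk("baseline_hosp_rate", nonneg, "rate must be >= 0")
  chk("hr_hosp_treatment", nonneg, "hazard ratio must be >= 0")
  chk("hr_mortality_admission", nonneg, "hazard ratio must be >= 0")
  for (f in c("baseline_mortality_12m_treatment", "p_complication",
              "p_procedural_death", "calibration_target_mortality")) {
    chk(f, in01, "probability must be in [0, 1]")
  }
  for (f in c("utility_baseline", "disutility_admission")) {
    chk(f, in01, "utility must be in [0, 1]")
  }
  for (f in .cost_ids) chk(f, nonneg, "cost must be >= 0")
  chk("discount_rate_annual", nonneg, "discount rate must be >= 0")
  chk("effect_duration_months", function(x) x >= 1, "must be >= 1 month")
  chk("calibration_horizon_months", function(x) x >= 1, "must be >= 1 month")
  if (!isTRUE(p$perspective %in% c("SS", "PS"))) {
    bad("perspective", p$perspective %||% "NULL", "must be 'SS' or 'PS'")
  }
  if (!isTRUE(p$utility_mode %in% c("carry_forward", "drift_to_60"))) {
    bad("utility_mode", p$utility_mode %||% "NULL",
        "must be 'carry_forward' or 'drift_to_60'")
  }

  for (id in names(p$uncertainty)) {
    u <- p$uncertainty[[id]]
    base <- p[[id]]
    if (u$bounds_kind != "sd" &&
        isTRUE(u$bounds_low > u$bounds_high)) {
      bad(id, sprintf("[%s, %s]", u$bounds_low, u$bounds_high),
          "uncertainty bounds_low must be <= bounds_high")
    }
    if (!is.null(base) && !is.na(u$dsa_low) && !is.na(u$dsa_high) &&
        !(u$dsa_low <= base && base <= u$dsa_high)) {
      bad(id, sprintf("dsa [%s, %s] base %s", u$dsa_low, u$dsa_high, base),
          "DSA range must span the base-case value")
    }
  }

  if (length(out) == 0) {
    data.frame(field = character(), value = character(), rule = character(),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, out)
  }
}

#' Write a parameter set back to a configuration file
#'
#' Serialises a single-perspective parameter set to YAML (or JSON when the
#' path ends in `.json`) in the same schema [load_parameters()] reads, so
#' that a write/load round trip reproduces every numeric field exactly.
#'
#' @param p A `pamcea_params` object.
#' @param path Output file path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(p, path) {
  stopifnot(inherits(p, "pamcea_params"))
  ser_entry <- function(id) {
    u <- p$uncertainty[[id]]
    e <- list(base = p[[id]], dist = u$distribution, kind = u$bounds_kind)
    if (u$bounds_kind == "sd") {
      e$sd <- u$bounds_low
    } else {
      e$low <- u$bounds_low
      e$high <- u$bounds_high
    }
    e
  }
  cfg <- list(
    clinical = stats::setNames(lapply(.clinical_ids, ser_entry), .clinical_ids),
    utility = stats::setNames(lapply(.utility_ids, ser_entry), .utility_ids),
    costs = stats::setNames(lapply(.cost_ids, ser_entry), .cost_ids),
    structural = p[names(.structural_defaults)]
  )
  # YAML has no native Inf; use a large sentinel understood on re-load
  if (is.infinite(cfg$structural$monitoring_duration_months)) {
    cfg$structural$monitoring_duration_months <- ".inf"
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

#' @export
print.pamcea_params <- function(x, ...) {
  cat("<pamcea_params> perspective:", x$perspective, "\n")
  cat("  entry age:", x$entry_age,
      "| admission rate:", x$baseline_hosp_rate, "/pt-yr",
      "| admission HR (device):", x$hr_hosp_treatment, "\n")
  cat("  discount:", x$discount_rate_annual,
      "| effect duration:", x$effect_duration_months, "months",
      "| utility mode:", x$utility_mode, "\n")
  cat("  upfront device + implant cost:",
      format(x$cost_device + x$cost_implant, big.mark = ","), "ARS\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: set one parameter on a copy, re-deriving nothing
set_param <- function(p, id, value) {
  if (!id %in% names(p)) stop("unknown parameter: ", id, call. = FALSE)
  p[[id]] <- value
  p
}
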