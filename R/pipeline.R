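# End-to-end orchestration: calibration -> base case -> requested analyses,
# with tabular CSV outputs and a JSON run manifest.

#' Convert an ARS amount to USD
#'
#' @param amount Amount in Argentine pesos (ARS).
#' @param rate Exchange rate in ARS per USD (> 0); the published analysis
#'   used 76.95.
#' @return Amount in USD.
#' @export
convert_to_usd <- function(amount, rate = 76.95) {
  if (any(rate <= 0)) stop("exchange rate must be > 0", call. = FALSE)
  amount / rate
}

#' Run the full analysis pipeline
#'
#' Loads (or accepts) a parameter configuration, builds the background life
#' table, calibrates the excess-mortality correction factor, runs the base
#' case and any requested analyses, and writes tabular outputs plus a JSON
#' manifest to `output_dir`.
#'
#' Files written (per requested analysis): `summary.csv` (per-arm cumulative
#' discounted/undiscounted cost and QALY, increments, ICERs -- in ARS and
#' USD), `trace_treatment.csv` / `trace_control.csv`, `tornado.csv`,
#' `psa_draws.csv`, `ceac.csv`, `scenarios.csv`, and `manifest.json`.
#'
#' @param config Path to a YAML/JSON parameter configuration, a config list,
#'   or `NULL` for the built-in reference fixture.
#' @param perspective `"SS"` or `"PS"` (no default: the perspectives are
#'   separate analyses).
#' @param scenario Treatment-effect scenario (default `"BASE_60M"`).
#' @param analyses Subset of `c("base", "dsa", "psa", "ceac", "scenarios")`.
#' @param seed Integer seed for the stochastic analyses.
#' @param output_dir Output directory (created if missing).
#' @param n_psa_draws PSA draws (default 1000, as published).
#' @param life_table Optional `life_table`; default [make_gompertz_life_table()].
#' @param usd_rate ARS-per-USD rate for reporting (default from the config).
#' @return Invisibly, a list with the calibrated `correction_factor`, the
#'   `base_case`, any analysis outputs, and `files` written.
#' @export
run_pipeline <- function(config = NULL, perspective, scenario = "BASE_60M",
                         analyses = c("base"), seed = 20210709L,
                         output_dir = ".", n_psa_draws = 1000,
                         life_table = NULL, usd_rate = NULL) {
  t0 <- Sys.time()
  analyses <- match.arg(analyses,
                        c("base", "dsa", "psa", "ceac", "scenarios"),
                        several.ok = TRUE)
  p <- if (is.null(config)) {
    reference_parameter_fixture(perspective)
  } else {
    load_parameters(config, perspective)
  }
  if (is.null(life_table)) life_table <- make_gompertz_life_table()
  if (is.null(usd_rate)) usd_rate <- p$exchange_rate_ars_per_usd
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(output_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
    path
  }

  message(sprintf("[calibrate] targeting %.0f%% control-arm mortality at %d months",
                  100 * p$calibration_target_mortality,
                  p$calibration_horizon_months))
  mm <- calibrated_mortality_model(p, life_table)
  message(sprintf("[calibrate] correction factor = %.3f (published value: 7.7)",
                  mm$correction_factor))

  out <- list(correction_factor = mm$correction_factor)
  bc <- run_base_case(p, scenario, mm)
  out$base_case <- bc

  if ("base" %in% analyses) {
    s <- rbind(
      data.frame(strategy = "usual_care", arm = "CONTROL",
                 cost_discounted = bc$control$cost_discounted,
                 cost_undiscounted = bc$control$cost_undiscounted,
                 qaly_discounted = bc$control$qaly_discounted,
                 qaly_undiscounted = bc$control$qaly_undiscounted),
      data.frame(strategy = "pap_monitoring", arm = "TREATMENT",
                 cost_discounted = bc$treatment$cost_discounted,
                 cost_undiscounted = bc$treatment$cost_undiscounted,
                 qaly_discounted = bc$treatment$qaly_discounted,
                 qaly_undiscounted = bc$treatment$qaly_undiscounted))
    s$cost_discounted_usd <- convert_to_usd(s$cost_discounted, usd_rate)
    s$delta_cost_discounted <- c(NA, bc$icer_discounted$delta_cost)
    s$delta_qaly_discounted <- c(NA, bc$icer_discounted$delta_qaly)
    s$icer_discounted <- c(NA, bc$icer_discounted$icer)
    s$icer_undiscounted <- c(NA, bc$icer_undiscounted$icer)
    emit(s, "summary.csv")
    emit(bc$treatment$per_cycle, "trace_treatment.csv")
    emit(bc$control$per_cycle, "trace_control.csv")
  }
  if ("dsa" %in% analyses) {
    out$tornado <- run_tornado(p, scenario = scenario, mortality_model = mm)
    emit(as.data.frame(out$tornado), "tornado.csv")
  }
  if (any(c("psa", "ceac") %in% analyses)) {
    message(sprintf("[psa] %d Monte Carlo draws, seed %d", n_psa_draws, seed))
    out$psa <- run_psa(p, scenario, mm, n_draws = n_psa_draws, seed = seed)
    if (attr(out$psa, "n_failed") > 0) {
      message(sprintf("[psa] %d failed draws were resampled",
                      attr(out$psa, "n_failed")))
    }
    emit(as.data.frame(out$psa), "psa_draws.csv")
    if ("ceac" %in% analyses) {
      out$ceac <- ceac(out$psa, gdp_per_capita = p$gdp_per_capita)
      emit(out$ceac, "ceac.csv")
    }
  }
  if ("scenarios" %in% analyses) {
    out$scenarios <- run_scenarios(p, mm)
    emit(out$scenarios, "scenarios.csv")
  }

  manifest <- list(
    package = "pamcea",
    version = as.character(utils::packageVersion("pamcea")),
    config = if (is.character(config)) config else "(in-memory)",
    config_hash = if (is.character(config) && file.exists(config)) {
      unname(tools::md5sum(config))
    } else {
      "(in-memory)"
    },
    perspective = perspective, scenario = scenario,
    analyses = analyses, seed = seed,
    discount_rate_annual = p$discount_rate_annual,
    correction_factor = mm$correction_factor,
    n_psa_draws = if (any(c("psa", "ceac") %in% analyses)) n_psa_draws else 0,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    files = basename(files)
  )
  mpath <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  out$files <- c(files, mpath)
  invisible(out)
}

#' Plot helpers (tornado, PSA scatter, CEAC)
#'
#' Lightweight ggplot2 renderings of the tabular sensitivity outputs.
#' ggplot2 is an optional dependency; these error informatively without it.
#'
#' @param tornado A `pamcea_tornado` from [run_tornado()].
#' @param base_icer Base-case ICER (vertical reference line).
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, base_icer) {
  .need_ggplot()
  td <- as.data.frame(tornado)
  td$parameter <- factor(td$parameter, levels = rev(td$parameter))
  ggplot2::ggplot(td, ggplot2::aes(y = parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = icer_at_low,
                                       xend = icer_at_high,
                                       yend = parameter),
                          linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, colour = "red") +
    ggplot2::labs(x = "ICER (ARS per QALY)", y = NULL)
}

#' @rdname plot_tornado
#' @param draws A `pamcea_psa` from [run_psa()].
#' @param wtp Willingness-to-pay thresholds to draw as reference lines.
#' @export
plot_psa_scatter <- function(draws, wtp = c(700473, 2101419, 3502363)) {
  .need_ggplot()
  d <- as.data.frame(draws)
  pl <- ggplot2::ggplot(d, ggplot2::aes(delta_qaly, delta_cost)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "Incremental QALYs", y = "Incremental cost (ARS)")
  for (l in wtp) {
    pl <- pl + ggplot2::geom_abline(slope = l, intercept = 0,
                                    linetype = "dashed", colour = "blue")
  }
  pl
}

#' @rdname plot_tornado
#' @param curve A data.frame from [ceac()].
#' @export
plot_ceac <- function(curve, wtp = c(700473, 2101419, 3502363)) {
  .need_ggplot()
  ggplot2::ggplot(curve, ggplot2::aes(wtp,
                                      probability_cost_effective)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = wtp, linetype = "dashed",
                        colour = "blue") +
    ggplot2::labs(x = "Willingness to pay (ARS per QALY)",
                  y = "P(cost-effective)") +
    ggplot2::ylim(0, 1)
}

utils::globalVariables(c("parameter", "icer_at_low", "icer_at_high",
  "delta_qaly", "delta_cost", "probability_cost_effective"))

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
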