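# Inverse-variance pooling of study-level hazard ratios on the log scale.
# The pooled admission hazard ratio for the device arm (base case 0.48,
# 95% CI 0.38-0.67) is carried in the parameter set; this module reproduces
# that meta-analytic input from study-level summaries.

.z975 <- stats::qnorm(0.975)

#' Standard error of a log hazard ratio from its 95% CI
#'
#' Back-calculates `SE(log HR) = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`.
#'
#' @param hr Point estimate (unused by the formula; kept for interface
#'   symmetry and validated against the bounds).
#' @param ci_low,ci_high 95% confidence bounds (0 < ci_low <= hr <= ci_high).
#' @return Standard error of the log hazard ratio.
#' @examples
#' se_from_ci(0.48, 0.38, 0.67)
#' @export
se_from_ci <- function(hr, ci_low, ci_high) {
  if (any(ci_low <= 0) || any(ci_high <= 0) || any(hr <= 0)) {
    stop("hazard ratios and CI bounds must be > 0", call. = FALSE)
  }
  if (any(ci_low > hr) || any(hr > ci_high)) {
    stop("require ci_low <= hr <= ci_high", call. = FALSE)
  }
  (log(ci_high) - log(ci_low)) / (2 * .z975)
}

#' Pool study hazard ratios (fixed or random effects)
#'
#' Inverse-variance pooling of log hazard ratios. Fixed effect: weights
#' `1/se_i^2`, pooled SE `1/sqrt(sum w_i)`. Random effects: DerSimonian-Laird
#' between-study variance `tau2` added to each study variance before
#' weighting. The 95% CI is `exp(pooled +/- 1.959964 * SE)`.
#'
#' @param studies A data.frame with columns `label`, `hr`, `ci_low`,
#'   `ci_high` (one row per study), e.g. from [make_study_effects()] or
#'   [read_study_effects()].
#' @param method `"fixed"` (default) or `"random"`.
#' @return A one-row data.frame of class `pooled_effect` with columns `hr`,
#'   `ci_low`, `ci_high`, `method`, `tau2`, `i2`, `n_studies`.
#' @examples
#' pool_hazard_ratios(make_study_effects(0.48, 3, seed = 1))
#' @export
pool_hazard_ratios <- function(studies, method = c("fixed", "random")) {
  method <- match.arg(method)
  if (is.null(studies) || nrow(studies) < 1) {
    stop("at least one study is required", call. = FALSE)
  }
  y <- log(studies$hr)
  se <- se_from_ci(studies$hr, studies$ci_low, studies$ci_high)
  if (any(se == 0) && nrow(studies) > 1) {
    stop("degenerate (zero-width) CI in a multi-study pool", call. = FALSE)
  }
  if (nrow(studies) == 1) {
    out <- data.frame(hr = studies$hr, ci_low = studies$ci_low,
                      ci_high = studies$ci_high, method = method,
                      tau2 = 0, i2 = 0, n_studies = 1L,
                      stringsAsFactors = FALSE)
    class(out) <- c("pooled_effect", "data.frame")
    return(out)
  }
  v <- se^2
  w <- 1 / v
  y_fe <- sum(w * y) / sum(w)
  q <- sum(w * (y - y_fe)^2)
  k <- length(y)
  tau2 <- 0
  i2 <- if (q > 0) max(0, (q - (k - 1)) / q) else 0
  if (method == "random") {
    c_w <- sum(w) - sum(w^2) / sum(w)
    tau2 <- max(0, (q - (k - 1)) / c_w)
    w <- 1 / (v + tau2)
  }
  y_pool <- sum(w * y) / sum(w)
  se_pool <- sqrt(1 / sum(w))
  out <- data.frame(hr = exp(y_pool),
                    ci_low = exp(y_pool - .z975 * se_pool),
                    ci_high = exp(y_pool + .z975 * se_pool),
                    method = method, tau2 = tau2, i2 = i2,
                    n_studies = as.integer(k), stringsAsFactors = FALSE)
  class(out) <- c("pooled_effect", "data.frame")
  out
}

#' Read / write study-effect CSV files
#'
#' @param path CSV with header `label,hr,ci_low,ci_high`.
#' @param pooled A `pooled_effect` (one row per pooling method is fine).
#' @return `read_study_effects()` returns a validated data.frame;
#'   `write_pooled_effects()` returns `path` invisibly.
#' @export
read_study_effects <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "hr", "ci_low", "ci_high")
  if (!all(need %in% names(x))) {
    stop("study CSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(x$ci_low <= 0) || any(x$ci_low > x$hr) || any(x$hr > x$ci_high)) {
    stop("each study must satisfy 0 < ci_low <= hr <= ci_high", call. = FALSE)
  }
  x[need]
}

#' @rdname read_study_effects
#' @export
write_pooled_effects <- function(pooled, path) {
  utils::write.csv(as.data.frame(pooled), path, row.names = FALSE)
  invisible(path)
}
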