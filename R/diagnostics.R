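#' Flag outlying observations after a fit
#'
#' For weighted (IRLS) fits an observation is flagged when its final
#' normalized weight falls below `weight_cutoff`: the fit itself has already
#' decided how much each point counts, and a near-zero weight is an effective
#' rejection. For OLS and LMS fits, which carry no weights, flagging uses
#' standardized residuals: an observation is flagged when `|r|` exceeds
#' `residual_cutoff` robust scale units. The robust scale is the MAD for OLS
#' and the finite-sample-corrected LMS scale
#' `1.4826 (1 + 5/(n - 2)) sqrt(median(r^2))` for LMS.
#'
#' @param fit An `rreg_fit`.
#' @param weight_cutoff Weight threshold in (0, 1) for weighted fits.
#' @param residual_cutoff Standardized-residual threshold for OLS/LMS fits.
#' @return Integer vector of flagged observation indices (possibly empty).
#' @examples
#' fit <- fit_irls(load_fixture("china"), psi_family("proposed", k = 2, a = 8))
#' flag_outliers(fit)
#' @export
flag_outliers <- function(fit, weight_cutoff = 0.01, residual_cutoff = 2.5) {
  if (!inherits(fit, "rreg_fit")) {
    rlang::abort("`fit` must be an rreg_fit.", class = "redescend_invalid_parameter")
  }
  if (!is.numeric(weight_cutoff) || weight_cutoff <= 0 || weight_cutoff >= 1) {
    rlang::abort("`weight_cutoff` must lie strictly between 0 and 1.",
                 class = "redescend_invalid_parameter")
  }
  if (!is.null(fit$weights)) {
    return(which(fit$weights < weight_cutoff))
  }
  r <- fit$residuals
  n <- length(r)
  s <- if (identical(fit$method, "lms")) {
    1.4826 * (1 + 5 / (n - 2)) * sqrt(stats::median(r^2))
  } else {
    stats::mad(r)
  }
  which(abs(r) > residual_cutoff * s)
}

#' Sum of squared errors over a retained subset
#'
#' Recomputes the fit's squared-error diagnostics over all observations and
#' over a retained subset (typically the complement of [flag_outliers()]),
#' mirroring the "values used" bookkeeping of robust-regression benchmark
#' tables.
#'
#' @param data Data frame with columns `x` and `y` the fit was computed on.
#' @param fit An `rreg_fit`.
#' @param retained Integer indices of retained observations.
#' @return One-row tibble with `sse_all`, `sse_retained` and `n_used`; the
#'   retained index set is attached as attribute `"retained"`.
#' @examples
#' d <- load_fixture("china")
#' f <- fit_ols(d)
#' subset_sse(d, f, retained = seq_len(nrow(d)))
#' @export
subset_sse <- function(data, fit, retained) {
  validate_regression_data(data)
  if (!inherits(fit, "rreg_fit")) {
    rlang::abort("`fit` must be an rreg_fit.", class = "redescend_invalid_parameter")
  }
  n <- nrow(data)
  retained <- as.integer(retained)
  if (length(retained) == 0L) {
    rlang::abort("`retained` must contain at least one index.",
                 class = "redescend_invalid_parameter")
  }
  if (anyNA(retained) || any(retained < 1L) || any(retained > n) ||
      anyDuplicated(retained)) {
    rlang::abort("`retained` must be distinct indices within the data.",
                 class = "redescend_invalid_parameter")
  }
  r <- data$y - fit$coefficients[1] - fit$coefficients[2] * data$x
  tibble::tibble(
    sse_all = sum(r^2),
    sse_retained = sum(r[retained]^2),
    n_used = length(retained)
  ) |>
    structure(retained = sort(retained))
}
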