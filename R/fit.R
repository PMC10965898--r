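validate_regression_data <- function(data, call = rlang::caller_env()) {
  if (!is.data.frame(data)) {
    rlang::abort("`data` must be a data frame with numeric columns `x` and `y`.",
                 class = "redescend_invalid_parameter", call = call)
  }
  if (!all(c("x", "y") %in% names(data))) {
    rlang::abort("`data` must contain columns `x` and `y`.",
                 class = "redescend_format_error", call = call)
  }
  x <- data$x; y <- data$y
  if (!is.numeric(x) || !is.numeric(y)) {
    rlang::abort("Columns `x` and `y` must be numeric.",
                 class = "redescend_format_error", call = call)
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(x)) || any(!is.finite(y))) {
    bad <- which(!is.finite(x) | !is.finite(y))[1]
    rlang::abort(paste0("Non-finite value in row ", bad, "."),
                 class = "redescend_format_error", call = call)
  }
  if (length(x) < 3L) {
    rlang::abort("At least 3 observations are required.",
                 class = "redescend_invalid_parameter", call = call)
  }
  if (diff(range(x)) == 0) {
    rlang::abort("Predictor `x` is constant: the design is degenerate.",
                 class = "redescend_degenerate_design", call = call)
  }
  invisible(data)
}

# closed-form weighted simple linear regression; w may be 1
wls_coef <- function(x, y, w = NULL) {
  if (is.null(w)) {
    xm <- mean(x); ym <- mean(y)
    sxx <- sum((x - xm)^2)
    slope <- sum((x - xm) * (y - ym)) / sxx
  } else {
    sw <- sum(w)
    xm <- sum(w * x) / sw; ym <- sum(w * y) / sw
    slope <- sum(w * (x - xm) * (y - ym)) / sum(w * (x - xm)^2)
  }
  c(intercept = ym - slope * xm, slope = slope)
}

new_rreg_fit <- function(data, coef, method, residuals, weights = NULL,
                         n_iterations = 0L, converged = TRUE, tuning = NULL,
                         extra = list()) {
  structure(
    c(list(
      coefficients = coef,
      residuals = residuals,
      weights = weights,
      n_iterations = n_iterations,
      converged = converged,
      method = method,
      tuning = tuning,
      data = tibble::tibble(x = data$x, y = data$y)
    ), extra),
    class = "rreg_fit"
  )
}

#' Ordinary least squares fit
#'
#' Closed-form simple linear regression, the non-robust baseline against which
#' the M-estimators are compared.
#'
#' @param data Data frame with numeric columns `x` and `y` (n >= 3,
#'   non-constant `x`).
#' @return An object of class `rreg_fit` with elements `coefficients`
#'   (intercept, slope), `residuals`, `method`, and metadata. Use [tidy()],
#'   [glance()] or [augment()] for tibble views.
#' @examples
#' fit_ols(load_fixture("telephone"))
#' @export
fit_ols <- function(data) {
  validate_regression_data(data)
  co <- wls_coef(data$x, data$y)
  r <- data$y - co[1] - co[2] * data$x
  new_rreg_fit(data, co, "ols", r)
}

#' Robust fit by iteratively reweighted least squares
#'
#' Solves the M-estimation problem: minimize the summed loss of the residuals,
#' by alternating residual evaluation, weight computation through the family's
#' weight function, and a weighted least-squares solve, until the coefficients
#' stop moving.
#'
#' With `scale = "mad"` (the default) residuals are standardized by the
#' median-absolute-deviation scale `mad(r)/0.6745` recomputed at every
#' iteration before weights are evaluated, so a family's tuning constant is
#' read in units of robust residual standard deviations. `scale = "mad_zero"`
#' uses the MAD about zero (the convention of `MASS::rlm`); `scale = "none"`
#' feeds raw residuals to the weight function.
#'
#' Redescending weight functions can have several IRLS fixed points; the
#' starting value matters. `start = "ols"` (default) starts from the
#' least-squares line, `"huber"` from a monotone Huber pre-fit (k = 1.345, MAD
#' scale), `"lms"` from the least-median-of-squares line.
#'
#' @param data Data frame with numeric columns `x` and `y`.
#' @param family A [psi_family()] object, or a family name string (default
#'   tuning constants are then used).
#' @param start Starting value strategy: `"ols"`, `"huber"` or `"lms"`; or
#'   supply `start_coef` directly.
#' @param scale Residual scale strategy: `"mad"` (default), `"mad_zero"` or
#'   `"none"`.
#' @param max_iter Maximum IRLS iterations.
#' @param tol Convergence tolerance on the maximum relative coefficient
#'   change.
#' @param start_coef Optional numeric `c(intercept, slope)` overriding
#'   `start`.
#' @return An `rreg_fit` with final `weights` normalized so that a zero
#'   residual receives weight 1, iteration count, and a `converged` flag.
#'   Non-convergence is reported with a warning, not an error.
#' @examples
#' fit_irls(load_fixture("china"), psi_family("proposed", k = 2, a = 8))
#' @export
fit_irls <- function(data, family, start = c("ols", "huber", "lms"),
                     scale = c("mad", "mad_zero", "none"), max_iter = 200L, tol = 1e-8,
                     start_coef = NULL) {
  validate_regression_data(data)
  if (is.character(family)) family <- psi_family(family)
  if (!inherits(family, "psi_family")) {
    rlang::abort("`family` must be a psi_family object or family name.",
                 class = "redescend_invalid_parameter")
  }
  if (isTRUE(family$as_printed)) {
    rlang::abort("The as-printed insha form has no valid weight function and cannot be fitted.",
                 class = "redescend_invalid_parameter")
  }
  scale <- match.arg(scale)
  if (!is.numeric(max_iter) || max_iter < 1) {
    rlang::abort("`max_iter` must be >= 1.", class = "redescend_invalid_parameter")
  }
  if (!is.numeric(tol) || tol <= 0) {
    rlang::abort("`tol` must be > 0.", class = "redescend_invalid_parameter")
  }

  x <- data$x; y <- data$y
  if (is.null(start_coef)) {
    start <- match.arg(start)
    co <- switch(start,
      ols = wls_coef(x, y),
      huber = irls_core(x, y, psi_family("huber"), wls_coef(x, y),
                        scale = "mad", max_iter = 100L, tol = 1e-8)$coef,
      lms = fit_lms(data)$coefficients
    )
  } else {
    co <- c(intercept = start_coef[[1]], slope = start_coef[[2]])
    start <- "supplied"
  }

  res <- irls_core(x, y, family, co, scale, max_iter, tol)
  if (!res$converged) {
    rlang::warn(paste0("IRLS did not converge in ", max_iter, " iterations."),
                class = "redescend_nonconvergence")
  }
  new_rreg_fit(
    data, res$coef, paste0("irls_", family$name), res$residuals,
    weights = res$weights / family$w0,
    n_iterations = res$iterations, converged = res$converged,
    tuning = family$tuning,
    extra = list(family = family, scale = scale, start = start)
  )
}

irls_core <- function(x, y, family, coef, scale, max_iter, tol) {
  wfun <- family$weight
  converged <- FALSE
  it <- 0L
  w <- rep(1, length(x))
  for (it in seq_len(max_iter)) {
    r <- y - coef[1] - coef[2] * x
    rs <- if (scale != "none") {
      s <- if (scale == "mad") stats::mad(r) else stats::mad(r, center = 0)
      if (s <= 0) s <- mean(abs(r))          # >half the points on the line
      if (s <= 0) { converged <- TRUE; break }  # exact interpolation
      r / s
    } else r
    w <- wfun(rs)
    if (all(w < 1e-300)) {
      rlang::abort(
        "All observations received (numerically) zero weight; increase the tuning constant k.",
        class = "redescend_degenerate_weights"
      )
    }
    new_coef <- wls_coef(x, y, w)
    delta <- max(abs(new_coef - coef) / pmax(abs(coef), 1e-8))
    coef <- new_coef
    if (delta < tol) { converged <- TRUE; break }
  }
  list(coef = coef, residuals = y - coef[1] - coef[2] * x, weights = w,
       iterations = it, converged = converged)
}

#' Least median of squares fit
#'
#' Minimizes the median of the squared residuals over candidate lines through
#' pairs of observations (elemental lines). When the number of pairs is at
#' most `n_subsets` all pairs are enumerated (the exact elemental LMS);
#' otherwise a seeded random subsample of pairs is searched, making the result
#' deterministic given `seed`. Ties on the objective keep the first candidate
#' in sorted index-pair order.
#'
#' @param data Data frame with numeric columns `x` and `y` (n >= 4).
#' @param n_subsets Maximum number of candidate pairs to evaluate.
#' @param seed Integer seed for the subsample, used only when subsampling.
#' @return An `rreg_fit` (no weights) whose `objective` element holds the
#'   minimized median squared residual.
#' @examples
#' fit_lms(load_fixture("telephone"))
#' @export
fit_lms <- function(data, n_subsets = 3000L, seed = 1L) {
  validate_regression_data(data)
  n <- nrow(data)
  if (n < 4L) {
    rlang::abort("LMS requires at least 4 observations.",
                 class = "redescend_invalid_parameter")
  }
  x <- data$x; y <- data$y
  all_pairs <- utils::combn(n, 2L)
  n_pairs <- ncol(all_pairs)
  pairs <- if (n_pairs <= n_subsets) {
    all_pairs
  } else {
    keep <- with_preserved_seed(seed, sort(sample.int(n_pairs, n_subsets)))
    all_pairs[, keep, drop = FALSE]
  }
  best <- Inf; best_co <- NULL
  for (jj in seq_len(ncol(pairs))) {
    i <- pairs[1L, jj]; j <- pairs[2L, jj]
    if (x[i] == x[j]) next
    b <- (y[j] - y[i]) / (x[j] - x[i])
    a <- y[i] - b * x[i]
    obj <- stats::median((y - a - b * x)^2)
    if (obj < best) { best <- obj; best_co <- c(intercept = a, slope = b) }
  }
  r <- y - best_co[1] - best_co[2] * x
  new_rreg_fit(data, best_co, "lms", r,
               extra = list(objective = best, n_candidates = ncol(pairs),
                            seed = seed))
}

# run code with a temporary RNG state; the caller's stream is untouched
with_preserved_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' @export
print.rreg_fit <- function(x, ...) {
  cat("<rreg_fit> method:", x$method, "\n")
  if (!is.null(x$tuning)) {
    cat("  tuning:", paste(names(x$tuning), unlist(x$tuning), sep = " = ",
                           collapse = ", "), "\n")
  }
  cat(sprintf("  intercept %.5f  slope %.5f  (n = %d)\n",
              x$coefficients[1], x$coefficients[2], nrow(x$data)))
  if (x$n_iterations > 0) {
    cat("  iterations:", x$n_iterations,
        if (!x$converged) "(NOT converged)", "\n")
  }
  invisible(x)
}

#' Tidy a robust regression fit
#'
#' @param x An `rreg_fit`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient (`term`, `estimate`).
#'   `glance()`: one-row fit summary (`method`, `sse`, `n`, `n_iterations`,
#'   `converged`). `augment()`: per-observation tibble with `.fitted`,
#'   `.resid` and `.weight`.
#' @method tidy rreg_fit
#' @export
tidy.rreg_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", "x"),
                 estimate = unname(x$coefficients))
}

#' @rdname tidy.rreg_fit
#' @method glance rreg_fit
#' @export
glance.rreg_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    sse = sum(x$residuals^2),
    n = nrow(x$data),
    n_iterations = x$n_iterations,
    converged = x$converged
  )
}

#' @rdname tidy.rreg_fit
#' @method augment rreg_fit
#' @export
augment.rreg_fit <- function(x, ...) {
  fit <- x
  tibble::tibble(
    x = fit$data$x, y = fit$data$y,
    .fitted = fit$data$y - fit$residuals,
    .resid = fit$residuals,
    .weight = fit$weights %||% rep(NA_real_, nrow(fit$data))
  )
}

#' Plot a robust regression fit
#'
#' Scatterplot of the data with the fitted line; for weighted fits the point
#' colour encodes the final IRLS weight, so rejected outliers are visible at a
#' glance.
#'
#' @param object An `rreg_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rreg_fit
#' @export
autoplot.rreg_fit <- function(object, ...) {
  df <- augment(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y))
  p <- if (all(is.na(df$.weight))) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$.weight)) +
      ggplot2::scale_colour_gradient(low = "#b2182b", high = "#2166ac",
                                     limits = c(0, 1), name = "weight")
  }
  p +
    ggplot2::geom_abline(intercept = object$coefficients[1],
                         slope = object$coefficients[2]) +
    ggplot2::labs(title = paste("Fit:", object$method))
}
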