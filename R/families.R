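#' The generalized redescending loss function
#'
#' Objective (rho) function of the generalized redescending M-estimator:
#' \deqn{\rho(r) = \frac{k^2}{2a}\left[1 - \left\{1 + (r/k)^2\right\}^{-a}\right]}
#' The loss is bounded above by \eqn{k^2/(2a)}, even, increasing in \eqn{|r|},
#' and everywhere differentiable, so its derivative [proposed_psi()] redescends
#' smoothly to zero instead of cutting observations off at a hard boundary.
#'
#' @param r Numeric vector of residuals.
#' @param k Positive tuning constant, in residual units. Trades robustness
#'   against Gaussian efficiency.
#' @param a Positive generalized tuning exponent. Larger `a` makes the weight
#'   of a large residual decay faster; `a = 6` and `a = 8` are the values used
#'   in the worked examples.
#' @return Numeric vector of non-negative loss values, one per residual.
#' @seealso [proposed_psi()], [proposed_weight()], [psi_family()]
#' @examples
#' proposed_rho(c(-2, 0, 2), k = 2, a = 8)
#' @export
proposed_rho <- function(r, k, a) {
  check_tuning_positive(k = k, a = a)
  (k^2 / (2 * a)) * (1 - (1 + (r / k)^2)^(-a))
}

#' The generalized redescending psi (influence) function
#'
#' Derivative of [proposed_rho()] with respect to the residual:
#' \deqn{\psi(r) = r\left[1 + (r/k)^2\right]^{-a-1}}
#' Odd, bounded, and tending to zero as \eqn{|r| \to \infty}; its maximum over
#' \eqn{r > 0} is attained at \eqn{r = k/\sqrt{2a + 1}}.
#'
#' @inheritParams proposed_rho
#' @return Numeric vector of influence values.
#' @examples
#' proposed_psi(3.5, k = 3.5, a = 6)  # 3.5 * 2^-7
#' @export
proposed_psi <- function(r, k, a) {
  check_tuning_positive(k = k, a = a)
  r * (1 + (r / k)^2)^(-a - 1)
}

#' The generalized redescending weight function
#'
#' Weight function \eqn{w(r) = \psi(r)/r} of the generalized redescending
#' family:
#' \deqn{w(r) = \left[1 + (r/k)^2\right]^{-a-1}}
#' Values lie in (0, 1]: every observation keeps strictly positive weight, but
#' the weight of a gross outlier is vanishingly small. At fixed \eqn{|r| > 0}
#' the weight is strictly decreasing in `a`, which is what makes the family
#' tunable beyond the single constant `k`.
#'
#' @inheritParams proposed_rho
#' @return Numeric vector of weights in (0, 1].
#' @examples
#' proposed_weight(c(0, 2), k = 2, a = 6)
#' @export
proposed_weight <- function(r, k, a) {
  check_tuning_positive(k = k, a = a)
  (1 + (r / k)^2)^(-a - 1)
}

check_tuning_positive <- function(...) {
  vals <- list(...)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (is.null(v)) next
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      rlang::abort(
        paste0("Tuning constant `", nm, "` must be a single positive number."),
        class = "redescend_invalid_parameter"
      )
    }
  }
  invisible(TRUE)
}

# Default tuning constants, as recommended by each family's proposing authors.
# Hampel takes three constants (k, l, m); the stored default is the classical
# 1:2:4 shape.
.family_defaults <- list(
  huber    = list(k = 1.345),
  hampel   = list(k = 2, l = 4, m = 8),
  andrew   = list(k = 3.2),
  tukey    = list(k = 4.865),
  qadir    = list(k = 4.0),
  ali      = list(k = 4.0),
  insha    = list(k = 4.0),
  alamgir  = list(k = 3.0),
  khalil   = list(k = 4.0),
  proposed = list(k = 2, a = 6)
)

#' List the registered psi-families
#'
#' @return Character vector of family names accepted by [psi_family()].
#' @export
family_names <- function() names(.family_defaults)

#' Construct a psi-family
#'
#' Builds an evaluatable M-estimation family: the influence function `psi`,
#' the IRLS weight function `weight = psi/r` (with its analytic limit at
#' `r = 0`), the analytic derivative `dpsi` used in efficiency integrals, and
#' for the generalized redescending family also the loss `rho`.
#'
#' Families: `huber` (monotone), `hampel` (three-part), `andrew` (sine),
#' `tukey` (biweight), `qadir` (beta), `ali`, `insha`, `alamgir`, `khalil`,
#' and `proposed` — the generalized smooth redescender of this package.
#'
#' Hampel: either supply all of `k`, `l`, `m` with `0 < k <= l < m`, or a
#' single `k`, read as the family's published single constant `c` and expanded
#' to `(c/2, c, 2c)`, preserving the classical 1:2:4 proportions.
#'
#' Insha: the form in circulation, `psi(r) = [1 + (r/k)^4]^-2`, is even rather
#' than odd and has `psi(0) = 1`, so it cannot be the influence function of
#' any symmetric loss. The default here multiplies by `r`, restoring oddness
#' and redescent; `as_printed = TRUE` gives the uncorrected form (its weight
#' is undefined at `r = 0` and it is excluded from fitting).
#'
#' @param name Family name (see [family_names()]). Case-insensitive.
#' @param k Primary tuning constant; default is the family's published value.
#' @param a Generalized tuning exponent (`proposed` family only).
#' @param l,m Second and third Hampel constants.
#' @param as_printed Logical; `insha` only (see Details).
#' @return An object of class `psi_family`: a list with elements `name`,
#'   `tuning`, `psi`, `weight`, `rho` (or `NULL`), `dpsi`, `is_redescending`,
#'   `has_rho`, `breakpoints` and `w0` (the weight at zero residual).
#' @examples
#' fam <- psi_family("proposed", k = 2, a = 8)
#' fam$psi(c(-1, 0, 1))
#' psi_family("tukey")$weight(0)
#' @export
psi_family <- function(name, k = NULL, a = NULL, l = NULL, m = NULL,
                       as_printed = FALSE) {
  if (!is.character(name) || length(name) != 1L) {
    rlang::abort("`name` must be a single family name string.",
                 class = "redescend_invalid_parameter")
  }
  name <- tolower(name)
  if (!name %in% names(.family_defaults)) {
    rlang::abort(
      paste0("Unknown psi-family '", name, "'. Registered families: ",
             paste(family_names(), collapse = ", "), "."),
      class = "redescend_not_found"
    )
  }
  defaults <- .family_defaults[[name]]

  if (name == "hampel") {
    if (!is.null(k) && is.null(l) && is.null(m)) {
      # single published constant c -> (c/2, c, 2c)
      check_tuning_positive(k = k)
      l <- k; m <- 2 * k; k <- k / 2
    }
    k <- k %||% defaults$k; l <- l %||% defaults$l; m <- m %||% defaults$m
    check_tuning_positive(k = k, l = l, m = m)
    if (!(k <= l && l < m)) {
      rlang::abort("Hampel constants must satisfy 0 < k <= l < m.",
                   class = "redescend_invalid_parameter")
    }
  } else {
    k <- k %||% defaults$k
    check_tuning_positive(k = k)
    if (name == "proposed") {
      a <- a %||% defaults$a
      check_tuning_positive(a = a)
    } else if (!is.null(a)) {
      rlang::abort("`a` applies only to the 'proposed' family.",
                   class = "redescend_invalid_parameter")
    }
  }
  if (as_printed && name != "insha") {
    rlang::abort("`as_printed` applies only to the 'insha' family.",
                 class = "redescend_invalid_parameter")
  }

  fam <- switch(name,
    huber = list(
      psi  = function(r) ifelse(abs(r) < k, r, k * sign(r)),
      weight = function(r) ifelse(r == 0, 1, pmin(1, k / abs(r))),
      dpsi = function(r) as.numeric(abs(r) < k),
      is_redescending = FALSE, breakpoints = k, w0 = 1
    ),
    hampel = list(
      psi = function(r) {
        ar <- abs(r)
        ifelse(ar <= k, r,
        ifelse(ar <= l, k * sign(r),
        ifelse(ar <= m, k * (m - ar) / (m - l) * sign(r), 0)))
      },
      weight = NULL,  # filled below as psi(r)/r
      dpsi = function(r) {
        ar <- abs(r)
        ifelse(ar <= k, 1, ifelse(ar <= l, 0, ifelse(ar <= m, -k / (m - l), 0)))
      },
      is_redescending = TRUE, breakpoints = c(k, l, m), w0 = 1
    ),
    andrew = list(
      psi  = function(r) ifelse(abs(r) < k * pi, k * sin(r / k), 0),
      weight = function(r) {
        u <- r / k
        ifelse(r == 0, 1, ifelse(abs(r) < k * pi, sin(u) / u, 0))
      },
      dpsi = function(r) ifelse(abs(r) < k * pi, cos(r / k), 0),
      is_redescending = TRUE, breakpoints = k * pi, w0 = 1
    ),
    tukey = list(
      psi  = function(r) { u <- (r / k)^2; ifelse(abs(r) <= k, r * (1 - u)^2, 0) },
      weight = function(r) { u <- (r / k)^2; ifelse(abs(r) <= k, (1 - u)^2, 0) },
      dpsi = function(r) { u <- (r / k)^2
        ifelse(abs(r) <= k, (1 - u) * (1 - 5 * u), 0) },
      is_redescending = TRUE, breakpoints = k, w0 = 1
    ),
    qadir = list(
      psi  = function(r) ifelse(abs(r) <= k,
                                r * (k + r)^2 * (k - r)^2 / (16 * k^4), 0),
      weight = function(r) ifelse(abs(r) <= k, (k^2 - r^2)^2 / (16 * k^4), 0),
      dpsi = function(r) ifelse(abs(r) <= k,
                                (k^2 - r^2) * (k^2 - 5 * r^2) / (16 * k^4), 0),
      is_redescending = TRUE, breakpoints = k, w0 = 1 / 16
    ),
    ali = list(
      psi  = function(r) { v <- (r / k)^4
        ifelse(abs(r) <= k, (2 * r / 3) * (1 - v)^2, 0) },
      weight = function(r) { v <- (r / k)^4
        ifelse(abs(r) <= k, (2 / 3) * (1 - v)^2, 0) },
      dpsi = function(r) { v <- (r / k)^4
        ifelse(abs(r) <= k, (2 / 3) * (1 - v) * (1 - 9 * v), 0) },
      is_redescending = TRUE, breakpoints = k, w0 = 2 / 3
    ),
    insha = if (as_printed) list(
      # uncorrected even form; kept for reference, unusable for fitting
      psi  = function(r) (1 + (r / k)^4)^(-2),
      weight = function(r) ifelse(r == 0, NaN, (1 + (r / k)^4)^(-2) / r),
      dpsi = function(r) { v <- (r / k)^4
        -8 * (v / r) * (1 + v)^(-3) * ifelse(r == 0, 0, 1) },
      is_redescending = TRUE, breakpoints = numeric(), w0 = NaN
    ) else list(
      psi  = function(r) r * (1 + (r / k)^4)^(-2),
      weight = function(r) (1 + (r / k)^4)^(-2),
      dpsi = function(r) { v <- (r / k)^4; (1 + v)^(-3) * (1 - 7 * v) },
      is_redescending = TRUE, breakpoints = numeric(), w0 = 1
    ),
    alamgir = list(
      # the closed form is discontinuous at |r| = k: the bounded branch does
      # not vanish there; kept as published
      psi  = function(r) { u <- (r / k)^2; s <- exp(-u)
        ifelse(abs(r) <= k, 16 * r * s^2 / (1 + s)^2, 0) },
      weight = function(r) { u <- (r / k)^2; s <- exp(-u)
        ifelse(abs(r) <= k, 16 * s^2 / (1 + s)^2, 0) },
      dpsi = function(r) { u <- (r / k)^2; s <- exp(-u)
        ifelse(abs(r) <= k, 16 * s^2 * (1 + s)^(-3) * ((1 + s) - 4 * u), 0) },
      is_redescending = TRUE, breakpoints = k, w0 = 4
    ),
    khalil = list(
      psi  = function(r) { g <- (1 - (r / k)^4)^2
        ifelse(abs(r) <= k, 1.5 * r * g * sin((2 / 3) * g), 0) },
      weight = function(r) { g <- (1 - (r / k)^4)^2
        ifelse(abs(r) <= k, 1.5 * g * sin((2 / 3) * g), 0) },
      dpsi = function(r) { v <- (r / k)^4; g <- (1 - v)^2; cg <- (2 / 3) * g
        ifelse(abs(r) <= k,
               1.5 * (g * sin(cg) - 8 * v * (1 - v) * (sin(cg) + cg * cos(cg))),
               0) },
      is_redescending = TRUE, breakpoints = k, w0 = 1.5 * sin(2 / 3)
    ),
    proposed = list(
      psi  = function(r) proposed_psi(r, k, a),
      weight = function(r) proposed_weight(r, k, a),
      rho  = function(r) proposed_rho(r, k, a),
      dpsi = function(r) { u <- (r / k)^2
        (1 + u)^(-a - 2) * (1 - (2 * a + 1) * u) },
      is_redescending = TRUE, breakpoints = numeric(), w0 = 1
    )
  )

  if (is.null(fam$weight)) {
    psi <- fam$psi
    fam$weight <- function(r) ifelse(r == 0, 1, psi(r) / r)
  }
  structure(
    list(
      name = name,
      tuning = c(list(k = k),
                 if (name == "proposed") list(a = a),
                 if (name == "hampel") list(l = l, m = m)),
      psi = fam$psi,
      weight = fam$weight,
      rho = fam$rho,
      dpsi = fam$dpsi,
      has_rho = !is.null(fam$rho),
      is_redescending = fam$is_redescending,
      breakpoints = fam$breakpoints,
      w0 = fam$w0,
      as_printed = as_printed
    ),
    class = "psi_family"
  )
}

#' Evaluate a family's psi function by name
#'
#' Convenience wrappers around [psi_family()] for one-off evaluation.
#'
#' @inheritParams psi_family
#' @param r Numeric vector of residuals.
#' @param ... Tuning constants passed to [psi_family()].
#' @return Numeric vector, elementwise over `r`.
#' @examples
#' family_psi("huber", 2, k = 1.345)
#' family_weight("tukey", 0)
#' @export
family_psi <- function(name, r, ...) psi_family(name, ...)$psi(r)

#' @rdname family_psi
#' @export
family_weight <- function(name, r, ...) psi_family(name, ...)$weight(r)

#' @export
print.psi_family <- function(x, ...) {
  tun <- paste(names(x$tuning), unlist(x$tuning), sep = " = ", collapse = ", ")
  cat("<psi_family> ", x$name, " (", tun, ")\n", sep = "")
  cat("  redescending: ", x$is_redescending,
      if (x$has_rho) "; closed-form rho available", "\n", sep = "")
  invisible(x)
}

#' Curves of a psi-family
#'
#' Plots the influence (psi) and weight curves of a family, and the loss (rho)
#' where it has a closed form, over a symmetric residual range.
#'
#' @param object A [psi_family()].
#' @param r_max Half-width of the residual range (default three rejection
#'   scales).
#' @param n Number of grid points.
#' @param ... Unused.
#' @return A ggplot object, faceted by curve type.
#' @method autoplot psi_family
#' @export
autoplot.psi_family <- function(object, r_max = NULL, n = 501, ...) {
  k_eff <- max(object$tuning$k, object$breakpoints, 1)
  r_max <- r_max %||% (3 * k_eff)
  r <- seq(-r_max, r_max, length.out = n)
  df <- dplyr::bind_rows(
    tibble::tibble(curve = "psi", r = r, value = object$psi(r)),
    tibble::tibble(curve = "weight", r = r, value = object$weight(r)),
    if (object$has_rho)
      tibble::tibble(curve = "rho", r = r, value = object$rho(r))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = r, y = .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~curve, scales = "free_y") +
    ggplot2::labs(
      title = paste0(object$name, " family"),
      x = "residual", y = NULL
    )
}
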