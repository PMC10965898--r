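#' Configuration for the contamination Monte Carlo study
#'
#' Describes the simulated population and sampling design of the estimator
#' comparison: a simple linear model `y = alpha + beta*x + e` with
#' `x ~ N(x_mean, x_sd^2)` and `e ~ N(0, error_sd^2)`, a fixed population of
#' `population_size` units from which each replicate draws a simple random
#' sample of `sample_size` without replacement, and optional y-direction
#' contamination that adds `contamination_shift` to a randomly chosen fraction
#' of the sampled responses.
#'
#' @param alpha,beta True intercept and slope (defaults 2 and 1).
#' @param x_mean,x_sd Predictor distribution parameters (defaults 20 and 10;
#'   `x_sd` is a standard deviation — set `x_sd = sqrt(10)` for the
#'   variance-10 reading of N(20, 10)).
#' @param error_sd Error standard deviation (default 1).
#' @param population_size Size of the generated population (default 10000).
#' @param sample_size Sample size per replicate (default 100).
#' @param n_reps Number of Monte Carlo replicates (default 1000).
#' @param contamination_fraction Fraction of sampled responses shifted in the
#'   contaminated case (default 0.10).
#' @param contamination_shift Size of the y-direction shift (default 50, so
#'   that mean-shift contamination inflates the expected OLS intercept by
#'   `fraction * shift = 5`).
#' @param seed Master integer seed; all population, sampling and
#'   contamination randomness derives from it.
#' @param fresh_population If `TRUE`, a new population is generated for every
#'   replicate instead of sampling one fixed population.
#' @return A `sim_config` list.
#' @export
sim_config <- function(alpha = 2, beta = 1, x_mean = 20, x_sd = 10,
                       error_sd = 1, population_size = 10000L,
                       sample_size = 100L, n_reps = 1000L,
                       contamination_fraction = 0.10,
                       contamination_shift = 50, seed = 1L,
                       fresh_population = FALSE) {
  if (sample_size > population_size) {
    rlang::abort("`sample_size` must not exceed `population_size`.",
                 class = "redescend_invalid_parameter")
  }
  if (n_reps < 1L) {
    rlang::abort("`n_reps` must be >= 1.", class = "redescend_invalid_parameter")
  }
  if (contamination_fraction < 0 || contamination_fraction >= 1) {
    rlang::abort("`contamination_fraction` must lie in [0, 1).",
                 class = "redescend_invalid_parameter")
  }
  if (x_sd <= 0 || error_sd < 0) {
    rlang::abort("`x_sd` must be positive and `error_sd` non-negative.",
                 class = "redescend_invalid_parameter")
  }
  structure(
    list(alpha = alpha, beta = beta, x_mean = x_mean, x_sd = x_sd,
         error_sd = error_sd, population_size = as.integer(population_size),
         sample_size = as.integer(sample_size), n_reps = as.integer(n_reps),
         contamination_fraction = contamination_fraction,
         contamination_shift = contamination_shift, seed = as.integer(seed),
         fresh_population = isTRUE(fresh_population)),
    class = "sim_config"
  )
}

#' Generate the simulated population
#'
#' Draws the full population of the linear model described by a
#' [sim_config()]. Deterministic given `config$seed`; the caller's RNG stream
#' is left untouched.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return Tibble with `population_size` rows and columns `x`, `y`.
#' @export
generate_population <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  with_preserved_seed(seed, {
    x <- stats::rnorm(config$population_size, config$x_mean, config$x_sd)
    e <- if (config$error_sd > 0) {
      stats::rnorm(config$population_size, 0, config$error_sd)
    } else {
      numeric(config$population_size)
    }
    tibble::tibble(x = x, y = config$alpha + config$beta * x + e)
  })
}

#' Contaminate responses with y-direction outliers
#'
#' Adds `shift` to the responses of `round(fraction * n)` uniformly chosen
#' observations; predictors are never touched (x-direction outliers are a
#' known failure mode of M-estimators and are out of scope here).
#'
#' @param data Data frame with columns `x` and `y`.
#' @param fraction Fraction of observations to shift, in [0, 1). `0` returns
#'   the data unchanged.
#' @param shift Amount added to each contaminated response.
#' @param seed Optional seed; if `NULL` the current RNG stream is used.
#' @return Tibble like `data`, with attribute `"contaminated"` holding the
#'   shifted row indices.
#' @examples
#' contaminate(load_fixture("china"), fraction = 0.2, shift = 100, seed = 1)
#' @export
contaminate <- function(data, fraction, shift = 50, seed = NULL) {
  validate_regression_data(data)
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    rlang::abort("`fraction` must lie in [0, 1).",
                 class = "redescend_invalid_parameter")
  }
  out <- tibble::as_tibble(data)
  if (fraction == 0) return(structure(out, contaminated = integer()))
  n <- nrow(out)
  m <- round(fraction * n)
  if (m < 1L) {
    rlang::abort("`fraction * n` must be at least 1 when fraction > 0.",
                 class = "redescend_invalid_parameter")
  }
  idx <- if (is.null(seed)) sample.int(n, m)
         else with_preserved_seed(seed, sample.int(n, m))
  out$y[idx] <- out$y[idx] + shift
  structure(out, contaminated = sort(idx))
}

#' Default estimator set for the contamination study
#'
#' The nine-estimator line-up of the benchmark comparison: OLS plus eight
#' M-estimators at the constants used there — Hampel (single constant 4,
#' i.e. (2, 4, 8)), Tukey 4.69, Andrews 3.2, Huber 4, Insha 4, Ali 4,
#' Khalil 5, and the generalized redescender at `k = 2` (with `a = 6`, the
#' smaller of the two exponents studied, since the comparison fixes only `k`).
#'
#' @return Named list mapping estimator label to `"ols"` or a [psi_family()].
#' @export
table4_estimators <- function() {
  list(
    ols      = "ols",
    hampel   = psi_family("hampel", k = 4),
    tukey    = psi_family("tukey", k = 4.69),
    andrew   = psi_family("andrew", k = 3.2),
    huber    = psi_family("huber", k = 4),
    insha    = psi_family("insha", k = 4),
    ali      = psi_family("ali", k = 4),
    khalil   = psi_family("khalil", k = 5),
    proposed = psi_family("proposed", k = 2, a = 6)
  )
}

#' Run the contamination Monte Carlo study
#'
#' For each replicate, draws a simple random sample from the fixed simulated
#' population, fits every estimator to the clean sample and (optionally) to a
#' contaminated copy, and averages the coefficient estimates per estimator
#' and case. Per-replicate seeds are derived from the master seed before any
#' fitting, so the estimator line-up never perturbs the data stream. A
#' replicate on which a fit fails is excluded for that estimator and counted,
#' never silently dropped.
#'
#' @param config A [sim_config()].
#' @param estimators Named list of `"ols"` or [psi_family()] objects; default
#'   [table4_estimators()].
#' @param cases Which cases to run: `"clean"` (no contamination),
#'   `"contaminated"`, or both (default).
#' @param keep_reps If `TRUE`, per-replicate estimates are attached as
#'   attribute `"reps"` (needed for Monte Carlo standard errors).
#' @param scale,start IRLS settings passed to [fit_irls()].
#' @return A `sim_result`: tibble with columns `estimator`, `case`,
#'   `mean_intercept`, `mean_slope`, `n_reps`, `n_excluded`; attributes
#'   `config` and (optionally) `reps`.
#' @examples
#' cfg <- sim_config(n_reps = 20, seed = 7)
#' run_study(cfg, estimators = table4_estimators()[c("ols", "proposed")])
#' @export
run_study <- function(config, estimators = table4_estimators(),
                      cases = c("clean", "contaminated"), keep_reps = FALSE,
                      scale = "mad", start = "ols") {
  stopifnot(inherits(config, "sim_config"))
  cases <- match.arg(cases, several.ok = TRUE)
  if (is.null(names(estimators)) || any(names(estimators) == "")) {
    rlang::abort("`estimators` must be a fully named list.",
                 class = "redescend_invalid_parameter")
  }
  pop <- if (config$fresh_population) NULL else generate_population(config)
  rep_seeds <- with_preserved_seed(config$seed,
    sample.int(.Machine$integer.max - 1L, config$n_reps + 1L))

  rows <- vector("list", config$n_reps)
  for (rep in seq_len(config$n_reps)) {
    rows[[rep]] <- with_preserved_seed(rep_seeds[rep], {
      this_pop <- pop %||% generate_population(config, seed = rep_seeds[rep] + 1L)
      idx <- sample.int(config$population_size, config$sample_size)
      samp <- this_pop[idx, ]
      dsets <- list()
      if ("clean" %in% cases) dsets$clean <- samp
      if ("contaminated" %in% cases) {
        dsets$contaminated <- contaminate(samp, config$contamination_fraction,
                                          config$contamination_shift)
      }
      purrr::imap_dfr(dsets, function(d, case_name) {
        purrr::imap_dfr(estimators, function(est, est_name) {
          co <- tryCatch({
            f <- if (identical(est, "ols")) fit_ols(d)
                 else suppressWarnings(
                   fit_irls(d, est, scale = scale, start = start))
            f$coefficients
          }, error = function(e) c(NA_real_, NA_real_))
          tibble::tibble(rep = rep, estimator = est_name, case = case_name,
                         intercept = co[[1]], slope = co[[2]])
        })
      })
    })
  }
  reps <- dplyr::bind_rows(rows)
  summary <- reps |>
    dplyr::group_by(.data$estimator, .data$case) |>
    dplyr::summarise(
      mean_intercept = mean(.data$intercept, na.rm = TRUE),
      mean_slope = mean(.data$slope, na.rm = TRUE),
      n_reps = sum(!is.na(.data$intercept)),
      n_excluded = sum(is.na(.data$intercept)),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$estimator, names(estimators)), .data$case)
  if (any(summary$n_excluded > 0)) {
    rlang::warn(paste0(sum(summary$n_excluded),
                       " replicate fits failed and were excluded."))
  }
  structure(summary, class = c("sim_result", class(summary)),
            config = config,
            reps = if (keep_reps) reps)
}

#' @export
print.sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<sim_result> ", cfg$n_reps, " replicates, n = ", cfg$sample_size,
      ", contamination ", 100 * cfg$contamination_fraction, "% (+",
      cfg$contamination_shift, "), seed ", cfg$seed, "\n", sep = "")
  NextMethod()
}

#' Tidy the Monte Carlo study result
#'
#' @param x A `sim_result`.
#' @param ... Unused.
#' @return `tidy()` returns the summary tibble (one row per estimator and
#'   case); `glance()` a one-row design summary.
#' @method tidy sim_result
#' @export
tidy.sim_result <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy.sim_result
#' @method glance sim_result
#' @export
glance.sim_result <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(
    n_reps = cfg$n_reps, sample_size = cfg$sample_size,
    contamination_fraction = cfg$contamination_fraction,
    contamination_shift = cfg$contamination_shift,
    seed = cfg$seed, n_excluded = sum(x$n_excluded)
  )
}

#' Plot the Monte Carlo study result
#'
#' Dot plot of mean coefficient estimates per estimator and case, with the
#' true parameter values as reference lines; estimators resistant to the
#' contamination sit on the lines in both panels.
#'
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sim_result
#' @export
autoplot.sim_result <- function(object, ...) {
  cfg <- attr(object, "config")
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_intercept", "mean_slope"),
                        names_to = "coefficient", values_to = "estimate") |>
    dplyr::mutate(coefficient = sub("mean_", "", .data$coefficient))
  truth <- tibble::tibble(coefficient = c("intercept", "slope"),
                          value = c(cfg$alpha, cfg$beta))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$estimator,
                                   colour = .data$case)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(data = truth,
                        ggplot2::aes(xintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~coefficient, scales = "free_x") +
    ggplot2::labs(x = "mean estimate", y = NULL)
}
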