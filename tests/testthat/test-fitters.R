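test_that("OLS is the exact closed-form least-squares solution", {
  d <- tibble::tibble(x = 1:10, y = 3 + 2 * (1:10))
  f <- fit_ols(d)
  expect_equal(unname(f$coefficients), c(3, 2))
  expect_equal(f$residuals, rep(0, 10))

  set.seed(11)
  d2 <- tibble::tibble(x = stats::rnorm(40), y = stats::rnorm(40))
  f2 <- fit_ols(d2)
  oracle <- unname(stats::coef(stats::lm(y ~ x, data = d2)))
  expect_equal(unname(f2$coefficients), oracle, tolerance = 1e-12)
  expect_lt(abs(sum(f2$residuals)), 1e-10)
})

test_that("degenerate regression inputs are rejected", {
  expect_error(fit_ols(tibble::tibble(x = rep(1, 5), y = 1:5)),
               class = "redescend_degenerate_design")
  expect_error(fit_ols(tibble::tibble(x = 1:2, y = 1:2)),
               class = "redescend_invalid_parameter")
  expect_error(fit_ols(tibble::tibble(a = 1:5, b = 1:5)),
               class = "redescend_format_error")
  expect_error(fit_ols(tibble::tibble(x = c(1, 2, NA, 4), y = 1:4)),
               class = "redescend_format_error")
})

test_that("IRLS in the unit-weight regime reproduces OLS", {
  set.seed(3)
  d <- tibble::tibble(x = 1:20, y = 2 + (1:20) + stats::rnorm(20, sd = 0.01))
  ols <- fit_ols(d)
  # k far above the residual scale puts every weight at 1
  f <- fit_irls(d, psi_family("huber", k = 1e9), scale = "none")
  expect_equal(unname(f$coefficients), unname(ols$coefficients),
               tolerance = 1e-6)
  expect_true(all(f$weights == 1))
  # and an outlier-free proposed fit agrees with OLS to first order
  g <- fit_irls(d, psi_family("proposed", k = 1e6, a = 6), scale = "none")
  expect_equal(unname(g$coefficients), unname(ols$coefficients),
               tolerance = 1e-6)
})

test_that("converged IRLS fits satisfy the weighted estimating equations", {
  cases <- list(
    list(data = china_xy(), fam = psi_family("proposed", k = 2, a = 8)),
    list(data = telephone_xy(), fam = psi_family("proposed", k = 3.5, a = 6)),
    list(data = telephone_xy(), fam = psi_family("tukey", k = 3.8)),
    list(data = china_xy(), fam = psi_family("huber", k = 1.345))
  )
  for (cs in cases) {
    for (scale in c("mad", "none")) {
      f <- suppressWarnings(fit_irls(cs$data, cs$fam, scale = scale, tol = 1e-10))
      if (!f$converged) next
      w <- f$weights
      r <- f$residuals
      norm <- sum(w) * stats::mad(cs$data$y)
      expect_lt(abs(sum(w * r)) / norm, 1e-6,
                label = paste(cs$fam$name, scale, "sum(w r)"))
      expect_lt(abs(sum(w * r * cs$data$x)) / (norm * max(abs(cs$data$x))), 1e-6,
                label = paste(cs$fam$name, scale, "sum(w r x)"))
    }
  }
})

test_that("IRLS reports rather than hides non-convergence", {
  expect_warning(
    f <- fit_irls(telephone_xy(), psi_family("proposed", k = 3.5, a = 6),
                  max_iter = 1),
    class = "redescend_nonconvergence"
  )
  expect_false(f$converged)
  expect_equal(f$n_iterations, 1L)
})

test_that("total weight collapse raises a degenerate-weights error", {
  expect_error(
    fit_irls(china_xy(), psi_family("proposed", k = 1e-30, a = 8),
             scale = "none"),
    class = "redescend_degenerate_weights"
  )
})

test_that("Huber fit with MAD rescaling matches the MASS::rlm oracle", {
  library(MASS)
  d <- telephone_xy()
  # rlm estimates scale by the MAD about zero; use the same convention here
  f <- fit_irls(d, psi_family("huber", k = 1.345), scale = "mad_zero",
                tol = 1e-12, max_iter = 500)
  oracle <- MASS::rlm(y ~ x, data = d, psi = MASS::psi.huber, k = 1.345,
                      maxit = 500, acc = 1e-12)
  expect_equal(unname(f$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-4)
  # the centered-MAD default lands on the same robust solution
  g <- fit_irls(d, psi_family("huber", k = 1.345), scale = "mad")
  expect_equal(unname(g$coefficients), unname(stats::coef(oracle)),
               tolerance = 0.03)
})

test_that("LMS equals the exhaustive elemental-line oracle for small n", {
  set.seed(9)
  for (rep in 1:4) {
    d <- tibble::tibble(x = stats::rnorm(8), y = stats::rnorm(8))
    f <- fit_lms(d)
    oracle <- lms_brute_force(d)
    expect_equal(f$objective, oracle$objective, tolerance = 1e-12)
    expect_equal(unname(f$coefficients), oracle$coef, tolerance = 1e-12)
  }
})

test_that("LMS recovers an exact-fit majority line under 46% contamination", {
  set.seed(21)
  x <- 1:24
  y <- 1 + 0.1 * x
  y[14:24] <- stats::runif(11, 50, 100)  # 11 arbitrary outliers, 13 exact points
  d <- tibble::tibble(x = x, y = y)
  f <- fit_lms(d)
  expect_equal(unname(f$coefficients), c(1, 0.1), tolerance = 1e-12)
  expect_equal(f$objective, 0)
})

test_that("LMS beats OLS on its own criterion for the telephone data", {
  d <- telephone_xy()
  lms <- fit_lms(d)
  ols <- fit_ols(d)
  expect_lte(lms$objective, median(ols$residuals^2))
})

test_that("LMS subsampling is deterministic given its seed", {
  set.seed(1234)
  d <- tibble::tibble(x = stats::rnorm(40), y = stats::rnorm(40))
  f1 <- fit_lms(d, n_subsets = 200, seed = 7)
  f2 <- fit_lms(d, n_subsets = 200, seed = 7)
  expect_identical(f1$coefficients, f2$coefficients)
  expect_equal(f1$n_candidates, 200)
})

test_that("fits are invariant to observation order", {
  d <- telephone_xy()
  set.seed(5)
  perm <- sample(nrow(d))
  dp <- d[perm, ]
  expect_lt(max(abs(fit_ols(d)$coefficients - fit_ols(dp)$coefficients)), 1e-10)
  fam <- psi_family("proposed", k = 3.5, a = 6)
  expect_lt(max(abs(fit_irls(d, fam)$coefficients -
                    fit_irls(dp, fam)$coefficients)), 1e-10)
  # exhaustive candidate set => permutation cannot change the optimum
  expect_lt(max(abs(fit_lms(d)$coefficients - fit_lms(dp)$coefficients)), 1e-10)
})

test_that("one gross y-outlier breaks OLS but barely moves the robust fit", {
  set.seed(77)
  x <- stats::rnorm(30, 20, 10)
  y <- 2 + x + stats::rnorm(30, sd = 0.5)
  clean <- tibble::tibble(x = x, y = y)
  dirty <- clean
  j <- which.max(abs(x - mean(x)))
  dirty$y[j] <- dirty$y[j] + 1e6
  fam <- psi_family("proposed", k = 2, a = 6)
  slope_clean <- fit_irls(clean, fam)$coefficients[2]
  slope_dirty <- fit_irls(dirty, fam)$coefficients[2]
  expect_lt(abs(slope_dirty - slope_clean), 0.01)
  expect_gt(abs(fit_ols(dirty)$coefficients[2] - fit_ols(clean)$coefficients[2]), 1)
})

test_that("tidy, glance and augment expose the fit as tibbles", {
  d <- china_xy()
  f <- fit_irls(d, psi_family("proposed", k = 2, a = 8))
  td <- tidy(f)
  expect_equal(td$term, c("(Intercept)", "x"))
  expect_equal(td$estimate, unname(f$coefficients))
  gl <- glance(f)
  expect_equal(gl$method, "irls_proposed")
  expect_true(gl$converged)
  au <- augment(f)
  expect_equal(nrow(au), 9)
  expect_equal(au$y - au$.fitted, au$.resid)
  expect_true(all(au$.weight >= 0 & au$.weight <= 1))
  # plots build without evaluation errors
  expect_s3_class(autoplot(f), "ggplot")
  expect_s3_class(autoplot(psi_family("proposed")), "ggplot")
})

test_that("outlier flagging uses weights for IRLS and residuals for OLS/LMS", {
  chi <- china_xy()
  # raw-residual fit: the two gross outliers are the only near-zero weights
  f <- fit_irls(chi, psi_family("proposed", k = 2, a = 8), scale = "none")
  expect_equal(flag_outliers(f), c(8L, 9L))
  # all-unit-weight fit flags nothing
  f1 <- fit_irls(chi, psi_family("huber", k = 1e9), scale = "none")
  expect_identical(flag_outliers(f1), integer(0))
  # LMS on the telephone data flags the 1963-1970 block, leaving 16 retained
  tel <- telephone_xy()
  flags <- flag_outliers(fit_lms(tel))
  expect_equal(flags, 14:21)
  expect_equal(setdiff(seq_len(24), flags), telephone_retained)
  expect_error(flag_outliers(f, weight_cutoff = 1.5),
               class = "redescend_invalid_parameter")
})

test_that("subset SSE accounting is consistent", {
  chi <- china_xy()
  f <- fit_ols(chi)
  s_all <- subset_sse(chi, f, seq_len(9))
  expect_equal(s_all$sse_all, s_all$sse_retained)
  s7 <- subset_sse(chi, f, 1:7)
  expect_lte(s7$sse_retained, s7$sse_all)
  expect_equal(s7$n_used, 7L)
  expect_error(subset_sse(chi, f, integer(0)),
               class = "redescend_invalid_parameter")
  expect_error(subset_sse(chi, f, c(1, 99)),
               class = "redescend_invalid_parameter")
})
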