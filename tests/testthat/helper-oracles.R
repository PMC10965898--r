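# Shared fixtures (built in code, independent of the packaged CSVs) and
# brute-force oracles used across the suite.

telephone_xy <- function() {
  tibble::tibble(
    x = as.numeric(50:73),
    y = c(0.44, 0.47, 0.47, 0.59, 0.66, 0.73, 0.81, 0.88, 1.06, 1.2, 1.35,
          1.49, 1.61, 2.12, 11.9, 12.4, 14.2, 15.9, 18.2, 21.2, 4.3, 2.4,
          2.7, 2.9)
  )
}

china_xy <- function() {
  tibble::tibble(
    x = as.numeric(40:48),
    y = c(1.62, 1.63, 1.90, 2.64, 2.05, 2.13, 1.94, 15.50, 364.00)
  )
}

# retained sets used in the benchmark tables
telephone_retained <- c(1:13, 22:24)
china_retained <- 1:7

# exhaustive least-median-of-squares over every two-point elemental line
lms_brute_force <- function(data) {
  x <- data$x; y <- data$y; n <- length(x)
  best <- Inf; best_co <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (x[i] == x[j]) next
      b <- (y[j] - y[i]) / (x[j] - x[i])
      a <- y[i] - b * x[i]
      obj <- median((y - a - b * x)^2)
      if (obj < best) { best <- obj; best_co <- c(a, b) }
    }
  }
  list(coef = best_co, objective = best)
}

# numerical derivative oracle (central differences)
num_deriv <- function(f, r, h = 1e-6) (f(r + h) - f(r - h)) / (2 * h)

all_family_objects <- function() {
  lapply(stats::setNames(nm = family_names()), psi_family)
}
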