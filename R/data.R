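#' Load a packaged benchmark dataset
#'
#' Two classical robust-regression benchmarks (both via Rousseeuw & Leroy,
#' *Robust Regression and Outlier Detection*, 1987) ship with the package:
#'
#' * `"telephone"` — yearly number of international phone calls from Belgium,
#'   1950–1973, in tens of millions (Belgian Statistical Survey). A recording
#'   fault (total call minutes instead of counts) inflates 1964–1969, with
#'   partial effects in 1963 and 1970.
#' * `"china"` — annual average price growth rates in China, 1940–1948, in
#'   percent. Hyperinflation makes the last two years (15.50 and 364.00) gross
#'   outliers.
#'
#' @param name `"telephone"` or `"china"`.
#' @param coding Predictor coding: `"two_digit"` (default; year minus 1900,
#'   e.g. 50–73) or `"full_year"`.
#' @return Tibble with columns `x` and `y` and attributes `label` (free-text
#'   provenance), `known_outliers` (row indices conventionally treated as
#'   contaminated) and `year`.
#' @examples
#' load_fixture("china")
#' attr(load_fixture("telephone"), "known_outliers")
#' @export
load_fixture <- function(name, coding = c("two_digit", "full_year")) {
  if (!is.character(name) || length(name) != 1L ||
      !tolower(name) %in% c("telephone", "china")) {
    rlang::abort("Unknown fixture; available: 'telephone', 'china'.",
                 class = "redescend_not_found")
  }
  name <- tolower(name)
  coding <- match.arg(coding)
  path <- system.file("extdata", paste0(name, ".csv"), package = "redescend",
                      mustWork = TRUE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
  out <- tibble::tibble(
    x = if (coding == "two_digit") raw$x else raw$year,
    y = raw$y
  )
  info <- switch(name,
    telephone = list(
      label = "International phone calls from Belgium 1950-1973 (tens of millions)",
      outliers = 14:21
    ),
    china = list(
      label = "Annual average price growth rate in China 1940-1948 (percent)",
      outliers = 8:9
    )
  )
  structure(out, label = info$label, known_outliers = info$outliers,
            year = raw$year)
}

#' Read and write regression data as CSV
#'
#' `read_regression_csv()` expects a header with numeric columns `x` and `y`
#' (comma separator, `.` decimal mark, UTF-8); extra columns are carried
#' along. A missing column, a non-numeric or missing cell, is a format error
#' naming the offending row. `write_regression_csv()` writes at full
#' precision, so a write–read round trip reproduces the values exactly.
#'
#' @param path File path.
#' @param data Data frame with numeric columns `x` and `y`.
#' @return `read_regression_csv()`: a tibble with columns `x` and `y` (first)
#'   plus any extras. `write_regression_csv()`: `data`, invisibly.
#' @export
read_regression_csv <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("File not found: ", path),
                 class = "redescend_not_found")
  }
  raw <- suppressWarnings(
    readr::read_csv(path, col_types = readr::cols(), progress = FALSE,
                    show_col_types = FALSE)
  )
  if (!all(c("x", "y") %in% names(raw))) {
    rlang::abort("CSV must contain columns `x` and `y`.",
                 class = "redescend_format_error")
  }
  for (col in c("x", "y")) {
    v <- raw[[col]]
    if (!is.numeric(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(!is.finite(v))
    if (length(bad) > 0L) {
      rlang::abort(
        paste0("Column `", col, "` is not numeric at row ", bad[1], "."),
        class = "redescend_format_error"
      )
    }
    raw[[col]] <- v
  }
  dplyr::relocate(tibble::as_tibble(raw), "x", "y")
}

#' @rdname read_regression_csv
#' @export
write_regression_csv <- function(data, path) {
  validate_regression_data(data)
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(data)
}
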