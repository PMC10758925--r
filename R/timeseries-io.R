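#' Read multichannel time series from delimited text
#'
#' Reads CSV/TSV files (one channel per column, optional header row used as
#' channel labels) or AFNI-style `.1D` column files (whitespace-delimited,
#' `#`-prefixed comment lines skipped). Every cell must parse as a finite
#' number; missing or non-numeric cells are rejected rather than imputed.
#'
#' @param path Path to the file.
#' @param format One of `"auto"` (infer from the extension), `"csv"`,
#'   `"tsv"`, or `"1d"`.
#' @param dt Sampling period in seconds attached to the result as the
#'   `"dt"` attribute (default 1).
#' @return A tibble with one numeric column per channel. Columns are named
#'   from the header row when present, otherwise `ch0 ... chQ-1`.
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_series(tibble::tibble(x = rnorm(10), y = rnorm(10)), path)
#' read_series(path)
#' @export
read_series <- function(path, format = c("auto", "csv", "tsv", "1d"), dt = 1) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "ccmdi_io_error")
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", tsv = "tsv", "1d" = "1d",
      abort(paste0("cannot infer format from extension '.", ext,
                   "'; pass `format` explicitly"), class = "ccmdi_io_error")
    )
  }
  if (format == "1d") {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
    cells <- strsplit(trimws(lines), "\\s+")
  } else {
    sep <- if (format == "csv") "," else "\t"
    raw <- utils::read.csv(path, header = FALSE, sep = sep,
                           colClasses = "character",
                           blank.lines.skip = TRUE, strip.white = TRUE)
    cells <- lapply(seq_len(nrow(raw)), function(i) as.character(raw[i, ]))
  }
  if (length(cells) == 0L) {
    abort("file contains no data rows", class = "ccmdi_format_error")
  }
  ncols <- vapply(cells, length, integer(1))
  if (length(unique(ncols)) != 1L) {
    bad <- which(ncols != ncols[1])[1]
    abort(paste0("ragged rows: row ", bad, " has ", ncols[bad],
                 " fields but row 1 has ", ncols[1]),
          class = "ccmdi_format_error")
  }
  q <- ncols[1]
  header <- cells[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(header)))
  labels <- if (has_header) header else paste0("ch", seq_len(q) - 1L)
  body <- if (has_header) cells[-1] else cells
  if (length(body) == 0L) {
    abort("file contains a header but no data rows",
          class = "ccmdi_format_error")
  }
  mat <- matrix(NA_real_, nrow = length(body), ncol = q)
  for (i in seq_along(body)) {
    vals <- suppressWarnings(as.numeric(body[[i]]))
    if (anyNA(vals) || any(!is.finite(vals))) {
      j <- which(is.na(vals) | !is.finite(vals))[1]
      abort(paste0("non-numeric value '", body[[i]][j], "' at data row ", i,
                   ", column ", j), class = "ccmdi_parse_error")
    }
    mat[i, ] <- vals
  }
  if (anyDuplicated(labels)) {
    abort("channel labels must be unique", class = "ccmdi_format_error")
  }
  out <- as_tibble(as.data.frame(mat), .name_repair = "minimal")
  names(out) <- labels
  attr(out, "dt") <- dt
  out
}

#' Write multichannel time series as CSV
#'
#' @param data A data frame of numeric channels.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_series <- function(data, path) {
  stopifnot(is.data.frame(data))
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Not-a-knot cubic spline (MATLAB `spline` boundary condition): the third
# derivative is continuous across the second and penultimate knots. Solves
# the banded system for the second derivatives M_i and evaluates piecewise.
notaknot_spline <- function(x, y, xi) {
  n <- length(x)
  stopifnot(n >= 4L, length(y) == n)
  h <- diff(x)
  ii <- integer(0); jj <- integer(0); vv <- numeric(0); rhs <- numeric(n)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); vv <<- c(vv, v)
  }
  # not-a-knot rows at the two ends
  add(1, 1, h[2]); add(1, 2, -(h[1] + h[2])); add(1, 3, h[1])
  add(n, n - 2, h[n - 1]); add(n, n - 1, -(h[n - 2] + h[n - 1]))
  add(n, n, h[n - 2])
  for (i in 2:(n - 1)) {
    add(i, i - 1, h[i - 1] / 6)
    add(i, i, (h[i - 1] + h[i]) / 3)
    add(i, i + 1, h[i] / 6)
    rhs[i] <- (y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1]
  }
  A <- Matrix::sparseMatrix(i = ii, j = jj, x = vv, dims = c(n, n))
  M <- as.numeric(Matrix::solve(A, rhs))
  k <- pmin(pmax(findInterval(xi, x), 1L), n - 1L)
  hk <- h[k]
  a <- (x[k + 1] - xi) / hk
  b <- (xi - x[k]) / hk
  a * y[k] + b * y[k + 1] +
    ((a^3 - a) * M[k] + (b^3 - b) * M[k + 1]) * hk^2 / 6
}

#' Upsample a time series by cubic spline interpolation
#'
#' Interpolates with a not-a-knot cubic spline (the boundary condition of
#' MATLAB's `spline` command). Upsampling an n-sample series by a factor f
#' yields `f * n - (f - 1)` samples: every original sample is preserved
#' exactly at stride `f`, with `f - 1` interpolated points between each
#' adjacent pair, and the sampling period shrinks from `dt` to `dt / f`.
#'
#' @param x Either a numeric vector (one channel) or a data frame of
#'   numeric channels, in which case every column is upsampled.
#' @param factor Positive integer upsampling factor.
#' @return An object of the same shape as `x` with
#'   `factor * n - (factor - 1)` samples. If `x` carries a `"dt"`
#'   attribute it is divided by `factor`.
#' @examples
#' length(spline_upsample(rnorm(192), 2)) # 383
#' @export
spline_upsample <- function(x, factor) {
  stopifnot(length(factor) == 1L, factor >= 1, factor == round(factor))
  factor <- as.integer(factor)
  if (is.data.frame(x)) {
    out <- as_tibble(lapply(x, spline_upsample, factor = factor))
    if (!is.null(attr(x, "dt"))) attr(out, "dt") <- attr(x, "dt") / factor
    return(out)
  }
  stopifnot(is.numeric(x))
  n <- length(x)
  if (factor == 1L) return(x)
  if (n < 4L) {
    abort(paste0("spline upsampling needs at least 4 samples, got ", n),
          class = "ccmdi_insufficient_data")
  }
  grid <- seq(1, n, by = 1 / factor)
  out <- notaknot_spline(seq_len(n), x, grid)
  out[seq(1, length(out), by = factor)] <- x  # knots reproduced exactly
  if (!is.null(attr(x, "dt"))) attr(out, "dt") <- attr(x, "dt") / factor
  out
}
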