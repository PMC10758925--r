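# plugin entropy in bits from an integer/real code vector
plugin_entropy <- function(code) {
  n <- length(code)
  cnt <- tabulate(match(code, unique(code)))
  log2(n) - sum(cnt * log2(cnt)) / n
}

#' Quantize a series into symbols
#'
#' Digitization step feeding the plugin information estimators. Uniform
#' binning spans `[min, max]` with equal-width, left-closed bins (the top
#' bin is closed on both sides); quantile binning aims for approximately
#' equal occupancy.
#'
#' @param x Numeric vector.
#' @param n_bins Number of bins (default 8, minimum 2).
#' @param strategy `"uniform"` (equal-width over the range) or
#'   `"quantile"` (equal-occupancy).
#' @return Integer symbols in `0 ... n_bins - 1`.
#' @examples
#' quantize(c(0, 0.5, 1), n_bins = 2) # 0 1 1
#' @export
quantize <- function(x, n_bins = 8, strategy = c("uniform", "quantile")) {
  strategy <- match.arg(strategy)
  stopifnot(is.numeric(x), n_bins >= 2, all(is.finite(x)))
  if (strategy == "uniform") {
    if (max(x) == min(x)) return(rep(0L, length(x)))
    breaks <- seq(min(x), max(x), length.out = n_bins + 1)
  } else {
    if (max(x) == min(x)) {
      abort("quantile quantizer is degenerate for a constant series",
            class = "ccmdi_degenerate_quantizer")
    }
    breaks <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                              names = FALSE))
    if (length(breaks) < 3) {
      abort("quantile quantizer is degenerate: too few distinct quantiles",
            class = "ccmdi_degenerate_quantizer")
    }
  }
  findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE) - 1L
}

#' Plugin mutual information between two symbol sequences
#'
#' `I(X; Y) = H(X) + H(Y) - H(X, Y)` in bits, with all entropies estimated
#' from the empirical joint histogram (zero-count cells contribute 0).
#'
#' @param xsym,ysym Equal-length integer symbol sequences.
#' @return Mutual information in bits per sample.
#' @export
estimate_mi <- function(xsym, ysym) {
  stopifnot(length(xsym) == length(ysym), length(xsym) >= 1)
  bx <- max(xsym) + 1
  plugin_entropy(xsym) + plugin_entropy(ysym) -
    plugin_entropy(xsym + bx * ysym)
}

#' Estimate directed information between symbol sequences
#'
#' Directed information from `X` to `Y` accumulates, sample by sample, the
#' information the current and past of `X` carry about `Y_i` beyond `Y`'s
#' own past, including the instantaneous exchange between `X_i` and `Y_i`:
#' `I(X^n -> Y^n) = sum_i I(X^i; Y_i | Y^{i-1})`. Full histories are not
#' estimable, so the estimator truncates conditioning to the last `order`
#' samples and pools the empirical joint frequencies over `i`
#' (stationarity): per sample,
#' `DI = H(Y_i | Ypast) - H(Y_i | Ypast, X_{i-order..i})` with plugin
#' conditional entropies.
#'
#' @param xsym,ysym Equal-length integer symbol sequences (see
#'   [quantize()]).
#' @param order Conditioning-history length `m >= 0` (default 2). With
#'   `order = 0` the estimate reduces to the instantaneous mutual
#'   information `I(X_i; Y_i)`.
#' @param bias_correction Apply the Miller–Madow correction to each plugin
#'   entropy (default `FALSE`, keeping the estimator identical to its
#'   brute-force definition).
#' @return An object of class `di_result` with fields `di_total` (bits),
#'   `di_per_sample`, `mi_per_sample`, `di_mi_ratio`, `order`, `n_bins`
#'   (alphabet sizes used), and `undersampled` (`TRUE` when the number of
#'   possible symbol-context combinations exceeds `n / 5`, in which case an
#'   under-sampling warning is also raised).
#' @examples
#' x <- sample(0:3, 5000, replace = TRUE)
#' estimate_di(x, x, order = 0) # identity channel: ~2 bits/sample
#' @export
estimate_di <- function(xsym, ysym, order = 2, bias_correction = FALSE) {
  stopifnot(length(xsym) == length(ysym), order >= 0,
            all(xsym >= 0), all(ysym >= 0))
  n <- length(xsym)
  m <- as.integer(order)
  if (n <= m) {
    abort(paste0("need n > order, got n = ", n, ", order = ", m),
          class = "ccmdi_domain_error")
  }
  bx <- max(xsym) + 1
  by <- max(ysym) + 1
  idx <- (m + 1):n
  ypast <- rep(0, length(idx))
  if (m > 0) {
    for (k in 1:m) ypast <- ypast + ysym[idx - k] * by^(k - 1)
  }
  xwin <- rep(0, length(idx))
  for (k in 0:m) xwin <- xwin + xsym[idx - k] * bx^k
  yi <- ysym[idx]
  ncells <- as.numeric(by)^(m + 1) * as.numeric(bx)^(m + 1)
  undersampled <- ncells > n / 5
  if (undersampled) {
    warn(paste0("alphabet-context combinations (", format(ncells),
                ") exceed n/5 = ", format(n / 5),
                "; the DI estimate is likely under-sampled"))
  }
  ent <- function(code) {
    h <- plugin_entropy(code)
    if (bias_correction) {
      h <- h + (length(unique(code)) - 1) / (2 * length(code) * log(2))
    }
    h
  }
  nypast <- max(ypast) + 1
  h_ypast <- if (m > 0) ent(ypast) else 0
  h_yi_ypast <- ent(yi + by * ypast)
  h_ypast_xwin <- ent(ypast + nypast * xwin)
  h_all <- ent(yi + by * (ypast + nypast * xwin))
  di <- (h_yi_ypast - h_ypast) - (h_all - h_ypast_xwin)
  mi <- estimate_mi(xsym, ysym)
  structure(
    list(di_total = di * n, di_per_sample = di, mi_per_sample = mi,
         di_mi_ratio = if (mi > 0) di / mi else NA_real_,
         order = m, n = n, n_bins = c(x = bx, y = by),
         undersampled = undersampled),
    class = "di_result"
  )
}

#' @export
print.di_result <- function(x, ...) {
  cat(sprintf("DI: %.4f bits/sample  (MI %.4f, DI/MI %s, order %d, n %d%s)\n",
              x$di_per_sample, x$mi_per_sample,
              ifelse(is.na(x$di_mi_ratio), "NA",
                     sprintf("%.3f", x$di_mi_ratio)),
              x$order, x$n,
              if (x$undersampled) ", UNDER-SAMPLED" else ""))
  invisible(x)
}

#' Tidy a directed-information result
#' @param x A `di_result` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.di_result <- function(x, ...) {
  tibble(di_per_sample = x$di_per_sample, di_total = x$di_total,
         mi_per_sample = x$mi_per_sample, di_mi_ratio = x$di_mi_ratio,
         order = x$order, n = x$n, undersampled = x$undersampled)
}

#' @export
glance.di_result <- function(x, ...) tidy(x)

#' Directed information between two channels of a data frame
#'
#' Convenience wrapper: quantizes both channels and calls [estimate_di()].
#'
#' @inheritParams ccm
#' @param n_bins,strategy Quantizer settings (see [quantize()]). For short
#'   series prefer small alphabets: the plugin estimator needs the number
#'   of symbol-context combinations to stay well below `n`.
#' @param order Conditioning-history length (see [estimate_di()]).
#' @param bias_correction See [estimate_di()].
#' @return A `di_result` object.
#' @export
di_causation <- function(data, x, y, n_bins = 8,
                         strategy = c("uniform", "quantile"), order = 2,
                         bias_correction = FALSE) {
  xq <- resolve_col(rlang::enquo(x))
  yq <- resolve_col(rlang::enquo(y))
  strategy <- match.arg(strategy)
  estimate_di(quantize(data[[xq]], n_bins, strategy),
              quantize(data[[yq]], n_bins, strategy),
              order = order, bias_correction = bias_correction)
}

#' Closed-form mutual information of a bivariate Gaussian
#'
#' For jointly Gaussian variables with correlation `rho`, the mutual
#' information is `-1/2 log2(1 - rho^2)` bits (Gel'fand's closed form).
#' This is the noiseless limit that links cross-map skill to directed
#' information for Gaussian processes.
#'
#' @param rho Correlation in `(-1, 1)`.
#' @return Mutual information in bits.
#' @examples
#' gaussian_mi(0.6) # 0.32193
#' @export
gaussian_mi <- function(rho) {
  if (any(abs(rho) >= 1)) {
    abort("|rho| must be < 1", class = "ccmdi_domain_error")
  }
  -0.5 * log2(1 - rho^2)
}
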