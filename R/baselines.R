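#' Granger causality between two channels
#'
#' Classical linear Granger test of the direction `x -> y`: an AR(p)
#' model of `y` on its own lags (restricted) is compared with the model
#' that adds `p` lags of `x` (unrestricted) by an F-test on the reduction
#' in residual sum of squares. As a linear-prediction measure it requires
#' separability and randomness; on deterministic inputs (e.g. noiseless
#' sinusoids) the restricted fit is already essentially exact, the test is
#' reported as degenerate with `significant = FALSE` rather than raising
#' an error.
#'
#' @inheritParams ccm
#' @param order AR lag order `p` (default 5).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `gc_result` with `f_statistic`, `p_value`,
#'   `significant`, `degenerate`, `order`, and the direction labels.
#' @examples
#' ex <- generate_example("ex8_2", n = 512, seed = 1)
#' granger_causality(ex, x, y, order = 5)
#' @export
granger_causality <- function(data, x, y, order = 5, alpha = 0.05) {
  xq <- resolve_col(rlang::enquo(x))
  yq <- resolve_col(rlang::enquo(y))
  xv <- data[[xq]]; yv <- data[[yq]]
  p <- as.integer(order)
  n <- length(yv)
  stopifnot(p >= 1, length(xv) == n)
  if (n <= 3 * p + 2) {
    abort(paste0("need n > 3p + 2 = ", 3 * p + 2, ", got n = ", n),
          class = "ccmdi_domain_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("constant input series", class = "ccmdi_domain_error")
  }
  idx <- (p + 1):n
  lag_mat <- function(v) {
    vapply(1:p, function(k) v[idx - k], numeric(length(idx)))
  }
  yt <- yv[idx]
  Xr <- cbind(1, lag_mat(yv))
  Xu <- cbind(Xr, lag_mat(xv))
  rss <- function(X) {
    q <- qr(X)
    r <- qr.resid(q, yt)
    list(rss = sum(r^2), rank = q$rank)
  }
  fr <- rss(Xr); fu <- rss(Xu)
  df2 <- length(yt) - ncol(Xu)
  scale0 <- sum((yt - mean(yt))^2)
  # An (almost) exact restricted fit leaves no residual variance to test
  # against (deterministic self-predictable input, e.g. noiseless
  # sinusoids): report degenerate instead of erroring. An exact
  # unrestricted fit with a non-exact restricted one is extreme evidence,
  # not degeneracy (F diverges, p -> 0).
  degenerate <- fu$rank < ncol(Xu) || fr$rank < ncol(Xr) ||
    fr$rss <= scale0 * 1e-12 || df2 < 1
  if (degenerate) {
    f <- NA_real_; pv <- NA_real_; sig <- FALSE
  } else if (fu$rss <= scale0 * 1e-12) {
    f <- Inf; pv <- 0; sig <- TRUE
  } else {
    f <- ((fr$rss - fu$rss) / p) / (fu$rss / df2)
    pv <- pf(f, p, df2, lower.tail = FALSE)
    sig <- pv < alpha
  }
  structure(
    list(from = xq, to = yq, f_statistic = f, p_value = pv,
         significant = sig, degenerate = degenerate, order = p,
         alpha = alpha, n = n),
    class = "gc_result"
  )
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("Granger causality %s -> %s (p = %d): %s\n", x$from, x$to,
              x$order,
              if (x$degenerate) "degenerate (deterministic or singular fit)"
              else sprintf("F = %.3f, p-value = %.4g, %ssignificant at %.2g",
                           x$f_statistic, x$p_value,
                           if (x$significant) "" else "not ", x$alpha)))
  invisible(x)
}

#' Tidy a Granger causality result
#' @param x A `gc_result` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.gc_result <- function(x, ...) {
  tibble(from = x$from, to = x$to, f_statistic = x$f_statistic,
         p_value = x$p_value, significant = x$significant,
         degenerate = x$degenerate, order = x$order, n = x$n)
}

#' @export
glance.gc_result <- function(x, ...) tidy(x)
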