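#' Map cross-map skill to directed information through the affine bridge
#'
#' For jointly Gaussian, stationary ergodic, dynamically coupled processes
#' the average directed information per sample approaches the Gel'fand
#' closed form of the cross-map skill,
#' `DI ~= -1/2 log2(1 - rho^2)`. On finite, quantized, noisy data the
#' realized relationship is an affine distortion of that closed form,
#' `DI ~= a * (-1/2 log2(1 - rho^2)) + b`, with dataset-specific constants
#' `a`, `b` (see [fit_bridge()]). With the identity bridge `a = 1, b = 0`
#' the mapping is the exact closed form.
#'
#' @param rho Cross-map skill(s) in `(-1, 1)`.
#' @param a,b Bridge slope and intercept (default the identity bridge), or
#'   pass an `affine_bridge` object as `a`.
#' @return Directed information in bits per sample.
#' @examples
#' di_from_cccm(0.6)                       # 0.32193 (closed form)
#' di_from_cccm(0.5, a = 0.7945, b = 0.2578)
#' @export
di_from_cccm <- function(rho, a = 1, b = 0) {
  if (inherits(a, "affine_bridge")) { b <- a$b; a <- a$a }
  a * gaussian_mi(rho) + b
}

#' Invert the affine bridge: cross-map skill magnitude from DI
#'
#' Exact inverse of [di_from_cccm()] on magnitudes:
#' `|rho| = sqrt(1 - 2^(-2 (di - b) / a))`.
#'
#' @param di Directed information in bits per sample.
#' @param a,b Bridge parameters (or an `affine_bridge` object as `a`).
#' @return `|rho|` in `[0, 1)`.
#' @examples
#' cccm_from_di(0.5) # sqrt(1 - 2^-1) = 0.7071
#' @export
cccm_from_di <- function(di, a = 1, b = 0) {
  if (inherits(a, "affine_bridge")) { b <- a$b; a <- a$a }
  z <- (di - b) / a
  if (any(z < 0)) {
    abort("(di - b)/a < 0: estimated DI lies below the bridge intercept",
          class = "ccmdi_domain_error")
  }
  sqrt(1 - 2^(-2 * z))
}

#' Fit the affine cCCM-DI bridge by least squares
#'
#' Regresses observed DI values on the Gel'fand transform of the cross-map
#' skill, `x = -1/2 log2(1 - rho^2)`, by ordinary least squares (vertical
#' residuals in DI). Magnitudes `|rho|` are used, matching the inversion
#' formula which returns a magnitude. The constants absorb quantization
#' noise, finite data size and error propagation in the DI estimate, so
#' they are dataset-specific; no default other than the identity bridge is
#' assumed.
#'
#' @param pairs A data frame with columns `rho` and `di` (one observation
#'   per coupled pair/condition), at least 2 rows with `|rho| < 1`.
#' @return An object of class `affine_bridge` with `a` (slope), `b`
#'   (intercept), `r_squared`, `n_points`, and the fitted `pairs` (with the
#'   transformed predictor). `tidy()`, `glance()` and `autoplot()` methods
#'   are provided.
#' @export
fit_bridge <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("rho", "di") %in% names(pairs)))
  pairs <- dplyr::filter(pairs, abs(.data$rho) < 1)
  if (nrow(pairs) < 2) {
    abort("need at least 2 pairs with |rho| < 1",
          class = "ccmdi_domain_error")
  }
  px <- gaussian_mi(abs(pairs$rho))
  if (max(px) - min(px) < .Machine$double.eps * 100) {
    abort("all transformed predictors identical; bridge fit is singular",
          class = "ccmdi_singular_fit")
  }
  fit <- lm(pairs$di ~ px)
  r2 <- 1 - sum(fit$residuals^2) / sum((pairs$di - mean(pairs$di))^2)
  structure(
    list(a = unname(coef(fit)[2]), b = unname(coef(fit)[1]),
         r_squared = r2, n_points = nrow(pairs),
         pairs = tibble(rho = pairs$rho, di = pairs$di, x = px)),
    class = "affine_bridge"
  )
}

#' @export
print.affine_bridge <- function(x, ...) {
  cat(sprintf("Affine cCCM-DI bridge: DI = %.4f * [-1/2 log2(1 - rho^2)] + %.4f   (r^2 = %.3f, n = %d)\n",
              x$a, x$b, x$r_squared, x$n_points))
  invisible(x)
}

#' Tidy the affine bridge fit
#' @param x An `affine_bridge` object.
#' @param ... Unused.
#' @return A one-row tibble with `a`, `b`, `r_squared`, `n_points`.
#' @export
tidy.affine_bridge <- function(x, ...) {
  tibble(a = x$a, b = x$b, r_squared = x$r_squared, n_points = x$n_points)
}

#' @export
glance.affine_bridge <- function(x, ...) tidy(x)

#' @export
autoplot.affine_bridge <- function(object, ...) {
  ggplot2::ggplot(object$pairs, ggplot2::aes(x = .data$x, y = .data$di)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = object$a, intercept = object$b,
                         colour = "red") +
    ggplot2::labs(
      x = expression(-frac(1, 2) ~ log[2](1 - rho^2)),
      y = "DI (bits/sample)",
      title = sprintf("Affine bridge: a = %.3f, b = %.3f, r2 = %.3f",
                      object$a, object$b, object$r_squared)
    )
}
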