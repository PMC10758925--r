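# Generator equations. ex3 (sine/cosine on t = 0:0.01*pi:2*pi), ex8_2
# (Y(t) = 0.8 X(t-1) + 0.8 X(t-4)) follow printed definitions; the
# remaining coupling equations are synthetic transcription stand-ins with
# the documented ground-truth causal structure (see the methods vignette).
example_table <- list(
  ex1 = list(
    description = "instantaneous bidirectional Gaussian coupling, X -> Y stronger",
    direction = "bidirectional",
    gen = function(n, params) {
      cxy <- params$cxy %||% 0.8   # X -> Y
      cyx <- params$cyx %||% 0.4   # Y -> X
      z1 <- rnorm(n); z2 <- rnorm(n)
      x <- (z1 + cyx * z2) / (1 - cxy * cyx)
      y <- cxy * x + z2
      tibble(x = x, y = y)
    }
  ),
  ex2 = list(
    description = "independent Gaussian white noise, no coupling",
    direction = "none",
    gen = function(n, params) tibble(x = rnorm(n), y = rnorm(n))
  ),
  ex3 = list(
    description = "X = sin(t), Y = cos(t) on t = 0, 0.01*pi, ..., 2*pi",
    direction = "bidirectional",
    gen = function(n, params) {
      t <- seq(0, (n - 1) * 0.01 * pi, by = 0.01 * pi)
      tibble(x = sin(t), y = cos(t))
    },
    default_n = 201L
  ),
  ex4 = list(
    description = "Y = X^2 of Gaussian X: unidirectional X -> Y, sign of X lost in Y",
    direction = "x_to_y",
    gen = function(n, params) {
      x <- rnorm(n)
      tibble(x = x, y = x^2)
    }
  ),
  ex5_1 = list(
    description = "bidirectionally coupled AR(1) pair, moderate X -> Y coupling",
    direction = "bidirectional",
    gen = function(n, params) ar_pair(n, params$cxy %||% 0.4,
                                      params$cyx %||% 0.2)
  ),
  ex5_2 = list(
    description = "bidirectionally coupled AR(1) pair, strong X -> Y coupling",
    direction = "bidirectional",
    gen = function(n, params) ar_pair(n, params$cxy %||% 0.8,
                                      params$cyx %||% 0.2)
  ),
  ex6_1 = list(
    description = "dominant sinusoid in noise driving a noisy response, moderate coupling",
    direction = "x_to_y",
    gen = function(n, params) freq_pair(n, params$cxy %||% 0.5)
  ),
  ex6_2 = list(
    description = "dominant sinusoid in noise driving a noisy response, strong coupling",
    direction = "x_to_y",
    gen = function(n, params) freq_pair(n, params$cxy %||% 1.0)
  ),
  ex7_1 = list(
    description = "coupled logistic maps, moderate X -> Y coupling",
    direction = "bidirectional",
    gen = function(n, params) logistic_pair(n, params$bxy %||% 0.15,
                                            params$byx %||% 0.05)
  ),
  ex7_2 = list(
    description = "coupled logistic maps, strong X -> Y coupling",
    direction = "bidirectional",
    gen = function(n, params) logistic_pair(n, params$bxy %||% 0.25,
                                            params$byx %||% 0.1)
  ),
  ex8_1 = list(
    description = "memory system Y(t) = 0.8 X(t-4), AR(1) driver",
    direction = "x_to_y", delays = 4L,
    gen = function(n, params) memory_pair(n, delays = 4,
                                          phi = params$phi %||% 0.5)
  ),
  ex8_2 = list(
    description = "memory system Y(t) = 0.8 X(t-1) + 0.8 X(t-4), AR(1) driver",
    direction = "x_to_y", delays = c(1L, 4L),
    gen = function(n, params) memory_pair(n, delays = c(1, 4),
                                          phi = params$phi %||% 0.5)
  )
)

`%||%` <- function(a, b) if (is.null(a)) b else a

ar_pair <- function(n, cxy, cyx, phi = 0.5, burn = 100L) {
  m <- n + burn
  x <- numeric(m); y <- numeric(m)
  ex <- rnorm(m); ey <- rnorm(m)
  for (t in 2:m) {
    x[t] <- phi * x[t - 1] + cyx * y[t - 1] + ex[t]
    y[t] <- phi * y[t - 1] + cxy * x[t - 1] + ey[t]
  }
  tibble(x = x[(burn + 1):m], y = y[(burn + 1):m])
}

freq_pair <- function(n, cxy, freq = 0.04, noise_sd = 0.5) {
  t <- seq_len(n + 1)
  x <- sin(2 * pi * freq * t) + noise_sd * rnorm(n + 1)
  y <- cxy * x[1:n] + noise_sd * rnorm(n)
  tibble(x = x[2:(n + 1)], y = y)
}

# Diffusively coupled logistic maps in the convex-mixing form, which is
# closed on [0, 1] for any coupling fraction: each map's next state blends
# its own logistic update with the partner's.
logistic_pair <- function(n, bxy, byx, rx = 3.8, ry = 3.5, burn = 300L) {
  m <- n + burn
  x <- numeric(m); y <- numeric(m)
  # random initial conditions in the basin, so Monte-Carlo runs differ
  x[1] <- runif(1, 0.1, 0.9); y[1] <- runif(1, 0.1, 0.9)
  fx <- function(u) rx * u * (1 - u)
  fy <- function(u) ry * u * (1 - u)
  for (t in 2:m) {
    x[t] <- (1 - byx) * fx(x[t - 1]) + byx * fy(y[t - 1])
    y[t] <- (1 - bxy) * fy(y[t - 1]) + bxy * fx(x[t - 1])
  }
  tibble(x = x[(burn + 1):m], y = y[(burn + 1):m])
}

memory_pair <- function(n, delays, phi, coef = 0.8) {
  d <- max(delays)
  m <- n + d
  xf <- as.numeric(stats::arima.sim(list(ar = phi), n = m))
  x <- xf[(d + 1):m]
  y <- rowSums(vapply(delays, function(dd) coef * xf[(d + 1 - dd):(m - dd)],
                      numeric(n)))
  tibble(x = x, y = y)
}

#' Generate a seeded simulation example pair
#'
#' Deterministic (given the seed) generators for the benchmark coupling
#' scenarios used throughout the package: coupled Gaussians (`ex1`),
#' independent noise (`ex2`), quadrature sinusoids (`ex3`), sign-destroying
#' quadratic coupling (`ex4`), bidirectionally coupled AR(1) pairs at two
#' coupling strengths (`ex5_1`, `ex5_2`), a dominant spectral component in
#' noise (`ex6_1`, `ex6_2`), coupled logistic maps (`ex7_1`, `ex7_2`), and
#' delay-memory systems (`ex8_1`: delay 4; `ex8_2`:
#' `Y(t) = 0.8 X(t-1) + 0.8 X(t-4)`). The ground-truth causal structure of
#' each generator is attached to the output.
#'
#' @param example_id One of `"ex1" ... "ex8_2"` (see Details).
#' @param n Series length (default 1024; `ex3` defaults to its natural
#'   201-sample grid `t = 0, 0.01*pi, ..., 2*pi`).
#' @param seed Integer RNG seed; equal specs give identical output.
#' @param params Optional named list of per-example parameters (coupling
#'   strengths `cxy`, `cyx`, `bxy`, `byx`, AR coefficient `phi`).
#' @return A tibble with channels `x`, `y` and attribute `ground_truth`
#'   (a list with `direction` in `{"bidirectional", "none", "x_to_y"}`,
#'   optional `delays`, and a description).
#' @examples
#' ex <- generate_example("ex3")
#' attr(ex, "ground_truth")$direction
#' @export
generate_example <- function(example_id, n = NULL, seed = 1,
                             params = list()) {
  if (!example_id %in% names(example_table)) {
    abort(paste0("unknown example_id '", example_id, "'; valid ids: ",
                 paste(names(example_table), collapse = ", ")),
          class = "ccmdi_domain_error")
  }
  spec <- example_table[[example_id]]
  n <- n %||% spec$default_n %||% 1024L
  stopifnot(n >= 16)
  out <- withr::with_seed(seed, spec$gen(n, params))
  attr(out, "ground_truth") <- list(
    example_id = example_id,
    direction = spec$direction,
    delays = spec$delays,
    description = spec$description
  )
  out
}

#' Add white Gaussian noise at a stated SNR
#'
#' Draws iid Gaussian noise with variance `signal power / 10^(snr_db/10)`
#' (signal power = mean square) and adds it to the series.
#' `snr_db = Inf` returns the input unchanged.
#'
#' @param x Numeric vector with positive power.
#' @param snr_db Signal-to-noise ratio in decibels.
#' @param seed Optional seed for the noise draw.
#' @return The noisy series.
#' @export
add_awgn <- function(x, snr_db, seed = NULL) {
  stopifnot(is.numeric(x), length(snr_db) == 1)
  if (is.infinite(snr_db) && snr_db > 0) return(x)
  p <- mean(x^2)
  if (p == 0) {
    abort("zero-power input: SNR undefined", class = "ccmdi_domain_error")
  }
  noise_sd <- sqrt(p / 10^(snr_db / 10))
  noise <- if (is.null(seed)) rnorm(length(x), sd = noise_sd) else
    withr::with_seed(seed, rnorm(length(x), sd = noise_sd))
  x + noise
}

#' Concatenation artifact demonstration
#'
#' Computes the causalized cross-map causation on `(X, Y)` and on the
#' doubled pair `([X, X], [Y, Y])`. Concatenating a series with itself
#' plants exact repeats of every delay vector in the "past", so
#' cross-mapping finds spurious zero-distance neighbours and a causal
#' pattern is enforced even for independent series - concatenation is not
#' a valid way to extend short records.
#'
#' @param x,y Equal-length numeric vectors.
#' @param E,tau Embedding parameters.
#' @return A one-row tibble with `rho_original` and `rho_concatenated`.
#' @export
concatenation_demo <- function(x, y, E = 5, tau = 1) {
  stopifnot(length(x) == length(y))
  orig <- ccm_pair(x, y, E = E, tau = tau, causal = TRUE)
  cat2 <- ccm_pair(c(x, x), c(y, y), E = E, tau = tau, causal = TRUE)
  tibble(rho_original = orig$rho, rho_concatenated = cat2$rho)
}

#' Seeded Monte-Carlo harness
#'
#' Runs a task under `runs` deterministic seeds and aggregates the
#' results. The task receives one seed per run and returns a numeric
#' scalar or named vector; failures abort with the run index and seed.
#'
#' @param task `function(seed) -> numeric` evaluation closure.
#' @param runs Number of runs (default 100).
#' @param base_seed Seed of the first run; run `r` uses
#'   `base_seed + r - 1`.
#' @return A list with `mean` and `sd` (named numerics) and `values`
#'   (tibble of per-run results with `run` and `seed` columns).
#' @export
monte_carlo <- function(task, runs = 100, base_seed = 1) {
  stopifnot(runs >= 1)
  seeds <- base_seed + seq_len(runs) - 1
  vals <- purrr::imap(seeds, function(s, r) {
    v <- tryCatch(task(s), error = function(e) {
      abort(paste0("monte_carlo task failed at run ", r, " (seed ", s,
                   "): ", conditionMessage(e)),
            class = "ccmdi_monte_carlo_error")
    })
    stopifnot(is.numeric(v))
    if (is.null(names(v))) names(v) <- if (length(v) == 1) "value" else
      paste0("value", seq_along(v))
    tibble(run = r, seed = s, !!!as.list(v))
  })
  values <- dplyr::bind_rows(vals)
  num <- dplyr::select(values, -dplyr::all_of(c("run", "seed")))
  list(mean = vapply(num, mean, numeric(1)),
       sd = vapply(num, sd, numeric(1)),
       values = values)
}
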