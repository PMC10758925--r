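#' Build a shadow manifold by delay embedding
#'
#' Reconstructs the attractor of the system generating `x` from lagged
#' copies of the single observable (Takens' theorem): each manifold point is
#' the delay vector `[X(t), X(t - tau), ..., X(t - (E - 1) tau)]`, so
#' coordinate 1 holds the most recent sample. Points exist for
#' `t = 1 + (E - 1) tau, ..., n` (1-based time indices of the input).
#'
#' @param x Numeric vector, the observed series.
#' @param E Embedding dimension (default 5).
#' @param tau Lag in samples (default 1).
#' @param name Optional channel label stored on the manifold.
#' @return An object of class `shadow_manifold`: a list with `points`
#'   (an `(n - (E-1) tau) x E` matrix), `time_index` (1-based original time
#'   of each row), `E`, `tau`, `n`, and `source_name`.
#' @examples
#' m <- build_shadow_manifold(c(1, 2, 3, 4), E = 2, tau = 1)
#' m$points      # rows [2,1], [3,2], [4,3]
#' m$time_index  # 2 3 4
#' @export
build_shadow_manifold <- function(x, E = 5, tau = 1, name = NULL) {
  stopifnot(is.numeric(x), E >= 1, tau >= 1,
            E == round(E), tau == round(tau))
  E <- as.integer(E); tau <- as.integer(tau)
  n <- length(x)
  first_t <- 1L + (E - 1L) * tau
  if (n <= (E - 1L) * tau) {
    abort(paste0("series of length ", n, " cannot be embedded with E = ", E,
                 ", tau = ", tau, "; at least ", first_t,
                 " samples are required"),
          class = "ccmdi_embedding_infeasible")
  }
  if (any(!is.finite(x))) {
    abort("series contains non-finite values", class = "ccmdi_domain_error")
  }
  if (E * tau >= n / 10) {
    warn(paste0("E * tau = ", E * tau, " is large relative to n = ", n,
                "; cross-mapping may not deliver meaningful results"))
  }
  time_index <- first_t:n
  points <- vapply(0:(E - 1L), function(k) x[time_index - k * tau],
                   numeric(length(time_index)))
  if (!is.matrix(points)) points <- matrix(points, nrow = 1L)
  structure(
    list(points = points, time_index = time_index, E = E, tau = tau,
         n = n, source_name = name),
    class = "shadow_manifold"
  )
}

#' @export
print.shadow_manifold <- function(x, ...) {
  cat("Shadow manifold", if (!is.null(x$source_name)) paste0("of '", x$source_name, "'") else "",
      "\n  E =", x$E, " tau =", x$tau,
      "\n ", nrow(x$points), "points over t =", x$time_index[1], "...",
      x$time_index[length(x$time_index)], "\n")
  invisible(x)
}

#' Check delay coverage of an embedding against dominant system delays
#'
#' For a system with memory whose output depends on inputs at known
#' dominant delays, causality is detectable by cross-mapping only when
#' (i) the embedding span exceeds the largest dominant delay
#' (`E * tau > max(delays)`), and (ii) each dominant delay `d` actually
#' appears among the lags of the delay vector, i.e.
#' `d` is a multiple of `tau` not exceeding `(E - 1) tau`. The report is
#' advisory: it drives warnings in callers, never aborts.
#'
#' @param E Embedding dimension.
#' @param tau Lag in samples.
#' @param dominant_delays Positive integer delays of the coupling.
#' @return A tibble with one row per delay (`delay`, `covered`) plus the
#'   attribute `product_ok` (`E * tau > max(delay)`); also accessible via
#'   the columns of the returned tibble.
#' @examples
#' check_memory_coverage(3, 2, c(1, 4)) # delay 4 covered, delay 1 not
#' @export
check_memory_coverage <- function(E, tau, dominant_delays) {
  stopifnot(length(dominant_delays) >= 1, all(dominant_delays >= 1))
  lags <- (0:(E - 1)) * tau
  covered <- dominant_delays %in% lags
  out <- tibble(delay = as.integer(dominant_delays), covered = covered)
  attr(out, "product_ok") <- E * tau > max(dominant_delays)
  out
}
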