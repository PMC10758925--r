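#' Exponential simplex weights from sorted neighbour distances
#'
#' Weights follow the standard simplex scheme of cross-mapping:
#' `u_i = exp(-d_i / d_1)` normalised to sum to one, where `d_1` is the
#' distance to the nearest neighbour. When `d_1 = 0` (exact match on the
#' manifold) the weight is split uniformly over all zero-distance
#' neighbours and the rest receive weight 0.
#'
#' @param distances Nonnegative distances sorted in ascending order.
#' @return Weights of the same length, summing to 1.
#' @examples
#' compute_weights(c(1, 2, 4))
#' compute_weights(c(0, 1, 2)) # exact match takes all the weight
#' @export
compute_weights <- function(distances) {
  stopifnot(length(distances) >= 1, all(distances >= 0),
            !is.unsorted(distances))
  if (distances[1] == 0) {
    w <- as.numeric(distances == 0)
    return(w / sum(w))
  }
  u <- exp(-distances / distances[1])
  u / sum(u)
}

#' Find nearest neighbours of a manifold point
#'
#' Euclidean K-nearest-neighbour search among admissible manifold points.
#' The query point itself is never admissible; in causal mode only points
#' with strictly earlier time index are admissible, so the future cannot
#' inform the prediction. Ties in distance are broken by the smaller time
#' index. If fewer than `K` admissible points exist, all of them are
#' returned and the shortfall is flagged.
#'
#' @param manifold A [build_shadow_manifold()] result.
#' @param query_t Time index (1-based, on the original series) of the query
#'   point; must be one of `manifold$time_index`.
#' @param K Number of neighbours (cross-mapping uses `E + 1`).
#' @param causal If `TRUE`, admit only neighbours with earlier time index.
#' @return A list with `query_t`, `neighbor_t`, `distances` (ascending),
#'   `weights`, and `shortfall` (`TRUE` when fewer than `K` admissible
#'   points existed).
#' @export
find_neighbors <- function(manifold, query_t, K, causal = TRUE) {
  stopifnot(inherits(manifold, "shadow_manifold"), K >= 1)
  pos <- match(query_t, manifold$time_index)
  if (is.na(pos)) {
    abort(paste0("query_t = ", query_t, " is not a manifold time index"),
          class = "ccmdi_domain_error")
  }
  admissible <- if (causal) {
    which(manifold$time_index < query_t)
  } else {
    setdiff(seq_along(manifold$time_index), pos)
  }
  if (length(admissible) == 0) {
    abort(paste0("no admissible neighbour for query_t = ", query_t,
                 if (causal) " in causal mode" else ""),
          class = "ccmdi_neighbor_unavailable")
  }
  d <- sqrt(colSums((t(manifold$points[admissible, , drop = FALSE]) -
                       manifold$points[pos, ])^2))
  ord <- order(d, manifold$time_index[admissible])
  take <- ord[seq_len(min(K, length(ord)))]
  dist <- d[take]
  list(query_t = query_t,
       neighbor_t = manifold$time_index[admissible][take],
       distances = dist,
       weights = compute_weights(dist),
       shortfall = length(admissible) < K)
}

#' Cross-map a target series from a source shadow manifold
#'
#' For each predictable time `t`, the target is estimated as the
#' simplex-weighted average of its own values at the time indices of the
#' `K` nearest neighbours of the source delay vector `x(t)`:
#' `Yhat(t) = sum_i w_i Y(t_i)`. In causal mode only neighbours with
#' `t_i < t` are used and prediction starts at the first `t` with at least
#' `min_neighbors` admissible past points (earlier times are excluded, never
#' zero-filled).
#'
#' @param manifold Source shadow manifold (built from the putative cause's
#'   effect-carrying series; see [ccm()]).
#' @param target Numeric vector, same length as the series the manifold was
#'   built from.
#' @param causal Restrict neighbours to the past (cCCM) or not (CCM).
#' @param K Number of neighbours; default `E + 1`.
#' @param min_neighbors Causal-mode burn-in: minimum number of admissible
#'   past neighbours required to predict (default `K`).
#' @return A tibble with columns `t` (time index), `observed`, `predicted`,
#'   restricted to the predicted (valid) times.
#' @export
cross_map_predict <- function(manifold, target, causal = TRUE,
                              K = manifold$E + 1, min_neighbors = K) {
  stopifnot(inherits(manifold, "shadow_manifold"), is.numeric(target))
  if (length(target) != manifold$n) {
    abort(paste0("target length ", length(target),
                 " does not match the manifold's source length ",
                 manifold$n), class = "ccmdi_domain_error")
  }
  tv <- target[manifold$time_index]
  res <- cross_map_core(manifold$points, tv, as.integer(K), causal,
                        as.integer(min_neighbors))
  keep <- res$valid
  tibble(t = manifold$time_index[keep],
         observed = tv[keep],
         predicted = res$pred[keep])
}

# vector-interface cross-map causation; all higher layers funnel through it
ccm_pair <- function(x, y, E = 5, tau = 1, causal = TRUE, K = E + 1,
                     min_neighbors = K, labels = c("X", "Y")) {
  stopifnot(length(x) == length(y))
  mx <- build_shadow_manifold(x, E = E, tau = tau, name = labels[1])
  pred <- cross_map_predict(mx, y, causal = causal, K = K,
                            min_neighbors = min_neighbors)
  if (nrow(pred) < 2 || sd(pred$observed) == 0) {
    abort("target has zero variance on the predicted times; correlation undefined",
          class = "ccmdi_undefined_correlation")
  }
  structure(
    list(rho = cor(pred$observed, pred$predicted),
         direction = labels, causal = causal, E = E, tau = tau, K = K,
         n = length(x), n_valid = nrow(pred), predictions = pred),
    class = "ccm_fit"
  )
}

#' Cross-map causation between two channels
#'
#' Computes the CCM (or causalized CCM) causation from channel `x` to
#' channel `y`: the target `y` is predicted by simplex cross-mapping from
#' the shadow manifold of `x`, and the causation is the Pearson correlation
#' between `y` and its prediction. With `causal = TRUE` (cCCM) the
#' neighbour search is limited to strictly earlier time indices, aligning
#' the measure with the presumption that the future of one process cannot
#' influence the past of the other.
#'
#' @param data A data frame of numeric channels.
#' @param x,y Channel columns (bare names or strings): causation is
#'   measured from `x` to `y`.
#' @param E Embedding dimension (default 5).
#' @param tau Lag in samples (default 1).
#' @param causal `TRUE` for cCCM (default), `FALSE` for classical CCM.
#' @param K Neighbours per prediction (default `E + 1`).
#' @param min_neighbors Causal-mode burn-in threshold (default `K`).
#' @return A `ccm_fit` object with the skill `rho` (signed), the direction,
#'   the predicted series, and the valid time indices. `tidy()` and
#'   `glance()` methods are provided.
#' @examples
#' ex <- generate_example("ex3")
#' ccm(ex, x, y, E = 5, tau = 1)
#' @export
ccm <- function(data, x, y, E = 5, tau = 1, causal = TRUE, K = E + 1,
                min_neighbors = K) {
  xq <- resolve_col(rlang::enquo(x))
  yq <- resolve_col(rlang::enquo(y))
  ccm_pair(data[[xq]], data[[yq]], E = E, tau = tau, causal = causal,
           K = K, min_neighbors = min_neighbors, labels = c(xq, yq))
}

#' @export
print.ccm_fit <- function(x, ...) {
  cat(sprintf("%s causation %s -> %s: rho = %.4f  (E = %d, tau = %d, n = %d, predicted = %d)\n",
              if (x$causal) "cCCM" else "CCM",
              x$direction[1], x$direction[2], x$rho, x$E, x$tau, x$n,
              x$n_valid))
  invisible(x)
}

#' Tidy a cross-map fit into a one-row tibble
#' @param x A `ccm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the direction, skill and configuration.
#' @export
tidy.ccm_fit <- function(x, ...) {
  tibble(from = x$direction[1], to = x$direction[2], rho = x$rho,
         causal = x$causal, E = x$E, tau = x$tau, n = x$n,
         n_valid = x$n_valid)
}

#' @export
glance.ccm_fit <- function(x, ...) tidy(x)

#' Convergence of cross-map skill with library length
#'
#' Recomputes the cross-map causation on prefixes of increasing length.
#' For dynamically coupled series the skill rises toward its asymptote as
#' the library grows; failure to converge (flat or erratic curves) signals
#' absent coupling or inadequate sampling.
#'
#' @inheritParams ccm
#' @param lengths Increasing integer library lengths; prefixes below
#'   embedding feasibility are skipped with a warning.
#' @return A tibble of class `ccm_convergence` with columns `L` and `rho`.
#' @export
convergence_curve <- function(data, x, y, E = 5, tau = 1, causal = TRUE,
                              lengths, K = E + 1, min_neighbors = K) {
  xq <- resolve_col(rlang::enquo(x))
  yq <- resolve_col(rlang::enquo(y))
  xv <- data[[xq]]; yv <- data[[yq]]
  stopifnot(all(lengths >= 1), !is.unsorted(lengths))
  if (max(lengths) > length(xv)) {
    abort("library lengths exceed the series length",
          class = "ccmdi_domain_error")
  }
  rows <- purrr::map(lengths, function(L) {
    fit <- tryCatch(
      ccm_pair(xv[seq_len(L)], yv[seq_len(L)], E = E, tau = tau,
               causal = causal, K = K, min_neighbors = min_neighbors,
               labels = c(xq, yq)),
      ccmdi_embedding_infeasible = function(e) NULL,
      ccmdi_undefined_correlation = function(e) NULL
    )
    if (is.null(fit)) {
      warn(paste0("library length L = ", L,
                  " below feasibility; skipped"))
      return(NULL)
    }
    tibble(L = L, rho = fit$rho)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ccm_convergence", class(out))
  attr(out, "direction") <- c(xq, yq)
  attr(out, "causal") <- causal
  out
}

#' @export
autoplot.ccm_convergence <- function(object, ...) {
  dir <- attr(object, "direction")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$L, y = .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "library length L",
      y = expression(rho),
      title = paste0(if (isTRUE(attr(object, "causal"))) "cCCM" else "CCM",
                     " convergence ", dir[1], " → ", dir[2])
    )
}

#' Pearson correlation with domain guards
#'
#' Plain sample Pearson correlation, kept as a named operation because the
#' contrast between correlation and cross-map causation is central to the
#' analysis: orthogonal deterministic signals (e.g. sine and cosine) have
#' zero correlation yet strong bidirectional causation.
#'
#' @param x,y Equal-length numeric vectors, both nonconstant.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for constant input",
          class = "ccmdi_undefined_correlation")
  }
  cor(x, y)
}
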