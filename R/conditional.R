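#' Per-manifold cross-map estimates of one channel from all others
#'
#' For a target channel `i` in a set of dynamically coupled channels, each
#' other channel `q` yields a cross-map estimate of the target from its own
#' shadow manifold. The estimates are aligned on the intersection of the
#' valid (predicted) time indices across sources, so downstream
#' variance comparisons are nested.
#'
#' @param data A data frame of numeric channels (Q >= 2 columns).
#' @param target Target channel (bare name or string).
#' @param E,tau Embedding parameters.
#' @param causal Causal (cCCM) or classical (CCM) neighbour search.
#' @param K,min_neighbors See [cross_map_predict()].
#' @return A list with `target` (label), `time` (common valid indices),
#'   `observed` (target values on those rows), and `estimates` (a matrix
#'   with one column per source channel, named by source).
#' @export
per_manifold_estimates <- function(data, target, E = 5, tau = 1,
                                   causal = TRUE, K = E + 1,
                                   min_neighbors = K) {
  tq <- resolve_col(rlang::enquo(target))
  per_manifold_estimates_impl(data, tq, E, tau, causal, K, min_neighbors)
}

per_manifold_estimates_impl <- function(data, tq, E, tau, causal, K,
                                        min_neighbors) {
  stopifnot(is.data.frame(data), tq %in% names(data), ncol(data) >= 2)
  sources <- setdiff(names(data), tq)
  preds <- lapply(sources, function(q) {
    mq <- build_shadow_manifold(data[[q]], E = E, tau = tau, name = q)
    cross_map_predict(mq, data[[tq]], causal = causal, K = K,
                      min_neighbors = min_neighbors)
  })
  common_t <- Reduce(intersect, lapply(preds, `[[`, "t"))
  if (length(common_t) == 0) {
    abort("no common valid time index across source manifolds",
          class = "ccmdi_insufficient_overlap")
  }
  est <- vapply(preds, function(p) p$predicted[match(common_t, p$t)],
                numeric(length(common_t)))
  if (!is.matrix(est)) est <- matrix(est, nrow = 1L)
  colnames(est) <- sources
  list(target = tq, time = common_t,
       observed = data[[tq]][common_t], estimates = est)
}

#' Combine per-manifold estimates by variance-minimizing weights
#'
#' Solves for the linear combination of per-manifold estimates that
#' minimizes the variance of the estimation error of the target:
#' target and estimate columns are mean-centered on the shared rows and the
#' coefficients solve the intercept-free least-squares problem. The
#' minimized error variance underlies the causality ratio.
#'
#' @param target_vals Observed target values on the shared rows.
#' @param estimates Matrix of per-manifold estimates (columns named by
#'   source).
#' @param exclude Optional source label to drop before fitting (the
#'   `Omega \\ {Xj}` model). `NULL` keeps all columns.
#' @return An object of class `conditional_fit` with `coefficients`
#'   (named), `residuals`, `residual_variance` (mean squared residual of
#'   the centered fit), `n`, and `excluded`.
#' @export
combine_estimates <- function(target_vals, estimates, exclude = NULL) {
  stopifnot(is.matrix(estimates), length(target_vals) == nrow(estimates))
  keep <- colnames(estimates)
  if (!is.null(exclude)) {
    if (!exclude %in% keep) {
      abort(paste0("exclude = '", exclude, "' is not an estimate column"),
            class = "ccmdi_domain_error")
    }
    keep <- setdiff(keep, exclude)
  }
  yc <- target_vals - mean(target_vals)
  if (length(keep) == 0) {
    # empty model: the bivariate limit of the excluded fit
    return(structure(
      list(coefficients = numeric(0), residuals = yc,
           residual_variance = mean(yc^2), n = length(yc),
           excluded = exclude),
      class = "conditional_fit"
    ))
  }
  X <- estimates[, keep, drop = FALSE]
  X <- sweep(X, 2, colMeans(X))
  if (nrow(X) <= ncol(X)) {
    abort("need more shared rows than retained estimate columns",
          class = "ccmdi_domain_error")
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("collinear estimate columns: ",
                 paste(bad, collapse = ", ")),
          class = "ccmdi_collinearity_error")
  }
  beta <- qr.coef(qrX, yc)
  res <- yc - as.numeric(X %*% beta)
  structure(
    list(coefficients = beta, residuals = res,
         residual_variance = mean(res^2), n = length(yc),
         excluded = exclude),
    class = "conditional_fit"
  )
}

#' @export
print.conditional_fit <- function(x, ...) {
  cat("Conditional cross-map combination",
      if (!is.null(x$excluded)) paste0("(excluding ", x$excluded, ")"),
      "\n  residual variance:", format(x$residual_variance), " n:", x$n, "\n")
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

# shared engine for the exported causality-ratio verbs
causality_ratio_impl <- function(data, target, source, E, tau, causal, K,
                                 min_neighbors) {
  pme <- per_manifold_estimates_impl(data, target, E, tau, causal, K,
                                     min_neighbors)
  if (!source %in% colnames(pme$estimates)) {
    abort(paste0("source '", source, "' is not a channel of the data"),
          class = "ccmdi_domain_error")
  }
  fit_with <- combine_estimates(pme$observed, pme$estimates)
  fit_without <- combine_estimates(pme$observed, pme$estimates,
                                   exclude = source)
  vw <- fit_with$residual_variance
  vwo <- fit_without$residual_variance
  if (vwo == 0) {
    abort("variance of the excluded-source model is zero; ratio undefined",
          class = "ccmdi_undefined_ratio")
  }
  structure(
    list(from = source, to = target, cr = (vwo - vw) / vwo,
         var_with = vw, var_without = vwo,
         conditioning = setdiff(colnames(pme$estimates), source),
         causal = causal, n = length(pme$time)),
    class = "causality_ratio"
  )
}

#' Causality ratio of one source on a target, conditioned on the rest
#'
#' Fractional reduction of the minimized prediction-error variance of the
#' target attributable to one source channel:
#' `CR = (Var(e | Omega \\ {Xj}) - Var(e | Omega)) / Var(e | Omega \\ {Xj})`,
#' with both error variances computed on identical shared rows so the
#' comparison is nested (hence `0 <= CR <= 1` up to floating point). With
#' only two channels the excluded-source model is empty and its variance is
#' that of the centered target, extending the ratio to the bivariate limit.
#'
#' Interdependent sources shadow each other: if the source is largely
#' predictable from the remaining conditioning channels, its ratio
#' collapses toward zero even under true bivariate causality.
#'
#' @inheritParams per_manifold_estimates
#' @param target Target channel `i` (bare name or string).
#' @param source Source channel `j` whose contribution is measured.
#' @return An object of class `causality_ratio` with `cr`, `var_with`,
#'   `var_without`, the labels and the conditioning set. `tidy()` provided.
#' @examples
#' ex <- generate_example("ex8_2", n = 400, seed = 1)
#' ex$z <- rnorm(400)
#' causality_ratio(ex, y, x, E = 5, tau = 1)
#' @export
causality_ratio <- function(data, target, source, E = 5, tau = 1,
                            causal = TRUE, K = E + 1, min_neighbors = K) {
  tq <- resolve_col(rlang::enquo(target))
  sq <- resolve_col(rlang::enquo(source))
  stopifnot(tq != sq)
  causality_ratio_impl(data, tq, sq, E, tau, causal, K, min_neighbors)
}

#' Causality ratio conditioned on a single channel
#'
#' Evaluates the causality ratio from `source` to `target` with the
#' channel set restricted to `{target, source, condition}`: the
#' single-conditioner variant used to probe which other channels carry the
#' same information as the source.
#'
#' @inheritParams causality_ratio
#' @param condition The single conditioning channel `c` (distinct from
#'   `target` and `source`).
#' @return A `causality_ratio` object.
#' @export
conditional_on_individual <- function(data, target, source, condition,
                                      E = 5, tau = 1, causal = TRUE,
                                      K = E + 1, min_neighbors = K) {
  tq <- resolve_col(rlang::enquo(target))
  sq <- resolve_col(rlang::enquo(source))
  cq <- resolve_col(rlang::enquo(condition))
  stopifnot(length(unique(c(tq, sq, cq))) == 3)
  causality_ratio_impl(data[, c(tq, sq, cq)], tq, sq, E, tau, causal, K,
                       min_neighbors)
}

#' @export
print.causality_ratio <- function(x, ...) {
  cat(sprintf("Causality ratio %s -> %s | {%s}: CR = %.4f  (var %.4g -> %.4g, n = %d)\n",
              x$from, x$to, paste(x$conditioning, collapse = ", "),
              x$cr, x$var_without, x$var_with, x$n))
  invisible(x)
}

#' Tidy a causality ratio
#' @param x A `causality_ratio` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.causality_ratio <- function(x, ...) {
  tibble(from = x$from, to = x$to, cr = x$cr, var_with = x$var_with,
         var_without = x$var_without,
         conditioning = paste(x$conditioning, collapse = ","),
         causal = x$causal, n = x$n)
}
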