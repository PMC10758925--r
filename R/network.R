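#' Directed pairwise causality matrix over many channels
#'
#' Evaluates the chosen causality metric for every ordered channel pair
#' (`Q * (Q - 1)` directed entries; the diagonal is masked). For the
#' cross-map metrics the network layer stores `|rho|`, since node
#' significance and pair selection are defined on magnitudes. A pair whose
#' metric is undefined (e.g. zero target variance) is masked as `NA` with
#' a warning rather than aborting the whole matrix.
#'
#' @param data A data frame of numeric channels (`Q >= 2`).
#' @param metric `"cccm"` (causal cross-mapping, the default), `"ccm"`
#'   (classical), or `"di"` (directed information per sample).
#' @param E,tau Embedding parameters for the cross-map metrics.
#' @param n_bins,strategy,order Quantizer and history settings for the DI
#'   metric (see [di_causation()]).
#' @return A `Q x Q` matrix of class `causality_matrix` (row = source,
#'   column = target, `NA` diagonal) with attribute `metric`. `tidy()`
#'   (long tibble of directed pairs) and `autoplot()` methods are
#'   provided.
#' @examples
#' ex <- generate_example("ex4", n = 300, seed = 1)
#' pairwise_matrix(ex, metric = "cccm")
#' @export
pairwise_matrix <- function(data, metric = c("cccm", "ccm", "di"),
                            E = 5, tau = 1, n_bins = 4,
                            strategy = "uniform", order = 1) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(data), ncol(data) >= 2)
  labels <- names(data)
  q <- length(labels)
  m <- matrix(NA_real_, q, q, dimnames = list(from = labels, to = labels))
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      val <- tryCatch({
        if (metric == "di") {
          estimate_di(quantize(data[[i]], n_bins, strategy),
                      quantize(data[[j]], n_bins, strategy),
                      order = order)$di_per_sample
        } else {
          abs(ccm_pair(data[[i]], data[[j]], E = E, tau = tau,
                       causal = metric == "cccm",
                       labels = c(labels[i], labels[j]))$rho)
        }
      }, error = function(e) {
        warn(paste0("pair ", labels[i], " -> ", labels[j], " masked: ",
                    conditionMessage(e)))
        NA_real_
      })
      m[i, j] <- val
    }
  }
  structure(m, class = c("causality_matrix", "matrix"), metric = metric,
            E = E, tau = tau)
}

#' @export
print.causality_matrix <- function(x, ...) {
  cat("Causality matrix (", attr(x, "metric"), "), ", nrow(x),
      " channels, ", sum(!is.na(x)), " directed pairs\n", sep = "")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Tidy a causality matrix into a long tibble of directed pairs
#' @param x A `causality_matrix`.
#' @param ... Unused.
#' @return A tibble with `from`, `to`, `value` (off-diagonal entries only).
#' @export
tidy.causality_matrix <- function(x, ...) {
  labels <- rownames(x)
  grid <- expand.grid(from = labels, to = labels,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  tibble(from = grid$from, to = grid$to,
         value = unclass(x)[cbind(grid$from, grid$to)],
         metric = attr(x, "metric"))
}

#' @export
autoplot.causality_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::labs(title = paste0("Directed ", attr(object, "metric"),
                                 " causality"),
                  x = "target", y = "source", fill = attr(object, "metric"))
}

#' Node transmitter/receiver significance
#'
#' Sums the magnitude of outgoing (transmit) and incoming (receive)
#' causation per node: `transmit(i) = sum_j |v(i -> j)|`,
#' `receive(j) = sum_i |v(i -> j)|`. Masked entries are treated as 0, with
#' a warning naming the affected count.
#'
#' @param matrix A `causality_matrix`.
#' @return A tibble with `node`, `transmit`, `receive`.
#' @export
node_significance <- function(matrix) {
  stopifnot(inherits(matrix, "causality_matrix"))
  m <- abs(unclass(matrix))
  diag(m) <- 0
  n_masked <- sum(is.na(m))
  if (n_masked > 0) {
    warn(paste0(n_masked, " masked entries treated as 0 in node sums"))
    m[is.na(m)] <- 0
  }
  tibble(node = rownames(m), transmit = unname(rowSums(m)),
         receive = unname(colSums(m)))
}

#' Select unidirectional pairs by thresholded directional differences
#'
#' Flags ordered pairs `(i, j)` whose causation exceeds the reverse
#' direction by more than the rule's thresholds in every required metric.
#' The `"resting"` rule asks for a cross-map asymmetry
#' `|rho_cCCM(i->j)| - |rho_cCCM(j->i)| > 0.15`; the `"task"` rule
#' requires the difference to exceed 0.1 for both CCM and cCCM and 0.01
#' for DI. Only the direction with the positive difference can satisfy a
#' rule, so `(j, i)` is never selected together with `(i, j)`.
#'
#' @param matrices A named list of `causality_matrix` objects sharing
#'   labels; the rule determines which of `cccm`, `ccm`, `di` must be
#'   present.
#' @param rule `"resting"` or `"task"`.
#' @param thresholds Named overrides for the rule thresholds
#'   (`cccm`, `ccm`, `di`).
#' @return A tibble with the selected `from`, `to`, the per-metric
#'   directional differences, ordered by the cCCM difference descending.
#' @export
select_unidirectional <- function(matrices, rule = c("resting", "task"),
                                  thresholds = NULL) {
  rule <- match.arg(rule)
  req <- switch(rule,
    resting = c(cccm = 0.15),
    task = c(ccm = 0.1, cccm = 0.1, di = 0.01)
  )
  if (!is.null(thresholds)) req[names(thresholds)] <- unlist(thresholds)
  missing <- setdiff(names(req), names(matrices))
  if (length(missing)) {
    abort(paste0("rule '", rule, "' needs matrices: ",
                 paste(missing, collapse = ", ")),
          class = "ccmdi_config_error")
  }
  labels <- rownames(matrices[[1]])
  for (m in matrices) {
    if (!identical(rownames(m), labels)) {
      abort("matrices must share channel labels",
            class = "ccmdi_config_error")
    }
  }
  grid <- expand.grid(from = labels, to = labels,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  diffs <- lapply(names(req), function(met) {
    m <- abs(unclass(matrices[[met]]))
    m[cbind(grid$from, grid$to)] - m[cbind(grid$to, grid$from)]
  })
  names(diffs) <- paste0("delta_", names(req))
  out <- tibble(from = grid$from, to = grid$to, !!!diffs)
  ok <- rep(TRUE, nrow(out))
  for (met in names(req)) {
    ok <- ok & !is.na(out[[paste0("delta_", met)]]) &
      out[[paste0("delta_", met)]] > req[[met]]
  }
  out <- out[ok, ]
  if ("delta_cccm" %in% names(out)) {
    out <- out[order(-out$delta_cccm), ]
  }
  attr(out, "rule") <- rule
  attr(out, "thresholds") <- req
  out
}
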