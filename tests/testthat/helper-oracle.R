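# Independent naive reimplementations (plain loops + sort) used as oracles
# for the fast package paths. These deliberately share no code with R/.

naive_embed <- function(x, E, tau) {
  n <- length(x)
  ts <- (1 + (E - 1) * tau):n
  emb <- matrix(NA_real_, length(ts), E)
  for (i in seq_along(ts)) {
    for (k in 0:(E - 1)) emb[i, k + 1] <- x[ts[i] - k * tau]
  }
  list(points = emb, t = ts)
}

naive_weights <- function(d) {
  if (d[1] == 0) {
    w <- as.numeric(d == 0)
    return(w / sum(w))
  }
  u <- exp(-d / d[1])
  u / sum(u)
}

naive_neighbors <- function(x, E, tau, query_t, K, causal) {
  e <- naive_embed(x, E, tau)
  i <- which(e$t == query_t)
  adm <- if (causal) which(e$t < query_t) else setdiff(seq_along(e$t), i)
  d <- numeric(length(adm))
  for (a in seq_along(adm)) {
    d[a] <- sqrt(sum((e$points[adm[a], ] - e$points[i, ])^2))
  }
  ord <- order(d, e$t[adm])
  sel <- ord[seq_len(min(K, length(ord)))]
  list(neighbor_t = e$t[adm][sel], distances = d[sel])
}

naive_crossmap <- function(x, y, E, tau, causal, K = E + 1,
                           min_neighbors = K) {
  e <- naive_embed(x, E, tau)
  ts <- e$t
  pred <- rep(NA_real_, length(ts))
  for (i in seq_along(ts)) {
    adm <- if (causal) which(ts < ts[i]) else setdiff(seq_along(ts), i)
    if (causal && length(adm) < min_neighbors) next
    if (length(adm) == 0) next
    d <- numeric(length(adm))
    for (a in seq_along(adm)) {
      d[a] <- sqrt(sum((e$points[adm[a], ] - e$points[i, ])^2))
    }
    ord <- order(d, ts[adm])
    sel <- ord[seq_len(min(K, length(ord)))]
    w <- naive_weights(d[sel])
    pred[i] <- sum(w * y[ts[adm]][sel])
  }
  keep <- !is.na(pred)
  list(t = ts[keep], pred = pred[keep],
       rho = stats::cor(y[ts[keep]], pred[keep]))
}

# brute-force plugin information measures over pasted string keys
naive_entropy <- function(keys) {
  p <- as.numeric(table(keys)) / length(keys)
  -sum(p * log2(p))
}

naive_mi <- function(a, b) {
  naive_entropy(paste(a)) + naive_entropy(paste(b)) -
    naive_entropy(paste(a, b))
}

naive_di <- function(xs, ys, m) {
  n <- length(xs)
  idx <- (m + 1):n
  ypast <- vapply(idx, function(i) {
    if (m == 0) "" else paste(ys[(i - m):(i - 1)], collapse = ",")
  }, character(1))
  xwin <- vapply(idx, function(i) paste(xs[(i - m):i], collapse = ","),
                 character(1))
  yi <- as.character(ys[idx])
  h_y_given_past <- naive_entropy(paste(yi, ypast)) - naive_entropy(ypast)
  h_y_given_past_x <- naive_entropy(paste(yi, ypast, xwin)) -
    naive_entropy(paste(ypast, xwin))
  h_y_given_past - h_y_given_past_x
}

# plugin block MI between the X window and the (Y_i, Y past) block: the
# chain rule makes this an exact upper bound for the truncated DI term
naive_block_mi <- function(xs, ys, m) {
  n <- length(xs)
  idx <- (m + 1):n
  ypast <- vapply(idx, function(i) {
    if (m == 0) "" else paste(ys[(i - m):(i - 1)], collapse = ",")
  }, character(1))
  xwin <- vapply(idx, function(i) paste(xs[(i - m):i], collapse = ","),
                 character(1))
  yblock <- paste(ys[idx], ypast)
  naive_mi(xwin, yblock)
}

example_ids <- c("ex1", "ex2", "ex3", "ex4", "ex5_1", "ex5_2",
                 "ex6_1", "ex6_2", "ex7_1", "ex7_2", "ex8_1", "ex8_2")
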