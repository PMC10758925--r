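test_that("simplex weights follow the exponential kernel", {
  expect_equal(compute_weights(rep(2, 4)), rep(0.25, 4))
  expect_equal(compute_weights(c(0, 1, 2)), c(1, 0, 0))
  u <- exp(-c(1, 2, 4) / 1)
  expect_equal(compute_weights(c(1, 2, 4)), u / sum(u))
  expect_equal(compute_weights(c(0, 0, 3)), c(0.5, 0.5, 0))
})

test_that("an exact duplicate of the query point is found at distance 0", {
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 4)
  m <- build_shadow_manifold(x, E = 2, tau = 1)
  nb <- find_neighbors(m, query_t = 8, K = 3, causal = FALSE)
  # t = 2 and t = 5 both repeat the (2, 1) delay vector exactly: the
  # zero-distance neighbours share all the weight uniformly
  expect_equal(nb$distances[1:2], c(0, 0))
  expect_equal(nb$neighbor_t[1:2], c(2, 5))
  expect_equal(nb$weights, c(0.5, 0.5, 0))
})

test_that("neighbour search matches the exhaustive sort oracle", {
  set.seed(21)
  x <- rnorm(30)
  m <- build_shadow_manifold(x, E = 2, tau = 1)
  for (qt in c(5, 14, 27)) {
    for (causal in c(FALSE, TRUE)) {
      got <- find_neighbors(m, qt, K = 4, causal = causal)
      want <- naive_neighbors(x, 2, 1, qt, 4, causal)
      expect_identical(got$neighbor_t, want$neighbor_t)
      expect_equal(got$distances, want$distances, tolerance = 1e-12)
    }
  }
})

test_that("causal neighbours all precede the query time", {
  set.seed(3)
  x <- rnorm(60)
  m <- build_shadow_manifold(x, E = 3, tau = 1)
  for (qt in c(10, 30, 60)) {
    nb <- find_neighbors(m, qt, K = 4, causal = TRUE)
    expect_true(all(nb$neighbor_t < qt))
  }
  expect_error(find_neighbors(m, m$time_index[1], K = 4, causal = TRUE),
               class = "ccmdi_neighbor_unavailable")
})

test_that("cross-mapping a constant target returns the constant", {
  set.seed(5)
  x <- rnorm(80)
  m <- build_shadow_manifold(x, E = 2, tau = 1)
  pred <- cross_map_predict(m, rep(3.5, 80), causal = FALSE)
  expect_equal(pred$predicted, rep(3.5, nrow(pred)))
})

test_that("self cross-mapping approaches a perfect map", {
  set.seed(6)
  x <- cumsum(rnorm(500)) # smooth series: self-map near exact
  fit <- ccm_self <- ccm(tibble::tibble(a = x, b = x), a, b, E = 2, tau = 1)
  expect_gte(fit$rho, 0.99)
})

test_that("the full pipeline matches the naive loop-and-sort oracle", {
  set.seed(31)
  x <- rnorm(40)
  y <- 0.6 * x + rnorm(40, sd = 0.4)
  for (causal in c(FALSE, TRUE)) {
    got <- suppressWarnings(
      ccm_pair <- ccm(tibble::tibble(x = x, y = y), x, y, E = 2, tau = 1,
                      causal = causal)
    )
    want <- naive_crossmap(x, y, 2, 1, causal)
    expect_equal(got$predictions$t, want$t)
    expect_equal(got$predictions$predicted, want$pred, tolerance = 1e-12)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
  }
})

test_that("zero-variance targets give an undefined-correlation error", {
  d <- tibble::tibble(x = rnorm(60), y = rep(1, 60))
  expect_error(ccm(d, x, y, E = 2), class = "ccmdi_undefined_correlation")
  expect_error(pearson_cor(d$y, d$x), class = "ccmdi_undefined_correlation")
})

test_that("pearson correlation matches the textbook formula and examples", {
  x <- c(2.1, -0.3, 1.7, 0.4, -1.2, 0.9, 2.6, -0.8, 0.1, 1.1)
  y <- c(1.0, 0.2, -0.5, 1.9, -2.2, 0.3, 1.8, -1.4, 0.6, 0.0)
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_cor(x, y), hand, tolerance = 1e-14)
  expect_equal(pearson_cor(x, x), 1)
  t <- seq(0, 2 * pi, by = 0.01 * pi)
  expect_lt(abs(pearson_cor(sin(t), cos(t))), 1e-10)
})

test_that("convergence curve at L = n reproduces the full-length causation", {
  ex <- generate_example("ex3")
  curve <- suppressWarnings(
    convergence_curve(ex, x, y, causal = FALSE, lengths = c(50, 100, 150, 201))
  )
  full <- ccm(ex, x, y, causal = FALSE)
  expect_equal(curve$rho[curve$L == 201], full$rho)
  # quadrature pair: skill is saturated at every library length
  expect_true(all(diff(curve$rho) > -0.02))
})

test_that("infeasible library lengths are skipped with a warning", {
  ex <- generate_example("ex3")
  expect_warning(
    curve <- convergence_curve(ex, x, y, E = 5, tau = 1,
                               lengths = c(6, 100, 201)),
    regexp = "skipped"
  )
  expect_equal(curve$L, c(100, 201))
})

test_that("CCM and cCCM convergence curves track each other on coupled Gaussians", {
  ex <- generate_example("ex1", seed = 4)
  L <- c(128, 256, 512, 1024)
  c1 <- convergence_curve(ex, x, y, causal = FALSE, lengths = L)
  c2 <- convergence_curve(ex, x, y, causal = TRUE, lengths = L)
  expect_true(all(abs(c1$rho - c2$rho) < 0.1))
})

test_that("periodic signals make CCM and cCCM agree closely", {
  ex <- generate_example("ex3")
  for (dir in list(c("x", "y"), c("y", "x"))) {
    a <- ccm(ex, !!dir[1], !!dir[2], causal = FALSE)$rho
    b <- ccm(ex, !!dir[1], !!dir[2], causal = TRUE)$rho
    expect_lt(abs(a - b), 0.06)
  }
})

test_that("runtime grows superlinearly with series length", {
  t_for <- function(n) {
    d <- generate_example("ex1", n = n, seed = 2)
    min(replicate(3, system.time(ccm(d, x, y))[["elapsed"]]))
  }
  expect_gt(t_for(2000) / max(t_for(500), 1e-4), 4)
})

test_that("tidy and glance summarise a fit", {
  ex <- generate_example("ex3")
  fit <- ccm(ex, x, y)
  td <- tidy(fit)
  expect_equal(td$from, "x")
  expect_equal(td$rho, fit$rho)
  expect_s3_class(glance(fit), "tbl_df")
})
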