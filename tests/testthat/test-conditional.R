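test_that("with two channels the estimate reduces to the bivariate cross-map", {
  set.seed(41)
  d <- generate_example("ex5_2", n = 200, seed = 2)
  pme <- per_manifold_estimates(d, y, E = 3, tau = 1)
  mx <- build_shadow_manifold(d$x, E = 3, tau = 1)
  biv <- cross_map_predict(mx, d$y)
  expect_equal(ncol(pme$estimates), 1)
  expect_equal(pme$time, biv$t)
  expect_equal(unname(pme$estimates[, 1]), biv$predicted)
})

test_that("identical channels cross-map each other almost exactly", {
  set.seed(42)
  base <- cumsum(rnorm(300))
  d <- tibble::tibble(a = base, b = base, c = base)
  pme <- per_manifold_estimates(d, a, E = 2, tau = 1)
  for (j in 1:2) {
    expect_gt(cor(pme$observed, pme$estimates[, j]), 0.99)
  }
})

test_that("three-channel estimates equal looped bivariate runs", {
  set.seed(43)
  d <- tibble::tibble(x = rnorm(60), y = rnorm(60), z = rnorm(60))
  pme <- suppressWarnings(per_manifold_estimates(d, y, E = 2, tau = 1))
  for (src in c("x", "z")) {
    m <- build_shadow_manifold(d[[src]], E = 2, tau = 1)
    biv <- cross_map_predict(m, d$y)
    expect_equal(unname(pme$estimates[, src]),
                 biv$predicted[match(pme$time, biv$t)])
  }
})

test_that("a single column equal to the target fits exactly", {
  y <- rnorm(50)
  est <- matrix(y, ncol = 1, dimnames = list(NULL, "x"))
  fit <- combine_estimates(y, est)
  expect_equal(unname(fit$coefficients), 1, tolerance = 1e-10)
  expect_lt(fit$residual_variance, 1e-20)
})

test_that("orthogonal predictors reproduce the normal-equations solution", {
  c1 <- rep(c(1, -1), 30)
  c2 <- rep(c(1, 1, -1, -1), 15)
  y <- 2 * c1 - 0.5 * c2
  est <- cbind(a = c1, b = c2)
  fit <- combine_estimates(y, est)
  # centered orthogonal columns: beta_j = <cj, y> / <cj, cj>
  expect_equal(unname(fit$coefficients["a"]), sum(c1 * y) / sum(c1 * c1),
               tolerance = 1e-10)
  expect_equal(unname(fit$coefficients["b"]), sum(c2 * y) / sum(c2 * c2),
               tolerance = 1e-10)
  expect_lt(fit$residual_variance, 1e-20)
})

test_that("excluding the informative source raises residual variance", {
  set.seed(44)
  x <- rnorm(100)
  est <- cbind(good = x + rnorm(100, sd = 0.1), junk = rnorm(100))
  y <- x
  with_all <- combine_estimates(y, est)
  without <- combine_estimates(y, est, exclude = "good")
  expect_gt(without$residual_variance, with_all$residual_variance)
})

test_that("collinear estimate columns are reported by name", {
  x <- rnorm(50)
  est <- cbind(a = x, b = 2 * x)
  expect_error(combine_estimates(rnorm(50), est),
               class = "ccmdi_collinearity_error")
})

test_that("chain system: coupled source dominates the noise source", {
  d <- generate_example("ex8_2", n = 800, seed = 7)
  d$z <- withr::with_seed(99, rnorm(800))
  cr_x <- causality_ratio(d, y, x)
  cr_z <- causality_ratio(d, y, z)
  expect_gt(cr_x$cr, 0.5)
  expect_lt(cr_z$cr, 0.1)
  expect_gt(cr_x$cr, 10 * max(cr_z$cr, 0.01))
})

test_that("duplicating a source collapses its causality ratio", {
  d <- generate_example("ex8_2", n = 800, seed = 8)
  d$z <- withr::with_seed(98, rnorm(800))
  base_cr <- causality_ratio(d, y, x)$cr
  d$x2 <- d$x + withr::with_seed(97, rnorm(800, sd = 0.01))
  dup_cr <- causality_ratio(d, y, x)$cr
  expect_lt(dup_cr, 0.05)
  expect_lt(dup_cr, base_cr / 5)
})

test_that("causality ratios are bounded and nonnegative on shared rows", {
  set.seed(45)
  for (rep in 1:5) {
    d <- tibble::tibble(x = rnorm(150), y = rnorm(150), z = rnorm(150))
    cr <- causality_ratio(d, y, x, E = 2)
    expect_lte(cr$cr, 1)
    expect_gte(cr$cr, -1e-10)
  }
})

test_that("single-conditioner ratios respect conditioner interdependence", {
  d <- generate_example("ex8_2", n = 800, seed = 9)
  d$indep <- withr::with_seed(96, rnorm(800))
  d$xcopy <- d$x + withr::with_seed(95, rnorm(800, sd = 0.05))
  cr_indep <- conditional_on_individual(d, y, x, indep)
  cr_shadow <- conditional_on_individual(d, y, x, xcopy)
  expect_gt(cr_indep$cr, cr_shadow$cr)
  expect_lt(cr_shadow$cr, 0.1)
  # CCM-mode and cCCM-mode conditioning agree on the ranking
  cc_indep <- conditional_on_individual(d, y, x, indep, causal = FALSE)
  cc_shadow <- conditional_on_individual(d, y, x, xcopy, causal = FALSE)
  expect_equal(order(c(cc_indep$cr, cc_shadow$cr)),
               order(c(cr_indep$cr, cr_shadow$cr)))
})

test_that("undefined ratios and missing channels error cleanly", {
  d <- tibble::tibble(x = rnorm(100), y = rnorm(100), z = rnorm(100))
  expect_error(causality_ratio(d, y, "w"), class = "ccmdi_domain_error")
})
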