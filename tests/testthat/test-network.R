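make_matrix <- function(vals, labels, metric = "cccm") {
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(from = labels, to = labels))
  m[cbind(vals$from, vals$to)] <- vals$v
  structure(m, class = c("causality_matrix", "matrix"), metric = metric)
}

test_that("an 18-channel matrix has 306 directed pairs", {
  set.seed(71)
  d <- tibble::as_tibble(as.data.frame(matrix(rnorm(18 * 60), ncol = 18)))
  m <- suppressWarnings(pairwise_matrix(d, metric = "cccm", E = 2))
  expect_equal(sum(!is.na(m)), 18 * 17)
  expect_true(all(is.na(diag(m))))
  expect_equal(nrow(tidy(m)), 306)
})

test_that("two channels reduce to the bivariate calls", {
  d <- generate_example("ex4", n = 300, seed = 2)
  m <- pairwise_matrix(d, metric = "cccm")
  expect_equal(m["x", "y"], abs(ccm(d, x, y)$rho))
  expect_equal(m["y", "x"], abs(ccm(d, y, x)$rho))
})

test_that("a four-channel matrix equals the looped bivariate oracle", {
  set.seed(72)
  d <- tibble::tibble(a = rnorm(80), b = rnorm(80), c = rnorm(80),
                      e = rnorm(80))
  m <- suppressWarnings(pairwise_matrix(d, metric = "ccm", E = 2))
  for (i in names(d)) {
    for (j in names(d)) {
      if (i == j) next
      expect_equal(m[i, j], abs(naive_crossmap(d[[i]], d[[j]], 2, 1,
                                               causal = FALSE)$rho),
                   tolerance = 1e-12)
    }
  }
})

test_that("node significance sums rows and columns of magnitudes", {
  vals <- expand.grid(from = c("a", "b", "c"), to = c("a", "b", "c"),
                      stringsAsFactors = FALSE)
  vals <- vals[vals$from != vals$to, ]
  vals$v <- c(0.2, 0.3, 0.1, 0.5, 0.4, 0.6)
  m <- make_matrix(vals, c("a", "b", "c"))
  ns <- node_significance(m)
  mm <- unclass(m); diag(mm) <- 0
  expect_equal(ns$transmit, unname(rowSums(mm)))
  expect_equal(ns$receive, unname(colSums(mm)))
  zero <- make_matrix(transform(vals, v = 0), c("a", "b", "c"))
  expect_true(all(node_significance(zero)$transmit == 0))
})

test_that("symmetric matrices have equal transmit and receive per node", {
  set.seed(73)
  labels <- c("p", "q", "r", "s")
  m0 <- matrix(runif(16), 4, 4, dimnames = list(labels, labels))
  m0 <- (m0 + t(m0)) / 2
  diag(m0) <- NA
  m <- structure(m0, class = c("causality_matrix", "matrix"),
                 metric = "cccm")
  ns <- node_significance(m)
  expect_equal(ns$transmit, ns$receive)
})

test_that("symmetric matrices yield an empty selection", {
  labels <- c("a", "b", "c")
  m0 <- matrix(0.4, 3, 3, dimnames = list(labels, labels))
  diag(m0) <- NA
  m <- structure(m0, class = c("causality_matrix", "matrix"),
                 metric = "cccm")
  sel <- select_unidirectional(list(cccm = m), rule = "resting")
  expect_equal(nrow(sel), 0)
})

test_that("an engineered asymmetric pair is selected under the task rule", {
  labels <- c("a", "b", "c")
  base <- expand.grid(from = labels, to = labels, stringsAsFactors = FALSE)
  base <- base[base$from != base$to, ]
  base$v <- 0.3
  mats <- list(ccm = make_matrix(base, labels, "ccm"),
               cccm = make_matrix(base, labels, "cccm"),
               di = make_matrix(transform(base, v = 0.1), labels, "di"))
  # push a -> b above the reverse direction by 0.2 / 0.2 / 0.02
  mats$ccm["a", "b"] <- 0.5
  mats$cccm["a", "b"] <- 0.5
  mats$di["a", "b"] <- 0.12
  sel <- select_unidirectional(mats, rule = "task")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$from, "a")
  expect_equal(sel$to, "b")
  # raising any threshold never adds a pair (monotone selection)
  sel2 <- select_unidirectional(mats, rule = "task",
                                thresholds = list(cccm = 0.25))
  expect_lte(nrow(sel2), nrow(sel))
  expect_true(all(paste(sel2$from, sel2$to) %in% paste(sel$from, sel$to)))
})

test_that("unidirectional simulated coupling is selected one way only", {
  d <- generate_example("ex4", n = 1024, seed = 5)
  m <- pairwise_matrix(d, metric = "cccm")
  sel <- select_unidirectional(list(cccm = m), rule = "resting")
  expect_equal(nrow(sel), 1)
  expect_equal(sel$from, "x")
  expect_equal(sel$to, "y")
})

test_that("the matrix is permutation-equivariant in channel order", {
  set.seed(74)
  d <- tibble::tibble(a = rnorm(100), b = rnorm(100), c = rnorm(100))
  m1 <- suppressWarnings(pairwise_matrix(d, metric = "ccm", E = 2))
  m2 <- suppressWarnings(pairwise_matrix(d[, c(3, 1, 2)], metric = "ccm",
                                         E = 2))
  expect_equal(unclass(m2)[names(d), names(d)], unclass(m1)[names(d), names(d)])
})

test_that("a rule without its required matrices is a configuration error", {
  labels <- c("a", "b")
  m0 <- matrix(c(NA, 0.1, 0.2, NA), 2, 2, dimnames = list(labels, labels))
  m <- structure(m0, class = c("causality_matrix", "matrix"),
                 metric = "cccm")
  expect_error(select_unidirectional(list(cccm = m), rule = "task"),
               class = "ccmdi_config_error")
})
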