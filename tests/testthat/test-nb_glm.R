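test_that("size factors match the hand-computed median-of-ratios example", {
  m <- rbind(c(10, 20), c(100, 200), c(4, 8))
  expect_equal(unname(estimate_size_factors(m)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-10)
  expect_equal(unname(estimate_size_factors(cbind(c(5, 7), c(5, 7)))),
               c(1, 1))
  expect_equal(unname(estimate_size_factors(matrix(c(3, 9), ncol = 1))), 1)
})

test_that("size factors agree with DESeq2 up to geometric-mean rescaling", {
  set.seed(1)
  m <- matrix(rnbinom(300 * 6, mu = 80, size = 10), 300, 6)
  m <- sweep(m, 2, c(1, 2, 0.5, 1.5, 1, 0.8), "*")
  storage.mode(m) <- "integer"
  ours <- estimate_size_factors(m)
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  ref <- ref / exp(mean(log(ref)))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("size factor invariances hold", {
  set.seed(2)
  m <- matrix(rnbinom(200 * 4, mu = 50, size = 5), 200, 4)
  sf <- estimate_size_factors(m)
  expect_equal(estimate_size_factors(m[sample(nrow(m)), ]), sf)
  m2 <- m
  m2[, 3] <- m2[, 3] * 4L
  sf2 <- estimate_size_factors(m2)
  # scaling one sample by c scales its factor by c (relative to others)
  expect_equal(sf2[3] / sf2[1], 4 * sf[3] / sf[1], tolerance = 1e-8)
  expect_error(estimate_size_factors(cbind(c(0, 5), c(5, 0))),
               "no gene has positive counts")
})

test_that("BH adjustment matches the worked example and p.adjust", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(3)
  for (n in c(1, 7, 100)) {
    p <- runif(n)^2
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  }
  p <- c(0.2, NA, 0.01)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
  expect_error(bh_adjust(c(0.5, 1.2)), "must lie")
})

test_that("intercept-only NB fit matches its closed form", {
  # with equal size factors the intercept MLE is log(mean(y)): the IRLS
  # weights cancel in the score equation
  y <- c(10L, 14L, 9L, 13L)
  fit <- fit_nb_glm(y, matrix(1, 4, 1), rep(1, 4), alpha = 0.1)
  expect_true(fit$converged)
  expect_equal(unname(fit$beta[1]), log(mean(y)), tolerance = 1e-7)
  # grid check that the returned beta maximizes the likelihood
  grid <- seq(log(mean(y)) - 0.3, log(mean(y)) + 0.3, length.out = 201)
  ll <- vapply(grid, function(b) {
    sum(dnbinom(y, mu = exp(b), size = 10, log = TRUE))
  }, numeric(1))
  expect_equal(unname(fit$beta[1]), grid[which.max(ll)], tolerance = 0.01)
})

test_that("all-zero genes are flagged degenerate, non-full-rank errors", {
  fit <- fit_nb_glm(c(0L, 0L, 0L), matrix(1, 3, 1), rep(1, 3), 0.1)
  expect_true(fit$degenerate)
  expect_error(fit_nb_glm(c(1L, 2L, 3L), cbind(1, c(2, 2, 2)), rep(1, 3),
                          0.1), "full rank")
})

test_that("LRT basics: identical designs error, nesting gives stat >= 0", {
  set.seed(4)
  x_full <- cbind(1, rep(c(0, 1), each = 4))
  x_red <- x_full[, 1, drop = FALSE]
  sf <- rep(1, 8)
  same <- fit_nb_glm(rnbinom(8, mu = 50, size = 10), x_full, sf, 0.1)
  expect_error(nb_lrt(same, same), "fewer coefficients")
  for (i in 1:25) {
    y <- rnbinom(8, mu = 50, size = 10)
    lr <- nb_lrt(fit_nb_glm(y, x_full, sf, 0.1),
                 fit_nb_glm(y, x_red, sf, 0.1))
    expect_gte(lr$stat, 0)
    expect_true(lr$p >= 0 && lr$p <= 1)
  }
})

test_that("nested deviance never increases when parameters are added", {
  set.seed(5)
  x_full <- cbind(1, rep(c(0, 1), each = 4), rnorm(8))
  sf <- exp(rnorm(8, 0, 0.1))
  for (i in 1:25) {
    y <- rnbinom(8, mu = 60, size = 8)
    d2 <- fit_nb_glm(y, x_full[, 1:2], sf, 0.1)$deviance
    d3 <- fit_nb_glm(y, x_full, sf, 0.1)$deviance
    d1 <- fit_nb_glm(y, x_full[, 1, drop = FALSE], sf, 0.1)$deviance
    expect_lte(d2, d1 + 1e-6)
    expect_lte(d3, d2 + 1e-6)
  }
})

test_that("dispersion estimator recovers Poisson and alpha = 0.1 data", {
  set.seed(6)
  n <- 1500
  g <- factor(rep(1:2, each = 4))
  sf <- rep(1, 8)
  a_pois <- estimate_dispersion(matrix(rpois(n * 8, 200), n), sf, g)
  expect_lte(median(a_pois), 0.01)
  a_nb <- estimate_dispersion(matrix(rnbinom(n * 8, mu = 200, size = 10),
                                     n), sf, g)
  expect_gte(median(a_nb), 0.05)
  expect_lte(median(a_nb), 0.2)
  # constant counts: zero excess variance pins the estimate at the floor
  m <- matrix(rnbinom(n * 8, mu = 100, size = 20), n)
  m[7, ] <- 50L
  a <- estimate_dispersion(m, sf, g)
  expect_equal(a[7], 1e-8)
  expect_error(estimate_dispersion(m[, 1:2], sf[1:2],
                                   factor(c(1, 2))), "insufficient")
})

test_that("Wald DE recovers a simulated 2-fold effect", {
  # the fold is spiked into a subset of genes only: a global fold would
  # be absorbed by the size factors by construction
  set.seed(7)
  n <- 500
  cond <- factor(rep(c("L", "LE"), each = 4), levels = c("L", "LE"))
  spike <- seq_len(50)
  fold <- rep(1, n); fold[spike] <- 2
  mu <- outer(fold, ifelse(cond == "LE", 1, 0)) * 150 +
    outer(rep(1, n), ifelse(cond == "LE", 0, 1)) * 150
  counts <- matrix(rnbinom(n * 8, mu = mu, size = 1 / 0.05), n)
  res <- nb_wald_de(counts, cond)
  expect_equal(mean(res$log2FC[spike]), 1, tolerance = 0.1)
  expect_lt(max(abs(res$log2FC[spike] - 1)), 1)
  expect_gte(mean(res$padj[spike] < 0.01), 0.6)
  expect_lte(mean(res$padj[-spike] < 0.01, na.rm = TRUE), 0.02)
})

test_that("LRT p-values are approximately uniform under the null", {
  set.seed(8)
  n <- 600
  x_full <- cbind(1, rep(c(0, 1), each = 6))
  x_red <- x_full[, 1, drop = FALSE]
  sf <- rep(1, 12)
  p <- vapply(seq_len(n), function(i) {
    y <- rnbinom(12, mu = 150, size = 20)
    nb_lrt(fit_nb_glm(y, x_full, sf, 0.05),
           fit_nb_glm(y, x_red, sf, 0.05))$p
  }, numeric(1))
  expect_lt(suppressWarnings(ks.test(p, "punif")$statistic), 0.05)
})
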