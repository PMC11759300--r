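test_that("parallel analysis retains nothing under the null, one strong factor otherwise", {
  k0 <- vapply(1:8, function(s) {
    x <- with_seed_matrix(s, 473, 48)
    parallel_analysis(x, seed = s + 100)$n_factors
  }, integer(1))
  expect_gte(mean(k0 == 0L), 0.9)

  k1 <- vapply(1:8, function(s) {
    set.seed(s)
    f <- rnorm(300)
    x <- outer(f, rep(0.8, 20)) + matrix(rnorm(300 * 20, 0, 0.6), 300, 20)
    colnames(x) <- paste0("v", 1:20)
    parallel_analysis(tibble::as_tibble(x), seed = s + 100)$n_factors
  }, integer(1))
  expect_gte(mean(k1 == 1L), 0.9)

  expect_error(parallel_analysis(tibble::tibble(a = 1:2, b = 2:3)), "at least 3")
})

test_that("maximum-likelihood fit with oblimin recovers an orthogonal 2-factor pattern", {
  set.seed(7)
  n <- 400
  lam <- cbind(c(rep(0.7, 6), rep(0, 6)), c(rep(0, 6), rep(0.7, 6)))
  f <- matrix(rnorm(n * 2), n, 2)
  x <- f %*% t(lam) + matrix(rnorm(n * 12, 0, sqrt(1 - 0.49)), n, 12)
  colnames(x) <- paste0("v", 1:12)
  fm <- fit_factor_model(tibble::as_tibble(x), n_factors = 2)
  cong <- abs(t(lam) %*% fm$loadings /
                outer(sqrt(colSums(lam^2)), sqrt(colSums(fm$loadings^2))))
  expect_gte(min(apply(cong, 1, max)), 0.95)
  expect_true(all(fm$uniquenesses >= 0 & fm$uniquenesses <= 1))
  expect_gt(fm$cumulative_variance, 0)
})

test_that("the saturated factor count is rejected and refits are deterministic", {
  x <- simulate_feature_matrix(200, seed = 9)
  expect_error(fit_factor_model(x, n_factors = 40), "degrees of freedom")
  f1 <- suppressWarnings(fit_factor_model(x, n_factors = 5))
  f2 <- suppressWarnings(fit_factor_model(x, n_factors = 5))
  expect_equal(f1$loadings, f2$loadings)
})

test_that("constant feature columns are rejected", {
  x <- simulate_feature_matrix(100, seed = 2)
  x$density_RTEMP <- 1
  expect_error(fit_factor_model(x, n_factors = 3), "constant feature")
})

test_that("tenBerge scores are centered, unit-scaled and correlation-preserving", {
  x <- simulate_feature_matrix(473, seed = 4)
  fm <- suppressWarnings(fit_factor_model(x, n_factors = 10))
  sc <- as.matrix(factor_scores(fm))
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  expect_equal(unname(apply(sc, 2, sd)), rep(1, 10), tolerance = 1e-6)
  expect_lt(max(abs(cor(sc) - fm$Phi)), 0.1)
  # duplicated record gives a duplicated score row
  sc2 <- factor_scores(fm, x[c(1, 1), ])
  expect_equal(sc2[1, ], sc2[2, ])
})

test_that("loadings are invariant to affine rescaling of input features", {
  x <- simulate_feature_matrix(300, seed = 6)
  f1 <- suppressWarnings(fit_factor_model(x, n_factors = 4))
  x2 <- x
  x2$ge_beta <- 100 * x2$ge_beta - 7
  x2$density_LABD <- 0.01 * x2$density_LABD + 3
  f2 <- suppressWarnings(fit_factor_model(x2, n_factors = 4))
  expect_equal(f1$loadings, f2$loadings, tolerance = 1e-6)
})

test_that("primary components apply the absolute 0.3 threshold convention", {
  x <- simulate_feature_matrix(300, seed = 8)
  fm <- suppressWarnings(fit_factor_model(x, n_factors = 10))
  fake <- fm
  fake$loadings[, ] <- 0
  fake$loadings[1, 1] <- 0.31
  fake$loadings[2, 1] <- 0.29
  fake$loadings[3, 1] <- -0.35
  pc <- suppressWarnings(primary_components(fake))
  got <- pc$feature[pc$factor == "factor1"]
  expect_setequal(got, rownames(fake$loadings)[c(1, 3)])
  expect_equal(got[1], rownames(fake$loadings)[3])  # descending |loading|

  expect_warning(out <- primary_components(fm, threshold = 1.01), "no feature")
  expect_equal(nrow(out), 0L)
  all_in <- primary_components(fm, threshold = 0)
  expect_equal(nrow(all_in), 48L * 10L)
})

test_that("the full chain recovers the generating latent structure", {
  congs <- vapply(1:5, function(s) {
    x <- simulate_feature_matrix(473, seed = s)
    k <- parallel_analysis(x, seed = s + 500)$n_factors
    fm <- suppressWarnings(fit_factor_model(x, n_factors = k))
    pat <- latent_pattern()
    gen <- sweep(pat, 2, ifelse(colSums(pat) <= 3, 0.85, 0.8), `*`)
    cong <- abs(t(gen) %*% fm$loadings /
                  outer(sqrt(colSums(gen^2)), sqrt(colSums(fm$loadings^2))))
    min(apply(cong[, seq_len(min(10, k)), drop = FALSE], 1, max))
  }, numeric(1))
  expect_gte(median(congs), 0.9)
})
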