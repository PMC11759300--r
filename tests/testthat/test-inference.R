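test_that("F1 is the harmonic mean of precision and recall", {
  expect_equal(f1_score(0.84, 0.87), 2 * 0.84 * 0.87 / (0.84 + 0.87))
  expect_equal(f1_score(1, 1), 1)
  expect_true(is.na(f1_score(0, 0)))
})

test_that("mixed-effects disease models report tests, contrasts and R2", {
  cohort <- generate_cohort(cohort_config(6, 0, 6, seed = 2))
  f <- simulate_feature_matrix(cohort = cohort, sentences_per_subject = 6, seed = 2)
  m <- suppressWarnings(fit_lme_nodal(f, "density"))
  expect_setequal(m$anova$effect, c("group", "node", "group:node"))
  expect_equal(nrow(m$contrasts), 6L)
  expect_true(all(m$contrasts$adj.p.value >= m$contrasts$p.value))
  expect_gte(m$r2["conditional"], m$r2["marginal"])
  expect_lt(m$anova$p.value[m$anova$effect == "group"], 0.05)

  e <- suppressWarnings(fit_lme_edgewise(f, "nodstr"))
  expect_setequal(e$anova$effect, c("group", "band", "group:band"))
  expect_equal(nrow(e$contrasts), 3L)
  expect_gte(e$r2["conditional"], e$r2["marginal"])
})

test_that("degenerate inputs to the disease models raise errors", {
  cohort <- generate_cohort(cohort_config(3, 0, 3, seed = 1))
  f <- simulate_feature_matrix(cohort = cohort, sentences_per_subject = 3, seed = 1)
  f[paste0("density_", MN_CHANNELS)] <- 1
  expect_error(suppressWarnings(fit_lme_nodal(f, "density")), "zero variance")
  f2 <- simulate_feature_matrix(cohort = cohort[cohort$group == "ALS", ],
                                sentences_per_subject = 3, seed = 1)
  expect_error(fit_lme_nodal(f2, "density"), "both groups")
})

test_that("an all-zero band still yields finite contrasts", {
  cohort <- generate_cohort(cohort_config(4, 0, 4, seed = 3))
  f <- simulate_feature_matrix(cohort = cohort, sentences_per_subject = 4, seed = 3)
  f$nodstr_gamma <- 0
  m <- suppressWarnings(fit_lme_edgewise(f, "nodstr"))
  expect_true(all(is.finite(m$contrasts$statistic[m$contrasts$level != "gamma"])))
})

test_that("backward stepwise keeps true predictors and drops noise", {
  res <- vapply(1:30, function(s) {
    set.seed(s)
    n_sub <- 20; n_rec <- 10
    subj <- rep(sprintf("S%02d", 1:n_sub), each = n_rec)
    f <- matrix(rnorm(n_sub * n_rec * 4), ncol = 4,
                dimnames = list(NULL, paste0("factor", 1:4)))
    y <- 2 * f[, 1] + rep(rnorm(n_sub, 0, 0.5), each = n_rec) + rnorm(n_sub * n_rec)
    d <- dplyr::bind_cols(tibble::tibble(subject_id = subj, stiffness = y),
                          tibble::as_tibble(f))
    sw <- stepwise_lme(d, "stiffness")
    c("factor1" %in% sw$selected,
      mean(paste0("factor", 2:4) %in% sw$selected),
      sw$r2["conditional"] >= sw$r2["marginal"])
  }, numeric(3))
  expect_gte(mean(res[1, ]), 0.9)
  expect_lte(mean(res[2, ]), 0.2)
  expect_true(all(res[3, ] == 1))
})

test_that("a near-deterministic outcome yields marginal R2 above 0.95", {
  set.seed(2)
  f <- matrix(rnorm(200 * 3), ncol = 3, dimnames = list(NULL, paste0("factor", 1:3)))
  d <- dplyr::bind_cols(
    tibble::tibble(subject_id = rep(sprintf("S%d", 1:20), each = 10),
                   acceleration_time = f[, 1] + 0.01 * rnorm(200)),
    tibble::as_tibble(f)
  )
  sw <- suppressWarnings(stepwise_lme(d, "acceleration_time"))
  expect_gt(sw$r2["marginal"], 0.95)
})

test_that("classification separates well-separated groups perfectly", {
  d <- scored_groups(1, delta = 8)
  for (alg in c("rf", "svm", "knn")) {
    rep <- classify_factors(d, alg, repeats = 2, seed = 5)
    expect_gte(rep$metrics$auc, 0.999)
    expect_gte(rep$metrics$f1, 0.99)
  }
})

test_that("classifier reports keep the F1 identity and valid ranges", {
  d <- scored_groups(2, delta = 1)
  rep <- classify_factors(d, "rf", repeats = 3, seed = 6)
  m <- rep$metrics
  expect_equal(m$f1, f1_score(m$precision, m$recall), tolerance = 1e-12)
  expect_true(all(unlist(m[c("auc", "f1", "precision", "recall")]) >= 0 &
                    unlist(m[c("auc", "f1", "precision", "recall")]) <= 1))
  expect_equal(nrow(rep$per_repeat), 3L)
})

test_that("subject grouping keeps a subject's records in one fold", {
  d <- scored_groups(3, delta = 1)
  rep <- classify_factors(d, "knn", repeats = 2, seed = 7)
  for (r in 1:2) {
    folds <- tapply(rep$fold_assignments[, r], d$subject_id,
                    function(v) length(unique(v)))
    expect_true(all(folds == 1L))
  }
})

test_that("impossible stratification is an error", {
  d <- scored_groups(4, n_sub = 6, delta = 1)  # 3 subjects per class < 5 folds
  expect_error(classify_factors(d, "knn", seed = 1), "fewer subjects than folds")
})

test_that("permuted labels give chance-level AUC", {
  aucs <- vapply(1:6, function(s) {
    d <- scored_groups(s, delta = 0)
    classify_factors(d, "knn", repeats = 2, seed = s)$metrics$auc
  }, numeric(1))
  expect_lt(abs(median(aucs) - 0.5), 0.1)
})
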