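test_that("cohort generation matches the study composition and is seeded", {
  cohort <- generate_cohort(cohort_config(seed = 1))
  expect_equal(nrow(cohort), 25L)
  expect_equal(sum(cohort$group == "ALS"), 15L)
  expect_equal(sum(cohort$stage == "prodromal"), 7L)
  expect_equal(sum(cohort$stage == "symptomatic"), 8L)
  expect_identical(cohort, generate_cohort(cohort_config(seed = 1)))
  expect_false(identical(cohort, generate_cohort(cohort_config(seed = 2))))
  expect_error(generate_cohort(cohort_config(0, 0, 0)), "zero subjects")
})

test_that("control profiles are the identity; ALS profiles drawn around stage means", {
  cohort <- generate_cohort(cohort_config(seed = 3))
  ctrl <- cohort[cohort$group == "control", ]
  expect_true(all(ctrl$amplitude_scale == 1))
  expect_true(all(ctrl$envelope_cv_scale == 1))
  expect_true(all(ctrl$coupling_beta == 1))
  sym <- cohort[cohort$stage == "symptomatic", ]
  pro <- cohort[cohort$stage == "prodromal", ]
  expect_lt(mean(sym$amplitude_scale), mean(pro$amplitude_scale))
  expect_gt(mean(sym$envelope_cv_scale), mean(pro$envelope_cv_scale))
  expect_lt(mean(sym$coupling_beta), mean(pro$coupling_beta))
})

test_that("effect profile validation enforces its ranges", {
  expect_error(effect_profile(amplitude_scale = 0), "amplitude_scale")
  expect_error(effect_profile(envelope_cv_scale = 0.5), "envelope_cv_scale")
  expect_error(effect_profile(coupling_scale = 1.5), "coupling_scale")
  expect_error(effect_profile(right_left_asymmetry = 2), "asymmetry")
  expect_error(effect_profile(kinematic_slowing = 0.5), "kinematic_slowing")
})

test_that("simulated recordings are seeded, sized and validated", {
  r1 <- simulate_semg(effect_profile(), 3, seed = 5)
  r2 <- simulate_semg(effect_profile(), 3, seed = 5)
  expect_identical(r1$samples, r2$samples)
  expect_equal(dim(r1$samples), c(6L, 6000L))
  expect_error(simulate_semg(effect_profile(), 1), "at least 2 s")
  expect_error(simulate_semg(effect_profile(), 3, fs = 100), "30-60 Hz")
})

test_that("amplitude scaling is linear in the envelope-driven component", {
  kw <- list(line_amplitude = 0, dc_offset = 0, noise_sd = 0, crosstalk_leak = 0)
  r1 <- do.call(simulate_semg,
                c(list(effect_profile(coupling_scale = 0), 3, seed = 5), kw))
  r05 <- do.call(simulate_semg,
                 c(list(effect_profile(amplitude_scale = 0.5, coupling_scale = 0),
                        3, seed = 5), kw))
  expect_equal(sd(r05$samples[1, ]) / sd(r1$samples[1, ]), 0.5, tolerance = 1e-6)
})

test_that("preprocessed simulated channels keep >= 90% power in 20-500 Hz", {
  rec <- preprocess_semg(simulate_semg(effect_profile(), 4, seed = 8))
  for (i in c(1L, 4L)) {
    sp <- stats::spec.pgram(stats::ts(rec$samples[i, ], frequency = 2000),
                            spans = 11, plot = FALSE)
    frac <- sum(sp$spec[sp$freq >= 20 & sp$freq <= 500]) / sum(sp$spec)
    expect_gte(frac, 0.9)
  }
})

test_that("jaw traces respond to slowing and support the pure-sinusoid mode", {
  med_ma <- vapply(c(1, 1.5, 2), function(ks) {
    median(vapply(1:6, function(s) {
      tr <- simulate_jaw(effect_profile(kinematic_slowing = ks), 5, seed = s)
      jaw_kinematic_metrics(tr)$mean_acceleration
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(med_ma) < 0))

  tr0 <- simulate_jaw(effect_profile(), 5, seed = 1, amplitude = 0)
  expect_lt(sd(distance_series(tr0)), 1e-10)
  expect_identical(simulate_jaw(effect_profile(), 5, seed = 2)$x,
                   simulate_jaw(effect_profile(), 5, seed = 2)$x)
})

test_that("the latent feature generator reproduces its factor structure", {
  x <- simulate_feature_matrix(300, seed = 1)
  expect_equal(dim(x), c(300L, 48L))
  expect_named(x, mn_feature_names())
  expect_identical(as.matrix(simulate_feature_matrix(50, seed = 2)),
                   as.matrix(simulate_feature_matrix(50, seed = 2)))
  # features of one factor correlate more within than across blocks
  cm <- cor(as.matrix(x))
  dens <- grep("^density_", colnames(x))
  wccg <- grep("^wcc_.*_gamma$", colnames(x))
  within <- mean(cm[dens, dens][upper.tri(diag(length(dens)))])
  across <- mean(cm[dens, wccg])
  expect_gt(within, across + 0.2)
})

test_that("cohort-structured features carry group effects and ids", {
  cohort <- generate_cohort(cohort_config(seed = 5))
  f <- simulate_feature_matrix(cohort = cohort, sentences_per_subject = 4, seed = 5)
  expect_equal(nrow(f), 100L)
  expect_true(all(c("subject_id", "group", "stage", "sentence") %in% names(f)))
  agg <- tapply(f$nodstr_beta, f$group, mean)
  expect_lt(agg[["ALS"]], agg[["control"]])
})
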