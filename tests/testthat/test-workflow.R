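small_config <- function(seed = 42) {
  cohort_config(2, 1, 1, sentences_per_subject = 2, sentence_duration_s = 4,
                seed = seed)
}

test_that("the pipeline is deterministic and produces the full feature table", {
  cfg <- small_config()
  r1 <- suppressWarnings(run_pipeline(cfg, stages = c("features", "kinematics")))
  r2 <- suppressWarnings(run_pipeline(cfg, stages = c("features", "kinematics")))
  expect_identical(r1$features, r2$features)
  expect_identical(r1$kinematics, r2$kinematics)
  # byte-identical on disk
  f1 <- tempfile(); f2 <- tempfile()
  utils::write.table(r1$features, f1, sep = "\t", row.names = FALSE)
  utils::write.table(r2$features, f2, sep = "\t", row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  feats <- musclenet:::feature_columns(r1$features)
  expect_equal(length(feats), 48L)
  expect_identical(feats, mn_feature_names())
  expect_equal(nrow(r1$features), 8L)
  expect_equal(nrow(r1$run_log) >= 2L, TRUE)
  expect_true(all(c("acceleration_time", "mean_acceleration", "stiffness") %in%
                    names(r1$kinematics)))
})

test_that("dropped recordings shrink the manifest deterministically", {
  cfg <- cohort_config(2, 1, 1, sentences_per_subject = 3,
                       sentence_duration_s = 4, seed = 9, drop_recordings = 2)
  man1 <- musclenet:::recording_manifest(generate_cohort(cfg), cfg)
  man2 <- musclenet:::recording_manifest(generate_cohort(cfg), cfg)
  expect_equal(nrow(man1), 4L * 3L - 2L)
  expect_identical(man1, man2)
})

test_that("recordings and jaw traces round-trip through the delimited format", {
  td <- withr::local_tempdir()
  rec <- simulate_semg(effect_profile(), 3, seed = 1, subject_id = "S01",
                       sentence_id = 2L, group_label = "control",
                       stage_label = "control")
  p <- write_semg_recording(rec, td)
  rec2 <- read_semg_recording(p)
  expect_lt(max(abs(rec$samples - rec2$samples)), 1e-4)
  expect_equal(rec2$subject_id, "S01")
  expect_equal(rec2$sentence_id, 2L)
  expect_equal(rec2$fs, 2000)

  tr <- simulate_jaw(effect_profile(), 4, seed = 1)
  pj <- write_jaw_trace(tr, td, "jaw1")
  tr2 <- read_jaw_trace(pj)
  expect_lt(max(abs(tr$x - tr2$x)), 1e-4)
  expect_equal(attr(tr2, "reference"), attr(tr, "reference"))
})

test_that("input validation flags channel, order and rate problems", {
  td <- withr::local_tempdir()
  rec <- simulate_semg(effect_profile(), 3, seed = 2)
  good <- write_semg_recording(rec, td, "good")
  expect_equal(nrow(validate_inputs(good)), 0L)

  bad5 <- file.path(td, "bad5.tsv")
  utils::write.table(matrix(rnorm(500), 100, 5), bad5, sep = "\t",
                     row.names = FALSE)
  iss <- validate_inputs(bad5)
  expect_true("channels" %in% iss$check)

  # fs mismatch between sidecar metadata and implied rate
  meta <- jsonlite::read_json(sub("[.]tsv$", ".json", good))
  meta$duration_s <- 30
  jsonlite::write_json(meta, sub("[.]tsv$", ".json", good), auto_unbox = TRUE)
  expect_true("fs" %in% validate_inputs(good)$check)

  expect_true("exists" %in% validate_inputs(file.path(td, "nope.tsv"))$check)
})

test_that("the CLI drives simulate, features and kinematics end to end", {
  td <- withr::local_tempdir()
  cfgf <- file.path(td, "cfg.json")
  jsonlite::write_json(list(n_control = 1, n_als_prodromal = 0,
                            n_als_symptomatic = 1, sentences_per_subject = 1,
                            sentence_duration_s = 3, seed = 9),
                       cfgf, auto_unbox = TRUE)
  out <- file.path(td, "out"); dir.create(out)
  expect_equal(musclenet_cli(c("simulate", "--config", cfgf, "--out", out)), 0L)
  tsvs <- list.files(out, pattern = "sent01[.]tsv$", full.names = TRUE)
  expect_equal(length(tsvs), 2L)
  expect_equal(musclenet_cli(c("features", "--out", out, tsvs)), 0L)
  feats <- utils::read.table(file.path(out, "features.tsv"), header = TRUE,
                             sep = "\t", check.names = FALSE)
  expect_equal(nrow(feats), 2L)
  expect_true(all(mn_feature_names() %in% colnames(feats)))
  jt <- list.files(out, pattern = "jaw[.]tsv$", full.names = TRUE)
  expect_equal(musclenet_cli(c("kinematics", "--out", out, jt)), 0L)
  expect_equal(musclenet_cli("bogus"), 1L)
})

test_that("tidiers and plots cover the fitted objects", {
  x <- simulate_feature_matrix(250, seed = 3)
  fm <- suppressWarnings(fit_factor_model(x, n_factors = 10))
  expect_equal(nrow(generics::tidy(fm)), 480L)
  gl <- generics::glance(fm)
  expect_equal(gl$n_factors, 10L)
  expect_true(gl$cumulative_variance > 0 && gl$cumulative_variance <= 1)
  expect_s3_class(ggplot2::autoplot(fm), "ggplot")

  net <- multiplex_weights(preprocess_semg(simulate_semg(effect_profile(), 4,
                                                         seed = 6)))
  expect_s3_class(plot_network(net), "ggplot")

  d <- scored_groups(5, delta = 2)
  rep <- classify_factors(d, "knn", repeats = 2, seed = 8)
  expect_s3_class(ggplot2::autoplot(rep), "ggplot")
  expect_equal(nrow(generics::tidy(rep)), 2L)

  cohort <- generate_cohort(cohort_config(4, 0, 4, seed = 4))
  f <- simulate_feature_matrix(cohort = cohort, sentences_per_subject = 4, seed = 4)
  m <- suppressWarnings(fit_lme_nodal(f, "density"))
  td <- generics::tidy(m)
  expect_true(all(c("anova", "contrast") %in% td$type))
  expect_s3_class(plot_feature_profiles(f), "ggplot")
})
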