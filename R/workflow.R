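# End-to-end orchestration: simulate -> preprocess -> features -> factors
# -> inference, plus delimited-file IO, input validation and the CLI
# entry point.

#' Extract the 48-feature vector of one recording
#'
#' Preprocesses (optionally) and computes the 12 nodal plus 36 edgewise
#' features.
#'
#' @param rec A `semg_recording`.
#' @param preprocess Run [preprocess_semg()] first (default TRUE).
#' @param bss Crosstalk-suppression toggle passed through.
#' @param window_len Local-SD window (samples).
#' @return One-row tibble: id columns then the 48 features.
#' @export
extract_features <- function(rec, preprocess = TRUE, bss = TRUE, window_len = 100L) {
  rec <- as_semg_recording(rec)
  if (preprocess) rec <- preprocess_semg(rec, bss = bss)
  nodal <- nodal_features(rec, window_len)
  edge <- edgewise_features(multiplex_weights(rec))
  dplyr::bind_cols(
    tibble::tibble(subject_id = rec$subject_id, group = rec$group_label,
                   stage = rec$stage_label, sentence = rec$sentence_id),
    nodal, edge
  )
}

# Recording-level manifest: one row per (subject, sentence), minus any
# dropped recordings.
recording_manifest <- function(cohort, config) {
  man <- tidyr::expand_grid(
    si = seq_len(nrow(cohort)),
    sentence = seq_len(config$sentences_per_subject)
  )
  man <- dplyr::bind_cols(cohort[man$si, ], man[c("si", "sentence")])
  if (config$drop_recordings > 0L) {
    drop <- with_seed(derive_seed(config$seed, 777L),
                      sample(nrow(man), min(config$drop_recordings, nrow(man))))
    man <- man[-drop, ]
  }
  man
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates the cohort manifest, simulates and processes each sentence
#' recording (sEMG features and jaw kinematics), and optionally fits the
#' factor model and the inference stages. Fully deterministic for a fixed
#' config: every recording derives its own seed stream from
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param stages Subset of `c("features", "kinematics", "factors",
#'   "inference", "classify")`; earlier stages required by later ones are
#'   implied.
#' @param n_factors Factor count for the factor stage (`NULL` = parallel
#'   analysis).
#' @param verbose Emit progress messages.
#' @return An object of class `musclenet_run`: list with `cohort`,
#'   `features`, `kinematics`, `factor_model`, `scores`, `lme`,
#'   `classifiers` (stages not run are NULL) and a `run_log` tibble.
#' @export
run_pipeline <- function(config = cohort_config(),
                         stages = c("features", "kinematics", "factors"),
                         n_factors = NULL, verbose = FALSE) {
  all_stages <- c("features", "kinematics", "factors", "inference", "classify")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  if (any(c("factors", "inference", "classify") %in% stages)) {
    stages <- union(stages, "features")
  }
  say <- function(...) if (verbose) inform(sprintf(...))
  log_rows <- list(tibble::tibble(stage = "config", seed = config$seed,
                                  hash = rlang::hash(unclass(config))))
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
            parent = e)
    })
  }
  cohort <- wrap_stage("cohort", generate_cohort(config))
  man <- recording_manifest(cohort, config)
  features <- NULL
  if ("features" %in% stages) {
    say("features: %d recordings", nrow(man))
    features <- wrap_stage("features", dplyr::bind_rows(
      purrr::map(seq_len(nrow(man)), function(r) {
        row <- man[r, ]
        rec <- simulate_semg(
          manifest_profile(row), duration = config$sentence_duration_s,
          fs = config$fs_semg, seed = derive_seed(config$seed, row$si, row$sentence),
          subject_id = row$subject_id, sentence_id = row$sentence,
          group_label = row$group, stage_label = row$stage
        )
        extract_features(rec)
      })
    ))
  }
  kinematics <- NULL
  if ("kinematics" %in% stages) {
    say("kinematics: %d recordings", nrow(man))
    kinematics <- wrap_stage("kinematics", dplyr::bind_rows(
      purrr::map(seq_len(nrow(man)), function(r) {
        row <- man[r, ]
        tr <- simulate_jaw(
          manifest_profile(row), duration = config$sentence_duration_s,
          fs = config$fs_kin,
          seed = derive_seed(config$seed, 5000L + row$si, row$sentence)
        )
        dplyr::bind_cols(
          tibble::tibble(subject_id = row$subject_id, group = row$group,
                         stage = row$stage, sentence = row$sentence),
          jaw_kinematic_metrics(tr)
        )
      })
    ))
  }
  factor_model <- NULL; scores <- NULL
  if ("factors" %in% stages) {
    say("factors")
    factor_model <- wrap_stage("factors", fit_factor_model(
      features, n_factors = n_factors, seed = derive_seed(config$seed, 9001L)
    ))
    scores <- dplyr::bind_cols(features[intersect(ID_COLS, colnames(features))],
                               factor_scores(factor_model))
  }
  lme <- NULL
  if ("inference" %in% stages) {
    say("inference")
    lme <- wrap_stage("inference", list(
      density = fit_lme_nodal(features, "density"),
      specradRatio = fit_lme_nodal(features, "specradRatio"),
      nodstr = fit_lme_edgewise(features, "nodstr"),
      ge = fit_lme_edgewise(features, "ge")
    ))
  }
  classifiers <- NULL
  if ("classify" %in% stages) {
    say("classify")
    classifiers <- wrap_stage("classify", classify_all(
      scores, seed = derive_seed(config$seed, 9002L)
    ))
  }
  log_rows <- c(log_rows, list(tibble::tibble(
    stage = stages, seed = config$seed, hash = rlang::hash(unclass(config))
  )))
  structure(
    list(config = config, cohort = cohort, features = features,
         kinematics = kinematics, factor_model = factor_model,
         scores = scores, lme = lme, classifiers = classifiers,
         run_log = dplyr::bind_rows(log_rows),
         version = as.character(utils::packageVersion("musclenet"))),
    class = "musclenet_run"
  )
}

#' @export
print.musclenet_run <- function(x, ...) {
  cat("<musclenet_run>\n")
  if (!is.null(x$features)) {
    cat(sprintf("  features: %d records x %d feature columns\n",
                nrow(x$features), length(feature_columns(x$features))))
  }
  if (!is.null(x$kinematics)) cat(sprintf("  kinematics: %d records\n", nrow(x$kinematics)))
  if (!is.null(x$factor_model)) cat(sprintf("  factors: %d\n", x$factor_model$n_factors))
  if (!is.null(x$classifiers)) {
    for (cr in x$classifiers) cat(sprintf("  %s AUC %.3f\n", cr$algorithm, cr$metrics$auc))
  }
  invisible(x)
}

# ---- Delimited IO ---------------------------------------------------------

#' Write / read a recording as a delimited matrix plus JSON sidecar
#'
#' The matrix is tab-delimited, one column per channel in canonical
#' order; the sidecar `<base>.json` holds fs, channel labels and
#' identifiers.
#'
#' @param rec A `semg_recording`.
#' @param dir Output directory.
#' @param basename File base name (default from subject/sentence).
#' @return The matrix file path, invisibly.
#' @export
write_semg_recording <- function(rec, dir, basename = NULL) {
  rec <- as_semg_recording(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(basename)) {
    basename <- sprintf("%s_sent%02d", rec$subject_id %||% "rec",
                        as.integer(rec$sentence_id %||% 0L))
  }
  path <- file.path(dir, paste0(basename, ".tsv"))
  utils::write.table(t(rec$samples), path, sep = "\t", row.names = FALSE,
                     col.names = MN_CHANNELS, quote = FALSE)
  meta <- list(fs = rec$fs, channel_labels = MN_CHANNELS,
               subject = rec$subject_id, sentence = rec$sentence_id,
               group = rec$group_label, stage = rec$stage_label)
  jsonlite::write_json(meta, file.path(dir, paste0(basename, ".json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_semg_recording
#' @param path Path to the `.tsv` matrix file (sidecar found alongside).
#' @export
read_semg_recording <- function(path) {
  mat <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                     check.names = FALSE))
  meta_path <- sub("\\.tsv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else list()
  labels <- unlist(meta$channel_labels %||% colnames(mat))
  if (!identical(as.character(labels), MN_CHANNELS) ||
      !identical(colnames(mat), MN_CHANNELS)) {
    abort("channel labels missing or out of canonical order.")
  }
  semg_recording(t(mat), fs = meta$fs %||% 2000,
                 subject_id = meta$subject %||% NA_character_,
                 sentence_id = as.integer(meta$sentence %||% NA_integer_),
                 group_label = meta$group %||% NA_character_,
                 stage_label = meta$stage %||% NA_character_)
}

#' Write / read a jaw trace as a 4-column delimited file plus sidecar
#'
#' @param trace A `jaw_trace`.
#' @param dir Output directory.
#' @param basename File base name.
#' @return The file path, invisibly.
#' @export
write_jaw_trace <- function(trace, dir, basename = "jaw") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, paste0(basename, ".tsv"))
  utils::write.table(as.data.frame(trace[c("t", "x", "y", "z")]), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(fs = trace_fs(trace), reference = trace_reference(trace)),
    file.path(dir, paste0(basename, ".json")), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_jaw_trace
#' @param path Path to the `.tsv` trace file.
#' @export
read_jaw_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- jsonlite::read_json(sub("\\.tsv$", ".json", path))
  jaw_trace(df$t, as.matrix(df[c("x", "y", "z")]),
            fs = meta$fs %||% 100,
            reference = unlist(meta$reference %||% c(0, 0, 0)))
}

#' Validate recording files
#'
#' Checks channel count and order, sampling-rate consistency between data
#' and sidecar, and finiteness, returning a machine-readable issue table
#' (empty when everything is valid).
#'
#' @param paths Paths to `.tsv` recording files.
#' @return Tibble with columns `path`, `check`, `message`.
#' @export
validate_inputs <- function(paths) {
  rows <- purrr::map(paths, function(p) {
    issues <- list()
    add <- function(check, msg) {
      issues[[length(issues) + 1L]] <<- tibble::tibble(path = p, check = check,
                                                       message = msg)
    }
    if (!file.exists(p)) {
      add("exists", "file not found")
      return(dplyr::bind_rows(issues))
    }
    mat <- tryCatch(as.matrix(utils::read.table(p, header = TRUE, sep = "\t",
                                                check.names = FALSE)),
                    error = function(e) NULL)
    if (is.null(mat)) {
      add("parse", "cannot parse delimited matrix")
      return(dplyr::bind_rows(issues))
    }
    if (ncol(mat) != 6L) add("channels", sprintf("expected 6 channels, found %d", ncol(mat)))
    else if (!identical(colnames(mat), MN_CHANNELS)) {
      add("channel_order", "channel labels not in canonical order")
    }
    if (!all(is.finite(mat))) add("finite", "non-finite values present")
    meta_path <- sub("\\.tsv$", ".json", p)
    if (!file.exists(meta_path)) {
      add("sidecar", "metadata sidecar missing")
    } else {
      meta <- jsonlite::read_json(meta_path)
      if (!is.null(meta$fs) && !is.null(meta$duration_s) && nrow(mat) > 0) {
        implied <- nrow(mat) / as.numeric(meta$duration_s)
        if (abs(implied - as.numeric(meta$fs)) > 0.01 * as.numeric(meta$fs)) {
          add("fs", sprintf("sampling rate mismatch: metadata %s Hz, implied %.1f Hz",
                            meta$fs, implied))
        }
      }
    }
    dplyr::bind_rows(issues)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(path = character(), check = character(),
                          message = character())
  }
  out
}

# ---- CLI ------------------------------------------------------------------

read_cli_config <- function(path) {
  if (is.null(path)) return(cohort_config())
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(cohort_config, raw[intersect(names(raw), names(formals(cohort_config)))])
}

#' Command-line entry point
#'
#' Dispatches the `musclenet` executable's subcommands: `simulate`,
#' `preprocess`, `features`, `kinematics`, `factors`, `run-all`. Options:
#' `--config <json>`, `--out <dir>`, `--seed <int>`, `--no-bss`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
musclenet_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    cat("usage: musclenet <simulate|preprocess|features|kinematics|factors|run-all> [--config cfg.json] [--out dir] [--seed n] [--no-bss] [inputs...]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt <- function(name, default = NULL) {
    i <- which(rest == paste0("--", name))
    if (length(i)) rest[i[1] + 1L] else default
  }
  flag <- function(name) any(rest == paste0("--", name))
  inputs <- rest[!startsWith(rest, "--")]
  drop_after <- which(rest %in% c("--config", "--out", "--seed")) + 1L
  inputs <- setdiff(inputs, rest[drop_after[drop_after <= length(rest)]])
  out_dir <- opt("out", ".")
  cfg <- read_cli_config(opt("config"))
  seed <- opt("seed")
  if (!is.null(seed)) cfg$seed <- as.integer(seed)

  if (cmd == "simulate") {
    cohort <- generate_cohort(cfg)
    man <- recording_manifest(cohort, cfg)
    for (r in seq_len(nrow(man))) {
      row <- man[r, ]
      rec <- simulate_semg(manifest_profile(row), cfg$sentence_duration_s,
                           cfg$fs_semg,
                           seed = derive_seed(cfg$seed, row$si, row$sentence),
                           subject_id = row$subject_id, sentence_id = row$sentence,
                           group_label = row$group, stage_label = row$stage)
      write_semg_recording(rec, out_dir)
      tr <- simulate_jaw(manifest_profile(row), cfg$sentence_duration_s, cfg$fs_kin,
                         seed = derive_seed(cfg$seed, 5000L + row$si, row$sentence))
      write_jaw_trace(tr, out_dir, sprintf("%s_sent%02d_jaw", row$subject_id, row$sentence))
    }
    utils::write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (cmd == "preprocess") {
    for (p in inputs) {
      rec <- preprocess_semg(read_semg_recording(p), bss = !flag("no-bss"))
      write_semg_recording(rec, out_dir,
                           paste0(sub("\\.tsv$", "", basename(p)), "_proc"))
    }
  } else if (cmd == "features") {
    feats <- dplyr::bind_rows(lapply(inputs, function(p) {
      extract_features(read_semg_recording(p), bss = !flag("no-bss"))
    }))
    utils::write.table(feats, file.path(out_dir, "features.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (cmd == "kinematics") {
    kin <- dplyr::bind_rows(lapply(inputs, function(p) {
      dplyr::bind_cols(tibble::tibble(path = p),
                       jaw_kinematic_metrics(read_jaw_trace(p)))
    }))
    utils::write.table(kin, file.path(out_dir, "kinematics.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (cmd == "factors") {
    feats <- tibble::as_tibble(utils::read.table(inputs[1], header = TRUE,
                                                 sep = "\t", check.names = FALSE))
    fm <- fit_factor_model(feats, seed = cfg$seed)
    utils::write.table(generics::tidy(fm), file.path(out_dir, "loadings.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    sc <- factor_scores(fm)
    utils::write.table(sc, file.path(out_dir, "scores.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else if (cmd == "run-all") {
    run <- run_pipeline(cfg, stages = c("features", "kinematics", "factors",
                                        "inference", "classify"))
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    utils::write.table(run$features, file.path(out_dir, "features.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(run$kinematics, file.path(out_dir, "kinematics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(run$scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(run$run_log, file.path(out_dir, "run_log.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    cat(sprintf("unknown subcommand '%s'\n", cmd))
    return(invisible(1L))
  }
  invisible(0L)
}
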