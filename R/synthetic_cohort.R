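# Seeded synthetic cohorts: burst-structured sEMG with band-limited common
# drives, quasi-periodic jaw traces, group labels and stage-dependent
# effect profiles, so every downstream stage is testable without human
# recordings.

#' Cohort configuration
#'
#' Defaults reproduce the study design: 10 controls, 7 prodromal and 8
#' symptomatic ALS subjects, 19 sentences per subject, 5 s sentences,
#' sEMG at 2,000 Hz and jaw kinematics at 100 Hz.
#'
#' @param n_control,n_als_prodromal,n_als_symptomatic Group sizes.
#' @param sentences_per_subject Sentences read per subject (default 19).
#' @param sentence_duration_s Sentence duration in seconds (default 5).
#' @param fs_semg,fs_kin Sampling rates, Hz.
#' @param seed Base seed; every recording derives its own stream from it.
#' @param drop_recordings Number of recordings dropped at random to
#'   emulate recording errors (default 0; the study design lost 2).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 10L, n_als_prodromal = 7L,
                          n_als_symptomatic = 8L,
                          sentences_per_subject = 19L,
                          sentence_duration_s = 5,
                          fs_semg = 2000, fs_kin = 100,
                          seed = 1L, drop_recordings = 0L) {
  for (nm in c("n_control", "n_als_prodromal", "n_als_symptomatic",
               "sentences_per_subject", "drop_recordings")) {
    if (!is_count(get(nm))) abort(sprintf("`%s` must be a non-negative count.", nm))
  }
  if (sentence_duration_s <= 0) abort("`sentence_duration_s` must be positive.")
  if (fs_semg <= 2 * 60) abort("`fs_semg` must exceed twice the highest simulated drive frequency (60 Hz).")
  if (fs_kin <= 0) abort("`fs_kin` must be positive.")
  structure(
    list(n_control = as.integer(n_control),
         n_als_prodromal = as.integer(n_als_prodromal),
         n_als_symptomatic = as.integer(n_als_symptomatic),
         sentences_per_subject = as.integer(sentences_per_subject),
         sentence_duration_s = sentence_duration_s,
         fs_semg = fs_semg, fs_kin = fs_kin,
         seed = as.integer(seed),
         drop_recordings = as.integer(drop_recordings)),
    class = "cohort_config"
  )
}

#' Disease effect profile
#'
#' Scales applied to the signal generator. The control profile is the
#' identity (all scales 1, asymmetry at its healthy right-dominant
#' default). Disease lowers the myoelectric level (`amplitude_scale`),
#' raises burst-amplitude variability (`envelope_cv_scale`), weakens the
#' shared band drives (`coupling_scale`), flattens the right-left
#' asymmetry and slows the jaw (`kinematic_slowing`).
#'
#' @param amplitude_scale Gain on the envelope-driven component, in (0, 1].
#' @param envelope_cv_scale Multiplier (>= 1) on the burst-amplitude
#'   coefficient of variation.
#' @param coupling_scale Per-band drive coupling in `[0, 1]`; scalar or
#'   named length-3 vector (theta.alpha, beta, gamma).
#' @param right_left_asymmetry Drive asymmetry in `[-1, 1]`; right-side
#'   channels receive `(1 + a)` times the drive, left-side `(1 - a)`.
#' @param kinematic_slowing Jaw cycle-rate divisor (>= 1).
#' @return An object of class `effect_profile`.
#' @export
effect_profile <- function(amplitude_scale = 1, envelope_cv_scale = 1,
                           coupling_scale = 1,
                           right_left_asymmetry = 0.15,
                           kinematic_slowing = 1) {
  if (amplitude_scale <= 0 || amplitude_scale > 1.5) {
    abort("`amplitude_scale` must lie in (0, 1.5].")
  }
  if (envelope_cv_scale < 1) abort("`envelope_cv_scale` must be >= 1.")
  cs <- coupling_scale
  if (length(cs) == 1L) cs <- rep(cs, 3L)
  cs <- setNames(as.numeric(cs), names(MN_BANDS))
  if (any(cs < 0 | cs > 1)) abort("`coupling_scale` must lie in [0, 1].")
  if (abs(right_left_asymmetry) > 1) abort("`right_left_asymmetry` must lie in [-1, 1].")
  if (kinematic_slowing < 1) abort("`kinematic_slowing` must be >= 1.")
  structure(
    list(amplitude_scale = amplitude_scale,
         envelope_cv_scale = envelope_cv_scale,
         coupling_scale = cs,
         right_left_asymmetry = right_left_asymmetry,
         kinematic_slowing = kinematic_slowing),
    class = "effect_profile"
  )
}

# Stage-dependent mean profiles. Symptomatic values follow the generator
# defaults (amplitude 0.7, coupling 0.6, envelope CV x1.5); prodromal sits
# between control and symptomatic.
stage_profile_means <- function(stage) {
  switch(stage,
    control = effect_profile(),
    prodromal = effect_profile(amplitude_scale = 0.85, envelope_cv_scale = 1.25,
                               coupling_scale = 0.8, right_left_asymmetry = 0.08,
                               kinematic_slowing = 1.15),
    symptomatic = effect_profile(amplitude_scale = 0.7, envelope_cv_scale = 1.5,
                                 coupling_scale = 0.6, right_left_asymmetry = 0.02,
                                 kinematic_slowing = 1.3),
    abort(sprintf("unknown stage '%s'.", stage))
  )
}

#' Generate a cohort manifest
#'
#' One row per subject with group and stage labels and the subject's
#' effect profile. Control subjects carry the identity profile; ALS
#' subjects are drawn around their stage-dependent means (symptomatic more
#' extreme than prodromal) with small multiplicative jitter.
#'
#' @param config A [cohort_config()].
#' @return Tibble with columns `subject_id`, `group`, `stage`,
#'   `amplitude_scale`, `envelope_cv_scale`, `coupling_theta.alpha`,
#'   `coupling_beta`, `coupling_gamma`, `right_left_asymmetry`,
#'   `kinematic_slowing`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n_als <- config$n_als_prodromal + config$n_als_symptomatic
  if (config$n_control + n_als == 0L) {
    abort("zero subjects in both groups: nothing to analyze.")
  }
  stages <- c(rep("control", config$n_control),
              rep("prodromal", config$n_als_prodromal),
              rep("symptomatic", config$n_als_symptomatic))
  with_seed(derive_seed(config$seed, 101L), {
    rows <- purrr::imap(stages, function(stage, i) {
      mu <- stage_profile_means(stage)
      if (stage == "control") {
        p <- mu
      } else {
        jit <- function(v, lo, hi) pmin(pmax(v * exp(rnorm(length(v), 0, 0.05)), lo), hi)
        p <- effect_profile(
          amplitude_scale = jit(mu$amplitude_scale, 0.2, 1),
          envelope_cv_scale = max(1, mu$envelope_cv_scale * exp(rnorm(1, 0, 0.05))),
          coupling_scale = jit(mu$coupling_scale, 0, 1),
          right_left_asymmetry = pmin(pmax(mu$right_left_asymmetry + rnorm(1, 0, 0.02), -1), 1),
          kinematic_slowing = max(1, mu$kinematic_slowing * exp(rnorm(1, 0, 0.05)))
        )
      }
      tibble::tibble(
        subject_id = sprintf("S%02d", i),
        group = if (stage == "control") "control" else "ALS",
        stage = stage,
        amplitude_scale = p$amplitude_scale,
        envelope_cv_scale = p$envelope_cv_scale,
        coupling_theta.alpha = p$coupling_scale[["theta.alpha"]],
        coupling_beta = p$coupling_scale[["beta"]],
        coupling_gamma = p$coupling_scale[["gamma"]],
        right_left_asymmetry = p$right_left_asymmetry,
        kinematic_slowing = p$kinematic_slowing
      )
    })
    dplyr::bind_rows(rows)
  })
}

# Rebuild an effect_profile from a manifest row.
manifest_profile <- function(row) {
  effect_profile(
    amplitude_scale = row$amplitude_scale,
    envelope_cv_scale = row$envelope_cv_scale,
    coupling_scale = c(theta.alpha = row$coupling_theta.alpha,
                       beta = row$coupling_beta,
                       gamma = row$coupling_gamma),
    right_left_asymmetry = row$right_left_asymmetry,
    kinematic_slowing = row$kinematic_slowing
  )
}

# Shared phrase gate: breath-group-scale loudness alternation, common to
# all channels of a sentence. The logistic squash gives phrase-length
# plateaus separated by near-silent pauses, as in connected speech: the
# envelope distribution is then bimodal (burst detection separates
# phrases from pauses) and the joint epoch selector finds shared
# activity stretches. The gate's spectral content sits below the 4 Hz
# edge of the lowest coherence band, so it does not masquerade as
# in-band coupling.
#
# `fragmentation` (0 = fluent, 1 = maximally effortful) reshapes the
# gate from regular alternating phrases to a single dominant activity
# excursion: slow, effortful speech concentrates the myoelectric output
# in fewer, relatively larger events with long low-level stretches.
# This is what drives the nodal visibility-graph signature of disease
# (density down, spectral radius ratio up).
prosody_modulation <- function(n, fs, fragmentation = 0, steepness = 3.5) {
  f <- min(1, max(0, fragmentation))
  z <- slow_noise(n, fs, c(0.25 - 0.15 * f, 0.55 - 0.2 * f))
  offset <- -0.55 + 0.1 * f
  # a read sentence carries speech in its interior: anchor an activity
  # hump spanning the recording so phrases cluster mid-sentence and the
  # edges hold the pauses; effortful speech leans on the single hump
  anchor <- (0.55 + 0.55 * f) * sin(pi * seq_len(n) / n)
  g <- stats::plogis(steepness * (z + offset + anchor))
  g / max(mean(g), 1e-9)
}

# Disease fragmentation of the phrase gate, driven by the envelope
# variability scale: identity profile gives 0, the symptomatic default
# (1.5) gives 1.
profile_fragmentation <- function(profile) {
  min(1, max(0, (profile$envelope_cv_scale - 1) / 0.5))
}

# Burst-train envelope: half-sine bursts at Gamma-distributed inter-burst
# intervals (mean 200 ms), log-normal burst amplitudes (unit mean) whose
# CV is scaled by `cv_scale`, over a small tonic baseline, all riding on
# the shared prosody modulation.
burst_envelope <- function(n, fs, cv_scale = 1, mean_ibi = 0.2,
                           burst_width = 0.12, baseline = 0.08,
                           prosody = NULL) {
  dur <- n / fs
  n_exp <- ceiling(dur / mean_ibi * 2) + 10L
  # cv_scale > 1 models the irregular, intermittent activation of the
  # diseased muscle: amplitudes more dispersed, burst timing more
  # erratic (lower Gamma shape), and occasional bursts dropped entirely
  shape <- max(2, 4 / cv_scale^2)
  ibis <- rgamma(n_exp, shape = shape, scale = mean_ibi / shape)
  onsets <- cumsum(ibis)
  onsets <- onsets[onsets < dur]
  p_skip <- min(0.15, 0.3 * (1 - 1 / cv_scale))
  if (p_skip > 0 && length(onsets)) {
    onsets <- onsets[runif(length(onsets)) >= p_skip]
  }
  cv0 <- 0.4
  cv <- cv0 * cv_scale
  sig <- sqrt(log(1 + cv^2))
  amps <- rlnorm(length(onsets), meanlog = -sig^2 / 2, sdlog = sig)
  env <- rep(baseline, n)
  wb <- as.integer(round(burst_width * fs))
  pulse <- sin(pi * seq_len(wb) / (wb + 1))
  for (k in seq_along(onsets)) {
    i0 <- as.integer(round(onsets[k] * fs)) + 1L
    if (i0 > n) next
    idx <- i0:min(i0 + wb - 1L, n)
    env[idx] <- env[idx] + amps[k] * pulse[seq_along(idx)]
  }
  if (!is.null(prosody)) env <- env * prosody + 0.02
  env
}

# Unit-SD band-passed Gaussian process.
bandpassed_noise <- function(n, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  z <- signal::filtfilt(bf, rnorm(n + 2L * fs))[(fs + 1L):(fs + n)]
  z / sd(z)
}

# Unit-SD slow (sub-2 Hz) Gaussian process, synthesized at a low rate and
# interpolated up: a direct IIR design at fs = 2,000 Hz would put the
# normalized cutoffs at ~1e-4, where the filter is numerically unstable.
slow_noise <- function(n, fs, band, fs_lo = 50) {
  n_lo <- ceiling(n / fs * fs_lo) + 4L * fs_lo
  bf <- signal::butter(2, band / (fs_lo / 2), type = "pass")
  z <- signal::filtfilt(bf, rnorm(n_lo + 2L * fs_lo))[(fs_lo + 1L):(fs_lo + n_lo)]
  t_lo <- seq_len(n_lo) / fs_lo
  zi <- stats::approx(t_lo, z, xout = seq_len(n) / fs, rule = 2)$y
  zi / max(sd(zi), 1e-12)
}

# Fixed nearest-neighbour crosstalk mixing (leakage between anatomically
# adjacent electrode sites).
crosstalk_matrix <- function(leak = 0.1) {
  m <- diag(6)
  nb <- rbind(c(1, 3), c(2, 4), c(3, 5), c(4, 6), c(5, 6))
  for (r in seq_len(nrow(nb))) {
    m[nb[r, 1], nb[r, 2]] <- leak
    m[nb[r, 2], nb[r, 1]] <- leak
  }
  m
}

#' Simulate a six-channel sEMG sentence recording
#'
#' Signal model per channel: an envelope-driven broadband carrier
#' (burst-train envelope times 80-400 Hz Gaussian carrier, scaled by
#' `amplitude_scale`), amplitude-modulated by shared band-limited drives
#' (4-12, 12-30, 30-60 Hz) injected with per-band coupling and right/left
#' asymmetry, plus a small additive drive leakage, a 60 Hz line component,
#' a DC offset, sensor noise, and an instantaneous nearest-neighbour
#' crosstalk mixture. The multiplicative (amplitude-modulation) route is
#' what makes the shared drives recoverable by rectified-signal coherence
#' after the 20 Hz high-pass, as in real EMG common drive.
#'
#' @param profile An [effect_profile()].
#' @param duration Seconds (>= 2).
#' @param fs Sampling rate, Hz (> 120).
#' @param seed Seed for this recording's stream.
#' @param line_amplitude 60 Hz line-noise amplitude.
#' @param dc_offset Per-channel DC offsets (recycled to 6).
#' @param noise_sd Additive sensor-noise SD.
#' @param crosstalk_leak Nearest-neighbour leakage coefficient (0 disables).
#' @param modulation_depth Depth of the shared-drive amplitude modulation.
#' @param additive_leak Amplitude of the small additive drive component.
#' @param ... Metadata passed to [semg_recording()] (subject_id, ...).
#' @return A `semg_recording`.
#' @export
simulate_semg <- function(profile = effect_profile(), duration = 5, fs = 2000,
                          seed = NULL, line_amplitude = 0.3,
                          dc_offset = c(0.2, -0.15, 0.1, -0.1, 0.25, -0.2),
                          noise_sd = 0.05, crosstalk_leak = 0.1,
                          modulation_depth = 0.8, additive_leak = 0.04, ...) {
  stopifnot(inherits(profile, "effect_profile"))
  if (duration < 2) abort("`duration` must be at least 2 s (one epoch).")
  if (fs <= 120) abort("`fs` too low for the 30-60 Hz shared drive (needs fs > 120 Hz).")
  n <- as.integer(round(duration * fs))
  dc_offset <- rep_len(dc_offset, 6L)
  with_seed(seed, {
    drives <- lapply(MN_BANDS, function(b) bandpassed_noise(n, fs, b))
    prosody <- prosody_modulation(n, fs, profile_fragmentation(profile))
    t <- seq_len(n) / fs
    line_phase <- runif(1, 0, 2 * pi)
    gains <- c(1, 0.95, 1.05, 1, 0.9, 1.1)
    side <- ifelse(startsWith(MN_CHANNELS, "R"),
                   1 + profile$right_left_asymmetry,
                   1 - profile$right_left_asymmetry)
    x <- matrix(0, 6L, n)
    # distinct per-muscle carrier bands (muscles differ in fiber
    # composition and hence spectral signature); the distinct
    # autocorrelations are also what makes the sources identifiable for
    # the temporal-decorrelation crosstalk stage
    carrier_lo <- c(70, 90, 110, 130, 150, 80)
    carrier_hi <- c(260, 330, 400, 450, 420, 300)
    for (i in seq_len(6L)) {
      env <- burst_envelope(n, fs, profile$envelope_cv_scale, prosody = prosody)
      carrier <- bandpassed_noise(n, fs, c(carrier_lo[i], min(carrier_hi[i], 0.45 * fs)))
      drivev <- rep(0, n)
      addv <- rep(0, n)
      for (b in names(MN_BANDS)) {
        cb <- profile$coupling_scale[[b]] * side[i]
        # drives ride on the shared slow gate only: gating by the fast
        # per-channel burst texture would smear their band content
        drivev <- drivev + modulation_depth / sqrt(3) * cb * prosody * drives[[b]]
        addv <- addv + additive_leak * cb * drives[[b]]
      }
      modv <- pmax(env + drivev, 0)
      x[i, ] <- profile$amplitude_scale * gains[i] * modv * carrier +
        addv +
        line_amplitude * sin(2 * pi * 60 * t + line_phase) +
        dc_offset[i] +
        noise_sd * rnorm(n)
    }
    if (crosstalk_leak > 0) x <- crosstalk_matrix(crosstalk_leak) %*% x
    semg_recording(x, fs = fs, ...)
  })
}

#' Simulate a 3D jaw trace
#'
#' The distance to the lower-incisor reference follows a quasi-sinusoidal
#' open/close cycle train (default 2.5 cycles/s, 5 mm amplitude around a
#' 30 mm base distance) with slow amplitude and rate modulation; the cycle
#' rate is divided by the profile's `kinematic_slowing`. A pure-sinusoid
#' mode is available for closed-form testing.
#'
#' @param profile An [effect_profile()].
#' @param duration Seconds (> one cycle).
#' @param fs Sampling rate, Hz (default 100).
#' @param seed Seed for this trace's stream.
#' @param pure_sinusoid Disable the quasi-periodic modulation.
#' @param amplitude Half-excursion, mm.
#' @param frequency Cycle rate before slowing, Hz.
#' @param base_distance Mean sensor-to-incisor distance, mm.
#' @return A `jaw_trace` with the reference point at the origin.
#' @export
simulate_jaw <- function(profile = effect_profile(), duration = 5, fs = 100,
                         seed = NULL, pure_sinusoid = FALSE,
                         amplitude = 5, frequency = 2.5, base_distance = 30) {
  stopifnot(inherits(profile, "effect_profile"))
  f <- frequency / profile$kinematic_slowing
  if (duration <= 1 / max(f, 1e-9)) abort("`duration` must exceed one jaw cycle.")
  n <- as.integer(round(duration * fs))
  t <- seq_len(n) / fs
  with_seed(seed, {
    if (pure_sinusoid || amplitude == 0) {
      d <- base_distance + amplitude * sin(2 * pi * f * t)
    } else {
      slow <- function() pmin(pmax(slow_noise(n, fs, c(0.05, 0.5), fs_lo = 10), -2), 2)
      amp <- amplitude * (1 + 0.25 * slow())
      finst <- f * (1 + 0.15 * slow())
      phase <- 2 * pi * cumsum(finst) / fs
      d <- base_distance + amp * sin(phase)
    }
    u <- c(0.2, -0.1, -0.97)
    u <- u / sqrt(sum(u^2))
    jaw_trace(t, outer(d, u), fs = fs, reference = c(0, 0, 0))
  })
}

# ---- Feature-level latent generator ---------------------------------------

#' Latent factor pattern of the 48 features
#'
#' The 48 x 10 primary-loading indicator pattern: factor 1 carries the 12
#' nodal features; factors 2-4 the gamma/theta-alpha/beta clustering
#' coefficients; factors 5, 7, 9 the theta-alpha/beta/gamma strength +
#' efficiency pairs; factor 6 the antagonist laterality indices; factor 8
#' the agonist laterality indices; factor 10 the assortativity
#' coefficients.
#'
#' @return 48 x 10 0/1 matrix with feature row names.
#' @export
latent_pattern <- function() {
  nm <- mn_feature_names()
  p <- matrix(0, length(nm), 10L, dimnames = list(nm, paste0("factor", 1:10)))
  assign_f <- function(k, sel) p[grepl(sel, nm), k] <<- 1
  assign_f(1, "^(density|specradRatio)_")
  assign_f(2, "^wcc_.*_gamma$")
  assign_f(3, "^wcc_.*_theta.alpha$")
  assign_f(4, "^wcc_.*_beta$")
  assign_f(5, "^(nodstr|ge)_theta.alpha$")
  assign_f(6, "^lat_(TEMP_ABD|MAS_ABD)_")
  assign_f(7, "^(nodstr|ge)_beta$")
  assign_f(8, "^lat_TEMP_MAS_")
  assign_f(9, "^(nodstr|ge)_gamma$")
  assign_f(10, "^ac_")
  p
}

#' Draw sentence-level feature records from the latent configuration
#'
#' Generates standardized 48-feature records from the 10-factor oblique
#' model implied by [latent_pattern()]: primary loadings `loading`,
#' uniform inter-factor correlation `factor_cor`, unit total variance per
#' feature. Optionally adds group mean shifts on the connectivity factors
#' and subject-level random intercepts, for classification and
#' mixed-model properties.
#'
#' @param n_records Number of sentence-level records (study design: 473).
#' @param seed Seed.
#' @param loading Primary loading (default 0.8). Factors carried by three
#'   or fewer features get `loading + 0.05`: few-indicator factors need
#'   stronger markers to be identifiable, a standard psychometric design
#'   rule.
#' @param factor_cor Uniform inter-factor correlation (default 0.15).
#' @param cohort Optional cohort manifest (from [generate_cohort()]); when
#'   given, records are generated per subject x sentence with group
#'   effects and subject intercepts, and id columns are attached.
#' @param sentences_per_subject Sentences per subject when `cohort` given.
#' @param effect_size Stage-dependent mean shift (SD units) applied to
#'   the nodal and band-connectivity factors (1, 5, 7, 9) for
#'   symptomatic subjects; the clustering and antagonist-laterality
#'   factors (2, 3, 4, 6) get a third of it and the agonist-laterality
#'   and assortativity factors (8, 10) a fifth, mirroring the reported
#'   gradient of disease effects across feature families. Prodromal
#'   subjects get 60% of every shift.
#' @param subject_sd SD of the per-subject factor intercepts.
#' @return Tibble of 48 feature columns (plus `subject_id`, `group`,
#'   `stage`, `sentence` when `cohort` is given), with the generating
#'   factor scores in attribute `"factor_scores"`.
#' @export
simulate_feature_matrix <- function(n_records = 473L, seed = NULL,
                                    loading = 0.8, factor_cor = 0.15,
                                    cohort = NULL, sentences_per_subject = 19L,
                                    effect_size = 1.8, subject_sd = 0.4) {
  pat <- latent_pattern()
  k <- ncol(pat)
  lvec <- ifelse(colSums(pat) <= 3, loading + 0.05, loading)
  lambda <- sweep(pat, 2L, lvec, `*`)
  phi <- matrix(factor_cor, k, k); diag(phi) <- 1
  communality <- diag(lambda %*% phi %*% t(lambda))
  if (any(communality >= 1)) abort("latent configuration implies communality >= 1.")
  psi <- sqrt(1 - communality)
  ch <- chol(phi)
  shift_profile <- c(1, 1 / 3, 1 / 3, 1 / 3, 1, 1 / 3, 1, 1 / 5, 1, 1 / 5)
  with_seed(seed, {
    if (is.null(cohort)) {
      f <- matrix(rnorm(n_records * k), n_records, k) %*% ch
      ids <- NULL
    } else {
      stage_shift <- c(control = 0, prodromal = 0.6, symptomatic = 1)
      subj_int <- matrix(rnorm(nrow(cohort) * k, 0, subject_sd), nrow(cohort), k)
      ids <- tidyr::expand_grid(si = seq_len(nrow(cohort)),
                                sentence = seq_len(sentences_per_subject))
      n_records <- nrow(ids)
      f <- matrix(rnorm(n_records * k), n_records, k) %*% ch
      for (r in seq_len(n_records)) {
        si <- ids$si[r]
        sh <- stage_shift[[cohort$stage[si]]] * effect_size
        f[r, ] <- f[r, ] - sh * shift_profile + subj_int[si, ]
      }
    }
    e <- matrix(rnorm(n_records * nrow(pat)), n_records, nrow(pat)) %*% diag(psi)
    x <- f %*% t(lambda) + e
    colnames(x) <- rownames(pat)
    out <- tibble::as_tibble(x)
    if (!is.null(ids)) {
      out <- dplyr::bind_cols(
        tibble::tibble(subject_id = cohort$subject_id[ids$si],
                       group = cohort$group[ids$si],
                       stage = cohort$stage[ids$si],
                       sentence = ids$sentence),
        out
      )
    }
    attr(out, "factor_scores") <- f
    out
  })
}
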