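# sEMG preprocessing chain: crosstalk suppression -> 60 Hz notch ->
# 20 Hz high-pass -> DC removal. All filters are applied forward-backward
# (zero phase) after 1 s reflect padding at each end.

#' Suppress inter-electrode crosstalk by source separation
#'
#' Reconstructs each channel from estimated independent sources so that
#' shared instantaneous-mixture components are attenuated. The separation
#' is a temporal-decorrelation (AMUSE/SOBI-style) method: the channels are
#' whitened and rotated so that a pooled set of symmetrized time-lagged
#' covariance matrices is (approximately) diagonalized; each electrode is
#' then back-projected from its single dominant source. The algorithm
#' lives behind a stable interface so it can be swapped without touching
#' the rest of the pipeline.
#'
#' @param rec A `semg_recording`.
#' @param method `"source_separation"` (default) or `"off"` (identity).
#' @param lags Sample lags pooled for temporal decorrelation.
#' @return A `semg_recording` of identical shape and labels.
#' @export
remove_crosstalk <- function(rec, method = c("source_separation", "off"),
                             lags = c(1L, 2L, 3L, 5L, 8L, 13L)) {
  rec <- as_semg_recording(rec)
  method <- match.arg(method)
  if (method == "off") return(rec)
  x <- rec$samples
  n <- ncol(x)

  cc <- suppressWarnings(cor(t(x)))
  cc[!is.finite(cc)] <- 1
  diag(cc) <- 0
  if (any(abs(cc) > 0.999)) {
    idx <- which(abs(cc) > 0.999, arr.ind = TRUE)[1, ]
    abort(sprintf("channels %s and %s are rank-deficient (near-duplicates); cannot separate.",
                  MN_CHANNELS[idx[1]], MN_CHANNELS[idx[2]]))
  }

  mu <- rowMeans(x)
  xc <- x - mu
  c0 <- tcrossprod(xc) / n
  e0 <- eigen(c0, symmetric = TRUE)
  if (min(e0$values) < 1e-12 * max(e0$values)) {
    abort("channel covariance is rank-deficient; cannot separate sources.")
  }
  w0 <- diag(1 / sqrt(e0$values)) %*% t(e0$vectors)   # whitener
  z <- w0 %*% xc

  ms <- lapply(lags, function(tau) {
    ct <- tcrossprod(z[, 1:(n - tau)], z[, (tau + 1):n]) / (n - tau)
    (ct + t(ct)) / 2
  })
  # burst-structured EMG is nonstationary: time-windowed covariances of
  # the whitened data differ across windows when the underlying sources
  # have independent activation envelopes, which makes them far more
  # discriminative than lagged covariances alone
  n_win <- max(4L, min(16L, n %/% as.integer(rec$fs %/% 2)))
  bounds <- floor(seq(0L, n, length.out = n_win + 1L))
  cw <- lapply(seq_len(n_win), function(k) {
    idx <- (bounds[k] + 1L):bounds[k + 1L]
    tcrossprod(z[, idx, drop = FALSE]) / length(idx)
  })
  u <- joint_diagonalize(c(ms, cw))
  s <- t(u) %*% z                                      # estimated sources
  a <- e0$vectors %*% diag(sqrt(e0$values)) %*% u      # mixing estimate

  # one source per electrode, assigned greedily by mixing magnitude so
  # two electrodes never collapse onto the same source (which would make
  # them exact copies)
  absa <- abs(a)
  assign_order <- order(apply(absa, 1, max), decreasing = TRUE)
  taken <- integer(0)
  dom <- integer(6)
  for (i in assign_order) {
    cand <- setdiff(order(absa[i, ], decreasing = TRUE), taken)
    dom[i] <- cand[1]
    taken <- c(taken, cand[1])
  }
  out <- x
  for (i in seq_len(6L)) {
    out[i, ] <- a[i, dom[i]] * s[dom[i], ] + mu[i]
  }
  rec$samples <- out
  rec
}

# Orthogonal joint approximate diagonalization of a set of symmetric
# matrices by Jacobi rotations (Cardoso-Souloumiac scheme). Returns the
# rotation U such that t(U) %*% M %*% U is as diagonal as possible for
# all M simultaneously.
joint_diagonalize <- function(ms, maxsweep = 100L, tol = 1e-10) {
  p <- nrow(ms[[1]])
  u <- diag(p)
  a <- ms
  for (sweep in seq_len(maxsweep)) {
    changed <- FALSE
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        # closed-form Givens angle maximizing the summed diagonality
        g <- vapply(a, function(m) c(m[i, i] - m[j, j], m[i, j] + m[j, i]),
                    numeric(2))
        gtg <- tcrossprod(g)
        on_diff <- gtg[1, 1] - gtg[2, 2]
        off <- gtg[1, 2] + gtg[2, 1]
        theta <- 0.5 * atan2(off, on_diff + sqrt(on_diff^2 + off^2))
        if (abs(theta) < tol) next
        changed <- TRUE
        cs <- cos(theta); sn <- sin(theta)
        rot <- diag(p); rot[i, i] <- cs; rot[j, j] <- cs
        rot[i, j] <- -sn; rot[j, i] <- sn
        u <- u %*% rot
        a <- lapply(a, function(m) t(rot) %*% m %*% rot)
      }
    }
    if (!changed) break
  }
  u
}

# RBJ-cookbook second-order IIR notch at `f0` Hz with quality factor `q`.
notch_coefficients <- function(f0, fs, q = 30) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Zero-phase filtering with reflect padding of `pad` samples at each end.
filtfilt_padded <- function(x, filt, a = NULL, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x, 2 * x[n] - rev(x[(n - pad):(n - 1)]))
  y <- if (is.null(a)) signal::filtfilt(filt, xp) else signal::filtfilt(filt, a, xp)
  y[(pad + 1):(pad + n)]
}

#' Apply the notch / high-pass / DC-removal filters
#'
#' 60 Hz second-order IIR notch (quality factor 30) followed by a
#' fourth-order Butterworth high-pass at 20 Hz, both run forward-backward
#' for zero phase over a 1 s reflect-padded signal, then per-channel mean
#' removal.
#'
#' @param rec A `semg_recording` with `fs > 120` Hz.
#' @param notch_freq Notch centre frequency, Hz.
#' @param notch_q Notch quality factor.
#' @param highpass_freq High-pass cutoff, Hz.
#' @return A `semg_recording` of identical shape, fs and labels.
#' @export
apply_filters <- function(rec, notch_freq = 60, notch_q = 30, highpass_freq = 20) {
  rec <- as_semg_recording(rec)
  fs <- rec$fs
  if (fs <= 2 * notch_freq) abort("`fs` must exceed twice the notch frequency.")
  n <- ncol(rec$samples)
  if (n < 24L) abort("signal too short to filter (needs at least 3x the filter-order padding).")
  nc <- notch_coefficients(notch_freq, fs, notch_q)
  hp <- signal::butter(4, highpass_freq / (fs / 2), type = "high")
  pad <- as.integer(fs)
  out <- rec$samples
  for (i in seq_len(6L)) {
    y <- filtfilt_padded(out[i, ], nc$b, nc$a, pad)
    y <- filtfilt_padded(y, hp, pad = pad)
    out[i, ] <- y - mean(y)
  }
  rec$samples <- out
  rec
}

#' Full sEMG preprocessing chain
#'
#' Crosstalk suppression (optional), 60 Hz notch, 20 Hz high-pass, DC
#' removal, in that order.
#'
#' @param rec A `semg_recording`.
#' @param bss Run the source-separation crosstalk stage (default TRUE).
#' @return A preprocessed `semg_recording`.
#' @export
preprocess_semg <- function(rec, bss = TRUE) {
  rec <- as_semg_recording(rec)
  rec <- remove_crosstalk(rec, if (bss) "source_separation" else "off")
  apply_filters(rec)
}
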