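# Edgewise connectivity: significance-gated, band-averaged, Fisher-z
# intermuscular coherence for all 15 muscle pairs x 3 bands.
#
# Each preprocessed channel pair is full-wave rectified, reduced to jointly
# selected 1 s epochs around activity bursts, and submitted to a Welch
# magnitude-squared coherence estimate (1,024-point Hamming window, 75%
# overlap, 4,096-point FFT). Within each band, coherence is zeroed unless
# some bin exceeds the 95% independence confidence limit; otherwise the
# band mean is Fisher-z transformed (atanh of the coherency magnitude).

#' Full-wave rectification
#'
#' @param x Numeric vector with finite values.
#' @return `abs(x)`.
#' @export
rectify <- function(x) {
  if (!all(is.finite(x))) abort("cannot rectify non-finite values.")
  abs(x)
}

# Smoothed RMS envelope (default 50 ms rectangular window).
rms_envelope <- function(x, fs, win_s = 0.05) {
  sqrt(moving_average(x^2, round(win_s * fs)))
}

# Per-channel supra-threshold mask: smoothed RMS envelope above its
# median + k * MAD (k = 1.5 for the primary detection pass).
channel_burst_mask <- function(x, fs, k = 1.5) {
  e <- rms_envelope(x, fs)
  spread <- mad(e)
  if (spread <= 100 * .Machine$double.eps * max(abs(e), 1e-300)) {
    return(rep(FALSE, length(e)))  # flat envelope: no detectable bursts
  }
  e > median(e) + k * spread
}

#' Extract jointly selected 1 s epochs around activity bursts
#'
#' Burst detection (the study protocol leaves it unspecified): the smoothed
#' RMS envelope (50 ms window) of each rectified channel must exceed its
#' `median + 1.5 * MAD` for at least 100 ms, on both channels jointly, so
#' that identical time windows are selected for the pair. Each qualifying
#' run contributes consecutive non-overlapping 1 s windows (at least one,
#' centred on the run).
#'
#' @param x,y Rectified signals of equal length.
#' @param fs Sampling rate, Hz.
#' @param epoch_len Epoch length in seconds (default 1).
#' @param min_burst_s Minimum supra-threshold run length, seconds.
#' @param merge_gap_s Runs separated by a shorter sub-threshold dip are
#'   merged (bursts of one phrase belong together).
#' @return List with `x`, `y` (concatenated epochs), `n_epochs`,
#'   `windows` (matrix of start/end sample indices) and `blocks`
#'   (lengths of contiguous epoch runs in the concatenation).
#' @export
extract_epochs <- function(x, y, fs, epoch_len = 1, min_burst_s = 0.1,
                           merge_gap_s = 0.5, masks = NULL) {
  if (length(x) != length(y)) abort("paired channels must have equal length.")
  n <- length(x)
  ep <- as.integer(round(epoch_len * fs))
  if (n < ep) abort("signal shorter than one epoch.")
  qualifying_runs <- function(mask) {
    runs <- true_runs(mask)
    if (nrow(runs) > 1L) {
      gap <- runs[-1L, "start"] - runs[-nrow(runs), "end"] - 1L
      grp <- cumsum(c(1L, as.integer(gap > merge_gap_s * fs)))
      runs <- cbind(start = tapply(runs[, "start"], grp, min),
                    end = tapply(runs[, "end"], grp, max))
    }
    # a merged run qualifies on its supra-threshold content, so chained
    # noise blips cannot masquerade as a burst
    supra <- cumsum(mask)
    content <- supra[runs[, "end"]] - supra[runs[, "start"]] + mask[runs[, "start"]]
    runs[content >= min_burst_s * fs, , drop = FALSE]
  }
  if (is.null(masks)) masks <- list(channel_burst_mask(x, fs), channel_burst_mask(y, fs))
  runs <- qualifying_runs(masks[[1]] & masks[[2]])
  if (nrow(runs) == 0L) {
    # weak recordings: relax the detection threshold stepwise before
    # declaring the pair unusable (fallback only engages when the
    # primary 1.5 MAD rule finds nothing)
    for (k in c(1, 0.5)) {
      runs <- qualifying_runs(channel_burst_mask(x, fs, k) &
                                channel_burst_mask(y, fs, k))
      if (nrow(runs) > 0L) break
    }
  }
  if (nrow(runs) == 0L) {
    abort("no supra-threshold activity: zero epochs found.", class = "mn_no_epochs")
  }
  cand <- list()
  for (r in seq_len(nrow(runs))) {
    a <- runs[r, "start"]; b <- runs[r, "end"]
    len <- b - a + 1L
    # windows may extend moderately past the run ends ("around" the
    # bursts), so a run of just over one epoch already supports two
    # windows
    k <- max(1L, as.integer(round(len / ep + 0.45)))
    ctr <- (a + b) %/% 2L
    first <- ctr - (k * ep) %/% 2L
    st <- first + (seq_len(k) - 1L) * ep
    st <- pmin(pmax(st, 1L), n - ep + 1L)
    cand[[r]] <- cbind(start = st, run_end = b)
  }
  cand <- do.call(rbind, cand)
  cand <- cand[order(cand[, "start"]), , drop = FALSE]
  # greedy non-overlapping placement: a window blocked by its predecessor
  # is shifted right while it still touches its burst run
  starts <- integer(0)
  last_end <- 0L
  for (i in seq_len(nrow(cand))) {
    s <- max(cand[i, "start"], last_end + 1L)
    if (s + ep - 1L > n || s > cand[i, "run_end"]) next
    starts <- c(starts, s)
    last_end <- s + ep - 1L
  }
  if (!length(starts)) {
    abort("no supra-threshold activity: zero epochs found.", class = "mn_no_epochs")
  }
  if (length(starts) == 1L && n >= 2L * ep) {
    # a single epoch leaves the coherence threshold undefined; centre two
    # adjacent epochs on the lone burst so its flanking context completes
    # the minimum estimable stretch
    s1 <- min(max(1L, starts + ep %/% 2L - ep), n - 2L * ep + 1L)
    starts <- c(s1, s1 + ep)
  }
  windows <- cbind(start = starts, end = starts + ep - 1L)
  # epochs adjacent in the original recording are contiguous in the
  # concatenation; downstream sliding windows may span them
  new_block <- c(TRUE, starts[-1L] != starts[-length(starts)] + ep)
  block_id <- cumsum(new_block)
  blocks <- as.integer(table(block_id) * ep)
  # standardize each contiguous block (center, unit SD): the selection is
  # then stationary in level, so phrase-level loudness co-modulation -- a
  # common gain shared by all muscles -- cannot inflate the coherence
  # estimate, and no artificial scale steps are introduced inside blocks
  take <- function(v) {
    out <- lapply(unique(block_id), function(bid) {
      w <- windows[block_id == bid, , drop = FALSE]
      seg <- v[w[1, 1]:w[nrow(w), 2]]
      s <- sd(seg)
      if (s <= 0) seg - mean(seg) else (seg - mean(seg)) / s
    })
    unlist(out)
  }
  list(x = take(x), y = take(y), n_epochs = nrow(windows), windows = windows,
       blocks = blocks)
}


# Windowed (Hamming), linearly detrended, unit-power segment FFTs. The
# detrend keeps slow trends from leaking into the lowest analysis bands;
# the unit-power normalization cancels slow common gains (e.g.
# phrase-level loudness shared by all muscles) that would otherwise
# inflate the coherence estimate, while leaving genuine cross-spectral
# structure untouched. Returns the first nfft/2 + 1 bins.
segment_fft <- function(v, starts, window, nfft) {
  w <- signal::hamming(window)
  tt <- seq_len(window) - (window + 1) / 2
  stt <- sum(tt^2)
  m <- matrix(0, nfft, length(starts))
  for (i in seq_along(starts)) {
    s <- v[starts[i]:(starts[i] + window - 1L)]
    s <- s - mean(s) - tt * (sum(tt * s) / stt)
    s <- s * w
    nrm <- sqrt(sum(s^2))
    if (nrm > 0) s <- s / nrm
    m[seq_len(window), i] <- s
  }
  stats::mvfft(m)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
}

# Window start positions for Welch analysis inside contiguous blocks.
welch_starts <- function(blocks, window, step) {
  bnd <- cumsum(c(0L, as.integer(blocks)))
  starts <- unlist(lapply(seq_along(blocks), function(b) {
    if (blocks[b] < window) return(integer(0))
    seq(bnd[b] + 1L, bnd[b + 1L] - window + 1L, by = step)
  }))
  starts
}


msc_from_fft <- function(fx, fy) {
  sxx <- rowMeans(Mod(fx)^2)
  syy <- rowMeans(Mod(fy)^2)
  sxy <- rowMeans(Conj(fx) * fy)
  msc <- Mod(sxy)^2 / (sxx * syy)
  msc[!is.finite(msc)] <- 0
  pmin(pmax(msc, 0), 1)
}

#' Welch magnitude-squared coherence spectrum
#'
#' `|S_xy|^2 / (S_xx S_yy)` estimated with a sliding Hamming window
#' (default 1,024 points, 75% overlap) and a zero-padded FFT (default
#' 4,096 points), giving a frequency grid of `fs / 4096`. The effective
#' segment count `L_hat` is conservatively taken as the number of disjoint
#' window-length blocks, and the independence significance level
#' `S = 1 - 0.05^(1 / (L_hat - 1))` is attached.
#'
#' @param x,y Equal-length signals, at least one window long.
#' @param fs Sampling rate, Hz.
#' @param window Window length in samples.
#' @param overlap Fractional overlap of consecutive windows.
#' @param nfft FFT length (>= window).
#' @param l_hat Override for the effective segment count (e.g. the Welch
#'   window count instead of the disjoint-block default).
#' @param blocks When the inputs are concatenated epoch blocks, the block
#'   lengths in samples (summing to the signal length): sliding windows
#'   are then kept inside blocks so that the junction discontinuities
#'   (which occur at identical positions in both channels) cannot
#'   masquerade as broadband coherence.
#' @return An object of class `coherence_spectrum`: list with `freq`,
#'   `msc`, `l_hat`, `significance`, `fs`, `n_windows`.
#' @export
ms_coherence <- function(x, y, fs, window = 1024L, overlap = 0.75,
                         nfft = 4096L, l_hat = NULL, blocks = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < window) abort(sprintf("signals shorter than one window (%d samples).", window))
  step <- as.integer(round(window * (1 - overlap)))
  if (is.null(blocks)) blocks <- n
  if (sum(blocks) != n) abort("`blocks` must sum to the signal length.")
  starts <- welch_starts(blocks, window, step)
  if (!length(starts)) abort("no window fits inside a block.")
  fx <- segment_fft(x, starts, window, nfft)
  fy <- segment_fft(y, starts, window, nfft)
  msc <- msc_from_fft(fx, fy)
  # disjoint-block segment count; a disjoint block cannot span a
  # discontinuity, so blocks are counted within contiguous segments
  lh <- if (is.null(l_hat)) sum(blocks %/% window) else as.integer(l_hat)
  structure(
    list(freq = (seq_len(nfft %/% 2L + 1L) - 1L) * fs / nfft, msc = msc,
         l_hat = lh,
         significance = if (lh >= 2L) significance_level(lh) else NA_real_,
         fs = fs, n_windows = length(starts)),
    class = "coherence_spectrum"
  )
}

#' Independence significance level for a coherence estimate
#'
#' Upper 95% confidence limit of magnitude-squared coherence under the
#' hypothesis of independence: `S = 1 - 0.05^(1 / (L_hat - 1))`, strictly
#' decreasing in the effective segment count `L_hat`.
#'
#' @param l_hat Effective number of segments (>= 2).
#' @return Significance level in (0, 1).
#' @export
significance_level <- function(l_hat) {
  if (!is.numeric(l_hat) || l_hat < 2) abort("`l_hat` must be at least 2.")
  1 - 0.05^(1 / (l_hat - 1))
}

# Spectral-bin membership of a band: [low, high), upper edge inclusive
# on request (used for the 60 Hz gamma edge).
band_bins <- function(freq, band, include_upper = FALSE) {
  sel <- freq >= band[1] & freq < band[2]
  if (include_upper) sel <- sel | freq == band[2]
  sel
}

#' Significance-gated Fisher-z band weight
#'
#' If no bin of the band exceeds the attached significance level the
#' weight is 0 (the gate rules out spurious connections); otherwise the
#' weight is `atanh(sqrt(mean msc))`, the Fisher z-transform of the mean
#' coherency magnitude over all bins in the band.
#'
#' @param spec A `coherence_spectrum`.
#' @param band A band name from [MN_BANDS] or a numeric `c(low, high)` Hz.
#' @param include_upper Include the upper band edge (automatic for the
#'   named gamma band).
#' @return Non-negative Fisher-z weight.
#' @export
band_weight <- function(spec, band, include_upper = NULL) {
  if (is.character(band)) {
    nm <- match.arg(band, names(MN_BANDS))
    if (is.null(include_upper)) include_upper <- identical(nm, "gamma")
    band <- MN_BANDS[[nm]]
  }
  include_upper <- isTRUE(include_upper)
  if (band[1] < 0 || band[2] > spec$fs / 2) abort("band must lie within [0, fs/2].")
  sel <- band_bins(spec$freq, band, include_upper)
  if (!any(sel)) abort("band contains no spectral bins.")
  if (is.na(spec$significance)) abort("spectrum has no significance level (l_hat < 2).")
  if (max(spec$msc[sel]) <= spec$significance) return(0)
  # cap just below 1 so a numerically perfect band cannot return Inf
  atanh(sqrt(min(mean(spec$msc[sel]), 1 - 1e-12)))
}

#' Multiplex coherence network of a recording
#'
#' Computes the 45 edge weights (15 muscle pairs x 3 bands) of the
#' multiplex network: per pair, rectification, joint epoch extraction,
#' Welch coherence, then the significance-gated Fisher-z weight per band.
#' Pairs with no supra-threshold activity yield missing weights and are
#' recorded in the edge table.
#'
#' @param rec A preprocessed `semg_recording`.
#' @param window,overlap,nfft Welch settings (see [ms_coherence()]).
#' @return An object of class `multiplex_network`: list with `layers`
#'   (named list of 6 x 6 symmetric weight matrices), `edge_table`
#'   (tidy tibble: edge, band, weight, l_hat, significance, n_epochs) and
#'   `nodes`.
#' @export
multiplex_weights <- function(rec, window = 1024L, overlap = 0.75, nfft = 4096L) {
  rec <- as_semg_recording(rec)
  pairs <- utils::combn(6L, 2L)
  layers <- lapply(MN_BANDS, function(b) {
    m <- matrix(0, 6, 6, dimnames = list(MN_CHANNELS, MN_CHANNELS))
    m
  })
  rows <- vector("list", ncol(pairs) * length(MN_BANDS))
  ri <- 0L
  rect <- abs(rec$samples)
  ch_masks <- lapply(seq_len(6L), function(i) channel_burst_mask(rect[i, ], rec$fs))
  # pairs sharing an identical window set reuse each channel's segment
  # FFTs (common with a shared phrase rhythm)
  fft_cache <- new.env(parent = emptyenv())
  step <- as.integer(round(window * (1 - overlap)))
  nb <- nfft %/% 2L + 1L
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    edge <- paste0(MN_CHANNELS[i], "-", MN_CHANNELS[j])
    ep <- tryCatch(extract_epochs(rect[i, ], rect[j, ], rec$fs,
                                  masks = list(ch_masks[[i]], ch_masks[[j]])),
                   mn_no_epochs = function(e) NULL)
    # need at least two disjoint blocks so the independence threshold exists
    if (is.null(ep) || sum(ep$blocks %/% window) < 2L) {
      for (b in names(MN_BANDS)) {
        ri <- ri + 1L
        rows[[ri]] <- tibble::tibble(edge = edge, band = b, weight = NA_real_,
                                     l_hat = NA_integer_, significance = NA_real_,
                                     n_epochs = if (is.null(ep)) 0L else ep$n_epochs)
        layers[[b]][i, j] <- layers[[b]][j, i] <- NA_real_
      }
      next
    }
    starts <- welch_starts(ep$blocks, window, step)
    wkey <- paste(ep$windows[, 1L], collapse = ",")
    get_fft <- function(ch, v) {
      key <- paste0(ch, "|", wkey)
      f <- get0(key, envir = fft_cache)
      if (is.null(f)) {
        f <- segment_fft(v, starts, window, nfft)
        assign(key, f, envir = fft_cache)
      }
      f
    }
    lh <- sum(ep$blocks %/% window)
    spec <- structure(
      list(freq = (seq_len(nb) - 1L) * rec$fs / nfft,
           msc = msc_from_fft(get_fft(i, ep$x), get_fft(j, ep$y)),
           l_hat = lh, significance = significance_level(lh),
           fs = rec$fs, n_windows = length(starts)),
      class = "coherence_spectrum"
    )
    for (b in names(MN_BANDS)) {
      wgt <- band_weight(spec, b)
      layers[[b]][i, j] <- layers[[b]][j, i] <- wgt
      ri <- ri + 1L
      rows[[ri]] <- tibble::tibble(edge = edge, band = b, weight = wgt,
                                   l_hat = spec$l_hat,
                                   significance = spec$significance,
                                   n_epochs = ep$n_epochs)
    }
  }
  structure(
    list(layers = layers,
         edge_table = dplyr::bind_rows(rows),
         nodes = MN_CHANNELS,
         subject_id = rec$subject_id, sentence_id = rec$sentence_id),
    class = "multiplex_network"
  )
}

#' @export
print.multiplex_network <- function(x, ...) {
  nz <- sum(x$edge_table$weight > 0, na.rm = TRUE)
  cat(sprintf("<multiplex_network> 6 nodes, 3 bands, 45 weights (%d nonzero, %d missing)\n",
              nz, sum(is.na(x$edge_table$weight))))
  invisible(x)
}
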