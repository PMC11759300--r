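# Jaw kinematic metrics from 3D jaw-position traces: acceleration time,
# mean acceleration and stiffness of the jaw open/close cycles.

#' Create a jaw kinematic trace
#'
#' @param t Time in seconds (uniform sampling).
#' @param xyz N x 3 matrix of jaw positions (mm).
#' @param fs Sampling rate, Hz (default 100).
#' @param reference Length-3 anatomical reference point (mm), the lower
#'   central incisor.
#' @return An object of class `jaw_trace`: tibble with columns `t`, `x`,
#'   `y`, `z` and attributes `fs`, `reference`.
#' @export
jaw_trace <- function(t, xyz, fs = 100, reference = c(0, 0, 0)) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, length(t) == nrow(xyz), length(reference) == 3L)
  if (!all(is.finite(xyz)) || !all(is.finite(reference))) {
    abort("jaw trace coordinates must be finite.")
  }
  out <- tibble::tibble(t = t, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  attr(out, "fs") <- fs
  attr(out, "reference") <- as.numeric(reference)
  class(out) <- c("jaw_trace", class(out))
  out
}

trace_fs <- function(trace) attr(trace, "fs") %||% 100
trace_reference <- function(trace) {
  ref <- attr(trace, "reference")
  if (is.null(ref)) abort("jaw trace has no reference point.")
  ref
}

#' Low-pass filter a jaw trace
#'
#' Second-order Butterworth at 15 Hz, run forward-backward (zero lag),
#' applied to each coordinate.
#'
#' @param trace A `jaw_trace` of at least 1 s.
#' @param cutoff Cutoff frequency, Hz.
#' @return Filtered `jaw_trace`.
#' @export
preprocess_trace <- function(trace, cutoff = 15) {
  fs <- trace_fs(trace)
  if (fs <= 2 * cutoff) abort("`fs` must exceed twice the low-pass cutoff.")
  if (nrow(trace) < fs) abort("jaw trace must span at least 1 s.")
  bf <- signal::butter(2, cutoff / (fs / 2))
  pad <- as.integer(min(fs, nrow(trace) - 1L))
  for (cl in c("x", "y", "z")) {
    trace[[cl]] <- filtfilt_padded(trace[[cl]], bf, pad = pad)
  }
  trace
}

#' Distance-to-reference series of a jaw trace
#'
#' Pointwise Euclidean distance between the jaw sensor and the anatomical
#' reference point (lower central incisor).
#'
#' @param trace A `jaw_trace` with a reference point.
#' @return Numeric vector (mm).
#' @export
distance_series <- function(trace) {
  ref <- trace_reference(trace)
  sqrt((trace$x - ref[1])^2 + (trace$y - ref[2])^2 + (trace$z - ref[3])^2)
}

# Central-difference first derivative (one-sided at the ends).
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

# Sub-sample zero-crossing time (linear) between samples k and k+1.
interp_crossing <- function(v, k) {
  k + v[k] / (v[k] - v[k + 1])
}

# Sub-sample extremum location and value by parabolic interpolation.
interp_peak <- function(y, k) {
  n <- length(y)
  if (k <= 1L || k >= n) return(list(pos = k, value = y[k]))
  denom <- y[k - 1] - 2 * y[k] + y[k + 1]
  if (abs(denom) < .Machine$double.eps) return(list(pos = k, value = y[k]))
  delta <- 0.5 * (y[k - 1] - y[k + 1]) / denom
  list(pos = k + delta, value = y[k] - 0.25 * (y[k - 1] - y[k + 1]) * delta)
}

#' Segment a distance series into opening/closing half-cycles
#'
#' Half-cycles are delimited by zero crossings of the velocity (central
#' differences of the distance series). Half-cycles whose excursion is
#' below 5% of the global excursion are discarded as noise.
#'
#' @param d Distance series (mm).
#' @param fs Sampling rate, Hz.
#' @param min_excursion_frac Qualification floor as a fraction of the
#'   global excursion.
#' @return An object of class `jaw_cycles`: list with `cycles` tibble
#'   (integer `start`/`end` samples and fractional `onset` crossing
#'   positions), `velocity`, `accel`, `distance`, `fs`.
#' @export
segment_cycles <- function(d, fs, min_excursion_frac = 0.05) {
  dt <- 1 / fs
  v <- central_diff(d, dt)
  a <- central_diff(v, dt)
  n <- length(v)
  sgn <- sign(v)
  # carry the previous sign across exact zeros so each crossing counts once
  for (i in seq(2, n)) if (sgn[i] == 0) sgn[i] <- sgn[i - 1]
  cross <- which(sgn[-n] * sgn[-1] < 0)
  if (length(cross) < 2L) abort("no full jaw open/close cycle found.")
  excursion <- max(d) - min(d)
  if (excursion <= 0) abort("zero excursion: distance series is constant.")
  starts <- cross[-length(cross)]
  ends <- cross[-1]
  keep <- vapply(seq_along(starts), function(i) {
    seg <- d[starts[i]:(ends[i] + 1L)]
    (max(seg) - min(seg)) >= min_excursion_frac * excursion
  }, logical(1))
  if (!any(keep)) abort("no qualifying jaw cycles above the excursion floor.")
  onset <- vapply(starts, function(k) interp_crossing(v, k), numeric(1))
  offset <- vapply(ends, function(k) interp_crossing(v, k), numeric(1))
  structure(
    list(cycles = tibble::tibble(start = starts[keep], end = ends[keep],
                                 onset = onset[keep], offset = offset[keep]),
         velocity = v, accel = a, distance = d, fs = fs),
    class = "jaw_cycles"
  )
}

#' Acceleration time
#'
#' Average, across half-cycles, of the duration from movement onset
#' (velocity zero crossing) to the within-cycle peak speed. For a pure
#' sinusoid of frequency `f` this is a quarter period, `1 / (4 f)`.
#'
#' @param cycles A `jaw_cycles` object.
#' @return Seconds.
#' @export
acceleration_time <- function(cycles) {
  stopifnot(inherits(cycles, "jaw_cycles"))
  sp <- abs(cycles$velocity)
  per <- purrr::pmap_dbl(cycles$cycles, function(start, end, onset, offset) {
    rng <- start:(end + 1L)
    pk <- interp_peak(sp, rng[which.max(sp[rng])])
    (pk$pos - onset) / cycles$fs
  })
  mean(per)
}

#' Mean acceleration
#'
#' Average acceleration over the accelerating phase (onset to peak
#' velocity) of each half-cycle, i.e. peak speed divided by acceleration
#' time, averaged across half-cycles. For a sinusoid of amplitude `A` and
#' angular frequency `w` this equals `(2 / pi) A w^2`.
#'
#' @param cycles A `jaw_cycles` object.
#' @return mm/s^2.
#' @export
mean_acceleration <- function(cycles) {
  stopifnot(inherits(cycles, "jaw_cycles"))
  sp <- abs(cycles$velocity)
  per <- purrr::pmap_dbl(cycles$cycles, function(start, end, onset, offset) {
    rng <- start:(end + 1L)
    pk <- interp_peak(sp, rng[which.max(sp[rng])])
    dt <- (pk$pos - onset) / cycles$fs
    if (dt <= 0) return(NA_real_)
    pk$value / dt
  })
  mean(per, na.rm = TRUE)
}

#' Jaw stiffness
#'
#' Ratio of maximum speed to maximum distance of motion (global excursion)
#' over the sentence. For a sinusoid of angular frequency `w`,
#' `A w / (2 A) = w / 2`, independent of amplitude.
#'
#' @param d Distance series (mm).
#' @param fs Sampling rate, Hz.
#' @return 1/s.
#' @export
stiffness <- function(d, fs) {
  excursion <- max(d) - min(d)
  if (excursion <= 0) abort("zero excursion: stiffness is undefined.")
  sp <- abs(central_diff(d, 1 / fs))
  pk <- interp_peak(sp, which.max(sp))
  pk$value / excursion
}

#' Kinematic metrics of a jaw trace
#'
#' Low-pass filters the trace, forms the distance-to-incisor series,
#' segments half-cycles, and returns the three metrics.
#'
#' @param trace A `jaw_trace`.
#' @return One-row tibble: `acceleration_time` (s), `mean_acceleration`
#'   (mm/s^2), `stiffness` (1/s).
#' @export
jaw_kinematic_metrics <- function(trace) {
  tr <- preprocess_trace(trace)
  d <- distance_series(tr)
  fs <- trace_fs(tr)
  seg <- segment_cycles(d, fs)
  tibble::tibble(
    acceleration_time = acceleration_time(seg),
    mean_acceleration = mean_acceleration(seg),
    stiffness = stiffness(d, fs)
  )
}
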