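#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` after `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  code
}

# Deterministic stream-specific child seed; keeps results < 2^31 - 1.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 104729 * k) %% 2147483629) + 1L
}

#' Amplitude envelope via the analytic signal
#'
#' Magnitude of the FFT-based analytic signal (one-sided spectrum doubling),
#' i.e. the instantaneous amplitude of a narrow-band real signal.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length, the amplitude envelope.
#' @keywords internal
analytic_envelope <- function(x) {
  n <- length(x)
  if (n < 2) return(abs(x))
  X <- stats::fft(x)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Zero-phase Butterworth band-pass (order 2 per pass direction).
bandpass <- function(x, fs, band) {
  if (fs <= 2 * band[2]) {
    stop("sampling rate ", fs, " Hz too low for band (", band[1], ", ", band[2], ") Hz")
  }
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

# Zero-phase Butterworth low-pass.
lowpass <- function(x, fs, cutoff_hz, order = 2) {
  if (cutoff_hz >= fs / 2) stop("low-pass cutoff must be below Nyquist")
  bf <- signal::butter(order, cutoff_hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# Convert a logical mask on a uniform grid to (start, end) index runs.
mask_runs <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(start = starts[r$values], end = ends[r$values])
}

# Mean over sliding non-overlapping windows of (max - min); the per-cycle
# peak-to-peak measure shared by the generator and peak_to_peak_by_state().
windowed_pp <- function(x, fs, window_s) {
  w <- max(2L, round(window_s * fs))
  nwin <- floor(length(x) / w)
  if (nwin < 1) return(max(x) - min(x))
  m <- matrix(x[seq_len(nwin * w)], nrow = w)
  mean(apply(m, 2, function(v) max(v) - min(v)))
}

#' Local field potential trace container
#'
#' @param samples Numeric vector, millivolts.
#' @param fs Sampling rate, Hz.
#' @param t0 Time of the first sample, seconds.
#' @return An object of class `lfp_trace`.
#' @export
lfp_trace <- function(samples, fs, t0 = 0) {
  stopifnot(is.numeric(samples), length(samples) > 0, fs > 0)
  if (!all(is.finite(samples))) stop("LFP samples must be finite")
  structure(list(samples = as.numeric(samples), fs = fs, t0 = t0),
            class = "lfp_trace")
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

lfp_times <- function(lfp) lfp$t0 + (seq_along(lfp$samples) - 1) / lfp$fs
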