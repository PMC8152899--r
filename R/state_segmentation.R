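#' Amplitude envelope of the 3-6 Hz LFP component
#'
#' Zero-phase Butterworth band-pass followed by the magnitude of the
#' analytic signal; returned on the same grid as the input.
#'
#' @param lfp An [lfp_trace()].
#' @param band Frequency band `(low, high)` in Hz.
#' @return Numeric envelope vector, same length as `lfp$samples`.
#' @export
band_envelope <- function(lfp, band = c(3, 6)) {
  stopifnot(inherits(lfp, "lfp_trace"))
  analytic_envelope(bandpass(lfp$samples, lfp$fs, band))
}

#' Segment quiet vs. active wakefulness from the LFP
#'
#' Quiet wakefulness (QW) is any period of at least `min_qw_s` seconds during
#' which the 3-6 Hz amplitude envelope exceeds `thresh_factor` times the
#' baseline envelope level; everything else is active wakefulness (AW).
#' The baseline is a lower quantile of the envelope over the whole recording
#' (robust to the QW fraction), and brief sub-threshold gaps shorter than
#' `bridge_s` are bridged before the minimum-duration rule is applied,
#' emulating semi-automated threshold cleanup.
#'
#' @param lfp An [lfp_trace()].
#' @param min_qw_s Minimum QW duration, seconds.
#' @param thresh_factor Envelope threshold as a multiple of baseline.
#' @param band Oscillation band, Hz.
#' @param baseline_quantile Quantile of the envelope used as baseline.
#' @param bridge_s Maximum sub-threshold gap bridged between QW runs, s.
#' @return A `state_segmentation` list: `epochs` (data frame `start_s`,
#'   `end_s`, `label`), `transitions` (data frame `time_s`, `direction`,
#'   `refined`), `envelope`, `baseline`, `fs`, `band`.
#' @export
segment_states <- function(lfp, min_qw_s = 3, thresh_factor = 2,
                           band = c(3, 6), baseline_quantile = 0.4,
                           bridge_s = 0.5) {
  stopifnot(inherits(lfp, "lfp_trace"))
  fs <- lfp$fs
  n <- length(lfp$samples)
  dur <- n / fs
  if (stats::sd(lfp$samples) < 1e-12) {
    warning("constant LFP signal: returning a single AW epoch")
    return(structure(list(
      epochs = data.frame(start_s = 0, end_s = dur, label = "AW"),
      transitions = data.frame(time_s = numeric(0), direction = character(0),
                               refined = logical(0)),
      envelope = rep(0, n), baseline = 0, fs = fs, band = band),
      class = "state_segmentation"))
  }
  # running-median smoothing of the instantaneous envelope: the raw
  # analytic envelope of band-limited noise has heavy (Rayleigh) tails
  # whose brief excursions would chatter across the threshold; a median
  # removes them without spreading epoch edges the way a linear filter does
  k <- round(0.3 * fs)
  if (k %% 2 == 0) k <- k + 1
  env <- stats::runmed(band_envelope(lfp, band), max(3, k))
  baseline <- as.numeric(stats::quantile(env, baseline_quantile))
  mask <- env >= thresh_factor * baseline
  # bridge short sub-threshold gaps flanked by supra-threshold runs
  gap_max <- round(bridge_s * fs)
  gaps <- mask_runs(!mask)
  for (i in seq_len(nrow(gaps))) {
    if (gaps$start[i] > 1 && gaps$end[i] < n &&
        (gaps$end[i] - gaps$start[i] + 1) < gap_max) {
      mask[gaps$start[i]:gaps$end[i]] <- TRUE
    }
  }
  qw_runs <- mask_runs(mask)
  keep <- (qw_runs$end - qw_runs$start + 1) >= round(min_qw_s * fs)
  qw_runs <- qw_runs[keep, , drop = FALSE]
  # build the tiling epoch list
  epochs <- data.frame(start_s = numeric(0), end_s = numeric(0),
                       label = character(0))
  cursor <- 0
  for (i in seq_len(nrow(qw_runs))) {
    qs <- (qw_runs$start[i] - 1) / fs
    qe <- qw_runs$end[i] / fs
    if (qs > cursor) {
      epochs <- rbind(epochs, data.frame(start_s = cursor, end_s = qs, label = "AW"))
    }
    epochs <- rbind(epochs, data.frame(start_s = qs, end_s = qe, label = "QW"))
    cursor <- qe
  }
  if (cursor < dur) {
    epochs <- rbind(epochs, data.frame(start_s = cursor, end_s = dur, label = "AW"))
  }
  rownames(epochs) <- NULL
  tr <- data.frame(time_s = numeric(0), direction = character(0))
  if (nrow(epochs) > 1) {
    tt <- epochs$start_s[-1]
    dirn <- ifelse(epochs$label[-1] == "QW", "AW->QW", "QW->AW")
    tr <- data.frame(time_s = tt, direction = dirn)
  }
  tr$refined <- rep(FALSE, nrow(tr))
  structure(list(epochs = epochs, transitions = tr, envelope = env,
                 baseline = baseline, fs = fs, band = band),
            class = "state_segmentation")
}

#' @export
print.state_segmentation <- function(x, ...) {
  qw <- sum(with(x$epochs, end_s - start_s)[x$epochs$label == "QW"])
  tot <- max(x$epochs$end_s)
  cat(sprintf("<state_segmentation> %d epochs, QW %.1f/%.1f s (%.0f%%), baseline %.3g mV\n",
              nrow(x$epochs), qw, tot, 100 * qw / tot, x$baseline))
  invisible(x)
}

# strict-left / non-strict-right local maxima indices of a vector
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Refine transition times to oscillation-cycle peaks
#'
#' Moves each AW->QW transition to the first positive peak of the
#' band-passed LFP inside the QW epoch and each QW->AW transition to the
#' last such peak, the cycle-resolved timing convention for state changes.
#' Epochs without a detectable oscillation peak keep their coarse time and
#' are flagged `refined = FALSE`.
#'
#' @param lfp An [lfp_trace()].
#' @param segmentation A `state_segmentation` from [segment_states()].
#' @return The segmentation with its `transitions` updated.
#' @export
refine_transitions <- function(lfp, segmentation) {
  stopifnot(inherits(segmentation, "state_segmentation"))
  tr <- segmentation$transitions
  if (!nrow(tr)) return(segmentation)
  bp <- bandpass(lfp$samples, lfp$fs, segmentation$band)
  bp_env <- analytic_envelope(bp)
  tt <- lfp_times(lfp)
  eps <- segmentation$epochs
  tr$refined <- FALSE
  for (k in seq_len(nrow(tr))) {
    qw_row <- if (tr$direction[k] == "AW->QW") {
      which(eps$label == "QW" & abs(eps$start_s - tr$time_s[k]) < 1e-9)
    } else {
      which(eps$label == "QW" & abs(eps$end_s - tr$time_s[k]) < 1e-9)
    }
    if (!length(qw_row)) next
    idx <- which(tt >= eps$start_s[qw_row[1]] & tt < eps$end_s[qw_row[1]])
    if (length(idx) < 3) next
    # only full-amplitude cycle peaks count: at least half the epoch's
    # typical oscillation envelope, so onset/offset filter smear is skipped
    min_height <- 0.5 * stats::median(bp_env[idx])
    pk <- local_maxima(bp[idx])
    pk <- pk[bp[idx][pk] > max(min_height, 1e-9)]
    if (!length(pk)) next
    tr$time_s[k] <- if (tr$direction[k] == "AW->QW") {
      tt[idx[pk[1]]]
    } else {
      tt[idx[pk[length(pk)]]]
    }
    tr$refined[k] <- TRUE
  }
  segmentation$transitions <- tr
  segmentation
}

#' State-conditioned LFP power spectrum
#'
#' Welch-style average periodogram over all epochs carrying `label`: each
#' epoch is cut into `seg_s`-second windows with 50% overlap, each window's
#' tapered periodogram is computed with a standard routine, and spectra are
#' averaged on the common frequency grid.
#'
#' @param lfp An [lfp_trace()].
#' @param epochs Epoch data frame (`start_s`, `end_s`, `label`).
#' @param label State label to average over.
#' @param seg_s Window length, seconds (sets the frequency resolution).
#' @return Data frame with columns `freq_hz` and `power`.
#' @export
state_power_spectrum <- function(lfp, epochs, label, seg_s = 2) {
  rows <- which(epochs$label == label)
  if (!length(rows)) stop("no epochs with label ", label)
  fs <- lfp$fs
  w <- round(seg_s * fs)
  tt <- lfp_times(lfp)
  acc <- NULL; freq <- NULL; k <- 0
  for (i in rows) {
    idx <- which(tt >= epochs$start_s[i] & tt < epochs$end_s[i])
    if (length(idx) < w) next
    starts <- seq(1, length(idx) - w + 1, by = max(1, round(w / 2)))
    for (s0 in starts) {
      seg <- lfp$samples[idx[s0:(s0 + w - 1)]]
      sp <- stats::spec.pgram(stats::ts(seg, frequency = fs), taper = 0.1,
                              detrend = TRUE, plot = FALSE)
      if (is.null(acc)) { acc <- sp$spec; freq <- sp$freq } else acc <- acc + sp$spec
      k <- k + 1
    }
  }
  if (k == 0) stop("no epoch with label ", label, " is at least ", seg_s, " s long")
  data.frame(freq_hz = freq, power = acc / k)
}

#' Per-state mean peak-to-peak LFP amplitude
#'
#' Band-limits the signal, splits each epoch into oscillation-cycle-scale
#' windows and averages the windowed `max - min` per state, the
#' peak-to-peak amplitude statistic used to contrast QW and AW.
#'
#' @param lfp An [lfp_trace()].
#' @param epochs Epoch data frame (`start_s`, `end_s`, `label`).
#' @param band Band limits in Hz, or `NULL` for the raw signal.
#' @param window_s Peak-to-peak window length, seconds (about one 3-6 Hz
#'   cycle).
#' @return Named numeric vector of mean peak-to-peak amplitude (mV) per
#'   state label.
#' @export
peak_to_peak_by_state <- function(lfp, epochs, band = c(0.5, 50),
                                  window_s = 0.3) {
  x <- if (is.null(band)) lfp$samples else bandpass(lfp$samples, lfp$fs, band)
  tt <- lfp_times(lfp)
  labs <- unique(epochs$label)
  out <- stats::setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    pps <- c()
    for (i in which(epochs$label == lab)) {
      idx <- which(tt >= epochs$start_s[i] & tt < epochs$end_s[i])
      if (length(idx) < 2) next
      w <- max(2L, round(window_s * lfp$fs))
      nwin <- floor(length(idx) / w)
      if (nwin < 1) next
      m <- matrix(x[idx[seq_len(nwin * w)]], nrow = w)
      pps <- c(pps, apply(m, 2, function(v) max(v) - min(v)))
    }
    out[lab] <- if (length(pps)) mean(pps) else NA_real_
  }
  out
}

#' Time-weighted agreement between two state labelings
#'
#' Fraction of the compared span on which two epoch lists assign the same
#' label; used to score segmentation recovery against ground truth.
#'
#' @param epochs_a,epochs_b Epoch data frames (`start_s`, `end_s`, `label`).
#' @param step_s Evaluation grid step, seconds.
#' @return Agreement fraction in `[0, 1]`.
#' @export
label_agreement <- function(epochs_a, epochs_b, step_s = 0.01) {
  t1 <- min(max(epochs_a$end_s), max(epochs_b$end_s))
  grid <- seq(0, t1 - step_s, by = step_s) + step_s / 2
  lab_at <- function(eps, t) {
    i <- findInterval(t, eps$start_s)
    eps$label[pmax(i, 1L)]
  }
  mean(lab_at(epochs_a, grid) == lab_at(epochs_b, grid))
}
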