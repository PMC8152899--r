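#' Extract classification features from a mean spike waveform
#'
#' Duration is the trough-to-subsequent-peak interval of the mean waveform
#' (the standard extracellular width metric); the height ratio is the
#' amplitude of the late positive peak divided by the trough amplitude,
#' both measured from baseline (the mean of the first quarter of the
#' waveform). Narrow, strongly biphasic waveforms (large height ratio)
#' are characteristic of LGN interneurons; broad waveforms of TC relay
#' cells.
#'
#' @param waveform Data frame with columns `t_ms` and `v`, or a numeric
#'   vector of samples.
#' @param fs Sampling rate in Hz (required when `waveform` is a vector).
#' @return List of class `waveform_features`: `duration_ms`,
#'   `height_ratio`, `trough_t_ms`, `peak_t_ms`.
#' @export
waveform_features <- function(waveform, fs = NULL) {
  if (is.data.frame(waveform)) {
    t_ms <- waveform$t_ms; v <- waveform$v
  } else {
    if (is.null(fs)) stop("fs required for a bare sample vector")
    v <- as.numeric(waveform)
    t_ms <- (seq_along(v) - 1) / fs * 1000
  }
  base <- mean(v[seq_len(max(1L, floor(length(v) / 4)))])
  v0 <- v - base
  i_tr <- which.min(v0)
  if (v0[i_tr] >= 0) stop("no detectable trough in waveform")
  after <- v0[i_tr:length(v0)]
  i_pk_rel <- which.max(after)
  if (i_pk_rel == 1 || after[i_pk_rel] < 0.05 * abs(v0[i_tr])) {
    stop("no positive peak after the trough: unexpected waveform polarity")
  }
  i_pk <- i_tr + i_pk_rel - 1L
  structure(list(duration_ms = t_ms[i_pk] - t_ms[i_tr],
                 height_ratio = after[i_pk_rel] / abs(v0[i_tr]),
                 trough_t_ms = t_ms[i_tr], peak_t_ms = t_ms[i_pk]),
            class = "waveform_features")
}

#' Classify a cell from its waveform duration
#'
#' Interneuron (`"IN"`) when the trough-to-peak duration is below the
#' threshold, TC relay cell (`"TC"`) otherwise; a duration exactly at the
#' threshold classifies as TC (documented tie-break).
#'
#' @param features A [waveform_features()] result (or a list with
#'   `duration_ms`).
#' @param duration_thresh_ms Duration threshold in ms (default 0.35; the
#'   alternative convention of 0.3 ms can be configured).
#' @return `"TC"` or `"IN"`.
#' @export
classify_cell <- function(features, duration_thresh_ms = 0.35) {
  if (features$duration_ms < duration_thresh_ms) "IN" else "TC"
}

#' Detect thalamic spike bursts
#'
#' A burst is a maximal cluster of at least two spikes whose consecutive
#' interspike intervals are all `<= max_isi_s`, and which is separated from
#' every other such cluster by more than `min_sep_s` (edge-to-edge); when
#' two clusters are too close, both are rejected. Single spikes are never
#' bursts.
#'
#' @param spike_times Strictly increasing spike times, seconds.
#' @param max_isi_s Maximum intra-burst ISI, seconds (default 10 ms).
#' @param min_sep_s Minimum separation between bursts, seconds (default
#'   100 ms).
#' @return Data frame with one row per burst: `start_s`, `end_s`,
#'   `n_spikes`, `first_isi_ms`, and a list column `spikes` of member spike
#'   times.
#' @export
detect_bursts <- function(spike_times, max_isi_s = 0.010, min_sep_s = 0.100) {
  if (is.unsorted(spike_times, strictly = TRUE)) {
    stop("spike_times must be strictly increasing")
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), first_isi_ms = numeric(0))
  empty$spikes <- list()
  n <- length(spike_times)
  if (n < 2) return(empty)
  linked <- diff(spike_times) <= max_isi_s
  runs <- mask_runs(linked)           # runs of linked ISIs -> spike clusters
  if (!nrow(runs)) return(empty)
  cl_start <- runs$start              # first spike index of each cluster
  cl_end <- runs$end + 1L             # last spike index
  ok <- rep(TRUE, nrow(runs))
  if (nrow(runs) > 1) {
    for (i in seq_len(nrow(runs) - 1)) {
      gap <- spike_times[cl_start[i + 1]] - spike_times[cl_end[i]]
      if (gap <= min_sep_s) { ok[i] <- FALSE; ok[i + 1] <- FALSE }
    }
  }
  cl_start <- cl_start[ok]; cl_end <- cl_end[ok]
  if (!length(cl_start)) return(empty)
  out <- data.frame(
    start_s = spike_times[cl_start],
    end_s = spike_times[cl_end],
    n_spikes = cl_end - cl_start + 1L,
    first_isi_ms = (spike_times[cl_start + 1L] - spike_times[cl_start]) * 1000)
  out$spikes <- lapply(seq_along(cl_start),
                       function(i) spike_times[cl_start[i]:cl_end[i]])
  out
}

#' Subtype a burst as low-threshold (LTS) or high-threshold (HT)
#'
#' LTS bursts ride a calcium spike from hyperpolarized potentials and have
#' a short first ISI (~3.4 ms); HT bursts occur at less hyperpolarized
#' potentials with a longer first ISI (~8 ms). Classification uses strict
#' inequalities around `isi_cut_ms` (and `vm_cut_mV` when a pre-burst
#' membrane potential is supplied); a first ISI exactly at the cut, or
#' conflicting ISI/Vm evidence, returns `"unclassified"`.
#'
#' @param burst One row of [detect_bursts()] output (or a list with
#'   `first_isi_ms` and `n_spikes`).
#' @param vm_mV Optional pre-burst membrane potential, mV.
#' @param isi_cut_ms First-ISI cut, ms (default 5, midway between the LTS
#'   and HT class means).
#' @param vm_cut_mV Membrane-potential cut, mV (default -60).
#' @return `"LTS"`, `"HT"`, or `"unclassified"`.
#' @export
classify_burst <- function(burst, vm_mV = NULL, isi_cut_ms = 5,
                           vm_cut_mV = -60) {
  if (!is.null(burst$n_spikes) && burst$n_spikes < 2) {
    stop("a burst must contain at least two spikes")
  }
  isi <- burst$first_isi_ms
  if (isi < isi_cut_ms) {
    if (is.null(vm_mV) || vm_mV < vm_cut_mV) return("LTS")
  } else if (isi > isi_cut_ms) {
    if (is.null(vm_mV) || vm_mV > vm_cut_mV) return("HT")
  }
  "unclassified"
}

epochs_of <- function(segmentation) {
  if (inherits(segmentation, "state_segmentation")) segmentation$epochs
  else segmentation
}

#' State-conditioned firing rate
#'
#' Spike count over all epochs of each label divided by the total time in
#' that label.
#'
#' @param spike_times Spike times, seconds.
#' @param segmentation A `state_segmentation` or an epoch data frame
#'   (`start_s`, `end_s`, `label`).
#' @return Named numeric vector of rates (Hz), one entry per label.
#' @export
firing_rate_by_state <- function(spike_times, segmentation) {
  eps <- epochs_of(segmentation)
  labs <- unique(eps$label)
  out <- stats::setNames(numeric(length(labs)), labs)
  for (lab in labs) {
    rows <- which(eps$label == lab)
    tot <- sum(eps$end_s[rows] - eps$start_s[rows])
    cnt <- 0
    for (i in rows) {
      cnt <- cnt + sum(spike_times >= eps$start_s[i] & spike_times < eps$end_s[i])
    }
    out[lab] <- if (tot > 0) cnt / tot else NA_real_
  }
  out
}

#' Arousal modulation index
#'
#' `MI = (FR_AW - FR_QW) / (FR_AW + FR_QW)`, bounded in `[-1, 1]`: 1 is the
#' strongest possible excitation on a QW-to-AW state change (silent in QW),
#' -1 the strongest possible suppression (silent in AW).
#'
#' @param fr_aw,fr_qw Non-negative firing rates in AW and QW, Hz.
#' @return The modulation index.
#' @export
modulation_index <- function(fr_aw, fr_qw) {
  if (fr_aw < 0 || fr_qw < 0) stop("firing rates must be non-negative")
  if (fr_aw + fr_qw == 0) stop("modulation index undefined when both rates are 0")
  (fr_aw - fr_qw) / (fr_aw + fr_qw)
}

#' Peri-event time histogram
#'
#' Average spike rate around a set of trigger events (e.g., state
#' transitions), in half-open bins `[t, t + bin)` relative to each event,
#' reported in Hz.
#'
#' @param spike_times Spike times, seconds.
#' @param event_times Trigger times, seconds.
#' @param window_s Half-width of the window around each event, seconds.
#' @param bin_s Bin width, seconds.
#' @return Data frame with `bin_center_s`, `count` (summed over events) and
#'   `rate_hz`.
#' @export
peri_event_histogram <- function(spike_times, event_times, window_s = 2,
                                 bin_s = 0.1) {
  if (!length(event_times)) stop("no trigger events supplied")
  edges <- seq(-window_s, window_s, by = bin_s)
  counts <- numeric(length(edges) - 1)
  for (ev in event_times) {
    rel <- spike_times - ev
    rel <- rel[rel >= -window_s & rel < window_s]
    if (length(rel)) {
      counts <- counts + tabulate(findInterval(rel, edges), length(counts))
    }
  }
  data.frame(bin_center_s = edges[-length(edges)] + bin_s / 2,
             count = counts,
             rate_hz = counts / (length(event_times) * bin_s))
}

#' Spike-train autocorrelogram
#'
#' Histogram of all spike-pair lags up to `max_lag_s`, excluding zero-lag
#' self-pairs; symmetric by construction, with bins centered on multiples
#' of `bin_s`.
#'
#' @param spike_times Sorted spike times, seconds.
#' @param max_lag_s Maximum lag, seconds.
#' @param bin_s Bin width, seconds.
#' @return Data frame with `lag_s` (bin centers, negative to positive) and
#'   `count`.
#' @export
autocorrelogram <- function(spike_times, max_lag_s = 0.5, bin_s = 0.01) {
  n <- length(spike_times)
  diffs <- numeric(0)
  if (n > 1) {
    hi <- findInterval(spike_times + max_lag_s, spike_times)
    diffs <- unlist(lapply(seq_len(n - 1), function(i) {
      if (hi[i] > i) spike_times[(i + 1):hi[i]] - spike_times[i] else numeric(0)
    }))
  }
  k <- floor(max_lag_s / bin_s)
  centers <- (-k:k) * bin_s
  pos_counts <- vapply(seq_len(k), function(j) {
    sum(diffs >= (j - 0.5) * bin_s & diffs < (j + 0.5) * bin_s)
  }, numeric(1))
  center_count <- 2 * sum(diffs < 0.5 * bin_s)
  data.frame(lag_s = centers,
             count = c(rev(pos_counts), center_count, pos_counts))
}

#' Detect large EPSP events on a membrane-potential trace
#'
#' Smooths the trace, finds onsets where the voltage slope exceeds
#' `min_slope` (mV/ms) and the subsequent rise within 3 ms reaches
#' `min_amp_mV`, merges events closer than a 3 ms refractory interval, and
#' masks windows around detected action potentials so spike upstrokes are
#' not counted. When a segmentation is supplied, per-state event rates are
#' reported as well.
#'
#' @param vm A `vm_trace` (list with `samples` in mV and `fs`), e.g. from
#'   [synth_vm()].
#' @param min_amp_mV Minimum EPSP amplitude, mV.
#' @param min_slope Minimum rising slope, mV/ms.
#' @param segmentation Optional `state_segmentation` or epoch data frame
#'   for per-state rates.
#' @param spike_thresh_mV Voltage above which a sample is treated as part
#'   of an action potential, mV.
#' @return List with `event_times_s`, `rate_hz` (overall), and (when a
#'   segmentation is given) `rate_by_state`.
#' @export
detect_epsps <- function(vm, min_amp_mV = 1, min_slope = 1.5,
                         segmentation = NULL, spike_thresh_mV = -40) {
  x <- vm$samples; fs <- vm$fs
  n <- length(x)
  spk <- x > spike_thresh_mV
  if (all(spk)) stop("membrane potential has no subthreshold segments")
  mask <- spk
  half <- round(0.002 * fs)
  spk_runs <- mask_runs(spk)
  for (i in seq_len(nrow(spk_runs))) {
    mask[max(1, spk_runs$start[i] - half):min(n, spk_runs$end[i] + half)] <- TRUE
  }
  xs <- if (fs > 2000) lowpass(x, fs, 1000) else x
  # filter settle margin: zero-phase filtering leaves transients at the ends
  edge <- round(0.05 * fs)
  mask[seq_len(min(edge, n))] <- TRUE
  mask[seq(max(1, n - edge + 1), n)] <- TRUE
  slope <- c(0, diff(xs)) * fs / 1000          # mV per ms
  cand <- slope > min_slope & !mask
  onsets <- mask_runs(cand)$start
  look <- round(0.003 * fs)
  ev <- c()
  for (o in onsets) {
    rise <- max(xs[o:min(n, o + look)]) - xs[o]
    if (rise >= min_amp_mV) ev <- c(ev, o)
  }
  if (length(ev) > 1) {                         # 3 ms refractory merge
    keep <- c(TRUE, diff(ev) > round(0.003 * fs))
    ev <- ev[keep]
  }
  times <- (ev - 1) / fs
  out <- list(event_times_s = times, rate_hz = length(times) / (n / fs))
  if (!is.null(segmentation)) {
    # dead-time corrected per-state rates: time under the spike/edge mask is
    # not exposure, so it is removed from each state's denominator
    eps <- epochs_of(segmentation)
    tt <- (seq_len(n) - 1) / fs
    labs <- unique(eps$label)
    rates <- stats::setNames(numeric(length(labs)), labs)
    for (lab in labs) {
      rows <- which(eps$label == lab)
      cnt <- 0; exposure <- 0
      for (i in rows) {
        in_ep <- tt >= eps$start_s[i] & tt < eps$end_s[i]
        exposure <- exposure + sum(in_ep & !mask) / fs
        cnt <- cnt + sum(times >= eps$start_s[i] & times < eps$end_s[i])
      }
      rates[lab] <- if (exposure > 0) cnt / exposure else NA_real_
    }
    out$rate_by_state <- rates
  }
  out
}
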