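#' Configuration for a synthetic recording session
#'
#' Bundles every tunable of the synthetic-session generator. Defaults encode
#' the study conditions the analysis targets: quiet wakefulness (QW) carries
#' large 3-6 Hz cortical LFP oscillations (mean peak-to-peak 0.77 mV) and a
#' constricted pupil; active wakefulness (AW) carries low-amplitude
#' desynchronized LFP (0.27 mV peak-to-peak) and a dilated pupil.
#' Thalamocortical (TC) relay cells fire at 6.2 Hz in QW (rhythmic bursts) and
#' 20.1 Hz in AW (tonic); interneurons are modulated in the opposite
#' direction. The membrane potential sits at -63.0 mV in QW and -59.1 mV in
#' AW, follows the pupil with a 5 s delay, and carries large retinogeniculate
#' EPSPs at a state-independent rate of ~18 Hz.
#'
#' @param duration_s Session length, seconds.
#' @param lfp_fs LFP sampling rate, Hz.
#' @param vm_fs Membrane-potential sampling rate, Hz.
#' @param video_fps Eye-video frame rate, frames/s.
#' @param seed Integer seed; every generator derives its stream from it.
#' @param qw_dwell_range_s,aw_dwell_range_s `(min, max)` dwell-time ranges in
#'   seconds for the two states; the QW minimum must be >= 3 s so generated
#'   states satisfy the detector's definition.
#' @param qw_osc_band_hz Frequency band of the QW oscillation, Hz.
#' @param qw_pp_amp_mV,aw_pp_amp_mV Target per-cycle peak-to-peak LFP
#'   amplitude in each state, mV.
#' @param lfp_noise_mV SD of the additive broadband measurement noise, mV.
#' @param pupil_lag_s Delay of the membrane potential behind the pupil, s.
#' @param pupil_r_qw_px,pupil_r_aw_px Pupil-radius plateaus, pixels.
#' @param pupil_tau_s Pupil relaxation time constant, s.
#' @param pupil_noise_px White measurement noise on the radius, pixels (SD).
#' @param pupil_drift_px Amplitude of a slow sinusoidal drift, pixels.
#' @param tc_rate_qw_hz,tc_rate_aw_hz TC firing rates per state, Hz.
#' @param in_rate_qw_hz,in_rate_aw_hz Interneuron firing rates per state, Hz.
#' @param epsp_rate_hz Poisson rate of planted EPSPs, Hz (state-independent).
#' @param epsp_amp_mV EPSP kernel peak amplitude, mV.
#' @param vm_noise_mV SD of colored membrane-potential noise, mV.
#' @param vm_qw_mV,vm_aw_mV Baseline membrane potential per state, mV.
#' @param frame_px Eye-video frame edge length, pixels (square frames).
#' @param sync_interval_s Interval between all-black synchronization frames, s.
#' @param video_noise Pixel noise SD on the unit intensity scale.
#' @return A validated list of class `session_config`.
#' @export
session_config <- function(duration_s = 60,
                           lfp_fs = 1000,
                           vm_fs = 20000,
                           video_fps = 50,
                           seed = 1L,
                           qw_dwell_range_s = c(4, 8),
                           aw_dwell_range_s = c(4, 8),
                           qw_osc_band_hz = c(3, 6),
                           qw_pp_amp_mV = 0.77,
                           aw_pp_amp_mV = 0.27,
                           lfp_noise_mV = 0.02,
                           pupil_lag_s = 5,
                           pupil_r_qw_px = 10,
                           pupil_r_aw_px = 16,
                           pupil_tau_s = 1,
                           pupil_noise_px = 0.1,
                           pupil_drift_px = 0.5,
                           tc_rate_qw_hz = 6.2,
                           tc_rate_aw_hz = 20.1,
                           in_rate_qw_hz = 15,
                           in_rate_aw_hz = 6,
                           epsp_rate_hz = 18,
                           epsp_amp_mV = 2,
                           vm_noise_mV = 0.1,
                           vm_qw_mV = -63.0,
                           vm_aw_mV = -59.1,
                           frame_px = 64,
                           sync_interval_s = 10,
                           video_noise = 0.02) {
  cfg <- list(duration_s = duration_s, lfp_fs = lfp_fs, vm_fs = vm_fs,
              video_fps = video_fps, seed = as.integer(seed),
              qw_dwell_range_s = qw_dwell_range_s,
              aw_dwell_range_s = aw_dwell_range_s,
              qw_osc_band_hz = qw_osc_band_hz,
              qw_pp_amp_mV = qw_pp_amp_mV, aw_pp_amp_mV = aw_pp_amp_mV,
              lfp_noise_mV = lfp_noise_mV,
              pupil_lag_s = pupil_lag_s,
              pupil_r_qw_px = pupil_r_qw_px, pupil_r_aw_px = pupil_r_aw_px,
              pupil_tau_s = pupil_tau_s, pupil_noise_px = pupil_noise_px,
              pupil_drift_px = pupil_drift_px,
              tc_rate_qw_hz = tc_rate_qw_hz, tc_rate_aw_hz = tc_rate_aw_hz,
              in_rate_qw_hz = in_rate_qw_hz, in_rate_aw_hz = in_rate_aw_hz,
              epsp_rate_hz = epsp_rate_hz, epsp_amp_mV = epsp_amp_mV,
              vm_noise_mV = vm_noise_mV,
              vm_qw_mV = vm_qw_mV, vm_aw_mV = vm_aw_mV,
              frame_px = as.integer(frame_px),
              sync_interval_s = sync_interval_s,
              video_noise = video_noise)
  validate_session_config(cfg)
  structure(cfg, class = "session_config")
}

validate_session_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$duration_s) || cfg$duration_s <= 0) {
    stop("duration_s must be positive")
  }
  rates <- c(cfg$tc_rate_qw_hz, cfg$tc_rate_aw_hz, cfg$in_rate_qw_hz,
             cfg$in_rate_aw_hz, cfg$epsp_rate_hz)
  if (any(rates < 0)) stop("all rates must be >= 0")
  if (cfg$qw_dwell_range_s[1] < 3) {
    stop("QW dwell minimum must be >= 3 s (state-definition constraint)")
  }
  if (diff(cfg$qw_dwell_range_s) < 0 || diff(cfg$aw_dwell_range_s) < 0) {
    stop("dwell ranges must be (min, max) with min <= max")
  }
  if (cfg$qw_osc_band_hz[1] >= cfg$qw_osc_band_hz[2]) {
    stop("oscillation band must have low < high")
  }
  if (any(c(cfg$lfp_fs, cfg$vm_fs, cfg$video_fps) <= 0)) {
    stop("sampling rates must be positive")
  }
  invisible(cfg)
}

#' Generate an alternating QW/AW state sequence
#'
#' Semi-Markov process with uniform dwell draws: intervals of the two
#' wakefulness states alternate and exactly tile `[0, duration_s]`. Each QW
#' interval additionally carries the frequency of its 3-6 Hz oscillation
#' (drawn uniformly from the configured band) so the LFP and the rhythmic
#' TC burst generator stay phase-consistent.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#' @return A data frame with columns `start_s`, `end_s`, `label`
#'   (`"QW"`/`"AW"`) and `osc_hz` (`NA` for AW rows).
#' @export
generate_state_sequence <- function(config, seed = config$seed) {
  validate_session_config(config)
  dur <- config$duration_s
  if (dur < config$qw_dwell_range_s[1] + config$aw_dwell_range_s[1]) {
    stop("duration too short to contain one interval of each state")
  }
  with_seed(child_seed(seed, 1L), {
    lab <- sample(c("QW", "AW"), 1L)
    starts <- numeric(0); ends <- numeric(0); labs <- character(0)
    t <- 0
    while (t < dur) {
      rng <- if (lab == "QW") config$qw_dwell_range_s else config$aw_dwell_range_s
      d <- stats::runif(1, rng[1], rng[2])
      starts <- c(starts, t); ends <- c(ends, min(t + d, dur)); labs <- c(labs, lab)
      t <- t + d
      lab <- if (lab == "QW") "AW" else "QW"
    }
    n <- length(labs)
    # A truncated trailing interval can violate the QW minimum-dwell rule;
    # fold it into the preceding interval instead.
    min_last <- if (labs[n] == "QW") config$qw_dwell_range_s[1] else 0.5
    if (n > 1 && (ends[n] - starts[n]) < min_last) {
      ends[n - 1] <- dur
      starts <- starts[-n]; ends <- ends[-n]; labs <- labs[-n]
      n <- n - 1L
    }
    osc <- ifelse(labs == "QW",
                  stats::runif(n, config$qw_osc_band_hz[1], config$qw_osc_band_hz[2]),
                  NA_real_)
    data.frame(start_s = starts, end_s = ends, label = labs, osc_hz = osc,
               stringsAsFactors = FALSE)
  })
}

state_mask <- function(states, times, label = "QW") {
  mask <- logical(length(times))
  for (i in which(states$label == label)) {
    mask <- mask | (times >= states$start_s[i] & times < states$end_s[i])
  }
  mask
}

#' Synthesize a cortical LFP trace from a state sequence
#'
#' QW epochs carry an amplitude-modulated sinusoid at the epoch's 3-6 Hz
#' frequency, calibrated so the per-cycle peak-to-peak amplitude matches
#' `qw_pp_amp_mV`; AW epochs carry broadband (1-30 Hz) noise rescaled so its
#' measured per-cycle peak-to-peak matches `aw_pp_amp_mV`. Small white noise
#' is added throughout.
#'
#' @param states Output of [generate_state_sequence()].
#' @param config A [session_config()].
#' @param seed Optional integer seed.
#' @return An [lfp_trace()].
#' @export
synth_lfp <- function(states, config, seed = config$seed) {
  fs <- config$lfp_fs
  dur <- max(states$end_s)
  n <- round(dur * fs)
  tt <- (seq_len(n) - 1) / fs
  with_seed(child_seed(seed, 2L), {
    x <- numeric(n)
    for (i in which(states$label == "QW")) {
      idx <- which(tt >= states$start_s[i] & tt < states$end_s[i])
      if (!length(idx)) next
      f <- states$osc_hz[i]
      a0 <- config$qw_pp_amp_mV / 2
      ph <- stats::runif(1, 0, 2 * pi)
      tl <- tt[idx] - states$start_s[i]
      am <- 1 + 0.15 * sin(2 * pi * 0.4 * tl + ph)
      x[idx] <- a0 * am * sin(2 * pi * f * tl)
    }
    aw_idx <- which(state_mask(states, tt, "AW"))
    if (length(aw_idx) > fs / 2 && config$aw_pp_amp_mV > 0) {
      bb <- bandpass(stats::rnorm(n), fs, c(1, 30))
      meas <- windowed_pp(bb[aw_idx], fs, 0.3)
      if (meas > 0) x[aw_idx] <- bb[aw_idx] * (config$aw_pp_amp_mV / meas)
    }
    if (config$lfp_noise_mV > 0) {
      x <- x + stats::rnorm(n, 0, config$lfp_noise_mV)
    }
    lfp_trace(x, fs)
  })
}

#' Synthesize a pupil-radius trace on the video frame grid
#'
#' The radius relaxes with first-order dynamics (`pupil_tau_s`) toward the
#' state-dependent plateau (dilated in AW, constricted in QW), plus a slow
#' sinusoidal drift and white measurement noise. Returned alongside a
#' noise-free ground-truth copy.
#'
#' @inheritParams synth_lfp
#' @return Data frame with columns `time_s`, `radius_px` (noisy trace) and
#'   `truth_px` (noise-free); attribute `fps`.
#' @export
synth_pupil <- function(states, config, seed = config$seed) {
  fps <- config$video_fps
  dur <- max(states$end_s)
  n <- round(dur * fps)
  tt <- (seq_len(n) - 1) / fps
  with_seed(child_seed(seed, 3L), {
    target <- ifelse(state_mask(states, tt, "QW"),
                     config$pupil_r_qw_px, config$pupil_r_aw_px)
    r <- numeric(n)
    r[1] <- target[1]
    alpha <- (1 / fps) / max(config$pupil_tau_s, 1 / fps)
    for (i in 2:n) r[i] <- r[i - 1] + alpha * (target[i] - r[i - 1])
    drift <- config$pupil_drift_px * sin(2 * pi * tt / 37 + stats::runif(1, 0, 2 * pi))
    truth <- r + drift
    noisy <- truth + stats::rnorm(n, 0, config$pupil_noise_px)
    out <- data.frame(time_s = tt, radius_px = noisy, truth_px = truth)
    attr(out, "fps") <- fps
    out
  })
}

#' Spike waveform template
#'
#' Parametric mean extracellular waveform: a negative Gaussian trough
#' followed by a positive Gaussian after-peak. `duration_ms` is the nominal
#' trough-to-peak interval and `height_ratio` the peak/trough amplitude
#' ratio, the two features used for cell-type classification.
#'
#' @param duration_ms Trough-to-peak interval, ms.
#' @param height_ratio After-peak amplitude / trough amplitude.
#' @param fs Waveform sampling rate, Hz.
#' @return Data frame with columns `t_ms` and `v` (arbitrary units,
#'   trough normalized to -1).
#' @export
spike_template <- function(duration_ms, height_ratio, fs = 50000) {
  stopifnot(duration_ms > 0, height_ratio >= 0)
  t_ms <- seq(-1, 2, by = 1000 / fs)
  w1 <- duration_ms / 4
  w2 <- duration_ms / 2.5
  v <- -exp(-(t_ms / w1)^2) + height_ratio * exp(-((t_ms - duration_ms) / w2)^2)
  data.frame(t_ms = t_ms, v = v)
}

# Default templates: broad TC spike (0.44 ms, height ratio 0.41) and narrow
# biphasic interneuron spike (0.23 ms, height ratio 0.73).
default_waveform <- function(cell_type, fs = 50000) {
  switch(cell_type,
         TC = spike_template(0.44, 0.41, fs),
         IN = spike_template(0.23, 0.73, fs),
         stop("unknown cell_type: ", cell_type))
}

poisson_times <- function(rate_hz, t0, t1, refractory_s = 0) {
  len <- t1 - t0
  if (rate_hz <= 0 || len <= 0) return(numeric(0))
  k <- stats::rpois(1, rate_hz * len)
  if (k == 0) return(numeric(0))
  ts <- sort(stats::runif(k, t0, t1))
  if (refractory_s > 0 && length(ts) > 1) {
    keep <- c(TRUE, diff(ts) > refractory_s)
    while (!all(keep)) {
      ts <- ts[keep]
      keep <- c(TRUE, diff(ts) > refractory_s)
    }
  }
  ts
}

#' Synthesize a state-modulated spike train
#'
#' TC neurons fire tonically at `tc_rate_aw_hz` during AW and emit rhythmic
#' bursts locked to the QW oscillation cycle during QW (2-4 spikes,
#' intra-burst interspike intervals <= 10 ms, LTS-like first ISI ~3.4 ms),
#' with burst probability chosen so the mean QW rate matches
#' `tc_rate_qw_hz`. Interneurons fire tonically with the opposite rate
#' modulation. Planted burst onsets are recorded as ground truth.
#'
#' @inheritParams synth_lfp
#' @param cell_type `"TC"` or `"IN"`.
#' @return List with `times_s` (spike times), `waveform` (mean waveform data
#'   frame), `waveform_fs`, `cell_type` and `bursts` (data frame of planted
#'   bursts; `NULL` for interneurons).
#' @export
synth_spike_train <- function(states, cell_type, config, seed = config$seed) {
  if (!cell_type %in% c("TC", "IN")) stop("unknown cell_type: ", cell_type)
  with_seed(child_seed(seed, if (cell_type == "TC") 4L else 5L), {
    times <- numeric(0)
    bursts <- NULL
    if (cell_type == "IN") {
      for (i in seq_len(nrow(states))) {
        r <- if (states$label[i] == "QW") config$in_rate_qw_hz else config$in_rate_aw_hz
        times <- c(times, poisson_times(r, states$start_s[i], states$end_s[i], 0.001))
      }
    } else {
      b_onset <- numeric(0); b_n <- integer(0); b_isi1 <- numeric(0)
      for (i in seq_len(nrow(states))) {
        if (states$label[i] == "AW") {
          times <- c(times, poisson_times(config$tc_rate_aw_hz,
                                          states$start_s[i], states$end_s[i], 0.002))
        } else {
          f <- states$osc_hz[i]
          if (is.na(f)) f <- mean(config$qw_osc_band_hz)
          # oscillation peaks of the epoch's LFP sinusoid
          peaks <- states$start_s[i] + (0.25 + 0:floor((states$end_s[i] - states$start_s[i]) * f)) / f
          peaks <- peaks[peaks + 0.04 < states$end_s[i]]
          p_burst <- min(1, config$tc_rate_qw_hz / (f * 3))
          for (pk in peaks) {
            if (stats::runif(1) > p_burst) next
            nsp <- sample(2:4, 1)
            isi1 <- max(2, stats::rnorm(1, 3.38, 0.15)) / 1000
            isis <- c(isi1, pmin(0.010, pmax(0.002, stats::rnorm(nsp - 2, 0.0045, 5e-4))))
            sp <- pk + c(0, cumsum(isis[seq_len(nsp - 1)]))
            times <- c(times, sp)
            b_onset <- c(b_onset, pk); b_n <- c(b_n, nsp)
            b_isi1 <- c(b_isi1, isi1 * 1000)
          }
        }
      }
      bursts <- data.frame(onset_s = b_onset, n_spikes = b_n, first_isi_ms = b_isi1)
      bursts <- bursts[order(bursts$onset_s), , drop = FALSE]
      rownames(bursts) <- NULL
    }
    list(times_s = sort(times),
         waveform = default_waveform(cell_type),
         waveform_fs = 50000,
         cell_type = cell_type,
         bursts = bursts)
  })
}

#' Synthesize an intracellular membrane-potential trace
#'
#' The subthreshold baseline is an affine map of the (ground-truth) pupil
#' radius delayed by `pupil_lag_s`, scaled between `vm_qw_mV` and
#' `vm_aw_mV`. Poisson EPSP events with a fixed double-exponential kernel
#' are added at `epsp_rate_hz` independently of state, action potentials are
#' superimposed at the supplied (or internally generated TC) spike times,
#' and colored noise completes the trace.
#'
#' @inheritParams synth_lfp
#' @param pupil Output of [synth_pupil()].
#' @param spike_times Optional spike times to superimpose; defaults to an
#'   internally generated TC train.
#' @return List of class `vm_trace` with `samples` (mV), `fs`, `t0`,
#'   planted `epsp_times` and `spike_times`, and the noise-free `baseline`.
#' @export
synth_vm <- function(states, pupil, config, seed = config$seed, spike_times = NULL) {
  fs <- config$vm_fs
  dur <- max(states$end_s)
  if (max(pupil$time_s) < dur - 1.5 / attr(pupil, "fps")) {
    stop("pupil trace shorter than session")
  }
  n <- round(dur * fs)
  tv <- (seq_len(n) - 1) / fs
  if (is.null(spike_times)) {
    spike_times <- synth_spike_train(states, "TC", config, seed)$times_s
  }
  with_seed(child_seed(seed, 6L), {
    p_del <- stats::approx(pupil$time_s, pupil$truth_px,
                           xout = tv - config$pupil_lag_s, rule = 2)$y
    span <- config$pupil_r_aw_px - config$pupil_r_qw_px
    baseline <- config$vm_qw_mV +
      (p_del - config$pupil_r_qw_px) / span * (config$vm_aw_mV - config$vm_qw_mV)
    x <- baseline
    # EPSPs: double-exponential kernel, peak normalized to epsp_amp_mV
    epsp_times <- poisson_times(config$epsp_rate_hz, 0, dur)
    if (length(epsp_times)) {
      tau_r <- 5e-4; tau_d <- 4e-3
      kt <- seq(0, 6 * tau_d, by = 1 / fs)
      kern <- exp(-kt / tau_d) - exp(-kt / tau_r)
      kern <- kern / max(kern) * config$epsp_amp_mV
      for (et in epsp_times) {
        i0 <- floor(et * fs) + 1L
        idx <- i0:min(n, i0 + length(kern) - 1L)
        x[idx] <- x[idx] + kern[seq_along(idx)]
      }
    }
    if (length(spike_times)) {
      akt <- seq(-1e-3, 1e-3, by = 1 / fs)
      ap <- 90 * exp(-(akt / 2.5e-4)^2)
      half <- (length(ap) - 1L) %/% 2L
      for (st in spike_times) {
        ic <- round(st * fs) + 1L
        idx <- max(1L, ic - half):min(n, ic + half)
        x[idx] <- x[idx] + ap[idx - ic + half + 1L]
      }
    }
    if (config$vm_noise_mV > 0) {
      nz <- lowpass(stats::rnorm(n), fs, min(500, fs / 2.5))
      x <- x + nz * (config$vm_noise_mV / stats::sd(nz))
    }
    structure(list(samples = x, fs = fs, t0 = 0,
                   epsp_times = epsp_times, spike_times = spike_times,
                   baseline = baseline),
              class = "vm_trace")
  })
}

render_eye_frame <- function(frame_px, cx, cy, r, iris_r,
                             pupil_int = 0.15, iris_in = 0.85,
                             iris_out = 0.55, bg_int = 0.5) {
  xs <- matrix(seq_len(frame_px), frame_px, frame_px, byrow = TRUE)
  ys <- matrix(seq_len(frame_px), frame_px, frame_px)
  d <- sqrt((xs - cx)^2 + (ys - cy)^2)
  ai <- pmin(pmax(iris_r - d + 0.5, 0), 1)   # anti-aliased iris edge
  ap <- pmin(pmax(r - d + 0.5, 0), 1)        # anti-aliased pupil edge
  # radial iris shading (brightest at the pupillary margin, as in IR
  # imaging); the outward intensity falloff makes the pupil edge a strict
  # optimum of the ring-minus-disc contrast energy
  iris_int <- iris_in - (iris_in - iris_out) * pmin(d / iris_r, 1)
  img <- bg_int * (1 - ai) + iris_int * ai
  img * (1 - ap) + pupil_int * ap
}

#' Synthesize an infrared eye video
#'
#' Each frame renders a dark pupil disc (radius from the supplied trace,
#' with slow centroid jitter) on a brighter iris disc over a mid-gray
#' background, plus pixel noise; designated synchronization frames are
#' rendered all-black. Per-frame ground-truth geometry is returned.
#'
#' @inheritParams synth_vm
#' @param black_frames Integer frame indices rendered all-black; default
#'   every `sync_interval_s` seconds (never frame 1).
#' @return List with `frames` (list of `frame_px` x `frame_px` matrices in
#'   `[0, 1]`), `black_frames`, `truth` (data frame: `frame`, `time_s`,
#'   `cx`, `cy`, `r`) and `fps`.
#' @export
synth_eye_video <- function(pupil, config, seed = config$seed, black_frames = NULL) {
  npx <- config$frame_px
  fps <- attr(pupil, "fps")
  if (is.null(fps)) fps <- config$video_fps
  n <- nrow(pupil)
  iris_r <- 0.45 * npx
  if (max(pupil$radius_px) + 2 > iris_r) {
    stop("pupil radius exceeds frame bounds (iris radius ", round(iris_r, 1), " px)")
  }
  if (is.null(black_frames)) {
    step <- round(config$sync_interval_s * fps)
    black_frames <- seq(step, n, by = step)
    black_frames <- black_frames[black_frames > 1]
  }
  with_seed(child_seed(seed, 7L), {
    c0 <- (npx + 1) / 2
    jx <- 1.5 * tanh(cumsum(stats::rnorm(n, 0, 0.03)) / 1.5)
    jy <- 1.5 * tanh(cumsum(stats::rnorm(n, 0, 0.03)) / 1.5)
    frames <- vector("list", n)
    for (i in seq_len(n)) {
      if (i %in% black_frames) {
        frames[[i]] <- matrix(0, npx, npx)
      } else {
        img <- render_eye_frame(npx, c0 + jx[i], c0 + jy[i],
                                pupil$radius_px[i], iris_r)
        if (config$video_noise > 0) {
          img <- img + matrix(stats::rnorm(npx * npx, 0, config$video_noise), npx, npx)
        }
        frames[[i]] <- pmin(pmax(img, 0), 1)
      }
    }
    truth <- data.frame(frame = seq_len(n), time_s = pupil$time_s,
                        cx = c0 + jx, cy = c0 + jy, r = pupil$radius_px)
    truth[truth$frame %in% black_frames, c("cx", "cy", "r")] <- NA
    list(frames = frames, black_frames = black_frames, truth = truth, fps = fps)
  })
}

#' Generate a complete synthetic session
#'
#' Convenience wrapper producing all coupled components of one recording:
#' state sequence, LFP, pupil trace, TC and interneuron spike trains,
#' membrane potential, and (optionally) the eye video. Identical
#' `(config, seed)` give bit-identical sessions.
#'
#' @param config A [session_config()].
#' @param seed Optional integer seed overriding `config$seed`.
#' @param video Logical; render the eye video (the slowest component)?
#' @return List with components `config`, `states`, `lfp`, `pupil`, `tc`,
#'   `inn`, `vm` and (if requested) `video`.
#' @export
generate_session <- function(config = session_config(), seed = config$seed,
                             video = TRUE) {
  states <- generate_state_sequence(config, seed)
  pupil <- synth_pupil(states, config, seed)
  tc <- synth_spike_train(states, "TC", config, seed)
  out <- list(config = config,
              states = states,
              lfp = synth_lfp(states, config, seed),
              pupil = pupil,
              tc = tc,
              inn = synth_spike_train(states, "IN", config, seed),
              vm = synth_vm(states, pupil, config, seed, spike_times = tc$times_s))
  if (video) out$video <- synth_eye_video(pupil, config, seed)
  out
}

#' Write a synthetic session to plain-text files
#'
#' LFP and pupil as two-column `(time_s, value)` tab-separated tables, spike
#' trains as one event time per row, and the ground truth (state intervals,
#' planted bursts, EPSP times, lag) as a YAML sidecar.
#'
#' @param session Output of [generate_session()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(lfp = file.path(dir, "lfp.tsv"),
             pupil = file.path(dir, "pupil.tsv"),
             tc = file.path(dir, "spikes_tc.txt"),
             inn = file.path(dir, "spikes_in.txt"),
             truth = file.path(dir, "ground_truth.yaml"))
  utils::write.table(
    data.frame(time_s = lfp_times(session$lfp), mV = session$lfp$samples),
    paths["lfp"], sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(time_s = session$pupil$time_s, radius_px = session$pupil$radius_px),
    paths["pupil"], sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(format(session$tc$times_s, digits = 10), paths["tc"])
  writeLines(format(session$inn$times_s, digits = 10), paths["inn"])
  yaml::write_yaml(list(
    lfp_fs = session$lfp$fs,
    video_fps = attr(session$pupil, "fps"),
    pupil_lag_s = session$config$pupil_lag_s,
    state_intervals = lapply(seq_len(nrow(session$states)), function(i) {
      as.list(session$states[i, c("start_s", "end_s", "label")])
    }),
    planted_burst_onsets_s = as.numeric(session$tc$bursts$onset_s),
    epsp_times_s = as.numeric(session$vm$epsp_times)
  ), paths["truth"])
  invisible(paths)
}
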