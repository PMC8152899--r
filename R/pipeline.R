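default_pipeline_config <- function() {
  list(
    seed = 1L,
    out_dir = file.path(tempdir(), "pupilstate-run"),
    log_level = "info",
    synthio = TRUE,
    inputs = list(),
    render_video = TRUE,
    figures = TRUE,
    session = list(),                       # session_config() overrides
    pupillometry = list(ratio = sqrt(2), black_thresh = 0.02,
                        steps = c(4, 2, 1, 0.5, 0.25), max_iter = 200),
    segmentation = list(min_qw_s = 3, thresh_factor = 2, band = c(3, 6),
                        baseline_quantile = 0.4, bridge_s = 0.5),
    spikes = list(duration_thresh_ms = 0.35, max_isi_s = 0.010,
                  min_sep_s = 0.100, isi_cut_ms = 5, vm_cut_mV = -60,
                  epsp_min_amp_mV = 1, epsp_min_slope = 1.5),
    stats = list(bin_s = 1, n_perm = 1000, band = 0.95,
                 lowpass_hz = 0.5, max_lag_s = 10)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every unset field with its default (the analysis conventions: 3 s
#' minimum QW, 2x envelope threshold, 3-6 Hz band, 10 ms / 100 ms burst
#' rules, 0.35 ms duration threshold, 1 s correlation bins, 1000
#' permutations, 95% band, terciles), checks consistency, and returns the
#' effective configuration. A path to a YAML file may be given instead of a
#' list.
#'
#' @param config Partial configuration list, or a YAML file path, or `NULL`
#'   for all defaults.
#' @return The normalized configuration list.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config)) config <- list()
  cfg <- merge_config(default_pipeline_config(), config)
  sc <- do.call(session_config,
                merge_config(list(seed = cfg$seed), cfg$session))
  cfg$session <- sc
  if (cfg$segmentation$min_qw_s < 3) {
    warning("minimum QW duration below the standard 3 s definition")
  }
  if (cfg$segmentation$thresh_factor <= 0) stop("thresh_factor must be positive")
  if (cfg$stats$n_perm < 1) stop("n_perm must be >= 1")
  if (cfg$stats$band <= 0 || cfg$stats$band >= 1) stop("band must be in (0, 1)")
  cfg
}

#' Load a session written by [write_session()]
#'
#' Reads the plain-text LFP/pupil tables, spike-time files and the
#' ground-truth YAML sidecar back into the in-memory session layout used by
#' [run_pipeline()]. Components without files (membrane potential, video)
#' are left `NULL` and their analysis stages are skipped.
#'
#' @param dir Directory produced by [write_session()].
#' @param config A [session_config()] supplying defaults for metadata
#'   missing from the sidecar.
#' @return A session list (`states`, `lfp`, `pupil`, `tc`, `inn`).
#' @export
load_session_dir <- function(dir, config = session_config()) {
  need <- file.path(dir, c("lfp.tsv", "pupil.tsv", "spikes_tc.txt", "spikes_in.txt"))
  miss <- need[!file.exists(need)]
  if (length(miss)) stop("missing session file(s): ", paste(basename(miss), collapse = ", "))
  gt_path <- file.path(dir, "ground_truth.yaml")
  gt <- if (file.exists(gt_path)) yaml::read_yaml(gt_path) else list()
  lt <- utils::read.delim(need[1])
  fs <- gt$lfp_fs %||% round(1 / stats::median(diff(lt$time_s)))
  pt <- utils::read.delim(need[2])
  pupil <- data.frame(time_s = pt$time_s, radius_px = pt$radius_px,
                      truth_px = pt$radius_px)
  attr(pupil, "fps") <- gt$video_fps %||% round(1 / stats::median(diff(pt$time_s)))
  states <- if (!is.null(gt$state_intervals)) {
    do.call(rbind, lapply(gt$state_intervals, as.data.frame))
  } else NULL
  list(config = config,
       states = states,
       lfp = lfp_trace(lt$mV, fs),
       pupil = pupil,
       tc = list(times_s = as.numeric(readLines(need[3])),
                 waveform = default_waveform("TC"), waveform_fs = 50000,
                 cell_type = "TC", bursts = NULL),
       inn = list(times_s = as.numeric(readLines(need[4])),
                  waveform = default_waveform("IN"), waveform_fs = 50000,
                  cell_type = "IN", bursts = NULL),
       vm = NULL, video = NULL)
}

log_line <- function(con, stage, msg) {
  writeLines(sprintf("[%s] %s", stage, msg), con)
}

analyze_neuron <- function(name, train, seg, track, cfg, seed) {
  feats <- waveform_features(train$waveform)
  cls <- classify_cell(feats, cfg$spikes$duration_thresh_ms)
  rates <- firing_rate_by_state(train$times_s, seg)
  fr_qw <- unname(rates["QW"]); fr_aw <- unname(rates["AW"])
  mi <- if (isTRUE(fr_qw + fr_aw > 0)) modulation_index(fr_aw, fr_qw) else NA_real_
  bursts <- detect_bursts(train$times_s, cfg$spikes$max_isi_s, cfg$spikes$min_sep_s)
  al <- align_session(train$times_s, track, cfg$stats$bin_s)
  pc <- permutation_correlation(al$fr_hz, al$pupil, cfg$stats$n_perm,
                                cfg$stats$band, seed = seed)
  masks <- tercile_partition(al$pupil)
  frt <- fr_by_pupil_tercile(al$fr_hz, masks)
  list(neuron = name, features = feats, cell_class = cls,
       fr_qw_hz = fr_qw, fr_aw_hz = fr_aw, mi = mi,
       n_bursts = nrow(bursts), bursts = bursts,
       r = pc$r_obs, p = pc$p_two_tailed, modulation_class = pc$modulation_class,
       fr_constricted_hz = unname(frt["constricted"]),
       fr_dilated_hz = unname(frt["dilated"]),
       aligned = al)
}

#' Run the full arousal-analysis pipeline on a synthetic session
#'
#' Generates a synthetic session, tracks the pupil across the rendered eye
#' video, segments wakefulness states from the LFP (with cycle-peak
#' transition refinement), analyzes both model neurons (waveform features,
#' cell class, bursts, state rates, modulation index, permutation
#' correlation, tercile rates), estimates the membrane-potential/pupil lag
#' and EPSP rates, and writes CSV tables, figures, a run log, and a
#' machine-readable JSON summary. The whole report is a pure function of
#' `(config, seed)`.
#'
#' @param config Partial pipeline configuration (see [validate_config()]).
#' @return Invisibly, the summary list (also written to
#'   `out_dir/summary.json`).
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- validate_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(cfg$out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)
  stage <- "simulate"
  res <- tryCatch({
    if (isTRUE(cfg$synthio)) {
      log_line(logf, stage, paste0("seed=", cfg$seed,
                                   " duration_s=", cfg$session$duration_s))
      ses <- generate_session(cfg$session, seed = cfg$seed,
                              video = isTRUE(cfg$render_video))
    } else {
      stage <- "load"
      if (is.null(cfg$inputs$session_dir)) {
        stop("synthetic generation disabled and no inputs$session_dir given")
      }
      ses <- load_session_dir(cfg$inputs$session_dir, cfg$session)
      cfg$render_video <- FALSE
      log_line(logf, stage, paste0("loaded session from ", cfg$inputs$session_dir))
    }

    stage <- "track"
    if (isTRUE(cfg$render_video)) {
      npx <- cfg$session$frame_px
      init <- snake((npx + 1) / 2, (npx + 1) / 2,
                    mean(c(cfg$session$pupil_r_qw_px, cfg$session$pupil_r_aw_px)),
                    ratio = cfg$pupillometry$ratio)
      iris <- c(max(1, round(npx * 0.08)), max(1, round(npx * 0.4)),
                max(2, round(npx * 0.1)), max(2, round(npx * 0.12)))
      track <- track_video(ses$video$frames, init, iris,
                           opts = c(cfg$pupillometry, list(fps = ses$video$fps)))
      log_line(logf, stage, paste0(sum(track$is_black), " black frame(s) flagged"))
    } else {
      track <- data.frame(frame = seq_len(nrow(ses$pupil)),
                          cx = NA, cy = NA, r = ses$pupil$radius_px,
                          is_black = FALSE, energy = NA)
      attr(track, "fps") <- attr(ses$pupil, "fps")
      class(track) <- c("pupil_track", "data.frame")
      log_line(logf, stage, "video rendering disabled; using generator pupil trace")
    }
    write_track_csv(track, file.path(cfg$out_dir, "pupil_track.csv"))

    stage <- "segment"
    seg <- segment_states(ses$lfp, cfg$segmentation$min_qw_s,
                          cfg$segmentation$thresh_factor, cfg$segmentation$band,
                          cfg$segmentation$baseline_quantile,
                          cfg$segmentation$bridge_s)
    seg <- refine_transitions(ses$lfp, seg)
    utils::write.csv(seg$epochs, file.path(cfg$out_dir, "state_epochs.csv"),
                     row.names = FALSE)
    utils::write.csv(seg$transitions, file.path(cfg$out_dir, "state_transitions.csv"),
                     row.names = FALSE)
    agree <- if (is.null(ses$states)) NA_real_ else label_agreement(seg$epochs, ses$states)
    log_line(logf, stage, sprintf("%d epochs, agreement with truth %.3f",
                                  nrow(seg$epochs), agree))
    pp <- peak_to_peak_by_state(ses$lfp, seg$epochs)

    stage <- "spikes"
    neurons <- list(
      analyze_neuron("tc1", ses$tc, seg, track, cfg, child_seed(cfg$seed, 101L)),
      analyze_neuron("in1", ses$inn, seg, track, cfg, child_seed(cfg$seed, 102L)))
    ntab <- do.call(rbind, lapply(neurons, function(nn) {
      data.frame(neuron = nn$neuron, cell_class = nn$cell_class,
                 duration_ms = nn$features$duration_ms,
                 height_ratio = nn$features$height_ratio,
                 fr_qw_hz = nn$fr_qw_hz, fr_aw_hz = nn$fr_aw_hz, mi = nn$mi,
                 n_bursts = nn$n_bursts, r = nn$r, p = nn$p,
                 modulation_class = nn$modulation_class,
                 fr_constricted_hz = nn$fr_constricted_hz,
                 fr_dilated_hz = nn$fr_dilated_hz)
    }))
    utils::write.csv(ntab, file.path(cfg$out_dir, "neurons.csv"), row.names = FALSE)
    tc_bursts <- neurons[[1]]$bursts
    if (nrow(tc_bursts)) {
      tc_bursts$subtype <- vapply(seq_len(nrow(tc_bursts)), function(i) {
        classify_burst(tc_bursts[i, ], isi_cut_ms = cfg$spikes$isi_cut_ms)
      }, character(1))
      utils::write.csv(tc_bursts[, c("start_s", "end_s", "n_spikes",
                                     "first_isi_ms", "subtype")],
                       file.path(cfg$out_dir, "bursts_tc.csv"), row.names = FALSE)
    }
    log_line(logf, stage, sprintf("tc class=%s in class=%s, %d TC bursts",
                                  ntab$cell_class[1], ntab$cell_class[2],
                                  nrow(tc_bursts)))

    stage <- "vm"
    lag <- NULL; epsp <- NULL
    if (!is.null(ses$vm)) {
      fps <- attr(ses$pupil, "fps")
      dec <- max(1L, round(ses$vm$fs / fps))
      vm_ds <- ses$vm$samples[seq(1, length(ses$vm$samples), by = dec)]
      m <- min(length(vm_ds), nrow(ses$pupil))
      lag <- vm_pupil_lag(vm_ds[seq_len(m)], ses$pupil$radius_px[seq_len(m)],
                          fs = fps, lowpass_hz = cfg$stats$lowpass_hz,
                          max_lag_s = cfg$stats$max_lag_s)
      epsp <- detect_epsps(ses$vm, cfg$spikes$epsp_min_amp_mV,
                           cfg$spikes$epsp_min_slope, segmentation = seg)
      log_line(logf, stage, sprintf("vm-pupil lag %.2f s, EPSP rate %.1f Hz",
                                    lag$lag_s, epsp$rate_hz))
    }

    stage <- "figures"
    if (isTRUE(cfg$figures)) {
      ev <- seg$transitions$time_s[seg$transitions$direction == "QW->AW"]
      if (length(ev)) {
        peth <- peri_event_histogram(ses$tc$times_s, ev, window_s = 2, bin_s = 0.2)
        grDevices::png(file.path(cfg$out_dir, "peth_tc.png"), 600, 400)
        graphics::plot(peth$bin_center_s, peth$rate_hz, type = "s",
                       xlab = "time from QW->AW (s)", ylab = "rate (Hz)",
                       main = "TC peri-transition histogram")
        grDevices::dev.off()
      }
      acg <- autocorrelogram(ses$tc$times_s, 0.5, 0.01)
      grDevices::png(file.path(cfg$out_dir, "acg_tc.png"), 600, 400)
      graphics::plot(acg$lag_s, acg$count, type = "h",
                     xlab = "lag (s)", ylab = "pairs", main = "TC autocorrelogram")
      grDevices::dev.off()
      spq <- state_power_spectrum(ses$lfp, seg$epochs, "QW")
      spa <- state_power_spectrum(ses$lfp, seg$epochs, "AW")
      grDevices::png(file.path(cfg$out_dir, "spectra.png"), 600, 400)
      graphics::matplot(spq$freq_hz, cbind(spq$power, spa$power), type = "l",
                        log = "y", xlim = c(0, 30), lty = 1,
                        xlab = "frequency (Hz)", ylab = "power",
                        main = "state-conditioned LFP spectra (QW black, AW red)")
      grDevices::dev.off()
      if (!is.null(lag)) {
        grDevices::png(file.path(cfg$out_dir, "vm_pupil_xcorr.png"), 600, 400)
        graphics::plot(lag$xcorr$lag_s, lag$xcorr$r, type = "l",
                       xlab = "lag (s)", ylab = "r",
                       main = "Vm x pupil cross-correlation")
        graphics::abline(v = lag$lag_s, lty = 2)
        grDevices::dev.off()
      }
    }

    stage <- "summary"
    summary <- list(
      seed = cfg$seed,
      duration_s = cfg$session$duration_s,
      n_epochs = nrow(seg$epochs),
      qw_fraction = sum(with(seg$epochs, end_s - start_s)[seg$epochs$label == "QW"]) /
        max(seg$epochs$end_s),
      label_agreement = agree,
      lfp_pp_mV = as.list(pp),
      neurons = lapply(neurons, function(nn) {
        nn[c("neuron", "cell_class", "fr_qw_hz", "fr_aw_hz", "mi",
             "n_bursts", "r", "p", "modulation_class",
             "fr_constricted_hz", "fr_dilated_hz")]
      }),
      vm_pupil_lag_s = if (is.null(lag)) NA else lag$lag_s,
      epsp_rate_hz = if (is.null(epsp)) NA else epsp$rate_hz,
      epsp_rate_by_state = if (is.null(epsp)) NULL else as.list(epsp$rate_by_state))
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_line(logf, stage, "done")
    summary
  }, error = function(e) {
    log_line(logf, stage, paste0("ERROR: ", conditionMessage(e)))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
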