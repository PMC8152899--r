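test_that("state sequences tile the session, alternate, and respect the QW minimum", {
  cfg <- session_config(duration_s = 60, seed = 1)
  st <- generate_state_sequence(cfg)
  expect_equal(st$start_s[1], 0)
  expect_equal(st$end_s[nrow(st)], 60)
  expect_equal(st$start_s[-1], st$end_s[-nrow(st)])
  expect_true(all(st$label[-1] != st$label[-nrow(st)]))
  qw <- st$label == "QW"
  expect_true(all((st$end_s - st$start_s)[qw] >= 3))
  expect_true(all(st$osc_hz[qw] >= 3 & st$osc_hz[qw] <= 6))
  expect_true(all(is.na(st$osc_hz[!qw])))
})

test_that("state generation is deterministic and rejects infeasible durations", {
  cfg <- session_config(duration_s = 60, seed = 11)
  expect_identical(generate_state_sequence(cfg), generate_state_sequence(cfg))
  expect_error(generate_state_sequence(session_config(duration_s = 2)),
               "too short")
  expect_error(session_config(qw_dwell_range_s = c(2, 5)), "QW dwell")
  expect_error(session_config(tc_rate_aw_hz = -1), "rates")
})

test_that("LFP oscillation amplitude is state dependent as constructed", {
  cfg <- session_config(duration_s = 30, seed = 2)
  qw_only <- data.frame(start_s = 0, end_s = 30, label = "QW", osc_hz = 4.5)
  lfp_qw <- synth_lfp(qw_only, cfg)
  env <- band_envelope(lfp_qw)
  inner <- seq(2 * cfg$lfp_fs, length(env) - 2 * cfg$lfp_fs)
  expect_lt(abs(mean(env[inner]) - cfg$qw_pp_amp_mV / 2), 0.15 * cfg$qw_pp_amp_mV / 2)

  aw_only <- data.frame(start_s = 0, end_s = 30, label = "AW", osc_hz = NA)
  env_aw <- band_envelope(synth_lfp(aw_only, cfg))
  expect_lt(mean(env_aw[inner]), 0.5 * mean(env[inner]))
})

test_that("zero-amplitude, zero-noise LFP is flat", {
  cfg <- session_config(duration_s = 12, qw_pp_amp_mV = 0, aw_pp_amp_mV = 0,
                        lfp_noise_mV = 0)
  st <- generate_state_sequence(cfg)
  expect_equal(max(abs(synth_lfp(st, cfg)$samples)), 0)
})

test_that("pupil is dilated in AW: upper tercile overlaps AW intervals", {
  cfg <- session_config(duration_s = 80, seed = 3)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  masks <- tercile_partition(pu$radius_px)
  aw <- pupilstate:::state_mask(st, pu$time_s, "AW")
  expect_gte(mean(aw[masks$dilated]), 0.8)
  expect_identical(pu, synth_pupil(st, cfg))
})

test_that("noise-free pupil settles onto exactly two plateau levels", {
  cfg <- session_config(duration_s = 20, pupil_noise_px = 0, pupil_drift_px = 0)
  st <- data.frame(start_s = c(0, 10), end_s = c(10, 20),
                   label = c("QW", "AW"), osc_hz = c(4, NA))
  pu <- synth_pupil(st, cfg)
  settled_qw <- pu$radius_px[pu$time_s > 5 & pu$time_s < 10]
  settled_aw <- pu$radius_px[pu$time_s > 15]
  expect_lt(max(abs(settled_qw - cfg$pupil_r_qw_px)), 0.1)
  expect_lt(max(abs(settled_aw - cfg$pupil_r_aw_px)), 0.1)
})

test_that("TC and interneuron trains are rate-modulated in opposite directions", {
  cfg <- session_config(duration_s = 60, seed = 4)
  st <- generate_state_sequence(cfg)
  eps <- st[, c("start_s", "end_s", "label")]
  tc <- synth_spike_train(st, "TC", cfg)
  inn <- synth_spike_train(st, "IN", cfg)
  r_tc <- firing_rate_by_state(tc$times_s, eps)
  r_in <- firing_rate_by_state(inn$times_s, eps)
  expect_gt(r_tc[["AW"]], r_tc[["QW"]])
  expect_gt(r_in[["QW"]], r_in[["AW"]])
  expect_error(synth_spike_train(st, "granule", cfg), "cell_type")
})

test_that("planted TC bursts are frequent in QW and satisfy the detector's rules", {
  cfg <- session_config(duration_s = 60, seed = 5)
  st <- generate_state_sequence(cfg)
  tc <- synth_spike_train(st, "TC", cfg)
  qw_time <- sum((st$end_s - st$start_s)[st$label == "QW"])
  expect_gte(nrow(tc$bursts) / qw_time, 1)
  expect_true(all(tc$bursts$first_isi_ms <= 10))
  # planted bursts fall inside QW intervals and are mutually separated
  qw_hit <- pupilstate:::state_mask(st, tc$bursts$onset_s, "QW")
  expect_true(all(qw_hit))
  expect_true(all(diff(tc$bursts$onset_s) > 0.1))
})

test_that("membrane potential matches the QW level and EPSP rate is state independent", {
  cfg <- session_config(duration_s = 40, seed = 6, pupil_lag_s = 0,
                        vm_noise_mV = 0)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  vm <- synth_vm(st, pu, cfg, spike_times = numeric(0))
  tv <- (seq_along(vm$samples) - 1) / vm$fs
  qw <- pupilstate:::state_mask(st, tv, "QW")
  base_no_epsp <- vm$baseline
  expect_lt(abs(mean(base_no_epsp[qw]) - cfg$vm_qw_mV), 1)
  # planted EPSP rates agree between states within 10%
  qw_ep <- pupilstate:::state_mask(st, vm$epsp_times, "QW")
  r_qw <- sum(qw_ep) / sum((st$end_s - st$start_s)[st$label == "QW"])
  r_aw <- sum(!qw_ep) / sum((st$end_s - st$start_s)[st$label == "AW"])
  expect_gt(r_qw / r_aw, 0.9)
  expect_lt(r_qw / r_aw, 1.1)
})

test_that("with zero lag the Vm baseline is an affine map of the pupil", {
  cfg <- session_config(duration_s = 20, seed = 7, pupil_lag_s = 0,
                        vm_noise_mV = 0, epsp_rate_hz = 0)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  vm <- synth_vm(st, pu, cfg, spike_times = numeric(0))
  tv <- (seq_along(vm$samples) - 1) / vm$fs
  p_up <- stats::approx(pu$time_s, pu$truth_px, xout = tv, rule = 2)$y
  fit <- stats::lm(vm$samples ~ p_up)
  expect_gt(summary(fit)$r.squared, 0.999999)
  # resting level stays below -45 mV without spikes
  expect_lt(max(vm$samples), -45)
  expect_error(synth_vm(st, pu[1:100, ], cfg), "shorter")
})

test_that("eye frames render the planted pupil area and black sync frames", {
  cfg <- session_config(duration_s = 2, video_noise = 0, seed = 8)
  pu <- make_eye_pupil(rep(10, 100))
  vid <- synth_eye_video(pu, cfg, black_frames = 50L)
  f <- vid$frames[[1]]
  midpoint <- (0.15 + 0.75) / 2
  area <- sum(f < midpoint)
  expect_lt(abs(area - pi * 100) / (pi * 100), 0.10)
  expect_equal(max(vid$frames[[50]]), 0)
  expect_false(50 %in% which(!is.na(vid$truth$r)))
  expect_error(synth_eye_video(make_eye_pupil(rep(40, 10)), cfg),
               "exceeds frame bounds")
  vid2 <- synth_eye_video(pu, cfg, black_frames = 50L)
  expect_identical(vid, vid2)
})

test_that("a session round-trips through the plain-text writers", {
  cfg <- session_config(duration_s = 25, seed = 9)
  ses <- generate_session(cfg, video = FALSE)
  dir <- withr::local_tempdir()
  write_session(ses, dir)
  back <- load_session_dir(dir, cfg)
  expect_equal(back$lfp$samples, ses$lfp$samples, tolerance = 1e-4)
  expect_equal(back$tc$times_s, ses$tc$times_s, tolerance = 1e-6)
  expect_equal(back$states$label, ses$states$label)
})
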