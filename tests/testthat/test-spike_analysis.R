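test_that("waveform features separate broad TC from narrow interneuron templates", {
  tc <- waveform_features(spike_template(0.44, 0.41))
  inn <- waveform_features(spike_template(0.23, 0.73))
  expect_gt(tc$duration_ms, 0.35)
  expect_lt(inn$duration_ms, 0.35)
  expect_lt(abs(tc$duration_ms - 0.44), 0.05)
  expect_lt(abs(inn$duration_ms - 0.23), 0.05)
  expect_lt(abs(tc$height_ratio - 0.41), 0.05)
  expect_lt(abs(inn$height_ratio - 0.73), 0.05)
  # time-reversed waveform has no positive peak after its trough
  wf <- spike_template(0.44, 0.41)
  rev_wf <- data.frame(t_ms = wf$t_ms, v = rev(wf$v))
  expect_error(waveform_features(rev_wf), "polarity|trough")
})

test_that("cell classification thresholds durations with ties going to TC", {
  expect_equal(classify_cell(list(duration_ms = 0.23)), "IN")
  expect_equal(classify_cell(list(duration_ms = 0.44)), "TC")
  expect_equal(classify_cell(list(duration_ms = 0.35)), "TC")
  expect_equal(classify_cell(list(duration_ms = 0.32), duration_thresh_ms = 0.3), "TC")
})

test_that("burst detection reproduces the worked example and edge rules", {
  b <- detect_bursts(c(0, 6, 9, 300, 306, 450) / 1000)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_spikes, c(3L, 2L))
  expect_equal(b$start_s, c(0, 0.300))
  expect_equal(b$first_isi_ms, c(6, 6))
  expect_equal(nrow(detect_bursts(c(0, 0.011))), 0)
  # two clusters 90 ms apart (edge-to-edge) are both rejected
  expect_equal(nrow(detect_bursts(c(0, 0.005, 0.095, 0.100))), 0)
  expect_error(detect_bursts(c(0.2, 0.1)), "increasing")
  expect_equal(nrow(detect_bursts(numeric(0))), 0)
})

test_that("burst detection agrees exactly with the brute-force oracle", {
  set.seed(41)
  for (k in 1:200) {
    n <- sample(2:60, 1)
    times <- random_burst_train(n)
    got <- detect_bursts(times)
    want <- oracle_bursts(times)
    expect_equal(got$start_s, want$start_s)
    expect_equal(got$end_s, want$end_s)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("burst subtyping follows the first-ISI and Vm conventions", {
  expect_equal(classify_burst(list(first_isi_ms = 3.38, n_spikes = 3), vm_mV = -65), "LTS")
  expect_equal(classify_burst(list(first_isi_ms = 8.15, n_spikes = 2), vm_mV = -55), "HT")
  expect_equal(classify_burst(list(first_isi_ms = 3.38, n_spikes = 3)), "LTS")
  expect_equal(classify_burst(list(first_isi_ms = 8.15, n_spikes = 2)), "HT")
  # boundary: first ISI exactly at the cut is left unclassified
  expect_equal(classify_burst(list(first_isi_ms = 5, n_spikes = 2)), "unclassified")
  # conflicting ISI and Vm evidence is left unclassified
  expect_equal(classify_burst(list(first_isi_ms = 3, n_spikes = 2), vm_mV = -50),
               "unclassified")
  expect_error(classify_burst(list(first_isi_ms = 3, n_spikes = 1)), "two spikes")
})

test_that("state-conditioned firing rates are count/duration", {
  eps <- data.frame(start_s = c(0, 2, 6), end_s = c(2, 6, 8),
                    label = c("QW", "AW", "QW"))
  r <- firing_rate_by_state(seq(0.1, 1.9, length.out = 10), eps)
  expect_equal(r[["QW"]], 10 / 4)
  expect_equal(r[["AW"]], 0)
  r0 <- firing_rate_by_state(numeric(0), eps)
  expect_equal(unname(r0), c(0, 0))
})

test_that("modulation index matches its definition, bounds, and antisymmetry", {
  expect_equal(modulation_index(10, 0), 1)
  expect_equal(modulation_index(0, 10), -1)
  expect_equal(modulation_index(20.1, 6.2), (20.1 - 6.2) / (20.1 + 6.2))
  expect_error(modulation_index(0, 0), "undefined")
  expect_error(modulation_index(-1, 2), "non-negative")
  set.seed(42)
  for (k in 1:50) {
    a <- stats::runif(1, 0, 50); b <- stats::runif(1, 0, 50)
    mi <- modulation_index(a, b)
    expect_gte(mi, -1); expect_lte(mi, 1)
    expect_equal(mi, -modulation_index(b, a))
  }
})

test_that("peri-event histograms are flat for Poisson trains and conserve mass", {
  set.seed(43)
  rejections <- 0
  for (k in 1:30) {
    spikes <- cumsum(stats::rexp(1500, 10))
    events <- stats::runif(25, 10, max(spikes) - 10)
    peth <- peri_event_histogram(spikes, events, window_s = 2, bin_s = 0.25)
    if (stats::chisq.test(peth$count)$p.value < 0.01) rejections <- rejections + 1
    # mass conservation: binned counts equal in-window spike-event pairs
    pairs <- sum(vapply(events, function(ev) {
      sum(spikes - ev >= -2 & spikes - ev < 2)
    }, numeric(1)))
    expect_equal(sum(peth$count), pairs)
  }
  expect_lte(rejections, 4)
  expect_error(peri_event_histogram(1:10, numeric(0)), "events")
})

test_that("TC firing increases across detected QW-to-AW transitions", {
  cfg <- session_config(duration_s = 80, seed = 44)
  st <- generate_state_sequence(cfg)
  tc <- synth_spike_train(st, "TC", cfg)
  ev <- st$start_s[st$label == "AW"]
  ev <- ev[ev > 2 & ev < 78]
  peth <- peri_event_histogram(tc$times_s, ev, window_s = 2, bin_s = 0.25)
  pre <- mean(peth$rate_hz[peth$bin_center_s < 0])
  post <- mean(peth$rate_hz[peth$bin_center_s > 0])
  expect_gt(post, pre)
})

test_that("autocorrelograms are symmetric with peaks at the planted rhythm", {
  acg <- autocorrelogram(seq(0, 10, by = 0.1), max_lag_s = 0.35, bin_s = 0.01)
  expect_equal(acg$count, rev(acg$count))
  peaks <- acg$lag_s[acg$count > 50]
  expect_true(all(abs(abs(peaks) - round(abs(peaks) / 0.1) * 0.1) < 1e-9))

  cfg <- session_config(duration_s = 120, seed = 45)
  st <- generate_state_sequence(cfg)
  tc <- synth_spike_train(st, "TC", cfg)
  eps <- st[, c("start_s", "end_s", "label")]
  qw_spikes <- tc$times_s[pupilstate:::state_mask(st, tc$times_s, "QW")]
  acg_qw <- autocorrelogram(qw_spikes, max_lag_s = 0.4, bin_s = 0.02)
  side <- acg_qw[acg_qw$lag_s >= 0.1, ]
  peak_lag <- side$lag_s[which.max(side$count)]
  expect_gte(peak_lag, 1 / 6)
  expect_lte(peak_lag, 1 / 3)
})

test_that("EPSP detection recovers the planted state-independent rate", {
  cfg <- session_config(duration_s = 40, seed = 46)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  tc <- synth_spike_train(st, "TC", cfg)
  vm <- synth_vm(st, pu, cfg, spike_times = tc$times_s)
  eps <- st[, c("start_s", "end_s", "label")]
  det <- detect_epsps(vm, segmentation = eps)
  expect_lt(abs(det$rate_hz - cfg$epsp_rate_hz) / cfg$epsp_rate_hz, 0.15)
  ratio <- det$rate_by_state[["QW"]] / det$rate_by_state[["AW"]]
  expect_gt(ratio, 0.85)
  expect_lt(ratio, 1.15)

  cfg0 <- session_config(duration_s = 20, seed = 47, epsp_rate_hz = 0)
  st0 <- generate_state_sequence(cfg0)
  pu0 <- synth_pupil(st0, cfg0)
  vm0 <- synth_vm(st0, pu0, cfg0, spike_times = numeric(0))
  expect_equal(length(detect_epsps(vm0)$event_times_s), 0)
})
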