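fake_track <- function(r, fps = 10, black = integer(0)) {
  tr <- data.frame(frame = seq_along(r), cx = 32, cy = 32, r = r,
                   is_black = FALSE, energy = NA_real_)
  tr$r[black] <- NA
  tr$is_black[black] <- TRUE
  attr(tr, "fps") <- fps
  class(tr) <- c("pupil_track", "data.frame")
  tr
}

test_that("alignment bins rates, interpolates pupil, and handles black-frame gaps", {
  spikes <- seq(0.05, 19.95, by = 0.1)          # constant 10 Hz
  al <- align_session(spikes, fake_track(rep(12, 200)), bin_s = 1)
  expect_true(all(al$fr_hz == 10))
  expect_true(all(al$pupil == 12))
  expect_false(anyNA(al))

  al2 <- align_session(spikes, fake_track(rep(12, 200), black = 100L), bin_s = 1)
  expect_equal(nrow(al2), nrow(al))
  expect_false(anyNA(al2))

  expect_error(align_session(spikes + 500, fake_track(rep(12, 200))), "overlap")
  expect_error(align_session(numeric(0), fake_track(rep(12, 200))), "overlap")
})

test_that("tercile partition selects the lower and upper thirds", {
  m <- tercile_partition(1:9)
  expect_equal(which(m$constricted), 1:3)
  expect_equal(which(m$dilated), 7:9)
  expect_error(tercile_partition(rep(2, 30)), "degenerate")
  set.seed(51)
  for (n in c(10, 35, 100)) {
    v <- stats::rnorm(n)
    m <- tercile_partition(v)
    expect_false(any(m$constricted & m$dilated))
    expect_true(sum(m$constricted) %in% c(floor(n / 3), ceiling(n / 3)))
    expect_true(sum(m$dilated) %in% c(floor(n / 3), ceiling(n / 3)))
    expect_true(max(v[m$constricted]) <= min(v[m$dilated]))
  }
})

test_that("permutation correlation flags perfect correlations and is reproducible", {
  x <- as.numeric(1:100) + stats::rnorm(100, 0, 1e-9)
  r1 <- permutation_correlation(x, x, seed = 5)
  expect_equal(r1$r_obs, 1)
  expect_true(r1$significant)
  expect_equal(r1$modulation_class, "positive")
  r2 <- permutation_correlation(x, -x, seed = 5)
  expect_equal(r2$r_obs, -1)
  expect_equal(r2$modulation_class, "negative")
  expect_identical(r1$null_r, permutation_correlation(x, x, seed = 5)$null_r)
  expect_error(permutation_correlation(rep(1, 50), stats::rnorm(50), seed = 1),
               "variance")
  expect_error(permutation_correlation(1:5, 1:5, seed = 1), "10")
})

test_that("observed r is invariant under joint reordering of the pair series", {
  set.seed(52)
  x <- stats::rnorm(80); y <- 0.5 * x + stats::rnorm(80)
  ord <- sample(80)
  a <- permutation_correlation(x, y, n_perm = 100, seed = 9)
  b <- permutation_correlation(x[ord], y[ord], n_perm = 100, seed = 9)
  expect_equal(a$r_obs, b$r_obs)
})

test_that("the pair-bootstrap null variant and block permutation run and calibrate sanely", {
  set.seed(53)
  x <- stats::rnorm(120); y <- stats::rnorm(120)
  rb <- permutation_correlation(x, y, n_perm = 200, seed = 3,
                                method = "pair_bootstrap")
  expect_length(rb$null_r, 200)
  expect_lt(abs(mean(rb$null_r)), 0.1)
  rblk <- permutation_correlation(x, y, n_perm = 200, seed = 3, block_s = 5)
  expect_length(rblk$null_r, 200)
})

test_that("quick type-I sanity: null sessions are rarely significant", {
  set.seed(54)
  hits <- sum(vapply(1:150, function(i) {
    permutation_correlation(stats::rnorm(100), stats::rnorm(100),
                            n_perm = 300, seed = i)$significant
  }, logical(1)))
  expect_gte(hits / 150, 0.0)
  expect_lte(hits / 150, 0.12)
})

test_that("modulation classing requires significance and follows the sign", {
  expect_equal(classify_modulation(list(significant = TRUE, r_obs = 0.411)), "positive")
  expect_equal(classify_modulation(list(significant = TRUE, r_obs = -0.4)), "negative")
  expect_equal(classify_modulation(list(significant = FALSE, r_obs = 0.3)), "uncorrelated")
})

test_that("tercile firing rates separate TC and interneuron modulation", {
  cfg <- session_config(duration_s = 80, seed = 55)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  tr <- fake_track(pu$radius_px, fps = attr(pu, "fps"))
  tc <- synth_spike_train(st, "TC", cfg)
  inn <- synth_spike_train(st, "IN", cfg)
  al_tc <- align_session(tc$times_s, tr)
  al_in <- align_session(inn$times_s, tr)
  f_tc <- fr_by_pupil_tercile(al_tc$fr_hz, tercile_partition(al_tc$pupil))
  f_in <- fr_by_pupil_tercile(al_in$fr_hz, tercile_partition(al_in$pupil))
  expect_gt(f_tc[["dilated"]], f_tc[["constricted"]])
  expect_gt(f_in[["constricted"]], f_in[["dilated"]])
  u <- fr_by_pupil_tercile(rep(4, nrow(al_tc)), tercile_partition(al_tc$pupil))
  expect_equal(u[["dilated"]], u[["constricted"]])
})

test_that("cross-correlation lag recovers pure shifts and the planted session lag", {
  fs <- 10
  tt <- seq(0, 120, by = 1 / fs)
  set.seed(56)
  p <- lowpass(stats::rnorm(length(tt)), fs, 0.2)
  v <- c(rep(p[1], 5 * fs), p[1:(length(p) - 5 * fs)])   # vm = pupil shifted 5 s
  lag <- vm_pupil_lag(v, p, fs = fs, max_lag_s = 15)
  expect_lt(abs(lag$lag_s - 5), 1 / fs + 1e-9)
  expect_false(lag$edge)
  lag0 <- vm_pupil_lag(p, p, fs = fs, max_lag_s = 15)
  expect_equal(lag0$lag_s, 0)

  cfg <- session_config(duration_s = 180, seed = 57)
  st <- generate_state_sequence(cfg)
  pu <- synth_pupil(st, cfg)
  tc <- synth_spike_train(st, "TC", cfg)
  vm <- synth_vm(st, pu, cfg, spike_times = tc$times_s)
  dec <- round(cfg$vm_fs / attr(pu, "fps"))
  vds <- vm$samples[seq(1, length(vm$samples), by = dec)]
  m <- min(length(vds), nrow(pu))
  lag_s <- vm_pupil_lag(vds[1:m], pu$radius_px[1:m], fs = attr(pu, "fps"))$lag_s
  expect_gte(lag_s, 4.5)
  expect_lte(lag_s, 5.5)
})

test_that("paired condition comparison detects halved coupling and id mismatches", {
  ra <- data.frame(neuron = paste0("n", 1:8), r = rep(0.3, 8))
  cmp0 <- compare_conditions(ra, ra)
  expect_equal(cmp0$mean_diff, 0)
  set.seed(58)
  mk <- function(beta) vapply(1:12, function(i) {
    x <- stats::rnorm(150)
    stats::cor(x, beta * x + stats::rnorm(150))
  }, numeric(1))
  a <- data.frame(neuron = paste0("n", 1:12), r = mk(0.5))
  b <- data.frame(neuron = paste0("n", 1:12), r = mk(0.25))
  cmp <- compare_conditions(a, b)
  expect_lt(cmp$mean_b, cmp$mean_a)
  expect_lt(cmp$p_value, 0.05)
  expect_error(compare_conditions(a, b[1:10, ]), "mismatch")
})
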