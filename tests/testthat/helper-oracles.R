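# Independent oracles and shared fixtures for the test suite.

# Exhaustive integer grid search over (cx, cy, r): the reference minimizer
# for the snake contrast energy on small images.
oracle_snake_grid <- function(inv, cx_range, cy_range, r_range, ratio = sqrt(2)) {
  best <- NULL
  ebest <- Inf
  dims <- dim(inv)
  for (cx in cx_range) for (cy in cy_range) for (r in r_range) {
    ro <- r * ratio
    if (cx - ro < 0.5 || cx + ro > dims[2] + 0.5 ||
        cy - ro < 0.5 || cy + ro > dims[1] + 0.5 || r < 2) next
    e <- snake_energy(inv, snake(cx, cy, r, ratio))
    if (e < ebest) {
      ebest <- e
      best <- c(cx = cx, cy = cy, r = r)
    }
  }
  list(par = best, energy = ebest)
}

# Brute-force burst enumerator: checks every contiguous spike window for the
# all-ISIs-small + maximality conditions, then applies the mutual-separation
# rejection pairwise. O(n^2); independent of the run-length implementation.
oracle_bursts <- function(times, max_isi = 0.010, min_sep = 0.100) {
  n <- length(times)
  cl <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (times[j] - times[j - 1] > max_isi) break
        if ((i == 1 || times[i] - times[i - 1] > max_isi) &&
            (j == n || times[j + 1] - times[j] > max_isi)) {
          cl[[length(cl) + 1]] <- c(i, j)
        }
      }
    }
  }
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), first_isi_ms = numeric(0))
  if (!length(cl)) return(empty)
  m <- do.call(rbind, cl)
  keep <- rep(TRUE, nrow(m))
  for (a in seq_len(nrow(m))) {
    for (b in seq_len(nrow(m))) {
      if (a == b) next
      gap <- if (times[m[b, 1]] > times[m[a, 2]]) {
        times[m[b, 1]] - times[m[a, 2]]
      } else {
        times[m[a, 1]] - times[m[b, 2]]
      }
      if (gap <= min_sep) keep[a] <- FALSE
    }
  }
  m <- m[keep, , drop = FALSE]
  if (!nrow(m)) return(empty)
  out <- data.frame(start_s = times[m[, 1]], end_s = times[m[, 2]],
                    n_spikes = m[, 2] - m[, 1] + 1L,
                    first_isi_ms = (times[m[, 1] + 1] - times[m[, 1]]) * 1000)
  out[order(out$start_s), , drop = FALSE]
}

# Random spike train with a bursty/tonic ISI mixture (guaranteed strictly
# increasing) for burst-detector property tests.
random_burst_train <- function(n, p_short = 0.3) {
  isi <- ifelse(stats::runif(n) < p_short,
                stats::rexp(n, 1 / 0.004), stats::rexp(n, 1 / 0.15))
  cumsum(isi + 1e-6)
}

# Single synthetic eye frame with known geometry, via the generator.
make_eye_pupil <- function(radii, fps = 50) {
  out <- data.frame(time_s = (seq_along(radii) - 1) / fps,
                    radius_px = radii, truth_px = radii)
  attr(out, "fps") <- fps
  out
}

default_iris_region <- function(frame_px = 64) {
  c(max(1, round(frame_px * 0.08)), max(1, round(frame_px * 0.4)),
    max(2, round(frame_px * 0.1)), max(2, round(frame_px * 0.12)))
}
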