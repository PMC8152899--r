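#' Align a spike train and a pupil track on a common grid
#'
#' Bins the spike train at `bin_s` over the overlap of the two recordings
#' and interpolates the pupil radius to the bin centers. Gaps left by black
#' synchronization frames are interpolated when shorter than `max_gap_s`;
#' longer gaps drop the affected bins from both series.
#'
#' @param spike_times Spike times, seconds.
#' @param pupil_track A `pupil_track` data frame ([track_video()]) or any
#'   data frame with `time_s`/`frame` and a radius column plus an `fps`
#'   attribute.
#' @param bin_s Bin width, seconds (default 1 s; pupil dynamics are
#'   multi-second).
#' @param max_gap_s Longest interpolated gap, seconds.
#' @return Data frame of class `aligned_series`: `time_s` (bin centers),
#'   `fr_hz`, `pupil`.
#' @export
align_session <- function(spike_times, pupil_track, bin_s = 1, max_gap_s = 2) {
  fps <- attr(pupil_track, "fps") %||% 50
  pt <- if ("time_s" %in% names(pupil_track)) pupil_track$time_s
        else (pupil_track$frame - 1) / fps
  pv <- if ("r" %in% names(pupil_track)) pupil_track$r
        else if ("radius_px" %in% names(pupil_track)) pupil_track$radius_px
        else stop("no radius column in pupil_track")
  valid <- !is.na(pv)
  if (!length(spike_times)) stop("no temporal overlap: empty spike train")
  t0 <- max(min(pt), min(spike_times))
  t1 <- min(max(pt), max(spike_times))
  if (t1 - t0 < 10 * bin_s) stop("no sufficient temporal overlap (need >= 10 bins)")
  edges <- seq(t0, t1, by = bin_s)
  if (length(edges) < 11) stop("no sufficient temporal overlap (need >= 10 bins)")
  centers <- edges[-length(edges)] + bin_s / 2
  fr <- tabulate(findInterval(spike_times[spike_times >= t0 & spike_times < edges[length(edges)]],
                              edges), length(centers)) / bin_s
  pint <- stats::approx(pt[valid], pv[valid], xout = centers, rule = 2)$y
  # drop bins whose nearest valid pupil sample is farther than max_gap_s
  gap <- vapply(centers, function(tc) min(abs(pt[valid] - tc)), numeric(1))
  keep <- gap <= max_gap_s
  out <- data.frame(time_s = centers[keep], fr_hz = fr[keep], pupil = pint[keep])
  attr(out, "bin_s") <- bin_s
  class(out) <- c("aligned_series", "data.frame")
  out
}

#' Tercile partition of the pupil-diameter distribution
#'
#' Rank-based split: the lower third of the values is the constricted-pupil
#' mask, the upper third the dilated-pupil mask; the middle tercile belongs
#' to neither.
#'
#' @param pupil Numeric vector of pupil diameters/radii.
#' @return List with logical masks `constricted` and `dilated`.
#' @export
tercile_partition <- function(pupil) {
  n <- length(pupil)
  if (n < 3) stop("need at least 3 samples for a tercile partition")
  if (stats::sd(pupil) < 1e-12) stop("degenerate (constant) pupil distribution")
  rk <- rank(pupil, ties.method = "average")
  res <- list(constricted = rk <= n / 3, dilated = rk > 2 * n / 3)
  if (!any(res$constricted) || !any(res$dilated)) {
    stop("degenerate pupil distribution: empty tercile mask")
  }
  res
}

#' Permutation test for the firing-rate/pupil correlation
#'
#' Computes the observed Pearson correlation and builds a null distribution
#' by re-pairing the two series at random `n_perm` times (default: full
#' random permutations of the pupil series; `method = "pair_bootstrap"`
#' instead draws `n` random (FR, pupil) pairs with replacement per
#' iteration). The observed r is significant when it falls outside the
#' central `band` (95%) interval of the null; the two-tailed p-value uses
#' the add-one permutation estimator.
#'
#' @param fr,pupil Paired numeric series (e.g. from [align_session()]).
#' @param n_perm Number of null iterations.
#' @param band Central confidence band of the null, e.g. 0.95.
#' @param seed Integer seed; the null is reproducible given the seed.
#' @param method `"permute"` (default) or `"pair_bootstrap"`.
#' @param block_s,bin_s Optional block length (s) and bin width (s) for a
#'   conservative block permutation that preserves serial dependence
#'   within blocks.
#' @return List of class `correlation_result`: `r_obs`, `null_r`,
#'   `p_two_tailed`, `significant`, `conf_band`, `modulation_class`, `n`.
#' @export
permutation_correlation <- function(fr, pupil, n_perm = 1000, band = 0.95,
                                    seed = 1L, method = c("permute", "pair_bootstrap"),
                                    block_s = NULL, bin_s = 1) {
  method <- match.arg(method)
  n <- length(fr)
  stopifnot(n == length(pupil))
  if (n < 10) stop("need at least 10 paired samples")
  if (stats::sd(fr) < 1e-12 || stats::sd(pupil) < 1e-12) {
    stop("zero variance in a series: correlation undefined")
  }
  r_obs <- stats::cor(fr, pupil)
  xs <- (fr - mean(fr)) / stats::sd(fr)
  ys <- (pupil - mean(pupil)) / stats::sd(pupil)
  null_r <- with_seed(seed, {
    if (method == "pair_bootstrap") {
      vapply(seq_len(n_perm), function(i) {
        stats::cor(fr[sample.int(n, n, replace = TRUE)],
                   pupil[sample.int(n, n, replace = TRUE)])
      }, numeric(1))
    } else if (!is.null(block_s)) {
      bl <- max(1L, round(block_s / bin_s))
      nb <- ceiling(n / bl)
      vapply(seq_len(n_perm), function(i) {
        ord <- unlist(lapply(sample.int(nb), function(b) {
          idx <- ((b - 1) * bl + 1):min(b * bl, n)
          idx
        }))
        sum(xs * ys[ord[seq_len(n)]]) / (n - 1)
      }, numeric(1))
    } else {
      idx <- replicate(n_perm, sample.int(n))
      colSums(xs * matrix(ys[idx], nrow = n)) / (n - 1)
    }
  })
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (n_perm + 1)
  qq <- stats::quantile(null_r, c((1 - band) / 2, 1 - (1 - band) / 2),
                        names = FALSE)
  sig <- r_obs < qq[1] || r_obs > qq[2]
  res <- structure(list(r_obs = r_obs, null_r = null_r, p_two_tailed = p,
                        significant = sig, conf_band = qq, band = band,
                        n = n),
                   class = "correlation_result")
  res$modulation_class <- classify_modulation(res)
  res
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> r = %.3f, p(two-tailed) = %.4f, %s (n = %d)\n",
              x$r_obs, x$p_two_tailed, x$modulation_class, x$n))
  invisible(x)
}

#' Classify arousal modulation from a correlation result
#'
#' `"positive"` when significant with r > 0, `"negative"` when significant
#' with r < 0, otherwise `"uncorrelated"`.
#'
#' @param result A `correlation_result` from [permutation_correlation()].
#' @return One of `"positive"`, `"negative"`, `"uncorrelated"`.
#' @export
classify_modulation <- function(result) {
  if (isTRUE(result$significant)) {
    if (result$r_obs > 0) return("positive")
    if (result$r_obs < 0) return("negative")
  }
  "uncorrelated"
}

#' Mean firing rate in the constricted and dilated pupil terciles
#'
#' @param fr Binned firing rate, Hz.
#' @param masks Output of [tercile_partition()] on the paired pupil series.
#' @return Named numeric vector `c(constricted = , dilated = )`, Hz.
#' @export
fr_by_pupil_tercile <- function(fr, masks) {
  c(constricted = mean(fr[masks$constricted]),
    dilated = mean(fr[masks$dilated]))
}

#' Membrane-potential/pupil cross-correlation lag
#'
#' Low-pass filters and z-scores both series on their common uniform grid,
#' then finds the lag maximizing the normalized cross-correlation. The
#' cross-correlogram is averaged over half-overlapping segments of
#' `seg_s` seconds (Welch style): the true-lag peak adds coherently across
#' segments while spurious echoes of the quasi-periodic state alternation
#' dephase and cancel. A positive lag means the membrane potential follows
#' (lags behind) the pupil.
#'
#' @param vm,pupil Numeric series on a common uniform grid.
#' @param fs Sampling rate of the grid, Hz.
#' @param lowpass_hz Zero-phase low-pass cutoff applied to both series, Hz.
#' @param max_lag_s Largest lag searched, seconds.
#' @param seg_s Averaging segment length, seconds; series shorter than one
#'   segment are used whole.
#' @return List: `lag_s`, `xcorr` (data frame `lag_s`, `r`, averaged over
#'   segments), `edge` (TRUE when the maximum sits at the search-window
#'   edge, i.e. the estimate is unreliable).
#' @export
vm_pupil_lag <- function(vm, pupil, fs, lowpass_hz = 0.5, max_lag_s = 10,
                         seg_s = 60) {
  n <- length(vm)
  stopifnot(n == length(pupil), n > 4)
  if (lowpass_hz >= fs / 2) stop("lowpass_hz must be below the grid Nyquist")
  v <- lowpass(vm, fs, lowpass_hz)
  p <- lowpass(pupil, fs, lowpass_hz)
  w <- if (is.null(seg_s)) n else min(n, round(seg_s * fs))
  starts <- seq(1, n - w + 1, by = max(1, round(w / 2)))
  kmax <- min(w - 2, round(max_lag_s * fs))
  lags <- -kmax:kmax
  acc <- numeric(length(lags))
  used <- 0
  for (s0 in starts) {
    vi <- v[s0:(s0 + w - 1)]
    pi_ <- p[s0:(s0 + w - 1)]
    if (stats::sd(vi) < 1e-12 || stats::sd(pi_) < 1e-12) next
    vi <- (vi - mean(vi)) / stats::sd(vi)
    pi_ <- (pi_ - mean(pi_)) / stats::sd(pi_)
    acc <- acc + vapply(lags, function(k) {
      if (k >= 0) stats::cor(vi[(1 + k):w], pi_[1:(w - k)])
      else stats::cor(vi[1:(w + k)], pi_[(1 - k):w])
    }, numeric(1))
    used <- used + 1
  }
  if (used == 0) stop("no segment with nonzero variance in both series")
  r <- acc / used
  i <- which.max(r)
  list(lag_s = lags[i] / fs,
       xcorr = data.frame(lag_s = lags / fs, r = r),
       edge = i == 1 || i == length(lags))
}

#' Compare per-neuron pupil correlations between two conditions
#'
#' Pairs per-neuron correlation values recorded in two conditions (e.g.
#' control vs. cortical inactivation), reports group means and the paired
#' differences, and delegates the significance test to the standard paired
#' Wilcoxon signed-rank routine.
#'
#' @param results_a,results_b Data frames with columns `neuron` and `r`
#'   (one row per neuron) for the two conditions.
#' @return List: `table` (per-neuron `r_a`, `r_b`, `diff`), `mean_a`,
#'   `mean_b`, `mean_diff`, `p_value` (paired Wilcoxon; `NA` when fewer
#'   than 3 pairs).
#' @export
compare_conditions <- function(results_a, results_b) {
  if (!setequal(results_a$neuron, results_b$neuron) ||
      nrow(results_a) != nrow(results_b)) {
    stop("mismatched neuron ids between conditions")
  }
  a <- results_a[order(results_a$neuron), ]
  b <- results_b[order(results_b$neuron), ]
  tab <- data.frame(neuron = a$neuron, r_a = a$r, r_b = b$r,
                    diff = b$r - a$r)
  p <- if (nrow(tab) >= 3 && stats::sd(tab$diff) > 0) {
    stats::wilcox.test(tab$r_a, tab$r_b, paired = TRUE, exact = FALSE)$p.value
  } else NA_real_
  list(table = tab, mean_a = mean(tab$r_a), mean_b = mean(tab$r_b),
       mean_diff = mean(tab$diff), p_value = p)
}
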