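#' Snakuscule pupil model
#'
#' A minimal active contour for circular objects: an inner disc of radius
#' `r` centered at `(cx, cy)` plus a concentric ring whose outer radius is
#' `ratio * r`. With `ratio = sqrt(2)` (the default) the ring and the disc
#' have equal area, so the contrast energy of a uniform image is zero.
#'
#' @param cx,cy Center, pixel coordinates (columns/rows, pixel centers at
#'   integers starting at 1).
#' @param r Inner radius, pixels (must be >= `r_min`).
#' @param ratio Outer/inner radius ratio, fixed across a tracking run.
#' @param r_min Smallest admissible inner radius, pixels.
#' @return List of class `snake`.
#' @export
snake <- function(cx, cy, r, ratio = sqrt(2), r_min = 2) {
  if (r < r_min) stop("snake radius below minimum (", r_min, " px)")
  if (ratio <= 1) stop("ratio must exceed 1")
  structure(list(cx = cx, cy = cy, r = r, ratio = ratio, r_min = r_min),
            class = "snake")
}

snake_in_bounds <- function(s, dim_img) {
  ro <- s$r * s$ratio
  s$cx - ro >= 0.5 && s$cx + ro <= dim_img[2] + 0.5 &&
    s$cy - ro >= 0.5 && s$cy + ro <= dim_img[1] + 0.5 &&
    s$r >= s$r_min
}

#' Invert a frame against an iris reference region
#'
#' Linear, monotone-decreasing intensity map anchored so that the mean
#' intensity of the iris reference rectangle maps to 0 and the darkest pixel
#' of the frame maps to 1; values are clipped at the bright end only, so
#' structure brighter than the reference (e.g. the inner iris) keeps a
#' graded, below-zero intensity instead of collapsing to a flat level —
#' a flat surround would leave the contour energy without a radius
#' gradient. After inversion the originally dark pupil is the brightest
#' object, as the contour energy requires.
#'
#' @param image Numeric matrix (rows = y, cols = x), intensities in `[0, 1]`.
#' @param iris_region Rectangle `c(x, y, w, h)` in pixel coordinates.
#' @return Inverted image matrix in `[0, 1]`.
#' @export
invert_frame <- function(image, iris_region) {
  x <- iris_region[1]; y <- iris_region[2]
  w <- iris_region[3]; h <- iris_region[4]
  if (x < 1 || y < 1 || w < 1 || h < 1 ||
      x + w - 1 > ncol(image) || y + h - 1 > nrow(image)) {
    stop("iris_region outside frame bounds")
  }
  m <- mean(image[y:(y + h - 1), x:(x + w - 1)])
  s <- m - min(image)
  if (s < 1e-9) return(matrix(0, nrow(image), ncol(image)))
  pmin((m - image) / s, 1)
}

#' Snakuscule contrast energy
#'
#' Sum of image intensities covered by the ring minus the sum covered by
#' the inner disc. Pixel membership is fractional at the boundaries: a
#' pixel whose center lies at distance `d` from the snake center
#' contributes to the disc with weight `clip(r - d + 1/2, 0, 1)` and to
#' the ring with the analogous weight at the outer radius minus its disc
#' weight — a sub-pixel discretization of the continuous region integrals.
#' Because the two regions have equal area the energy is ~0 on uniform
#' images and strongly negative when the disc sits on a bright blob
#' against a darker ring.
#'
#' @param image Inverted image matrix (pupil bright).
#' @param s A [snake()].
#' @return Scalar energy (arbitrary intensity units).
#' @export
snake_energy <- function(image, s) {
  if (!snake_in_bounds(s, dim(image))) stop("snake outside image bounds")
  ro <- s$r * s$ratio
  x0 <- max(1L, floor(s$cx - ro)); x1 <- min(ncol(image), ceiling(s$cx + ro))
  y0 <- max(1L, floor(s$cy - ro)); y1 <- min(nrow(image), ceiling(s$cy + ro))
  sub <- image[y0:y1, x0:x1, drop = FALSE]
  xs <- matrix((x0:x1), nrow(sub), ncol(sub), byrow = TRUE)
  ys <- matrix((y0:y1), nrow(sub), ncol(sub))
  d <- sqrt((xs - s$cx)^2 + (ys - s$cy)^2)
  wd <- pmin(pmax(s$r - d + 0.5, 0), 1)
  wr <- pmin(pmax(ro - d + 0.5, 0), 1) - wd
  sum(sub * wr) - sum(sub * wd)
}

#' Minimize the snake energy by annealed coordinate descent
#'
#' Greedy descent over `(cx, cy, r)`: at each step size of an annealed
#' schedule (integer steps down to sub-pixel), the best of the six
#' single-coordinate moves is taken while it strictly lowers the energy.
#' The energy is non-increasing across iterations and the result never
#' exceeds the initial energy.
#'
#' @param image Inverted image matrix (pupil bright).
#' @param init A [snake()] within bounds, the initial solution.
#' @param opts List of options: `steps` (step-size schedule, px; default
#'   `c(4, 2, 1, 0.5, 0.25)`), `max_iter` (move budget, default 200).
#' @return List with `snake` (the minimizer), `energy`, `trace` (energy per
#'   accepted move), `iterations`, and `stuck` (TRUE when no valid move
#'   existed from `init`).
#' @export
optimize_snake <- function(image, init, opts = list()) {
  steps <- opts$steps %||% c(4, 2, 1, 0.5, 0.25)
  max_iter <- opts$max_iter %||% 200L
  if (!snake_in_bounds(init, dim(image))) stop("initial snake outside image bounds")
  cur <- init
  e_cur <- snake_energy(image, cur)
  trace <- e_cur
  iter <- 0L
  any_valid <- FALSE
  for (st in steps) {
    repeat {
      if (iter >= max_iter) break
      cand <- list(
        c(cur$cx + st, cur$cy, cur$r), c(cur$cx - st, cur$cy, cur$r),
        c(cur$cx, cur$cy + st, cur$r), c(cur$cx, cur$cy - st, cur$r),
        c(cur$cx, cur$cy, cur$r + st), c(cur$cx, cur$cy, cur$r - st))
      best <- NULL; e_best <- e_cur
      for (cc in cand) {
        s2 <- cur; s2$cx <- cc[1]; s2$cy <- cc[2]; s2$r <- cc[3]
        if (s2$r < s2$r_min || !snake_in_bounds(s2, dim(image))) next
        any_valid <- TRUE
        e2 <- snake_energy(image, s2)
        if (e2 < e_best - 1e-12) { best <- s2; e_best <- e2 }
      }
      iter <- iter + 1L
      if (is.null(best)) break
      cur <- best; e_cur <- e_best
      trace <- c(trace, e_cur)
    }
  }
  if (!any_valid) {
    warning("no valid move from initial snake; returning it unchanged")
  }
  list(snake = cur, energy = e_cur, trace = trace, iterations = iter,
       stuck = !any_valid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect an all-black synchronization frame
#'
#' @param image Raw (pre-inversion) image matrix in `[0, 1]`.
#' @param threshold Mean-intensity threshold on the unit scale; frames with
#'   mean intensity `<= threshold` (inclusive) are black. Default 0.02
#'   (2% of full scale).
#' @return Logical flag.
#' @export
detect_black_frame <- function(image, threshold = 0.02) {
  mean(image) <= threshold
}

#' Track the pupil across a video
#'
#' Per-frame Snakuscule optimization seeded, as in manual-first-frame
#' workflows, by a user-supplied snake on frame 1 and thereafter by the
#' result of the previous non-black frame. Black synchronization frames are
#' flagged and skipped; tracking resumes from the last valid snake.
#'
#' @param frames List of image matrices (raw intensities, pupil dark).
#' @param init_snake A [snake()] for frame 1.
#' @param iris_region Iris reference rectangle `c(x, y, w, h)` for inversion.
#' @param opts Options passed to [optimize_snake()], plus `black_thresh`
#'   (default 0.02) and `fps` (stored as an attribute, default 50).
#' @return A `pupil_track` data frame: `frame`, `cx`, `cy`, `r`,
#'   `is_black`, `energy` (geometry is `NA` on black frames).
#' @export
track_video <- function(frames, init_snake, iris_region, opts = list()) {
  if (!length(frames)) stop("no frames supplied")
  black_thresh <- opts$black_thresh %||% 0.02
  if (detect_black_frame(frames[[1]], black_thresh)) {
    stop("frame 1 is black: supply an initial snake on a visible frame")
  }
  n <- length(frames)
  out <- data.frame(frame = seq_len(n), cx = NA_real_, cy = NA_real_,
                    r = NA_real_, is_black = FALSE, energy = NA_real_)
  prev <- init_snake
  for (i in seq_len(n)) {
    if (detect_black_frame(frames[[i]], black_thresh)) {
      out$is_black[i] <- TRUE
      next
    }
    inv <- invert_frame(frames[[i]], iris_region)
    fit <- optimize_snake(inv, prev, opts)
    prev <- fit$snake
    out$cx[i] <- prev$cx; out$cy[i] <- prev$cy; out$r[i] <- prev$r
    out$energy[i] <- fit$energy
  }
  attr(out, "fps") <- opts$fps %||% 50
  class(out) <- c("pupil_track", "data.frame")
  out
}

#' Write a pupil track to CSV
#'
#' Columns `frame_index, cx, cy, radius, is_black` in fixed order; black
#' frames carry empty geometry fields.
#'
#' @param track A `pupil_track` from [track_video()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_track_csv <- function(track, path) {
  df <- data.frame(frame_index = track$frame, cx = track$cx, cy = track$cy,
                   radius = track$r, is_black = as.integer(track$is_black))
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = ""),
    error = function(e) stop("cannot write track CSV to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Read a pupil track CSV written by [write_track_csv()]
#'
#' @param path CSV file path.
#' @param fps Frame rate to attach, frames/s.
#' @return A `pupil_track` data frame.
#' @export
read_track_csv <- function(path, fps = 50) {
  df <- utils::read.csv(path)
  out <- data.frame(frame = df$frame_index, cx = df$cx, cy = df$cy,
                    r = df$radius, is_black = df$is_black == 1,
                    energy = NA_real_)
  attr(out, "fps") <- fps
  class(out) <- c("pupil_track", "data.frame")
  out
}
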