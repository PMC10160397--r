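# Synthetic stimulus generation.
#
# The network is exercised on simple dark-object-on-light-background movies:
# a centred square whose edge grows linearly until it fills the field
# (looming; the fill frame is the ground-truth collision time), its exact
# time reverse (receding), and rigid translation of a block or bar along one
# of the eight canonical directions.  Additive Gaussian noise can be scaled
# to a prescribed signal-to-noise ratio.  All generators are deterministic
# given their arguments (only the noise uses the seed).

#' Luminance sequence container
#'
#' @param frames `H x W x T` numeric array with values in `[0, 1]`.
#' @param frame_interval Frame interval in seconds (metadata only).
#' @return An object of class `luminance_sequence`.
#' @export
luminance_sequence <- function(frames, frame_interval = 1 / 30) {
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stop("`frames` must be an H x W x T array", call. = FALSE)
  }
  if (dim(frames)[3] < 3L) {
    stop("a sequence needs at least 3 frames (the direction layer uses t-2)",
         call. = FALSE)
  }
  rng <- range(frames)
  if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 1) {
    stop("luminance values must lie in [0, 1]", call. = FALSE)
  }
  structure(list(frames = frames, frame_interval = frame_interval),
            class = "luminance_sequence")
}

#' @export
print.luminance_sequence <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<luminance_sequence> %d x %d pixels, %d frames (dt = %.4fs)\n",
              d[1], d[2], d[3], x$frame_interval))
  invisible(x)
}

#' @export
dim.luminance_sequence <- function(x) dim(x$frames)

# separable Gaussian optical blur with replicate padding; emulates the
# point spread of real optics so sub-pixel motion stays smooth at the
# pixel level instead of flickering with the rasterisation phase
.gauss_blur <- function(M, sigma) {
  if (sigma <= 0) return(M)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq.int(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  n1 <- nrow(M); n2 <- ncol(M)
  pad_idx <- function(n) pmin(pmax(seq_len(n + 2L * r) - r, 1L), n)
  P <- M[pad_idx(n1), ]
  out <- matrix(0, n1, n2)
  for (a in seq_along(k)) out <- out + k[a] * P[(a - 1L) + seq_len(n1), ]
  P <- out[, pad_idx(n2)]
  out <- matrix(0, n1, n2)
  for (a in seq_along(k)) out <- out + k[a] * P[, (a - 1L) + seq_len(n2)]
  out
}

# fractional coverage of the interval [lo, hi] by unit pixels centred at
# 1..n; anti-aliased rendering keeps sub-pixel motion and growth smooth
.interval_coverage <- function(n, lo, hi) {
  cov <- pmin(seq_len(n) + 0.5, hi) - pmax(seq_len(n) - 0.5, lo)
  pmin(pmax(cov, 0), 1)
}

# H x W coverage field of an axis-aligned rectangle centred at (cx, cy) on
# screen axes (x right, y up) with half-widths (wx, wy)
.rect_coverage <- function(H, W, cx, cy, wx, wy) {
  cov_x <- .interval_coverage(W, cx - wx, cx + wx)
  cov_y <- .interval_coverage(H, cy - wy, cy + wy)
  outer(rev(cov_y), cov_x)  # screen y up -> matrix row 1 at top
}

# linear edge-length schedule reaching the full field at fill_frame
.loom_schedule <- function(n_frames, fill_frame, start_size, full) {
  t <- seq_len(n_frames)
  s <- start_size + (t - 1) / (fill_frame - 1) * (full - start_size)
  pmin(s, full)
}

#' Looming stimulus
#'
#' A centred dark square grows linearly in edge length from `start_size`
#' until it fills the field at `fill_frame` (the ground-truth collision
#' time); later frames are identical.
#'
#' @param grid `(H, W)` pixel dimensions.
#' @param n_frames Number of frames (>= 3).
#' @param fill_frame Frame at which the object fills the field.
#' @param start_size Initial edge length in pixels.
#' @param object_luminance,background_luminance Values in `[0, 1]`.
#' @param blur_sigma Optical point-spread (Gaussian sigma, pixels) applied
#'   to each rendered frame; keeps sub-pixel edge motion smooth.  `0`
#'   disables it.
#' @param frame_interval Frame interval in seconds (metadata).
#' @return A [luminance_sequence()].
#' @export
stim_looming <- function(grid = c(128, 128), n_frames = 60, fill_frame = 37,
                         start_size = 8, object_luminance = 0,
                         background_luminance = 1, blur_sigma = 0.8,
                         frame_interval = 1 / 30) {
  H <- grid[1]; W <- grid[2]
  if (fill_frame < 2 || fill_frame > n_frames) {
    stop("`fill_frame` must lie in [2, n_frames]", call. = FALSE)
  }
  full <- max(H, W)  # an axis-aligned square of this edge covers the field
  sizes <- .loom_schedule(n_frames, fill_frame, start_size, full)
  frames <- array(background_luminance, dim = c(H, W, n_frames))
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  for (t in seq_len(n_frames)) {
    cov <- .rect_coverage(H, W, cx, cy, sizes[t] / 2, sizes[t] / 2)
    frames[, , t] <- .gauss_blur(background_luminance +
      (object_luminance - background_luminance) * cov, blur_sigma)
  }
  luminance_sequence(frames, frame_interval)
}

#' Receding stimulus
#'
#' The exact time reverse of the matching looming stimulus: the dark square
#' starts filling the field and shrinks towards `start_size`.
#'
#' @inheritParams stim_looming
#' @return A [luminance_sequence()].
#' @export
stim_receding <- function(grid = c(128, 128), n_frames = 60, fill_frame = 37,
                          start_size = 8, object_luminance = 0,
                          background_luminance = 1, blur_sigma = 0.8,
                          frame_interval = 1 / 30) {
  loom <- stim_looming(grid, n_frames, fill_frame, start_size,
                       object_luminance, background_luminance, blur_sigma,
                       frame_interval)
  loom$frames <- loom$frames[, , rev(seq_len(n_frames)), drop = FALSE]
  loom
}

#' Translating stimulus
#'
#' A dark block (or bar) translates rigidly at `speed` pixels per frame
#' along one of the eight canonical directions (theta = 0 rightward,
#' pi/2 upward on screen).  The object is rendered with fractional pixel
#' coverage (anti-aliased), so its luminance mass is constant while it is
#' fully inside the grid and its intensity centroid moves at exactly
#' `speed` px/frame; parts leaving the grid are clipped.  By default the
#' path is centred so the object stays clear of the borders for the whole
#' run.
#'
#' @param grid `(H, W)` pixel dimensions.
#' @param n_frames Number of frames.
#' @param direction One of the 8 canonical angles (radians).
#' @param speed Pixels per frame (> 0).
#' @param size Object edge length in pixels.
#' @param shape `"block"` (size x size square) or `"bar"` (a bar of length
#'   `4 * size` perpendicular to the motion; cardinal directions only).
#' @param start Optional `(x, y)` start centre on screen axes (x right from
#'   column 1, y up from the bottom row); default centres the whole path.
#' @param object_luminance,background_luminance Values in `[0, 1]`.
#' @param blur_sigma Optical point-spread (Gaussian sigma, pixels); see
#'   [stim_looming()].
#' @param frame_interval Frame interval in seconds (metadata).
#' @return A [luminance_sequence()] with attribute `"trajectory"` (the
#'   continuous centre positions, `T x 2`).
#' @export
stim_translating <- function(grid = c(128, 128), n_frames = 60,
                             direction = 0, speed = 0.5, size = 15,
                             shape = c("block", "bar"), start = NULL,
                             object_luminance = 0, background_luminance = 1,
                             blur_sigma = 0.8, frame_interval = 1 / 30) {
  shape <- match.arg(shape)
  H <- grid[1]; W <- grid[2]
  .theta_index(direction)
  if (speed <= 0) stop("`speed` must be positive", call. = FALSE)
  u <- c(cos(direction), sin(direction))
  travel <- speed * (n_frames - 1)
  if (is.null(start)) {
    centre <- c((W + 1) / 2, (H + 1) / 2)
    start <- centre - u * travel / 2
  }
  if (shape == "bar" && !isTRUE(all.equal(direction %% (pi / 2), 0))) {
    stop("`bar` stimuli are defined for cardinal directions only",
         call. = FALSE)
  }
  sz <- if (shape == "block") c(size, size) else {
    if (abs(u[1]) > 0.5) c(size, 4 * size) else c(4 * size, size)
  }
  frames <- array(background_luminance, dim = c(H, W, n_frames))
  traj <- matrix(NA_real_, n_frames, 2)
  mass3 <- 0
  for (t in seq_len(n_frames)) {
    pos <- start + (t - 1) * speed * u
    traj[t, ] <- pos
    cov <- .rect_coverage(H, W, pos[1], pos[2], sz[1] / 2, sz[2] / 2)
    if (t == 3L) mass3 <- sum(cov)
    frames[, , t] <- .gauss_blur(background_luminance +
      (object_luminance - background_luminance) * cov, blur_sigma)
  }
  if (mass3 == 0) {
    stop("object leaves the grid before frame 3; reduce `speed` or move `start`",
         call. = FALSE)
  }
  out <- luminance_sequence(frames, frame_interval)
  attr(out, "trajectory") <- traj
  out
}

#' Add Gaussian noise at a prescribed SNR
#'
#' Adds zero-mean Gaussian noise scaled so that
#' \eqn{10 \log_{10}(P_{signal} / P_{noise})} equals `snr_db`, where the
#' signal power is the mean squared deviation of each pixel from its
#' temporal mean.  The output is clipped to `[0, 1]`.  The empirical SNR of
#' the realised (pre-clipping) noise field is attached as attribute
#' `"snr_empirical"`.
#'
#' @param seq A [luminance_sequence()].
#' @param snr_db Target SNR in dB; `Inf` returns the input unchanged.
#' @param seed Integer seed; the same seed gives an identical sequence.
#' @return A noisy [luminance_sequence()].
#' @export
add_gaussian_noise <- function(seq, snr_db, seed = 1L) {
  stopifnot(inherits(seq, "luminance_sequence"))
  if (!is.numeric(snr_db) || length(snr_db) != 1L || is.na(snr_db)) {
    stop("`snr_db` must be a single (possibly infinite) number", call. = FALSE)
  }
  if (is.infinite(snr_db) && snr_db > 0) return(seq)
  if (!is.finite(snr_db)) stop("`snr_db` must be finite or +Inf", call. = FALSE)
  fr <- seq$frames
  mu <- apply(fr, c(1, 2), mean)
  p_sig <- mean(sweep(fr, c(1, 2), mu)^2)
  if (p_sig == 0) {
    stop("sequence has no temporal variation; SNR is undefined", call. = FALSE)
  }
  sd_n <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- .with_seed(seed, {
    array(stats::rnorm(length(fr), 0, sd_n), dim = dim(fr))
  })
  snr_emp <- 10 * log10(p_sig / mean(noise^2))
  out <- luminance_sequence(pmin(pmax(fr + noise, 0), 1), seq$frame_interval)
  attr(out, "snr_empirical") <- snr_emp
  out
}

# evaluate expr under a local RNG state, restoring the caller's stream
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
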