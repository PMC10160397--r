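# Direction layer, direction-selective LGMD units, motion-direction
# estimation and collision-peak reporting.
#
# Coordinate convention: luminance matrices are stored in image order
# (row 1 at the top), but directions are expressed on screen axes -- theta =
# 0 is rightward and theta = pi/2 is upward.  A displacement (dx, dy) on
# screen axes therefore maps to (+dx columns, -dy rows) on the matrix.

#' The eight canonical directions
#'
#' @return Numeric vector `(0, pi/4, ..., 7*pi/4)`.
#' @export
theta_set <- function() (0:7) * pi / 4

# round half away from zero (base round() is banker's rounding)
.round_away <- function(x) sign(x) * floor(abs(x) + 0.5)

.theta_index <- function(theta) {
  idx <- which(abs(((theta - theta_set() + pi) %% (2 * pi)) - pi) < 1e-9)
  if (length(idx) != 1L) {
    stop("`theta` must be one of the 8 canonical angles k*pi/4", call. = FALSE)
  }
  idx
}

#' Correlation-partner displacement
#'
#' Integer pixel displacement of the correlation partner of a unit tuned to
#' direction `theta`: \eqn{(\mathrm{round}(m\cos\theta),
#' \mathrm{round}(m\sin\theta))}, rounded half away from zero so `m = 1`
#' yields the 8-neighbourhood.
#'
#' @param theta One of the 8 canonical angles.
#' @param m Displacement magnitude in pixels.
#' @return Integer vector `(dx, dy)` on screen axes (x right, y up).
#' @examples
#' neighbor_offset(0, 1)      # (1, 0)
#' neighbor_offset(pi / 4, 1) # (1, 1)
#' @export
neighbor_offset <- function(theta, m = 1) {
  .theta_index(theta)
  if (!is.numeric(m) || m <= 0) stop("`m` must be positive", call. = FALSE)
  c(dx = .round_away(m * cos(theta)), dy = .round_away(m * sin(theta)))
}

# Field sampled at (x + dx, y + dy) on screen axes, zeros off grid.
shift_field <- function(M, dx, dy) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(0, nr, nc)
  # screen y up = matrix row down: row' = row - dy
  sr <- seq_len(nr) - dy
  sc <- seq_len(nc) + dx
  ok_r <- sr >= 1L & sr <= nr
  ok_c <- sc >= 1L & sc <= nc
  if (any(ok_r) && any(ok_c)) {
    out[which(ok_r), which(ok_c)] <- M[sr[ok_r], sc[ok_c]]
  }
  out
}

# Bilinearly interpolated sample at fractional screen displacement.
shift_field_bilinear <- function(M, dx, dy) {
  x0 <- floor(dx); y0 <- floor(dy)
  fx <- dx - x0; fy <- dy - y0
  (1 - fx) * (1 - fy) * shift_field(M, x0, y0) +
    fx * (1 - fy) * shift_field(M, x0 + 1, y0) +
    (1 - fx) * fy * shift_field(M, x0, y0 + 1) +
    fx * fy * shift_field(M, x0 + 1, y0 + 1)
}

#' Direction-layer correlation
#'
#' Per-pixel correlation output for preferred direction `theta`:
#' \deqn{D_{ij}(t,\theta) = S_{ij}(t) S_{xy}(t-2) -
#'       S_{ij}(t-1) S_{xy}(t-1),}
#' where \eqn{(x, y)} is the pixel displaced by
#' `params$offset_sign * neighbor_offset(theta, m)`.  Off-grid partners
#' contribute zero.  With the default orientation the partner lies opposite
#' the preferred direction, i.e. where a signal moving towards `theta` was
#' on earlier frames, so coincidence of \eqn{S(t)} with the partner's
#' \eqn{S(t-2)} marks motion towards `theta`; the \eqn{t-1} product
#' subtracts the static coincidence baseline.
#'
#' @param S_t,S_t1,S_t2 Combined S fields at frames t, t-1 and t-2.
#' @param theta Preferred direction, one of the 8 canonical angles.
#' @param params A [dflgmd_params()].
#' @return The D field (matrix, same shape as the inputs).
#' @export
direction_correlate <- function(S_t, S_t1, S_t2, theta, params) {
  if (!identical(dim(S_t), dim(S_t1)) || !identical(dim(S_t), dim(S_t2))) {
    stop("S fields differ in shape", call. = FALSE)
  }
  use_interp <- params$interpolate_diagonals
  if (use_interp) {
    dx <- params$offset_sign * params$m * cos(theta)
    dy <- params$offset_sign * params$m * sin(theta)
    .theta_index(theta)
    S_t * shift_field_bilinear(S_t2, dx, dy) -
      S_t1 * shift_field_bilinear(S_t1, dx, dy)
  } else {
    off <- params$offset_sign * neighbor_offset(theta, params$m)
    S_t * shift_field(S_t2, off[1], off[2]) -
      S_t1 * shift_field(S_t1, off[1], off[2])
  }
}

#' LGMD spatial integration
#'
#' Signed sum of the direction-layer output over the grid.
#'
#' @param D A D field from [direction_correlate()].
#' @return Scalar \eqn{R_1(t, \theta) = \sum_{ij} D_{ij}(t, \theta)}.
#' @export
lgmd_integrate <- function(D) sum(D)

#' LGMD membrane drive
#'
#' Affine drive of the direction-selective LGMD unit
#' \deqn{D^\alpha L_1 = g_{leak}(V_{rest} - L_1) +
#'       \xi_{ex} R_1 (E_{ex} - L_1),}
#' to be advanced with [frac_step()]; the reported response is
#' \eqn{\hat L_1 = \max(L_1, 0)}.  `R1` is a signed sum, so the effective
#' input conductance `xi_ex * R1` can be negative; the run loop floors the
#' decay so the semi-implicit update stays contractive (see the methods
#' vignette).
#'
#' @param R1 Integrated direction-layer output (scalar).
#' @param params A [dflgmd_params()].
#' @return `list(A, B)` scalar drive/decay.
#' @export
lgmd_drive <- function(R1, params) {
  A <- params$g_leak * params$V_rest + params$xi_ex * R1 * params$E_ex
  B <- params$g_leak + params$xi_ex * R1
  list(A = A, B = B)
}

#' Local motion-direction angles
#'
#' Two-argument arctangent of the vertical against the horizontal
#' direction-layer outputs, mapped into `[0, 2*pi)`, with a mask marking
#' pixels that carry a meaningful motion vector.
#'
#' Two refinements make the pixelwise angle usable in practice (see the
#' methods vignette).  First, the inputs should be opponent signals
#' \eqn{D(\theta) - D(\theta + \pi)}: a raw correlation can go negative for
#' purely temporal (direction-neutral) change, and differencing opposed
#' channels cancels that component.  Second, the fields are pooled over a
#' small Gaussian neighbourhood (`params$angle_pool_sigma`) before the
#' arctangent, because the horizontal and vertical coincidence evidence for
#' oblique motion peaks at slightly different pixels.  The mask requires
#' the pooled magnitude to exceed both the absolute `energy_floor` (the
#' angle of a numerically silent pixel is meaningless) and `energy_rel`
#' times the frame's maximum magnitude, so the mode is taken over pixels
#' that actually detected motion.
#'
#' @param D_h,D_v Horizontal and vertical direction signals, normally the
#'   opponent differences \eqn{D(0) - D(\pi)} and \eqn{D(\pi/2) - D(3\pi/2)}.
#' @param params A [dflgmd_params()].
#' @return `list(E_angle, motion_mask)`.
#' @export
local_angle <- function(D_h, D_v, params) {
  if (!identical(dim(D_h), dim(D_v))) {
    stop("horizontal and vertical D fields differ in shape", call. = FALSE)
  }
  ps <- if (!is.null(params$angle_pool_sigma)) params$angle_pool_sigma else 0
  if (ps > 0) {
    D_h <- .gauss_blur(D_h, ps)
    D_v <- .gauss_blur(D_v, ps)
  }
  ang <- atan2(D_v, D_h) %% (2 * pi)
  energy <- pmax(abs(D_h), abs(D_v))
  rel <- if (!is.null(params$energy_rel)) params$energy_rel else 0
  mask <- energy > max(params$energy_floor, rel * max(energy))
  list(E_angle = ang, motion_mask = mask)
}

#' Global motion direction (mode)
#'
#' Quantises masked local angles to the nearest canonical direction and
#' returns the most frequent one.  Ties break towards the smaller angle;
#' an empty mask gives `NA` (no measurable motion).
#'
#' @param E_angle Local angle field from [local_angle()].
#' @param motion_mask Logical mask of pixels with measurable motion energy.
#' @return A canonical angle in radians, or `NA_real_`.
#' @export
direction_mode <- function(E_angle, motion_mask) {
  a <- E_angle[motion_mask]
  if (length(a) == 0L) return(NA_real_)
  bin <- floor(a / (pi / 4) + 0.5) %% 8  # nearest canonical direction
  counts <- tabulate(bin + 1L, nbins = 8L)
  theta_set()[which.max(counts)]  # which.max takes the first (smaller angle)
}

#' Collision-peak report
#'
#' Locates the peak of the per-frame aggregate LGMD output and measures its
#' prominence as peak value over the run median (floored at `eps` to avoid
#' division by zero).  An identically zero trace reports no response.
#'
#' @param C Per-frame aggregate output, `sum` over the eight rectified
#'   direction channels.
#' @param eps Floor for the median.
#' @return `list(peak_frame, peak_value, peak_prominence, no_response)`;
#'   `peak_frame` is 1-based and earliest-on-ties.
#' @export
collision_peak <- function(C, eps = 1e-9) {
  if (length(C) == 0L) stop("empty response series", call. = FALSE)
  if (all(C == 0)) {
    return(list(peak_frame = NA_integer_, peak_value = 0,
                peak_prominence = NA_real_, no_response = TRUE))
  }
  pk <- which.max(C)
  md <- max(stats::median(C), eps)
  list(peak_frame = as.integer(pk), peak_value = C[pk],
       peak_prominence = C[pk] / md, no_response = FALSE)
}

#' Direction tuning curve
#'
#' Time-integrated rectified response per direction channel and the
#' preferred direction (argmax; ties towards the smaller angle).  All-zero
#' scores are flagged as no motion.
#'
#' @param L1_rect A `T x 8` matrix of rectified LGMD responses, columns in
#'   [theta_set()] order.
#' @return `list(scores, preferred_theta, no_motion)`.
#' @export
tuning_curve <- function(L1_rect) {
  if (is.null(dim(L1_rect)) || ncol(L1_rect) != 8L) {
    stop("`L1_rect` must be a T x 8 matrix", call. = FALSE)
  }
  scores <- colSums(L1_rect)
  names(scores) <- sprintf("theta_%d", round(theta_set() * 180 / pi))
  list(scores = scores,
       preferred_theta = theta_set()[which.max(scores)],
       no_motion = all(scores == 0))
}
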