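# Excitatory/inhibitory layer, Gaussian lateral inhibition, summing layer.
#
# The excitatory path is an identity copy of the rectified photoreceptor
# output.  The inhibitory path low-passes the same signal through a
# conductance membrane, rectifies it, and spreads it laterally: the current
# frame is convolved with the nearest-neighbour kernel G1 and the previous
# frame with the wider next-nearest-neighbour kernel G2 (a delayed
# inhibition surround).  Summing units then weigh excitation against the
# spread inhibition, and ON and OFF channels are recombined superlinearly.

#' Lateral inhibition kernel
#'
#' Evaluates the Gaussian-shaped inhibition kernel
#' \deqn{G(x, y) = \frac{F}{2\pi\sigma^2}
#'       \exp\!\left(-\frac{x^2 + y^2}{2\sigma}\right)}
#' on integer offsets \eqn{x, y \in [-r, r]}.  Radius 1 gives the 3 x 3
#' nearest-neighbour kernel G1, radius 2 the 5 x 5 next-nearest-neighbour
#' kernel G2.  The reference exponent divides by \eqn{2\sigma}; set
#' `variant = "sigma_squared"` for the conventional \eqn{2\sigma^2}.
#'
#' @param F Scale coefficient (> 0).
#' @param sigma Width parameter (> 0).
#' @param radius Kernel radius: 1 or 2.
#' @param variant Exponent form, `"sigma"` or `"sigma_squared"`.
#' @return A `(2r+1) x (2r+1)` numeric matrix of class `dflgmd_kernel`;
#'   `weights[a, b]` holds the value at offset `(x = b - r - 1, y = a - r - 1)`.
#' @examples
#' G1 <- inhibition_kernel(5, 0.3, 1)
#' G1[2, 2] # centre: 5 / (2 * pi * 0.09)
#' @export
inhibition_kernel <- function(F, sigma, radius,
                              variant = c("sigma", "sigma_squared")) {
  variant <- match.arg(variant)
  if (!is.numeric(F) || F <= 0 || !is.numeric(sigma) || sigma <= 0) {
    stop("`F` and `sigma` must be positive", call. = FALSE)
  }
  if (!radius %in% c(1, 2)) {
    stop("`radius` must be 1 (G1, 3x3) or 2 (G2, 5x5)", call. = FALSE)
  }
  off <- seq.int(-radius, radius)
  r2 <- outer(off^2, off^2, `+`)
  denom <- if (variant == "sigma") 2 * sigma else 2 * sigma^2
  w <- F / (2 * pi * sigma^2) * exp(-r2 / denom)
  structure(w, class = c("dflgmd_kernel", "matrix"))
}

# 2-D convolution with replicate (edge-clamped) padding.  Kernels here are
# centro-symmetric so convolution and correlation coincide.
conv2_replicate <- function(M, k) {
  r <- (nrow(k) - 1L) %/% 2L
  nr <- nrow(M); nc <- ncol(M)
  ir <- pmin(pmax(seq_len(nr + 2L * r) - r, 1L), nr)
  ic <- pmin(pmax(seq_len(nc + 2L * r) - r, 1L), nc)
  P <- M[ir, ic]
  out <- matrix(0, nr, nc)
  for (a in seq_len(2L * r + 1L)) {
    rows <- (a - 1L) + seq_len(nr)
    for (b in seq_len(2L * r + 1L)) {
      w <- k[a, b]
      if (w != 0) out <- out + w * P[rows, (b - 1L) + seq_len(nc)]
    }
  }
  out
}

#' Excitatory pass-through
#'
#' The excitatory neurons copy the rectified ON/OFF photoreceptor outputs
#' unchanged to the summing layer.
#'
#' @param P_on,P_off Rectified ON and OFF fields.
#' @return `list(E_on, E_off)`, identical copies of the inputs.
#' @export
excitatory_pass <- function(P_on, P_off) {
  list(E_on = P_on, E_off = P_off)
}

#' Inhibitory-neuron drive
#'
#' Affine drive of the inhibitory membrane
#' \eqn{D^\alpha I = g_{leak}(V_{rest} - I) + \delta_{ex} P (E_{ex} - I)},
#' to be advanced with [frac_step()]; the rectified output is
#' \eqn{\hat I = \max(I, 0)}.
#'
#' @param P Rectified ON or OFF field driving the inhibitory unit.
#' @param params A [dflgmd_params()].
#' @return `list(A, B)` drive/decay fields.
#' @export
inhibitory_drive <- function(P, params) {
  A <- params$g_leak * params$V_rest + params$delta_ex * P * params$E_ex
  B <- params$g_leak + params$delta_ex * P
  list(A = A, B = B)
}

#' Delayed Gaussian lateral inhibition
#'
#' Spreads the rectified inhibitory field over its neighbourhood:
#' \deqn{\bar I(t) = \hat I(t) \otimes G_1 +
#'       \beta \, [\hat I(t-1) \otimes G_2],}
#' with replicate padding at the borders.  At the first frame the delayed
#' term is zero.
#'
#' @param Ihat_t Rectified inhibition at the current frame.
#' @param Ihat_prev Rectified inhibition one frame earlier (zeros at t = 1).
#' @param beta Delay regulator (`beta_on` or `beta_off`).
#' @param G1,G2 Kernels from [inhibition_kernel()].
#' @return The spread inhibition field, same shape as the input.
#' @export
lateral_inhibition <- function(Ihat_t, Ihat_prev, beta, G1, G2) {
  if (!identical(dim(Ihat_t), dim(Ihat_prev))) {
    stop("current and delayed inhibition fields differ in shape", call. = FALSE)
  }
  out <- conv2_replicate(Ihat_t, G1)
  if (any(Ihat_prev != 0)) {
    out <- out + beta * conv2_replicate(Ihat_prev, G2)
  }
  out
}

#' Summing-unit drive
#'
#' Affine drive of the summing membrane.  Excitation pulls towards
#' \eqn{E_{ex}}; the lateral term uses battery `E_batt`, which is
#' \eqn{E_{ex}} for the ON channel in the reference formulation
#' (`on_lateral_battery = "excitatory"`) and \eqn{E_{in}} otherwise:
#' \deqn{D^\alpha S = g_{leak}(V_{rest} - S) + \varepsilon_{ex} E (E_{ex}-S)
#'       + \varepsilon_{in} \bar I (E_{batt} - S).}
#'
#' @param E Excitatory field (identity copy of the channel's P output).
#' @param Ibar Spread inhibition field from [lateral_inhibition()].
#' @param channel `"on"` or `"off"`.
#' @param params A [dflgmd_params()].
#' @return `list(A, B)` drive/decay fields.
#' @export
summing_drive <- function(E, Ibar, channel = c("on", "off"), params) {
  channel <- match.arg(channel)
  if (!identical(dim(E), dim(Ibar))) {
    stop("excitation and inhibition fields differ in shape", call. = FALSE)
  }
  E_batt <- if (channel == "on" && params$on_lateral_battery == "excitatory")
    params$E_ex else params$E_in
  A <- params$g_leak * params$V_rest + params$eps_ex * E * params$E_ex +
    params$eps_in * Ibar * E_batt
  B <- params$g_leak + params$eps_ex * E + params$eps_in * Ibar
  list(A = A, B = B)
}

#' Superlinear ON/OFF combination
#'
#' \deqn{S = \mu_1 \hat S^{ON} + \mu_2 \hat S^{OFF} +
#'       \mu_3 \hat S^{ON} \hat S^{OFF}.}
#'
#' @param Shat_on,Shat_off Rectified summing fields.
#' @param params A [dflgmd_params()] (uses `params$mu`).
#' @return Combined S field.
#' @export
combine_on_off <- function(Shat_on, Shat_off, params) {
  mu <- params$mu
  mu[1] * Shat_on + mu[2] * Shat_off + mu[3] * Shat_on * Shat_off
}
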