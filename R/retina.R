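# Photoreceptor layer and ON/OFF channel split.
#
# Each pixel is an independent conductance membrane excited by the current
# luminance and inhibited by the one-frame-delayed luminance; the batteries
# E_ex and E_in confine the potential to [E_in, E_ex].  The first frame uses
# itself as its own delayed copy, so a static first view is not a full-field
# transient.  Half-wave rectification against small thresholds then splits
# the potential into a brightness-increment (ON) and a brightness-decrement
# (OFF) channel.

#' Photoreceptor drive
#'
#' Affine drive of the photoreceptor membrane
#' \deqn{D^\alpha P = g_{leak}(V_{rest} - P) + \lambda_{ex} L(t)(E_{ex} - P)
#'       + \lambda_{in} L(t-1)(E_{in} - P),}
#' to be advanced with [frac_step()].
#'
#' @param L_t Current luminance field, values in `[0, 1]`.
#' @param L_prev Previous frame's luminance (pass `L_t` at the first frame).
#' @param params A [dflgmd_params()].
#' @return `list(A, B)` drive/decay fields for [frac_step()].
#' @export
photoreceptor_drive <- function(L_t, L_prev, params) {
  if (!identical(dim(L_t), dim(L_prev))) {
    stop("luminance fields differ in shape", call. = FALSE)
  }
  A <- params$g_leak * params$V_rest + params$lambda_ex * L_t * params$E_ex +
    params$lambda_in * L_prev * params$E_in
  B <- params$g_leak + params$lambda_ex * L_t + params$lambda_in * L_prev
  list(A = A, B = B)
}

#' ON channel split
#'
#' \eqn{P^{ON} = \gamma_1 [P - V_{th1}]^+}: the super-threshold (brightness
#' increment) part of the photoreceptor potential, amplified.
#'
#' @param P Photoreceptor potential field.
#' @param params A [dflgmd_params()].
#' @return Non-negative ON field.
#' @export
split_on <- function(P, params) {
  params$gamma1 * pmax(P - params$V_th1, 0)
}

#' OFF channel split
#'
#' \eqn{P^{OFF} = -\gamma_2 [P - V_{th2}]^-}: the sub-threshold (brightness
#' decrement) part, sign-flipped so the OFF output is non-negative.
#'
#' @inheritParams split_on
#' @return Non-negative OFF field.
#' @export
split_off <- function(P, params) {
  -params$gamma2 * pmin(P - params$V_th2, 0)
}
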