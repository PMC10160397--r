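# Model parameters.
#
# All tunable constants of the network live in one object, created by
# dflgmd_params().  Defaults are the model's standard operating point;
# parameters that are specified as ranges rather than points (g_leak, V_rest,
# E_in, beta_on, beta_off) default to mid-range values, and values outside
# those ranges raise a warning rather than an error.

.range_params <- list(
  g_leak   = c(25, 50),
  V_rest   = c(-0.001, 0),
  E_in     = c(-1, -0.3),
  beta_on  = c(1.0, 1.2),
  beta_off = c(1.0, 1.2)
)

#' Network parameters
#'
#' Creates the parameter set controlling every layer of the network.  The
#' defaults are the model's standard operating point for 128 x 128 input;
#' the LGMD gain `xi_ex` scales as \eqn{5 \cdot 128^2 / n^2} with the grid
#' side `n`, so smaller grids are driven proportionally harder and the
#' integrated response is grid-size consistent.
#'
#' @param n Grid side (number of rows/columns of the square pixel array).
#' @param alpha Order of the fractional differential operator, in `(0, 1]`.
#'   `alpha = 1` gives the integer-order variant of the same architecture.
#' @param g_leak Leak conductance of every membrane unit (range `[25, 50]`).
#' @param V_rest Resting potential (range `[-0.001, 0]`).
#' @param V_th1,V_th2 ON/OFF half-wave rectification thresholds.
#' @param E_ex,E_in Excitatory and inhibitory synaptic batteries; they bound
#'   the dynamic range of the conductance-driven units.
#' @param lambda_ex,lambda_in Photoreceptor gains on the current and
#'   one-frame-delayed luminance.
#' @param gamma1,gamma2 ON/OFF channel gains.
#' @param eps_ex,eps_in Summing-layer weights of the excitatory and
#'   inhibitory synapses.
#' @param delta_ex Inhibitory-neuron input gain.
#' @param beta_on,beta_off Regulators of the one-frame-delayed (next-nearest
#'   neighbour) lateral inhibition term (range `[1.0, 1.2]`).
#' @param m Displacement magnitude of the direction-layer correlation, in
#'   pixels; `m = 1` correlates each pixel with its 8-neighbourhood.
#' @param F1,sigma1 Scale and width of the nearest-neighbour (3 x 3)
#'   inhibition kernel G1.
#' @param F2,sigma2 Scale and width of the next-nearest-neighbour (5 x 5)
#'   inhibition kernel G2.
#' @param xi_ex LGMD input gain; `NULL` (default) derives it from `n`.
#' @param mu Length-3 coefficients of the superlinear ON/OFF combination
#'   \eqn{\mu_1 S^{ON} + \mu_2 S^{OFF} + \mu_3 S^{ON} S^{OFF}}.
#' @param h Time step of the fractional scheme, in frames.
#' @param memory_window History depth of the fractional memory; `Inf` keeps
#'   the full run.
#' @param on_lateral_battery Battery of the ON summing unit's
#'   lateral-interaction term: `"excitatory"` (default) uses `E_ex`, the
#'   model's reference formulation; `"inhibitory"` selects the symmetric
#'   variant in which both channels use `E_in`.  See the methods vignette:
#'   with the standard gains the symmetric variant silences the summing
#'   layer entirely.
#' @param kernel_exponent_variant `"sigma"` evaluates the inhibition
#'   kernel with exponent \eqn{-(x^2+y^2)/(2\sigma)} (the reference
#'   formulation); `"sigma_squared"` uses the conventional
#'   \eqn{-(x^2+y^2)/(2\sigma^2)}.
#' @param offset_sign `+1` or `-1`: orientation of the direction-layer
#'   displacement.  `-1` (default) places the correlation partner of a unit
#'   preferring direction theta at \eqn{-m(\cos\theta, \sin\theta)}, i.e.
#'   where a theta-ward moving signal was on earlier frames, so the channel
#'   labelled theta is maximal for motion towards theta.
#' @param interpolate_diagonals If `TRUE`, diagonal correlation partners are
#'   sampled bilinearly instead of rounded to the integer 8-neighbourhood.
#' @param energy_floor Minimum pooled correlation magnitude (squared-S
#'   units) for a pixel to enter the motion-direction mode estimate; set
#'   well above the slowly decaying fractional settle transient of a static
#'   scene and well below a moving edge's response, so a motionless view
#'   yields an undefined direction rather than noise.
#' @param energy_rel Relative floor for the same mask: a pixel must also
#'   exceed this fraction of the frame's maximum correlation magnitude, so
#'   the mode is taken over the pixels that actually detected motion.
#' @param angle_pool_sigma Gaussian radius (pixels) over which the opponent
#'   direction signals are pooled before the local arctangent; pooling lets
#'   single pixels carry both the horizontal and the vertical coincidence
#'   evidence of oblique motion.
#' @param inhibition_delays Integer delays (frames) of the G1 and G2
#'   lateral-inhibition terms relative to the excitation they oppose.
#'   `c(0, 1)` (default): G1 acts within the frame and G2 one frame back;
#'   `c(1, 2)` delays both terms by one further frame (two genuine delay
#'   units).
#' @return An object of class `dflgmd_params` (a validated list).
#' @examples
#' p <- dflgmd_params()
#' p$xi_ex                    # 5 at n = 128
#' dflgmd_params(n = 64)$xi_ex # 20
#' @export
dflgmd_params <- function(n = 128,
                          alpha = 0.4,
                          g_leak = 30,
                          V_rest = 0,
                          V_th1 = 5e-4,
                          V_th2 = 5e-4,
                          E_ex = 1,
                          E_in = -0.5,
                          lambda_ex = 1.2,
                          lambda_in = 1.2,
                          gamma1 = 150,
                          gamma2 = 150,
                          eps_ex = 1,
                          eps_in = 100,
                          delta_ex = 1.5,
                          beta_on = 1.1,
                          beta_off = 1.1,
                          m = 1,
                          F1 = 5,
                          sigma1 = 0.3,
                          F2 = 1,
                          sigma2 = 0.4,
                          xi_ex = NULL,
                          mu = c(1, 1, 0),
                          h = 1,
                          memory_window = Inf,
                          on_lateral_battery = c("excitatory", "inhibitory"),
                          kernel_exponent_variant = c("sigma", "sigma_squared"),
                          offset_sign = -1,
                          interpolate_diagonals = FALSE,
                          energy_floor = 1e-3,
                          energy_rel = 0.25,
                          angle_pool_sigma = 3,
                          inhibition_delays = c(0L, 1L)) {
  on_lateral_battery <- match.arg(on_lateral_battery)
  kernel_exponent_variant <- match.arg(kernel_exponent_variant)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(n) || length(n) != 1L || n < 3 || n != round(n)) {
    stop("`n` must be an integer grid side >= 3", call. = FALSE)
  }
  if (is.null(xi_ex)) xi_ex <- 5 * 128^2 / n^2
  if (!offset_sign %in% c(-1, 1)) {
    stop("`offset_sign` must be +1 or -1", call. = FALSE)
  }
  if (length(mu) != 3L || !is.numeric(mu)) {
    stop("`mu` must be three numeric coefficients", call. = FALSE)
  }
  gains <- c(lambda_ex = lambda_ex, lambda_in = lambda_in, gamma1 = gamma1,
             gamma2 = gamma2, eps_ex = eps_ex, eps_in = eps_in,
             delta_ex = delta_ex, xi_ex = xi_ex, g_leak = g_leak,
             F1 = F1, F2 = F2, sigma1 = sigma1, sigma2 = sigma2, m = m)
  bad <- gains[!is.finite(gains) | gains < 0]
  if (length(bad)) {
    stop("gain parameters must be non-negative: ",
         paste(names(bad), collapse = ", "), call. = FALSE)
  }
  if (sigma1 <= 0 || sigma2 <= 0 || m <= 0 || h <= 0) {
    stop("`sigma1`, `sigma2`, `m` and `h` must be positive", call. = FALSE)
  }
  if (!(E_in <= V_rest && V_rest <= 0 && 0 <= E_ex)) {
    stop("batteries must satisfy E_in <= V_rest <= 0 <= E_ex", call. = FALSE)
  }
  p <- list(
    n = as.integer(n), alpha = alpha, g_leak = g_leak, V_rest = V_rest,
    V_th1 = V_th1, V_th2 = V_th2, E_ex = E_ex, E_in = E_in,
    lambda_ex = lambda_ex, lambda_in = lambda_in,
    gamma1 = gamma1, gamma2 = gamma2, eps_ex = eps_ex, eps_in = eps_in,
    delta_ex = delta_ex, beta_on = beta_on, beta_off = beta_off,
    m = m, F1 = F1, sigma1 = sigma1, F2 = F2, sigma2 = sigma2,
    xi_ex = xi_ex, mu = as.numeric(mu), h = h,
    memory_window = memory_window,
    on_lateral_battery = on_lateral_battery,
    kernel_exponent_variant = kernel_exponent_variant,
    offset_sign = offset_sign,
    interpolate_diagonals = isTRUE(interpolate_diagonals),
    energy_floor = energy_floor,
    energy_rel = energy_rel,
    angle_pool_sigma = angle_pool_sigma,
    inhibition_delays = as.integer(inhibition_delays)
  )
  for (nm in names(.range_params)) {
    rg <- .range_params[[nm]]
    v <- p[[nm]]
    if (v < rg[1] || v > rg[2]) {
      warning(sprintf("`%s` = %g is outside its standard range [%g, %g]",
                      nm, v, rg[1], rg[2]), call. = FALSE)
    }
  }
  structure(p, class = "dflgmd_params")
}

#' @export
print.dflgmd_params <- function(x, ...) {
  cat(sprintf("<dflgmd_params> %dx%d grid, alpha=%g, xi_ex=%g\n",
              x$n, x$n, x$alpha, x$xi_ex))
  cat(sprintf("  membranes: g_leak=%g V_rest=%g E_ex=%g E_in=%g\n",
              x$g_leak, x$V_rest, x$E_ex, x$E_in))
  cat(sprintf("  retina: lambda=(%g,%g) gamma=(%g,%g) V_th=(%g,%g)\n",
              x$lambda_ex, x$lambda_in, x$gamma1, x$gamma2,
              x$V_th1, x$V_th2))
  cat(sprintf("  lateral: delta_ex=%g eps=(%g,%g) beta=(%g,%g) G1=(F=%g,s=%g) G2=(F=%g,s=%g)\n",
              x$delta_ex, x$eps_ex, x$eps_in, x$beta_on, x$beta_off,
              x$F1, x$sigma1, x$F2, x$sigma2))
  cat(sprintf("  direction: m=%g offset_sign=%+d mu=(%g,%g,%g)\n",
              x$m, x$offset_sign, x$mu[1], x$mu[2], x$mu[3]))
  cat(sprintf("  scheme: h=%g memory_window=%s on_lateral_battery=%s kernel=%s\n",
              x$h,
              if (is.finite(x$memory_window)) x$memory_window else "full",
              x$on_lateral_battery, x$kernel_exponent_variant))
  invisible(x)
}
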