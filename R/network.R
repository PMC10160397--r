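# End-to-end network run.
#
# One call of dflgmd_run() advances every layer frame by frame:
#   luminance -> photoreceptor membrane -> ON/OFF split -> excitatory copy
#   and inhibitory membrane -> delayed Gaussian lateral inhibition ->
#   summing membranes -> superlinear ON/OFF combination -> direction-layer
#   correlation over 8 angles -> direction-selective LGMD membranes ->
#   aggregate collision trace, tuning curve and motion-direction estimate.
# The run is deterministic: no randomness enters after stimulus generation.

#' Run the visual network on a luminance sequence
#'
#' @param input A [luminance_sequence()] or an `H x W x T` array in `[0,1]`.
#' @param params A [dflgmd_params()]; defaults to the standard parameter set
#'   with the grid side taken from the input (which sets the LGMD gain
#'   `xi_ex = 5 * 128^2 / n^2`).
#' @param keep_fields If `TRUE`, the combined S fields and the final-frame
#'   direction fields are returned for diagnostics (memory-heavy).
#' @return An object of class `dflgmd_report`: a list with
#'   \describe{
#'     \item{table}{per-frame data frame: `frame`, aggregate output `C`,
#'       rectified per-direction responses `L1_0` ... `L1_315` (degrees),
#'       and the motion-direction estimate `MD_deg` (`NA` when no pixel has
#'       measurable correlation energy).}
#'     \item{R1}{`T x 8` matrix of integrated direction-layer inputs.}
#'     \item{scores}{time-integrated rectified response per direction.}
#'     \item{preferred_theta}{argmax direction of `scores`, radians.}
#'     \item{peak_frame, peak_prominence, no_response}{collision-peak
#'       report on `C` (see [collision_peak()]).}
#'     \item{params}{the parameter set used.}
#'   }
#' @examples
#' \donttest{
#' stim <- stim_translating(grid = c(48, 48), n_frames = 30, direction = 0,
#'                          speed = 1, size = 9)
#' rep <- dflgmd_run(stim)
#' rep$preferred_theta  # 0: rightward motion recovered
#' }
#' @export
dflgmd_run <- function(input, params = NULL, keep_fields = FALSE) {
  seq <- if (inherits(input, "luminance_sequence")) input
         else luminance_sequence(input)
  fr <- seq$frames
  H <- dim(fr)[1]; W <- dim(fr)[2]; Tn <- dim(fr)[3]
  if (Tn < 3L) stop("need at least 3 frames", call. = FALSE)
  if (is.null(params)) {
    params <- dflgmd_params(n = round(sqrt(H * W)))
  } else if (params$n != round(sqrt(H * W))) {
    warning(sprintf(
      "params built for n = %d but input grid is %d x %d; xi_ex = %g kept",
      params$n, H, W, params$xi_ex), call. = FALSE)
  }
  cfg <- frac_config(params$alpha, params$h, params$memory_window)
  G1 <- inhibition_kernel(params$F1, params$sigma1, 1,
                          params$kernel_exponent_variant)
  G2 <- inhibition_kernel(params$F2, params$sigma2, 2,
                          params$kernel_exponent_variant)
  V0 <- matrix(params$V_rest, H, W)
  st_P    <- frac_state(V0, cfg, Tn)
  st_Ion  <- frac_state(V0, cfg, Tn)
  st_Ioff <- frac_state(V0, cfg, Tn)
  st_Son  <- frac_state(V0, cfg, Tn)
  st_Soff <- frac_state(V0, cfg, Tn)
  st_L1   <- frac_state(rep(params$V_rest, 8L), cfg, Tn)
  thetas <- theta_set()
  zeros <- matrix(0, H, W)
  dly <- params$inhibition_delays
  max_d <- max(dly)
  # ring buffer of past rectified inhibition fields; index d+1 = delay d
  Ihat_on_hist <- rep(list(zeros), max_d + 1L)
  Ihat_off_hist <- rep(list(zeros), max_d + 1L)
  S_t1 <- zeros; S_t2 <- zeros
  R1 <- matrix(0, Tn, 8L)
  L1_rect <- matrix(0, Tn, 8L)
  MD <- rep(NA_real_, Tn)
  S_fields <- if (keep_fields) vector("list", Tn) else NULL
  D_last <- NULL
  for (t in seq_len(Tn)) {
    L_t <- fr[, , t]
    L_prev <- if (t == 1L) L_t else fr[, , t - 1L]
    dp <- photoreceptor_drive(L_t, L_prev, params)
    P <- frac_step(st_P, dp$A, dp$B)
    P_on <- split_on(P, params)
    P_off <- split_off(P, params)
    E <- excitatory_pass(P_on, P_off)
    di_on <- inhibitory_drive(P_on, params)
    Ihat_on <- pmax(frac_step(st_Ion, di_on$A, di_on$B), 0)
    di_off <- inhibitory_drive(P_off, params)
    Ihat_off <- pmax(frac_step(st_Ioff, di_off$A, di_off$B), 0)
    Ihat_on_hist <- c(list(Ihat_on), Ihat_on_hist[seq_len(max_d)])
    Ihat_off_hist <- c(list(Ihat_off), Ihat_off_hist[seq_len(max_d)])
    Ibar_on <- lateral_inhibition(Ihat_on_hist[[dly[1] + 1L]],
                                  Ihat_on_hist[[dly[2] + 1L]],
                                  params$beta_on, G1, G2)
    Ibar_off <- lateral_inhibition(Ihat_off_hist[[dly[1] + 1L]],
                                   Ihat_off_hist[[dly[2] + 1L]],
                                   params$beta_off, G1, G2)
    ds_on <- summing_drive(E$E_on, Ibar_on, "on", params)
    Shat_on <- pmax(frac_step(st_Son, ds_on$A, ds_on$B), 0)
    ds_off <- summing_drive(E$E_off, Ibar_off, "off", params)
    Shat_off <- pmax(frac_step(st_Soff, ds_off$A, ds_off$B), 0)
    S <- combine_on_off(Shat_on, Shat_off, params)
    if (t >= 3L) {
      Dk <- vector("list", 8L)
      for (k in seq_along(thetas)) {
        Dk[[k]] <- direction_correlate(S, S_t1, S_t2, thetas[k], params)
        R1[t, k] <- lgmd_integrate(Dk[[k]])
      }
      # opponent signals cancel direction-neutral temporal change
      D_h <- Dk[[1L]] - Dk[[5L]]
      D_v <- Dk[[3L]] - Dk[[7L]]
      la <- local_angle(D_h, D_v, params)
      MD[t] <- direction_mode(la$E_angle, la$motion_mask)
      if (keep_fields && t == Tn) D_last <- list(D_h = D_h, D_v = D_v)
    }
    ld <- lgmd_drive(R1[t, ], params)
    # R1 is signed; a strongly negative input makes the nominal decay
    # g_leak + xi_ex*R1 negative, where the implicit divide loses meaning.
    # Conductances are floored at zero and the state confined to the
    # battery range, mirroring the membrane's physical bounds.
    L1 <- frac_step(st_L1, ld$A, pmax(ld$B, 0),
                    lower = params$E_in, upper = params$E_ex)
    L1_rect[t, ] <- pmax(L1, 0)
    if (keep_fields) S_fields[[t]] <- S
    S_t2 <- S_t1; S_t1 <- S
  }
  C <- rowSums(L1_rect)
  pk <- collision_peak(C)
  tc <- tuning_curve(L1_rect)
  deg <- round(thetas * 180 / pi)
  tab <- data.frame(frame = seq_len(Tn), C = C)
  for (k in seq_along(thetas)) tab[[sprintf("L1_%d", deg[k])]] <- L1_rect[, k]
  tab$MD_deg <- round(MD * 180 / pi)
  out <- list(
    table = tab, R1 = R1, L1_rect = L1_rect, MD = MD,
    scores = tc$scores, preferred_theta = tc$preferred_theta,
    no_motion = tc$no_motion,
    peak_frame = pk$peak_frame, peak_value = pk$peak_value,
    peak_prominence = pk$peak_prominence, no_response = pk$no_response,
    params = params
  )
  if (keep_fields) {
    out$S_fields <- S_fields
    out$D_last <- D_last
  }
  class(out) <- "dflgmd_report"
  out
}

#' @export
print.dflgmd_report <- function(x, ...) {
  Tn <- nrow(x$table)
  cat(sprintf("<dflgmd_report> %d frames, alpha=%g\n", Tn, x$params$alpha))
  if (x$no_response) {
    cat("  no response (aggregate output identically zero)\n")
  } else {
    cat(sprintf("  peak: frame %d, value %.4g, prominence %.3g\n",
                x$peak_frame, x$peak_value, x$peak_prominence))
  }
  if (x$no_motion) {
    cat("  no motion registered on any direction channel\n")
  } else {
    cat(sprintf("  preferred direction: %g deg\n",
                round(x$preferred_theta * 180 / pi)))
  }
  cat("  integrated per-direction scores:\n")
  print(round(x$scores, 4))
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes `timeseries.csv` (the per-frame table) and `summary.json`
#' (peak/tuning summary plus the effective parameters) into `dir`.
#'
#' @param report A `dflgmd_report` from [dflgmd_run()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "dflgmd_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  csv <- file.path(dir, "timeseries.csv")
  utils::write.csv(report$table, csv, row.names = FALSE)
  js <- file.path(dir, "summary.json")
  pars <- unclass(report$params)
  pars$memory_window <- if (is.finite(pars$memory_window)) {
    pars$memory_window
  } else "full"
  summ <- list(
    n_frames = nrow(report$table),
    peak_frame = report$peak_frame,
    peak_value = report$peak_value,
    peak_prominence = report$peak_prominence,
    no_response = report$no_response,
    preferred_theta_deg = round(report$preferred_theta * 180 / pi),
    no_motion = report$no_motion,
    scores = as.list(report$scores),
    params = pars
  )
  jsonlite::write_json(summ, js, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(c(csv, js))
}
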