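# Numerical engine for the fractional-order membrane dynamics.
#
# Every dynamic layer of the network obeys an equation of the affine form
#   D^alpha x = A - B x,   B >= 0,
# where D^alpha is a fractional derivative of order alpha in (0, 1].  The
# operator is discretised with Grünwald-Letnikov (GL) binomial weights and a
# semi-implicit treatment of the state (the right-hand side is linear in x,
# so the implicit solve is an elementwise division).  The memory sum is taken
# over deviations from the initial state (Caputo-style initialisation), which
# makes constant initial conditions genuine rest states and reduces exactly
# to one-step implicit Euler when alpha = 1.

#' Grünwald-Letnikov coefficients
#'
#' Computes the signed binomial weights \eqn{c_k = (-1)^k \binom{\alpha}{k}}
#' of the discrete fractional-order derivative, via the stable recurrence
#' \eqn{c_k = c_{k-1} (1 - (\alpha + 1)/k)} with \eqn{c_0 = 1}.
#'
#' For \eqn{0 < \alpha < 1} all coefficients beyond the first are negative
#' and their partial sums decrease monotonically towards zero, which is what
#' gives the operator its long (power-law) memory.
#'
#' @param alpha Fractional order, in `(0, 1]`.
#' @param K Number of past steps; `K + 1` coefficients are returned.
#' @return Numeric vector `c_0, ..., c_K` with `c_0 = 1`.
#' @examples
#' gl_coefficients(0.4, 3) # 1, -0.4, -0.12, -0.064
#' gl_coefficients(1, 3)   # 1, -1, 0, 0
#' @export
gl_coefficients <- function(alpha, K) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(K) || length(K) != 1L || K < 0 || K != round(K)) {
    stop("`K` must be a single non-negative integer", call. = FALSE)
  }
  co <- numeric(K + 1)
  co[1] <- 1
  if (K >= 1) {
    for (k in seq_len(K)) co[k + 1] <- co[k] * (1 - (alpha + 1) / k)
  }
  co
}

#' Fractional-scheme configuration
#'
#' @param alpha Fractional order in `(0, 1]`; `alpha = 1` recovers ordinary
#'   first-order (implicit Euler) dynamics.
#' @param h Time step, in frames; must be positive.
#' @param memory_window Maximum history depth used in the memory sum, in
#'   steps; `Inf` (the default) keeps the full history.
#' @return An object of class `frac_config`.
#' @export
frac_config <- function(alpha = 0.4, h = 1, memory_window = Inf) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha > 1) {
    stop("`alpha` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0) {
    stop("`h` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(memory_window) || length(memory_window) != 1L ||
      memory_window < 1) {
    stop("`memory_window` must be >= 1 (or Inf)", call. = FALSE)
  }
  structure(
    list(alpha = alpha, h = h, memory_window = memory_window),
    class = "frac_config"
  )
}

#' Create a fractional state (history buffer)
#'
#' Seeds the per-unit history with the initial condition `x0` and precomputes
#' GL coefficients.  The returned object is an environment: [frac_step()]
#' updates it in place, so the per-frame network loop does not copy the
#' history matrix.
#'
#' @param x0 Initial state; a numeric vector or matrix (the pixel grid).
#' @param cfg A [frac_config()].
#' @param capacity Expected number of steps (the buffer grows if exceeded).
#' @return An object of class `frac_state`.
#' @export
frac_state <- function(x0, cfg = frac_config(), capacity = 64L) {
  if (!inherits(cfg, "frac_config")) stop("`cfg` must be a frac_config")
  if (!is.numeric(x0) || length(x0) == 0L) {
    stop("`x0` must be a non-empty numeric vector or matrix", call. = FALSE)
  }
  st <- new.env(parent = emptyenv())
  st$dim <- dim(x0)
  st$npix <- length(x0)
  st$cfg <- cfg
  st$ha <- cfg$h^cfg$alpha
  capacity <- max(as.integer(capacity), 8L)
  st$coeffs <- gl_coefficients(cfg$alpha, capacity)
  st$csum <- cumsum(st$coeffs)
  st$hist <- matrix(0, st$npix, capacity + 1L)
  st$hist[, 1L] <- as.numeric(x0)
  st$x0 <- as.numeric(x0)
  st$len <- 1L
  class(st) <- "frac_state"
  st
}

# Extend coefficient table and history buffer when capacity is exceeded.
.frac_grow <- function(st, need) {
  cap <- ncol(st$hist)
  newcap <- max(2L * cap, need + 1L)
  h <- matrix(0, st$npix, newcap)
  h[, seq_len(st$len)] <- st$hist[, seq_len(st$len)]
  st$hist <- h
  st$coeffs <- gl_coefficients(st$cfg$alpha, newcap)
  st$csum <- cumsum(st$coeffs)
  invisible(st)
}

#' Advance a fractional state by one step
#'
#' Performs one semi-implicit GL update of \eqn{D^\alpha x = A - B x}:
#' \deqn{x_n (1 + h^\alpha B) = h^\alpha A - \sum_{k=1}^{K} c_k x_{n-k}
#'       + S_K x_0,}
#' where \eqn{S_K = \sum_{k=0}^{K} c_k} and \eqn{K} is the effective history
#' depth (capped by `memory_window`).  The \eqn{S_K x_0} term applies the
#' operator to the deviation from the initial state, so a system at rest
#' with zero drive stays at rest for any order.  The new field is appended
#' to the history and returned.
#'
#' @param state A [frac_state()]; modified in place.
#' @param A,B Drive and decay fields: the state-independent part of the
#'   right-hand side and the coefficient of \eqn{-x}.  Scalars are recycled
#'   over the grid.
#' @param lower,upper Optional clamp applied to the new state before it is
#'   stored (battery-style confinement of the dynamic range).
#' @return The new state field (numeric, same shape as `x0`), invisibly the
#'   same object stored in the history.
#' @export
frac_step <- function(state, A, B, lower = -Inf, upper = Inf) {
  if (!inherits(state, "frac_state")) stop("`state` must be a frac_state")
  if (state$len < 1L) stop("state history is empty", call. = FALSE)
  npix <- state$npix
  if (length(A) != 1L && length(A) != npix) {
    stop("drive field `A` does not match the grid shape", call. = FALSE)
  }
  if (length(B) != 1L && length(B) != npix) {
    stop("decay field `B` does not match the grid shape", call. = FALSE)
  }
  n <- state$len
  if (n + 1L > ncol(state$hist)) .frac_grow(state, n + 1L)
  K <- as.integer(min(n, state$cfg$memory_window))
  # memory sum: columns n, n-1, ..., n-K+1 weighted by c_1..c_K
  cols <- seq.int(n, n - K + 1L)
  w <- state$coeffs[2L:(K + 1L)]
  mem <- if (K == 1L) state$hist[, n] * w else
    drop(state$hist[, cols, drop = FALSE] %*% w)
  num <- state$ha * A - mem + state$csum[K + 1L] * state$x0
  x <- num / (1 + state$ha * B)
  if (is.finite(lower) || is.finite(upper)) x <- pmin(pmax(x, lower), upper)
  state$hist[, n + 1L] <- x
  state$len <- n + 1L
  if (!is.null(state$dim)) dim(x) <- state$dim
  x
}

#' Simulate an affine fractional system over a drive sequence
#'
#' Batch wrapper over [frac_step()]: runs \eqn{D^\alpha x = A(t) - B(t) x}
#' from the `x0`-seeded history over `T` steps.
#'
#' @param A,B Drive sequences: numeric vectors of length `T` (scalar system)
#'   or lists of `T` fields matching `x0`.
#' @param x0 Initial state.
#' @param cfg A [frac_config()].
#' @return For scalar systems a numeric vector of length `T`; otherwise a
#'   list of `T` fields.  Element `t` is the state after step `t`.
#' @export
simulate_affine <- function(A, B, x0, cfg = frac_config()) {
  a_list <- if (is.list(A)) A else as.list(A)
  b_list <- if (is.list(B)) B else as.list(B)
  if (length(a_list) != length(b_list)) {
    stop("`A` and `B` must have the same length", call. = FALSE)
  }
  Tn <- length(a_list)
  st <- frac_state(x0, cfg, capacity = Tn)
  out <- vector("list", Tn)
  for (t in seq_len(Tn)) out[[t]] <- frac_step(st, a_list[[t]], b_list[[t]])
  if (length(x0) == 1L) unlist(out) else out
}

#' @export
print.frac_state <- function(x, ...) {
  cat(sprintf(
    "<frac_state> alpha=%g h=%g window=%s, %d unit(s), %d state(s) stored\n",
    x$cfg$alpha, x$cfg$h,
    if (is.finite(x$cfg$memory_window)) x$cfg$memory_window else "full",
    x$npix, x$len
  ))
  invisible(x)
}

#' @export
print.frac_config <- function(x, ...) {
  cat(sprintf(
    "<frac_config> alpha=%g h=%g memory_window=%s\n",
    x$alpha, x$h,
    if (is.finite(x$memory_window)) x$memory_window else "full"
  ))
  invisible(x)
}
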