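# Independent oracles and small shared helpers for the test suite.

# Truncated Mittag-Leffler series E_a(z) = sum_j z^j / Gamma(a j + 1).
# Accurate in double precision for moderate |z| (alternating series with
# bounded intermediate terms for the arguments used here).
ml_series <- function(z, a, terms = 300L) {
  j <- 0:terms
  sum(z^j / gamma(a * j + 1))
}

# GL coefficients by direct evaluation of (-1)^k * binom(alpha, k) through
# base R's generalised choose() -- independent of the package's recurrence.
gl_direct <- function(alpha, K) {
  k <- 0:K
  (-1)^k * choose(alpha, k)
}

# One-step implicit Euler for dx/dt = A - B x (independent of fracdyn).
implicit_euler <- function(A, B, x0, h, n) {
  x <- numeric(n)
  prev <- x0
  for (t in seq_len(n)) {
    prev <- (prev + h * A[t]) / (1 + h * B[t])
    x[t] <- prev
  }
  x
}

# speed at which the 2-frame correlation displacement matches the m = 1
# partner offset for direction theta
matched_speed <- function(theta) {
  sqrt(sum(neighbor_offset(theta, 1)^2)) / 2
}

# angular identity on the canonical set (mod 2*pi)
same_angle <- function(a, b, tol = 1e-9) {
  abs(((a - b + pi) %% (2 * pi)) - pi) < tol
}

# standard small translation stimulus used across behavioural tests
test_translation <- function(theta, n = 64, n_frames = 40, size = 9,
                             speed = matched_speed(theta), ...) {
  stim_translating(grid = c(n, n), n_frames = n_frames, direction = theta,
                   speed = speed, size = size, ...)
}
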