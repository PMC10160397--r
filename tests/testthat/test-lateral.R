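# Lateral inhibition kernels, inhibitory/summing membranes, ON/OFF fusion.

p128 <- dflgmd_params()

test_that("kernel values match the closed-form expression and its symmetries", {
  G1 <- inhibition_kernel(5, 0.3, 1)
  expect_equal(G1[2, 2], 5 / (2 * pi * 0.09), tolerance = 1e-9)
  expect_equal(G1[2, 2], 8.8419, tolerance = 1e-4)
  expect_equal(G1[2, 3], 8.8419 * exp(-1 / 0.6), tolerance = 1e-4)
  expect_equal(G1[2, 3], 1.6700, tolerance = 1e-4)
  expect_equal(G1[2, 1], G1[2, 3])
  expect_equal(G1[1, 2], G1[3, 2])
  expect_equal(G1, t(G1))
  # strictly decreasing with squared distance
  G2 <- inhibition_kernel(1, 0.4, 2)
  d2 <- outer((-2:2)^2, (-2:2)^2, `+`)
  o <- order(d2)
  expect_true(all(diff(G2[o][!duplicated(d2[o])]) < 0))
  expect_true(which.max(G2) == 13)  # centre of the 5x5
  expect_error(inhibition_kernel(5, 0.3, 3), "radius")
  expect_error(inhibition_kernel(-1, 0.3, 1), "positive")
})

test_that("the sigma-squared kernel variant uses the conventional exponent", {
  Ga <- inhibition_kernel(5, 0.3, 1, "sigma")
  Gb <- inhibition_kernel(5, 0.3, 1, "sigma_squared")
  expect_equal(Gb[2, 3] / Gb[2, 2], exp(-1 / (2 * 0.09)))
  expect_gt(Ga[2, 3], Gb[2, 3])  # the 2*sigma exponent decays more slowly here
})

test_that("excitatory pass is an identity per channel", {
  a <- matrix(rnorm(16), 4, 4); b <- matrix(rnorm(16), 4, 4)
  e <- excitatory_pass(a, b)
  expect_identical(e$E_on, a)
  expect_identical(e$E_off, b)
})

test_that("inhibitory membrane relaxes to its closed-form fixed point", {
  p <- p128
  # P = 0: leak only
  d <- inhibitory_drive(matrix(0, 2, 2), p)
  tr <- simulate_affine(rep(list(d$A), 100), rep(list(d$B), 100),
                        x0 = matrix(p$V_rest, 2, 2), cfg = frac_config(p$alpha))
  expect_lt(max(abs(tr[[100]] - p$V_rest)), 1e-6)
  # P = 1: I* = delta_ex / (g_leak + delta_ex)
  d <- inhibitory_drive(matrix(1, 2, 2), p)
  Istar <- 1.5 / 31.5
  expect_equal(Istar, 0.047619, tolerance = 1e-5)
  tr <- simulate_affine(rep(list(d$A), 200), rep(list(d$B), 200),
                        x0 = matrix(p$V_rest, 2, 2), cfg = frac_config(p$alpha))
  expect_lt(max(abs(tr[[200]] - Istar)) / Istar, 0.01)
})

test_that("lateral inhibition spreads by convolution with replicate padding", {
  G1 <- inhibition_kernel(5, 0.3, 1)
  G2 <- inhibition_kernel(1, 0.4, 2)
  z <- matrix(0, 9, 9)
  expect_equal(lateral_inhibition(z, z, 1.1, G1, G2), z)
  # unit impulse at the centre stamps G1
  imp <- z; imp[5, 5] <- 1
  out <- lateral_inhibition(imp, z, 1.1, G1, G2)
  expect_equal(out[4:6, 4:6], unclass(G1), ignore_attr = TRUE)
  expect_equal(sum(out != 0), 9)
  # uniform field scales by the kernel masses under replicate padding
  u <- matrix(0.3, 9, 9)
  out <- lateral_inhibition(u, u, 1.1, G1, G2)
  expect_equal(out, matrix(0.3 * (sum(G1) + 1.1 * sum(G2)), 9, 9),
               tolerance = 1e-12)
  # translation equivariance in the interior
  f <- matrix(0, 9, 9); f[4, 4] <- 2; f[5, 6] <- 1
  fs <- matrix(0, 9, 9); fs[5, 4] <- 2; fs[6, 6] <- 1  # shifted down 1 row
  a <- lateral_inhibition(f, z, 1.1, G1, G2)
  b <- lateral_inhibition(fs, z, 1.1, G1, G2)
  expect_equal(a[3:6, 2:8], b[4:7, 2:8], tolerance = 1e-12)
})

test_that("summing units reach their closed-form fixed points", {
  p_sym <- dflgmd_params(on_lateral_battery = "inhibitory")
  run_sum <- function(E, Ibar, channel, p, n = 200) {
    d <- summing_drive(matrix(E, 1, 1), matrix(Ibar, 1, 1), channel, p)
    tr <- simulate_affine(rep(list(d$A), n), rep(list(d$B), n),
                          x0 = matrix(p$V_rest, 1, 1),
                          cfg = frac_config(p$alpha))
    tr[[n]][1]
  }
  expect_lt(abs(run_sum(0, 0, "on", p_sym) - p_sym$V_rest), 1e-6)
  # excitation only: S* = 1/31
  expect_lt(abs(run_sum(1, 0, "on", p_sym) - 1 / 31) / (1 / 31), 0.01)
  expect_equal(1 / 31, 0.032258, tolerance = 1e-5)
  # inhibition silences the unit in the symmetric variant
  Sstar <- (1 * 1 + 5 * (-0.5)) / (30 + 1 + 5)
  expect_equal(Sstar, -0.041667, tolerance = 1e-5)
  got <- run_sum(1, 0.05, "on", p_sym)
  expect_lt(abs(got - Sstar) / abs(Sstar), 0.01)
  expect_equal(max(got, 0), 0)
  # the reference ON formulation uses the excitatory battery instead
  d_ref <- summing_drive(matrix(1, 1, 1), matrix(0.05, 1, 1), "on", p128)
  expect_gt(d_ref$A[1], 0)
})

test_that("steady summing output is monotone in its inputs", {
  p0 <- dflgmd_params(eps_in = 0)
  fixed_point <- function(E, Ibar, p, channel = "on") {
    d <- summing_drive(matrix(E, 1, 1), matrix(Ibar, 1, 1), channel, p)
    d$A[1] / d$B[1]
  }
  # more excitation, more output (eps_in = 0)
  Es <- seq(0, 3, by = 0.5)
  expect_true(all(diff(vapply(Es, fixed_point, numeric(1), Ibar = 0,
                              p = p0)) > 0))
  # more inhibition never increases output (symmetric variant)
  p_sym <- dflgmd_params(on_lateral_battery = "inhibitory")
  Is <- seq(0, 0.2, by = 0.05)
  ss <- vapply(Is, function(i) fixed_point(1, i, p_sym), numeric(1))
  expect_true(all(diff(ss) <= 0))
})

test_that("ON/OFF combination follows the superlinear rule", {
  on <- matrix(0.2, 1, 1); off <- matrix(0.3, 1, 1)
  expect_equal(combine_on_off(on, off, p128)[1], 0.5)
  p111 <- dflgmd_params(mu = c(1, 1, 1))
  expect_equal(combine_on_off(on, off, p111)[1], 0.56)
  z <- matrix(0, 1, 1)
  p_w <- dflgmd_params(mu = c(2, 3, 5))
  expect_equal(combine_on_off(on, z, p_w)[1], 2 * 0.2)
  expect_equal(combine_on_off(z, off, p_w)[1], 3 * 0.3)
})

test_that("summing membranes stay within the battery range on random input", {
  p <- p128
  cfg <- frac_config(p$alpha)
  st <- frac_state(matrix(p$V_rest, 4, 4), cfg)
  set.seed(11)
  for (t in 1:60) {
    E <- matrix(runif(16, 0, 5), 4, 4)
    Ibar <- matrix(runif(16, 0, 3), 4, 4)
    d <- summing_drive(E, Ibar, "on", p)
    S <- frac_step(st, d$A, d$B)
    expect_true(all(S >= p$E_in - 1e-6 & S <= p$E_ex + 1e-6))
  }
})
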