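# Synthetic stimulus generator and frame I/O.

test_that("looming grows monotonically and freezes after the fill frame", {
  st <- stim_looming(grid = c(48, 48), n_frames = 50, fill_frame = 37,
                     start_size = 8)
  fr <- st$frames
  for (t in 37:50) expect_identical(fr[, , t], fr[, , 37])
  # object mass (dark area) non-decreasing before the fill frame
  mass <- apply(1 - fr, 3, sum)
  expect_true(all(diff(mass[1:37]) >= 0))
  expect_gt(mean(fr[, , 1]), mean(fr[, , 37]))
  expect_equal(mean(fr[, , 37]), 0)  # dark object fills the field
  expect_error(stim_looming(grid = c(48, 48), n_frames = 30, fill_frame = 37),
               "fill_frame")
})

test_that("receding is the exact time reverse of looming", {
  loom <- stim_looming(grid = c(32, 32), n_frames = 20, fill_frame = 15)
  rec <- stim_receding(grid = c(32, 32), n_frames = 20, fill_frame = 15)
  expect_equal(rec$frames, loom$frames[, , 20:1])
  mass <- apply(1 - rec$frames, 3, sum)
  expect_true(all(diff(mass) <= 0))
  expect_gte(mass[20], 0)
})

test_that("translation moves the centroid at the requested velocity", {
  st <- stim_translating(grid = c(64, 64), n_frames = 20, direction = 0,
                         speed = 1, size = 9, blur_sigma = 0)
  fr <- st$frames
  centroid_col <- function(M) {
    w <- 1 - M  # object mass
    sum(col(M) * w) / sum(w)
  }
  cc <- apply(fr, 3, centroid_col)
  expect_equal(diff(cc), rep(1, 19), tolerance = 1e-9)
  # object mass constant while fully inside the grid
  mass <- apply(1 - fr, 3, sum)
  expect_equal(max(mass) - min(mass), 0, tolerance = 1e-9)
})

test_that("opposite directions are mirror images for symmetric geometry", {
  n <- 33  # odd grid: centre is a pixel centre
  a <- stim_translating(grid = c(n, n), n_frames = 12, direction = 0,
                        speed = 1, size = 7)
  b <- stim_translating(grid = c(n, n), n_frames = 12, direction = pi,
                        speed = 1, size = 7)
  expect_equal(b$frames, a$frames[, n:1, ], tolerance = 1e-12)
})

test_that("translation rejects objects that exit before frame 3", {
  expect_error(
    stim_translating(grid = c(32, 32), n_frames = 20, direction = 0,
                     speed = 40, size = 5, start = c(3, 16)),
    "leaves the grid"
  )
  expect_error(
    stim_translating(grid = c(32, 32), n_frames = 10, direction = pi / 3),
    "canonical"
  )
})

test_that("gaussian noise is seeded, scaled to the requested SNR, and clipped", {
  st <- stim_translating(grid = c(64, 64), n_frames = 40, direction = 0,
                         speed = 0.5, size = 9, object_luminance = 0.2,
                         background_luminance = 0.8)
  a <- add_gaussian_noise(st, 10, seed = 99)
  b <- add_gaussian_noise(st, 10, seed = 99)
  expect_identical(a$frames, b$frames)
  c2 <- add_gaussian_noise(st, 10, seed = 100)
  expect_false(identical(a$frames, c2$frames))
  # realised (pre-clipping) SNR within 0.1 dB of the request
  for (snr in c(5, 30)) {
    noisy <- add_gaussian_noise(st, snr, seed = 1)
    expect_lt(abs(attr(noisy, "snr_empirical") - snr), 0.1)
    expect_true(all(noisy$frames >= 0 & noisy$frames <= 1))
  }
  expect_identical(add_gaussian_noise(st, Inf), st)
  expect_error(add_gaussian_noise(st, NA_real_), "snr")
})

test_that("all generators produce valid luminance sequences", {
  stims <- list(
    stim_looming(grid = c(24, 24), n_frames = 10, fill_frame = 8),
    stim_receding(grid = c(24, 24), n_frames = 10, fill_frame = 8),
    stim_translating(grid = c(24, 24), n_frames = 10, direction = 5 * pi / 4,
                     speed = 0.7, size = 5),
    stim_translating(grid = c(32, 32), n_frames = 10, direction = pi / 2,
                     speed = 0.5, size = 4, shape = "bar")
  )
  for (st in stims) {
    expect_s3_class(st, "luminance_sequence")
    expect_gte(dim(st)[3], 3)
    expect_true(all(st$frames >= 0 & st$frames <= 1))
  }
  expect_error(luminance_sequence(array(0.5, c(4, 4, 2))), "3 frames")
  expect_error(luminance_sequence(array(2, c(4, 4, 5))), "\\[0, 1\\]")
})

test_that("frame directories round-trip within 8-bit quantisation", {
  st <- stim_translating(grid = c(24, 24), n_frames = 5, direction = 0,
                         speed = 1, size = 7)
  dir <- withr::local_tempdir()
  save_frames(st, dir)
  back <- load_frames(dir)
  expect_equal(dim(back), dim(st))
  expect_lt(max(abs(back$frames - st$frames)), 1 / 255 + 1e-12)
  # an all-zeros sequence round-trips exactly
  z <- luminance_sequence(array(0, c(4, 4, 3)))
  dir2 <- withr::local_tempdir()
  save_frames(z, dir2)
  expect_equal(load_frames(dir2)$frames, z$frames)
  expect_error(load_frames(withr::local_tempdir()), "no PNG/TIFF")
})

test_that("zero-padded frame names order numerically", {
  dir <- withr::local_tempdir()
  png::writePNG(matrix(0.2, 4, 4), file.path(dir, "frame_0002.png"))
  png::writePNG(matrix(0.8, 4, 4), file.path(dir, "frame_0010.png"))
  png::writePNG(matrix(0.5, 4, 4), file.path(dir, "frame_0005.png"))
  got <- load_frames(dir)
  expect_equal(got$frames[1, 1, ], c(0.2, 0.5, 0.8), tolerance = 1 / 254)
})
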