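test_that("accumulated exposure reproduces the published bookkeeping", {
  # 130 frames at 0.769 e-/A^2 per frame: total exposure ~100 e-/A^2
  s <- exposure_schedule(0.769, 130)
  expect_equal(accumulated_exposure(s, 130), 100, tolerance = 1e-3)
  # 3-frame sums at 0.77 e-/A^2 per frame carry 2.31 e-/A^2 per sum
  s3 <- exposure_schedule(0.77, 3)
  expect_equal(accumulated_exposure(s3, 3), 2.31)
  expect_error(accumulated_exposure(s, 131), "out of range")
  expect_error(accumulated_exposure(s, 0), "out of range")
  expect_error(exposure_schedule(0, 5))
})

test_that("exposure conventions and additivity behave", {
  s <- exposure_schedule(2, 10, pre_exposure = 5)
  expect_equal(accumulated_exposure(s, 1), 7)       # end of frame 1
  sm <- exposure_schedule(2, 10, pre_exposure = 5, convention = "mid")
  expect_equal(accumulated_exposure(sm, 1), 6)      # mid frame 1
  expect_true(all(diff(accumulated_exposure(s, 1:10)) > 0))
  # concatenation: a second schedule pre-exposed by the first's total
  tail_sched <- exposure_schedule(2, 4, pre_exposure = accumulated_exposure(s, 10))
  expect_equal(accumulated_exposure(tail_sched, 4),
               accumulated_exposure(exposure_schedule(2, 14, pre_exposure = 5), 14))
})

test_that("MRC write/read round-trips stacks bit-exactly", {
  set.seed(1)
  # values exactly representable in 32-bit floats (dyadic rationals)
  v <- round(rnorm(16 * 12 * 5) * 64) / 64
  frames <- array(v, dim = c(16, 12, 5))
  st <- movie_stack(frames, pixel_size = 1.023)
  path <- tempfile(fileext = ".mrcs")
  write_movie(st, path)
  st2 <- read_movie(path)
  expect_identical(st2$frames, frames)
  expect_equal(st2$pixel_size, 1.023, tolerance = 1e-6)
  expect_equal(st2$n_frames, 5)
  # single-image MRC is a 1-frame stack
  p1 <- tempfile(fileext = ".mrc")
  write_movie(frames[, , 1], p1, pixel_size = 2)
  expect_equal(read_movie(p1)$n_frames, 1)
})

test_that("malformed MRC input is rejected with context", {
  p <- tempfile()
  writeBin(raw(100), p)
  expect_error(read_movie(p), "1024")
  # truncate a valid file: header claims more sections than data present
  frames <- array(seq_len(8 * 8 * 4), dim = c(8, 8, 4))
  pv <- tempfile(fileext = ".mrc")
  write_movie(movie_stack(frames, 1), pv)
  full <- readBin(pv, "raw", n = file.size(pv))
  pt <- tempfile(fileext = ".mrc")
  writeBin(full[1:(1024 + 8 * 8 * 2 * 4)], pt)  # only 2 of 4 sections
  expect_error(read_movie(pt), "truncated")
  # pixel-size override disagreement warns and wins
  expect_warning(st <- read_movie(pv, pixel_size = 3), "override")
  expect_equal(st$pixel_size, 3)
})

test_that("Fourier cropping preserves band-limited content and the mean", {
  expect_equal(fourier_crop(matrix(5, 64, 64), 2), matrix(5, 32, 32))
  # pure cosine below the new Nyquist survives exactly at halved sampling
  x <- outer(cos(2 * pi * 3 * (0:63) / 64), rep(1, 64))
  expect_equal(fourier_crop(x, 2),
               outer(cos(2 * pi * 3 * (0:31) / 32), rep(1, 32)),
               tolerance = 1e-12)
  img <- smooth_image(64)
  expect_equal(mean(fourier_crop(img, 2)), mean(img), tolerance = 1e-12)
  expect_error(fourier_crop(matrix(0, 63, 63), 2), "divisible")
  # any band-limited image is decimated exactly: compare against direct
  # sampling of an analytic band-limited signal
  f <- function(t) 1 + cos(2 * pi * 5 * t) + sin(2 * pi * 2 * t)
  grid <- outer(f((0:63) / 64), f((0:63) / 64))
  expect_equal(fourier_crop(grid, 2),
               outer(f((0:31) / 32), f((0:31) / 32)), tolerance = 1e-10)
})

test_that("sub-pixel shifts compose and reduce to circular rolls", {
  img <- smooth_image(64)
  expect_identical(shift_image(img, 0, 0), img)
  rolled <- img[((seq_len(64) - 1 - 3) %% 64) + 1, ((seq_len(64) - 1 + 2) %% 64) + 1]
  expect_equal(shift_image(img, 3, -2), rolled, tolerance = 1e-12)
  # two half-pixel shifts equal one integer shift
  expect_equal(shift_image(shift_image(img, 0.5, 0), 0.5, 0),
               shift_image(img, 1, 0), tolerance = 1e-9)
  # round trip (band-limited content)
  expect_equal(shift_image(shift_image(img, 2.3, -1.7), -2.3, 1.7), img,
               tolerance = 1e-9)
})

test_that("shell statistics partition the grid and average correctly", {
  si <- shell_index(c(32, 32), pixel_size = 1)
  expect_true(all(diff(si$freq) > 0))
  # every voxel within Nyquist belongs to exactly one shell
  r <- radial_freq_grid(c(32, 32), 1) * 32
  expect_equal(sum(si$counts), sum(r <= 16))
  # delta at the origin puts all power in shell 0
  d <- matrix(0, 32, 32); d[1, 1] <- 1
  pw <- shell_average(Mod(stats::fft(shift_image(d, 5, 5)))^2, si)
  expect_true(pw$mean[1] > 0)
  # white-noise power is flat across shells (Monte Carlo)
  set.seed(2)
  acc <- 0
  for (i in 1:40) {
    acc <- acc + shell_average(Mod(stats::fft(matrix(rnorm(32^2), 32)))^2, si)$mean
  }
  prof <- acc / 40 / 32^2
  # shells with a handful of voxels fluctuate; check the populated ones
  expect_true(all(abs(prof[si$counts >= 12] - 1) < 0.25))
  expect_error(shell_average(matrix(0, 16, 16), si), "mismatch")
})
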