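test_that("FSC of a map with itself is 1, of independent noise near 0", {
  img <- make_reference(32, seed = 4)
  f <- compute_fsc(img, img, 1)
  expect_equal(f$fsc, rep(1, length(f$fsc)), tolerance = 1e-10)
  # independent white noise: per-shell FSC scatter ~ 1/sqrt(n/2)
  set.seed(6)
  devs <- replicate(30, {
    f <- compute_fsc(matrix(rnorm(32^2), 32), matrix(rnorm(32^2), 32), 1)
    f$fsc
  })
  sds <- apply(devs, 1, sd)
  pred <- 1 / sqrt(compute_fsc(img, img, 1)$n_voxels / 2)
  expect_equal(mean(rowMeans(devs)), 0, tolerance = 0.05)
  expect_equal(sds[-1] / pred[-1], rep(1, length(sds) - 1), tolerance = 0.6)
  expect_error(compute_fsc(img, matrix(0, 16, 16)), "mismatch")
  expect_error(compute_fsc(img, img, mask = matrix(2, 32, 32)), "mask")
})

test_that("shared signal plus independent noise gives the closed-form FSC", {
  # per-half-map SNR s gives expected FSC = s / (s + 1)
  set.seed(14)
  sig <- make_reference(64, seed = 3)
  noise_sd <- 0.5
  fmean <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    a <- sig + matrix(rnorm(64^2, 0, noise_sd), 64)
    b <- sig + matrix(rnorm(64^2, 0, noise_sd), 64)
    fmean <- fmean + compute_fsc(a, b, 1)$fsc
  }
  fmean <- fmean / reps
  si <- shell_index(c(64, 64), 1)
  psig <- shell_average(Mod(stats::fft(sig))^2, si)$mean
  s <- psig / (noise_sd^2 * 64^2)
  expect_equal(fmean[-1], (s / (s + 1))[-1], tolerance = 0.1)
})

test_that("FSC and half-map simulation extend to 3D grids", {
  set.seed(31)
  vol <- array(rnorm(16^3), dim = c(16, 16, 16))
  f <- compute_fsc(vol, vol, pixel_size = 2)
  expect_equal(f$fsc, rep(1, length(f$fsc)), tolerance = 1e-10)
  expect_equal(max(f$freq), 0.25, tolerance = 1e-9)  # Nyquist at 2 A/px
  hm <- simulate_half_map_series(vol, c(5, 10), noise_sd = 0, seed = 2)
  f2 <- compute_fsc(hm$maps[[2]]$map_a, hm$maps[[2]]$map_b, 2)
  expect_equal(f2$fsc, rep(1, length(f2$fsc)), tolerance = 1e-9)
})

test_that("FSC/SNR conversion identities hold exactly and round-trip", {
  expect_equal(fsc_to_snr(0.5), 2)
  expect_equal(fsc_to_snr(1 / 3), 1)
  expect_equal(fsc_to_snr(0), 0)
  x <- seq(-0.5, 0.99, by = 0.01)
  expect_equal(snr_to_fsc(fsc_to_snr(x[x >= 0])), x[x >= 0], tolerance = 1e-12)
  expect_equal(fsc_to_snr(snr_to_fsc(c(0, 1, 2, 50))), c(0, 1, 2, 50),
               tolerance = 1e-12)
  expect_warning(v <- fsc_to_snr(1), "SNR")
  expect_identical(v, Inf)
  expect_error(fsc_to_snr(-1), "domain")
  expect_error(snr_to_fsc(-0.5), ">= 0")
})

test_that("threshold resolution interpolates the first crossing", {
  freq <- (0:32) / 64
  # analytic curve with a known 0.143 crossing
  fsc <- 1 - freq * 2
  cross <- (1 - 0.143) / 2
  res <- resolution_at_threshold(data.frame(freq = freq, fsc = fsc), 0.143)
  expect_equal(as.numeric(res), 1 / cross, tolerance = 1e-6)
  expect_true(attr(res, "crossed"))
  # a curve stepping below 0.143 exactly at 1/2.59 per-A reports 2.59 A
  freq2 <- c(0.1, 0.2, 1 / 2.59, 0.45)
  fsc2 <- c(0.9, 0.8, 0.143, 0.05)
  res2 <- resolution_at_threshold(data.frame(freq = freq2, fsc = fsc2), 0.1435)
  expect_equal(as.numeric(res2), 2.59, tolerance = 0.01)
  expect_warning(
    res3 <- resolution_at_threshold(data.frame(freq = freq, fsc = rep(0.9, 33)), 0.5),
    "Nyquist")
  expect_equal(as.numeric(res3), 2)
  expect_false(attr(res3, "crossed"))
})

test_that("exact exponential SNR series yields Ne at machine precision", {
  freq <- c(0.05, 0.1, 0.2, 0.3)
  expos <- seq(2, 40, by = 2)
  snr <- outer(rep(1, 4), exp(-expos / 5)) * 50
  ser <- manual_snr_series(freq, expos, snr)
  est <- estimate_critical_exposure(ser)
  expect_equal(est$ne, rep(5, 4), tolerance = 1e-9)
  expect_equal(est$slope, rep(-1 / 5, 4), tolerance = 1e-9)
  # flat series: dropped for lack of decay
  flat <- manual_snr_series(freq, expos, matrix(3, 4, length(expos)))
  expect_error(estimate_critical_exposure(flat), "usable")
})

test_that("noisy series recover Ne without bias (Monte Carlo)", {
  set.seed(15)
  expos <- seq(1, 60, length.out = 30)
  ne_hat <- replicate(100, {
    snr <- matrix(40 * exp(-expos / 10) * exp(rnorm(30, 0, 0.2)), 1)
    ser <- manual_snr_series(0.2, expos, snr)
    estimate_critical_exposure(ser, min_points = 3)$ne
  })
  expect_equal(mean(ne_hat), 10, tolerance = 0.05 * 10)
})

test_that("censoring truncates at the noise floor, start_exposure skips early frames", {
  expos <- seq(2, 60, by = 2)
  snr <- matrix(100 * exp(-expos / 4), 1)
  fsc <- snr / (snr + 2)
  ser <- manual_snr_series(0.25, expos, snr, sigma = 0.05)
  est <- estimate_critical_exposure(ser)
  # points beyond the 3-sigma FSC floor are not used
  expect_lt(est$n_points[1], length(expos))
  expect_equal(est$ne[1], 4, tolerance = 1e-6)
  # early points can be excluded (motion not yet plateaued)
  est2 <- estimate_critical_exposure(ser, start_exposure = 10)
  expect_true(est2$n_points[1] < est$n_points[1])
  expect_equal(est2$ne[1], 4, tolerance = 1e-6)
})

test_that("power-law fit is exact on exact samples and robust to noise", {
  k <- seq(0.05, 0.5, length.out = 20)
  ne <- 0.245 * k^(-1.665) + 2.81
  fit <- fit_power_law(k, ne)
  expect_equal(c(fit$a, fit$b, fit$c), c(0.245, -1.665, 2.81),
               tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  # constant data: prefactor collapses, flagged degenerate
  fitc <- fit_power_law(k, rep(5, 20))
  expect_true(fitc$degenerate)
  expect_equal(fitc$c, 5, tolerance = 0.05)
  expect_error(fit_power_law(k[1:3], ne[1:3]), ">= 4")
  # 5% noise, 50 replicates: median recovery within 10%
  set.seed(16)
  fits <- replicate(50, {
    f <- fit_power_law(k, ne * exp(rnorm(20, 0, 0.05)))
    c(f$a, f$b, f$c)
  })
  med <- apply(fits, 1, median)
  expect_equal(med, c(0.245, -1.665, 2.81), tolerance = 0.1)
})

test_that("FSC CSV round-trips with exposure labels", {
  img <- make_reference(32, seed = 2)
  f <- compute_fsc(img, img + 0.01 * matrix(rnorm(32^2), 32), 1,
                   exposure = 12.5)
  p <- tempfile(fileext = ".csv")
  write_fsc(f, p)
  f2 <- read_fsc(p)
  expect_equal(f2$fsc, f$fsc, tolerance = 1e-9)
  expect_equal(attr(f2, "exposure"), 12.5)
  expect_equal(f2$n_voxels, f$n_voxels)
})

test_that("the classed estimator exposes the standard model interface", {
  ref <- make_reference(64, seed = 5)
  hm <- simulate_half_map_series(ref, seq(2, 50, length.out = 20),
                                 pixel_size = 1, noise_sd = 0.02, seed = 5)
  fit <- fit_critical_exposure(half_map_fsc(hm))
  expect_s3_class(fit, "critexp")
  expect_named(coef(fit), c("a", "b", "c"))
  expect_equal(unname(predict(fit, k = 0.25)),
               fit$coefficients[["a"]] * 0.25^fit$coefficients[["b"]] +
                 fit$coefficients[["c"]], tolerance = 1e-9)
  expect_equal(predict(fit, k = 0.25, what = "optimal"),
               2.5 * predict(fit, k = 0.25), tolerance = 1e-12)
  expect_equal(length(residuals(fit)), sum(fit$shells$in_fit))
  expect_output(print(fit), "Critical-exposure fit")
  expect_output(summary(fit), "Per-shell")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # slopes of retained shells are negative by construction
  expect_true(all(fit$shells$slope[fit$shells$retained] < 0))
})
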