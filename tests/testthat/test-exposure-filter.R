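test_that("frame weights follow the attenuation model", {
  m <- dose_model()
  q <- frame_weights(c(0.05, 0.2, 0.4), c(0, 10, 50), m)
  expect_equal(q[, 1], rep(1, 3))                      # zero exposure
  expect_true(all(diff(t(q)[, 1]) < 0))                # decays with exposure
  expect_true(all(q[1, ] >= q[3, ]))                   # high k decays faster
  expect_equal(q[2, 3], exp(-50 / (2 * ne_oracle(0.2))), tolerance = 1e-12)
  # the DC term inherits the smallest nonzero shell's weight
  qdc <- frame_weights(c(0, 0.01, 0.1), 30, m)
  expect_equal(qdc[1, 1], qdc[2, 1])
})

test_that("filtered sum reduces to identities in degenerate cases", {
  img <- smooth_image(32)
  st1 <- movie_stack(array(img, dim = c(32, 32, 1)), 1)
  expect_equal(filtered_sum(st1, 37), img, ignore_attr = TRUE,
               tolerance = 1e-10)
  # equal exposures: plain sum / sqrt(n)
  frames <- array(0, dim = c(32, 32, 4))
  set.seed(8)
  for (i in 1:4) frames[, , i] <- img + matrix(rnorm(32^2, 0, 0.1), 32)
  st <- movie_stack(frames, 1)
  plain <- apply(frames, c(1, 2), sum)
  expect_equal(filtered_sum(st, rep(12, 4)), plain / 2, ignore_attr = TRUE,
               tolerance = 1e-9)
  expect_error(filtered_sum(st, rep(12, 3)), "length")
  expect_error(filtered_sum(st, c(-1, 1, 2, 3)), ">= 0")
})

test_that("variance-preserving normalization keeps unit noise variance", {
  # white-noise frames with a realistic exposure ladder: the output's
  # per-shell Fourier variance must stay that of one frame
  n <- 32; nf <- 8
  expos <- (1:nf) * 4
  si <- shell_index(c(n, n), 1)
  set.seed(13)
  acc <- 0
  draws <- 60
  for (r in seq_len(draws)) {
    st <- movie_stack(array(rnorm(n * n * nf), dim = c(n, n, nf)), 1)
    out <- filtered_sum(st, expos)
    acc <- acc + shell_average(Mod(stats::fft(out))^2, si)$mean / n^2
  }
  prof <- acc / draws
  expect_true(all(abs(prof[-1] - 1) < 0.2))
})

test_that("Wiener variant obeys its stated limits", {
  img <- smooth_image(32)
  set.seed(9)
  frames <- array(rep(img, 3), dim = c(32, 32, 3)) +
    array(rnorm(32^2 * 3, 0, 0.05), dim = c(32, 32, 3))
  st <- movie_stack(frames, 1)
  expos <- c(5, 10, 15)
  # SNR -> Inf: least-squares restoration sum(qF)/sum(q^2)
  winf <- wiener_filtered_sum(st, expos, snr = Inf)
  expect_equal(winf, filtered_sum(st, expos, variant = "nosqrt"),
               tolerance = 1e-10, ignore_attr = TRUE)
  # small SNR: output proportional to SNR * sum(qF) (scales linearly)
  w1 <- wiener_filtered_sum(st, expos, snr = 1e-6)
  w2 <- wiener_filtered_sum(st, expos, snr = 2e-6)
  expect_equal(w2, 2 * w1, tolerance = 1e-4, ignore_attr = TRUE)
  # zero SNR is the limit, not an error
  w0 <- wiener_filtered_sum(st, expos, snr = 0)
  expect_true(all(is.finite(w0)))
  expect_equal(max(abs(w0)), 0, tolerance = 1e-12)
})

test_that("two-frame Wiener combination matches hand arithmetic", {
  set.seed(21)
  f1 <- matrix(rnorm(16 * 16), 16)
  f2 <- matrix(rnorm(16 * 16), 16)
  st <- movie_stack(array(c(f1, f2), dim = c(16, 16, 2)), 1)
  expos <- c(8, 30)
  snr0 <- 0.7
  out <- wiener_filtered_sum(st, expos, snr = snr0)
  # direct per-voxel evaluation of the formula
  kk <- radial_freq_grid(c(16, 16), 1)
  kk[1, 1] <- min(kk[kk > 0])
  ne <- 0.245 * kk^(-1.665) + 2.81
  q1 <- exp(-expos[1] / (2 * ne)); q2 <- exp(-expos[2] / (2 * ne))
  num <- q1 * stats::fft(f1) + q2 * stats::fft(f2)
  den <- q1^2 + q2^2 + 1 / snr0
  ref <- Re(stats::fft(num / den, inverse = TRUE)) / 16^2
  expect_equal(out, ref, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("CTF-aware combination reduces and corrects as stated", {
  set.seed(10)
  img <- smooth_image(32)
  frames <- array(rep(img, 2), dim = c(32, 32, 2))
  st <- movie_stack(frames, 1)
  expos <- c(4, 20)
  ones <- list(matrix(1, 32, 32), matrix(1, 32, 32))
  expect_equal(reconstruction_weights(st, ones, expos, snr = 3),
               wiener_filtered_sum(st, expos, snr = 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  # single frame, real CTF, huge SNR: phase-corrected division by the CTF
  ctf <- matrix(0.5 + 0.4 * cos(outer((1:32) / 5, (1:32) / 7)), 32)
  st1 <- movie_stack(array(img, dim = c(32, 32, 1)), 1)
  got <- reconstruction_weights(st1, list(ctf), 0, snr = Inf)
  want <- Re(stats::fft(stats::fft(img) / ctf, inverse = TRUE)) / 32^2
  expect_equal(got, want, tolerance = 1e-8, ignore_attr = TRUE)
  # two frames with opposite-sign CTFs, hand-evaluated
  c1 <- matrix(0.8, 32, 32); c2 <- matrix(-0.6, 32, 32)
  f1 <- frames[, , 1]; f2 <- shift_image(img, 1, 0)
  st2 <- movie_stack(array(c(f1, f2), dim = c(32, 32, 2)), 1)
  kk <- radial_freq_grid(c(32, 32), 1); kk[1, 1] <- min(kk[kk > 0])
  ne <- 0.245 * kk^(-1.665) + 2.81
  q1 <- exp(-expos[1] / (2 * ne)); q2 <- exp(-expos[2] / (2 * ne))
  num <- 0.8 * q1 * stats::fft(f1) - 0.6 * q2 * stats::fft(f2)
  den <- (0.8 * q1)^2 + (0.6 * q2)^2 + 1 / 2
  want2 <- Re(stats::fft(num / den, inverse = TRUE)) / 32^2
  expect_equal(reconstruction_weights(st2, list(c1, c2), expos, snr = 2),
               want2, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(reconstruction_weights(st2, list(c1), expos), "per frame")
})

test_that("relative SNR of the plain sum follows the weight arithmetic", {
  expect_equal(relative_snr_of_plain_sum(rep(7, 5), 0.2), 1.0)
  # two frames, second fully decayed: the plain sum wastes half its frames
  expect_equal(relative_snr_of_plain_sum(c(1e-9, 1e9), 1 / 3), 0.5,
               tolerance = 1e-6)
  # monotone: longer tails of dead frames hurt more at high k
  r <- relative_snr_of_plain_sum((1:38) * 53 / 38, c(0.05, 0.2, 1 / 3))
  expect_true(all(diff(r) < 0))
})

test_that("filtering commutes with sub-pixel shifting", {
  img <- smooth_image(32)
  set.seed(12)
  frames <- array(rep(img, 3), dim = c(32, 32, 3)) +
    array(rnorm(32^2 * 3, 0, 0.05), dim = c(32, 32, 3))
  expos <- c(3, 9, 15)
  shift_stack <- function(fr) {
    out <- fr
    for (i in 1:3) out[, , i] <- shift_image(fr[, , i], 1.3, -0.6)
    out
  }
  a <- filtered_sum(movie_stack(shift_stack(frames), 1), expos)
  b <- shift_image(filtered_sum(movie_stack(frames, 1), expos), 1.3, -0.6)
  expect_equal(a, b, tolerance = 1e-9, ignore_attr = TRUE)
})
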