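# Shared fixtures for the test suite. Everything is generated in code.

# A smooth, strictly band-limited, periodic test image (spectral power
# negligible near Nyquist), for tests of sub-pixel shifting where
# Nyquist-frequency content is undefined. Built directly in Fourier space:
# Gaussian spectra with phase ramps placing two blobs off-center.
smooth_image <- function(n = 64) {
  f <- doseweight:::fft_freq(n)
  k2 <- outer(f^2, f^2, "+")
  blob <- function(cx, cy, s, amp) {
    amp * exp(-2 * (pi * s)^2 * k2) *
      exp(-2i * pi * outer(f * cx, f * cy, "+"))
  }
  spec <- blob(n / 3, n / 2, 4, 1) + blob(2 * n / 3, n / 3, 5.5, 0.7)
  Re(stats::fft(spec, inverse = TRUE))
}

# Published 300 kV calibration constants, used as ground truth throughout.
ref_constants <- c(a = 0.245, b = -1.665, c = 2.81)

# Independent evaluation of the critical-exposure law (plain arithmetic,
# no package code) for cross-checking.
ne_oracle <- function(k, scale = 1) {
  scale * (0.245 * k^(-1.665) + 2.81)
}

# Build an snr_series by hand from known SNR values (bypasses FSC
# computation; sigma_noise tiny so nothing is censored unless asked).
manual_snr_series <- function(freq, exposures, snr_matrix,
                              sigma = rep(1e-8, length(freq))) {
  fsc <- snr_matrix / (snr_matrix + 2)
  structure(
    list(freq = freq, exposures = exposures, fsc = fsc, snr = snr_matrix,
         sigma_noise = sigma, n_voxels = rep(1000L, length(freq))),
    class = "snr_series"
  )
}
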