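# The optimal exposure filter: per-frame, per-frequency attenuation weights
# q_i(k) and the SNR-maximizing weighted frame sums.

# Resolve an exposures argument: numeric vector or exposure_schedule.
.resolve_exposures <- function(exposures, n_frames) {
  if (inherits(exposures, "exposure_schedule")) {
    if (exposures$n_frames != n_frames) {
      stop("exposure schedule length does not match frame count")
    }
    exposures <- accumulated_exposure(exposures, seq_len(n_frames))
  }
  stopifnot(is.numeric(exposures), length(exposures) == n_frames)
  if (any(exposures < 0)) stop("accumulated exposures must be >= 0")
  exposures
}

# Critical-exposure grid with the DC term mapped to the smallest nonzero
# frequency present, so the DC component is never up-weighted relative to
# its neighbors.
.ne_of_freqs <- function(k, params) {
  k <- as.numeric(k)
  if (any(k == 0) && any(k > 0)) k[k == 0] <- min(k[k > 0])
  critical_exposure(k, params)
}

#' Per-frame exposure-filter weights
#'
#' Evaluates the amplitude attenuation `q_i(k) = exp(-N_i / (2 Ne(k)))` for
#' each frame `i` at each supplied frequency. The DC term (`k = 0`) is given
#' the weight of the smallest nonzero frequency supplied.
#'
#' @param k Spatial frequencies in 1/Angstrom (vector, or array for a full
#'   Fourier grid).
#' @param exposures Accumulated exposure per frame (electrons/A^2), or an
#'   [exposure_schedule()].
#' @param params A [dose_model()].
#' @return Matrix of weights with `length(k)` rows and one column per frame
#'   (frequencies in supply order).
#' @export
frame_weights <- function(k, exposures, params = dose_model()) {
  if (inherits(exposures, "exposure_schedule")) {
    exposures <- accumulated_exposure(exposures, seq_len(exposures$n_frames))
  }
  if (any(exposures < 0)) stop("accumulated exposures must be >= 0")
  ne <- .ne_of_freqs(k, params)
  outer(-1 / (2 * ne), exposures) |> exp()
}

# Shared engine for the weighted sums. Returns real image with pixel_size.
.weighted_sum_engine <- function(stack, exposures, params, denominator_fn,
                                 ctfs = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  n <- stack$n_frames
  exposures <- .resolve_exposures(exposures, n)
  d <- dim(stack$frames)[1:2]
  kk <- radial_freq_grid(d, stack$pixel_size)
  ne <- .ne_of_freqs(kk, params)
  dim(ne) <- d
  num <- matrix(0 + 0i, d[1], d[2])
  den <- matrix(0, d[1], d[2])
  for (i in seq_len(n)) {
    q <- exp(-exposures[i] / (2 * ne))
    Fi <- stats::fft(get_frame(stack, i))
    if (is.null(ctfs)) {
      num <- num + q * Fi
      den <- den + q^2
    } else {
      num <- num + Conj(ctfs[[i]]) * q * Fi
      den <- den + (Mod(ctfs[[i]]) * q)^2
    }
  }
  w <- denominator_fn(den, kk)
  out <- Re(ifft(num / w))
  attr(out, "pixel_size") <- stack$pixel_size
  out
}

#' Exposure-filtered (dose-weighted) frame sum
#'
#' The matched-filter sum that maximizes spectral SNR in every resolution
#' shell under the exponential damage model:
#' \deqn{\tilde F(k) = \sum_i q_i(k) F_i(k) / \sqrt{\sum_i q_i(k)^2}.}
#' The square-root normalization preserves the noise variance of a single
#' frame at every frequency (independent unit-variance frame noise stays
#' unit variance in the output), so features are re-weighted, not inflated.
#' With all exposures equal the result is the plain sum divided by
#' `sqrt(n)`; a single frame passes through unchanged. The non-root variant
#' (`variant = "nosqrt"`, denominator `sum(q^2)`) is provided for
#' comparison.
#'
#' @param stack A [movie_stack()] of aligned frames.
#' @param exposures Accumulated exposure per frame (electrons/A^2), or an
#'   [exposure_schedule()]. Pre-summed inputs (e.g. 3-frame sub-sums)
#'   should use the sub-sum's mean accumulated exposure.
#' @param params A [dose_model()].
#' @param variant `"sqrt"` (default, variance-preserving) or `"nosqrt"`.
#' @return Real matrix (the filtered sum) with attribute `pixel_size`.
#' @export
filtered_sum <- function(stack, exposures, params = dose_model(),
                         variant = c("sqrt", "nosqrt")) {
  variant <- match.arg(variant)
  fn <- if (variant == "sqrt") function(den, kk) sqrt(den) else function(den, kk) den
  .weighted_sum_engine(stack, exposures, params, fn)
}

# Build an SNR grid from a scalar, per-shell vector, or function of k.
.snr_grid <- function(snr, kk, dims, pixel_size) {
  if (is.function(snr)) {
    g <- snr(kk)
  } else if (length(snr) == 1) {
    g <- rep(as.numeric(snr), length(kk))
  } else {
    si <- shell_index(dims, pixel_size)
    idx <- si$shell + 1L
    idx[is.na(idx)] <- length(si$freq)  # beyond Nyquist: use last shell
    if (length(snr) != length(si$freq)) {
      stop(sprintf("per-shell SNR must have %d values (shells 0..%d)",
                   length(si$freq), length(si$freq) - 1))
    }
    g <- as.numeric(snr)[idx]
  }
  if (any(g < 0, na.rm = TRUE)) stop("SNR values must be >= 0")
  dim(g) <- dims
  g
}

#' Wiener-style exposure-filtered sum
#'
#' The restoring variant of the exposure filter:
#' \deqn{F^W(k) = \sum_i q_i(k) F_i(k) / (\sum_i q_i(k)^2 + 1/\mathrm{SNR}(k)),}
#' where SNR(k) is the unattenuated per-shell SNR of a single frame (PSSNR).
#' As SNR grows the filter approaches the least-squares restoration
#' `sum(q F) / sum(q^2)`; as SNR tends to zero it approaches (per shell) the
#' matched filter `SNR(k) * sum(q F)` — zero SNR is handled as that limit,
#' never as a division by zero.
#'
#' @inheritParams filtered_sum
#' @param snr Unattenuated single-frame SNR: scalar, per-shell vector
#'   (shells 0..n/2), or function of frequency (1/Angstrom).
#' @return Real matrix with attribute `pixel_size`.
#' @export
wiener_filtered_sum <- function(stack, exposures, params = dose_model(),
                                snr = Inf) {
  d <- dim(stack$frames)[1:2]
  ps <- stack$pixel_size
  fn <- function(den, kk) den + 1 / .snr_grid(snr, kk, d, ps)
  .weighted_sum_engine(stack, exposures, params, fn)
}

#' Damage- and CTF-aware weighted Fourier combination
#'
#' The general per-voxel weighted combine for reconstruction from
#' individually damaged, CTF-modulated frames:
#' \deqn{F(k) = \sum_i CTF_i^*(k) q_i(k) F_i(k) /
#'   (\sum_i (|CTF_i(k)| q_i(k))^2 + 1/\mathrm{SNR}(k)).}
#' With CTF identically 1 this reduces exactly to
#' [wiener_filtered_sum()]. This is a generic weighted combine, not a
#' reconstruction engine; CTF values are supplied externally on the data
#' grid.
#'
#' @inheritParams wiener_filtered_sum
#' @param ctfs List of CTF value matrices (real or complex), one per frame,
#'   on the same Fourier grid as the frames.
#' @return Real matrix with attribute `pixel_size`.
#' @export
reconstruction_weights <- function(stack, ctfs, exposures,
                                   params = dose_model(), snr = Inf) {
  stopifnot(inherits(stack, "movie_stack"))
  if (length(ctfs) != stack$n_frames) {
    stop("need one CTF grid per frame")
  }
  d <- dim(stack$frames)[1:2]
  for (ct in ctfs) {
    if (!identical(dim(ct), d)) stop("CTF grid dimensions must match frames")
  }
  ps <- stack$pixel_size
  fn <- function(den, kk) den + 1 / .snr_grid(snr, kk, d, ps)
  .weighted_sum_engine(stack, exposures, params, fn, ctfs = ctfs)
}

#' Model-predicted relative SNR of the unweighted frame sum
#'
#' The SNR of the plain (unweighted) n-frame sum relative to the
#' matched-filter sum at frequency `k`, under the exponential decay model:
#' `(sum q_i)^2 / (n * sum q_i^2)`. Equals 1 when all weights are equal
#' (Cauchy-Schwarz equality) and drops well below 1 at high resolution for
#' long exposures, where late frames contribute mostly noise.
#'
#' @param exposures Accumulated exposure per frame, or an
#'   [exposure_schedule()].
#' @param k Spatial frequency in 1/Angstrom (vectorized).
#' @param params A [dose_model()].
#' @return Ratio(s) in (0, 1].
#' @export
relative_snr_of_plain_sum <- function(exposures, k, params = dose_model()) {
  if (inherits(exposures, "exposure_schedule")) {
    exposures <- accumulated_exposure(exposures, seq_len(exposures$n_frames))
  }
  stopifnot(length(exposures) >= 1)
  q <- frame_weights(k, exposures, params)   # |k| x n
  n <- length(exposures)
  as.numeric(rowSums(q)^2 / (n * rowSums(q^2)))
}
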