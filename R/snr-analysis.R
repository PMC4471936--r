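# Fourier shell correlation, FSC <-> SNR conversion, and resolution
# estimation. The critical-exposure estimation built on these lives in
# critexp-fit.R.

#' Fourier shell correlation between two maps
#'
#' Per radial shell,
#' \deqn{FSC(k) = \mathrm{Re}\sum A \bar B / \sqrt{\sum |A|^2 \sum |B|^2}}
#' over the shell's Fourier voxels of the (optionally soft-masked)
#' transforms. Works on 2D images and 3D maps of equal (square/cubic) size.
#'
#' @param map_a,map_b Real arrays of identical dimension.
#' @param pixel_size Pixel size in Angstrom.
#' @param mask Optional real-valued soft mask with values between 0 and 1,
#'   applied to both maps before transforming.
#' @param exposure Optional accumulated-exposure label (electrons/A^2)
#'   attached to the curve.
#' @return An `fsc_curve`: data frame with columns `freq` (1/Angstrom),
#'   `fsc`, `n_voxels` (Fourier voxels per shell), and attributes
#'   `pixel_size` and `exposure`.
#' @export
compute_fsc <- function(map_a, map_b, pixel_size = 1, mask = NULL,
                        exposure = NA_real_) {
  if (!identical(dim(map_a), dim(map_b))) stop("grid mismatch between maps")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(map_a))) stop("mask grid mismatch")
    if (any(mask < 0) || any(mask > 1)) stop("mask values must lie in [0, 1]")
    map_a <- map_a * mask
    map_b <- map_b * mask
  }
  A <- stats::fft(map_a)
  B <- stats::fft(map_b)
  si <- shell_index(dim(map_a), pixel_size)
  ok <- !is.na(si$shell)
  g <- si$shell[ok] + 1L
  nb <- length(si$freq)
  num <- rowsum_by(Re(A[ok] * Conj(B[ok])), g, nb)
  pa <- rowsum_by(Mod(A[ok])^2, g, nb)
  pb <- rowsum_by(Mod(B[ok])^2, g, nb)
  den <- sqrt(pa * pb)
  fsc <- ifelse(den > 0, num / den, 0)
  out <- data.frame(freq = si$freq, fsc = fsc, n_voxels = si$counts)
  attr(out, "pixel_size") <- pixel_size
  attr(out, "exposure") <- exposure
  class(out) <- c("fsc_curve", "data.frame")
  out
}

#' Convert FSC to spectral SNR, and back
#'
#' For half-map FSC values, `SNR = 2 FSC / (1 - FSC)` (the SNR of the
#' combined data); the inverse is `FSC = SNR / (SNR + 2)`. FSC values at or
#' above 1 map to `Inf` with a warning; values at or below -1 are a domain
#' error.
#'
#' @param fsc FSC value(s) in (-1, 1].
#' @return `fsc_to_snr`: SNR value(s) >= 0 for FSC >= 0.
#' @export
fsc_to_snr <- function(fsc) {
  fsc <- as.numeric(fsc)
  if (any(fsc <= -1, na.rm = TRUE)) stop("FSC <= -1 is outside the domain")
  if (any(fsc >= 1, na.rm = TRUE)) {
    warning("FSC >= 1: returning infinite SNR")
  }
  ifelse(fsc >= 1, Inf, 2 * fsc / (1 - fsc))
}

#' @rdname fsc_to_snr
#' @param snr SNR value(s) >= 0.
#' @return `snr_to_fsc`: FSC value(s) in [0, 1).
#' @export
snr_to_fsc <- function(snr) {
  snr <- as.numeric(snr)
  if (any(snr < 0, na.rm = TRUE)) stop("SNR must be >= 0")
  ifelse(is.infinite(snr), 1, snr / (snr + 2))
}

#' Resolution at an FSC threshold
#'
#' Frequency of the first crossing of the FSC curve below a threshold
#' (0.143 for half-map curves, 0.5 for map-vs-model), linearly interpolated
#' between shells, reported as a resolution in Angstrom. If the curve never
#' drops below the threshold, the Nyquist resolution is returned with
#' attribute `crossed = FALSE` and a warning.
#'
#' @param fsc An `fsc_curve` (or data frame with `freq` and `fsc` columns).
#' @param threshold FSC threshold in (0, 1); default 0.143.
#' @return Resolution in Angstrom with attribute `crossed`.
#' @export
resolution_at_threshold <- function(fsc, threshold = 0.143) {
  stopifnot(threshold > 0, threshold < 1)
  f <- fsc$freq
  v <- fsc$fsc
  use <- f > 0
  f <- f[use]; v <- v[use]
  below <- which(v < threshold)
  if (length(below) == 0) {
    warning("FSC never drops below threshold; reporting Nyquist resolution")
    return(structure(1 / f[length(f)], crossed = FALSE))
  }
  i <- below[1]
  if (i == 1) {
    return(structure(1 / f[1], crossed = TRUE))
  }
  fr <- f[i - 1] + (threshold - v[i - 1]) * (f[i] - f[i - 1]) / (v[i] - v[i - 1])
  structure(1 / fr, crossed = TRUE)
}

#' Exposure-resolved SNR series from FSC curves
#'
#' Collects FSC curves measured at increasing accumulated exposures into a
#' shell-by-exposure SNR matrix, with a per-shell pure-noise floor used for
#' censoring. The standard deviation of a pure-noise FSC in a shell of `n`
#' Fourier voxels is taken as `1/sqrt(n/2)` (the factor 2 accounts for
#' Hermitian symmetry; divide `n` additionally by the symmetry order if the
#' maps were symmetrized).
#'
#' @param fsc_list List of `fsc_curve` objects on a common shell grid, each
#'   carrying its accumulated exposure (attribute `exposure`, or supply
#'   `exposures`).
#' @param exposures Optional numeric vector of accumulated exposures
#'   overriding the curves' labels.
#' @param symmetry Symmetry order by which the independent voxel count is
#'   reduced (default 1).
#' @return An `snr_series`: list with `freq`, `exposures` (sorted
#'   increasing), `fsc` and `snr` matrices (shell x exposure), `sigma_noise`
#'   (per-shell noise-floor FSC s.d.), `n_voxels`.
#' @export
snr_series <- function(fsc_list, exposures = NULL, symmetry = 1) {
  stopifnot(length(fsc_list) >= 1, symmetry >= 1)
  if (is.null(exposures)) {
    exposures <- vapply(fsc_list, function(f) as.numeric(attr(f, "exposure")),
                        numeric(1))
  }
  if (any(!is.finite(exposures))) {
    stop("every FSC curve needs an accumulated-exposure label")
  }
  freq <- fsc_list[[1]]$freq
  for (f in fsc_list) {
    if (!isTRUE(all.equal(f$freq, freq))) stop("FSC curves on different shell grids")
  }
  o <- order(exposures)
  fsc_list <- fsc_list[o]
  exposures <- exposures[o]
  fmat <- vapply(fsc_list, function(f) f$fsc, numeric(length(freq)))
  nvox <- fsc_list[[1]]$n_voxels
  smat <- apply(fmat, 2, function(col) {
    ifelse(col >= 1, Inf, pmax(2 * col / (1 - col), 0))
  })
  structure(
    list(freq = freq, exposures = exposures, fsc = fmat, snr = smat,
         sigma_noise = 1 / sqrt(pmax(nvox / symmetry, 1) / 2),
         n_voxels = nvox),
    class = "snr_series"
  )
}

#' Write / read an FSC curve as CSV
#'
#' Columns `shell_frequency_invA, fsc, n_voxels`; the accumulated exposure
#' and pixel size are recorded in commented header lines.
#'
#' @param fsc An `fsc_curve`.
#' @param path File path.
#' @return `write_fsc` returns `path` invisibly; `read_fsc` an `fsc_curve`.
#' @export
write_fsc <- function(fsc, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# exposure_e_per_A2: %.10g",
                     as.numeric(attr(fsc, "exposure"))), con)
  writeLines(sprintf("# pixel_size_A: %.10g",
                     as.numeric(attr(fsc, "pixel_size"))), con)
  writeLines("shell_frequency_invA,fsc,n_voxels", con)
  writeLines(sprintf("%.10g,%.10g,%d", fsc$freq, fsc$fsc, fsc$n_voxels), con)
  invisible(path)
}

#' @rdname write_fsc
#' @export
read_fsc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  getnum <- function(key, default = NA_real_) {
    l <- grep(key, hdr, value = TRUE)
    if (length(l)) as.numeric(sub(paste0(".*", key, ":\\s*"), "", l[1]))
    else default
  }
  dat <- utils::read.csv(text = lines[!grepl("^#", lines)])
  out <- data.frame(freq = dat$shell_frequency_invA, fsc = dat$fsc,
                    n_voxels = dat$n_voxels)
  attr(out, "exposure") <- getnum("exposure_e_per_A2")
  attr(out, "pixel_size") <- getnum("pixel_size_A", 1)
  class(out) <- c("fsc_curve", "data.frame")
  out
}
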