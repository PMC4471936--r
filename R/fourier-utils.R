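# Fourier-grid helpers shared by the alignment, filtering and FSC code.
# All grids use the unshifted FFT layout (DC at element [1,1]).

#' Discrete Fourier transform sample frequencies
#'
#' Frequencies (cycles per sample) for an `n`-point DFT in the unshifted
#' layout: `0, 1/n, ..., -2/n, -1/n`.
#'
#' @param n Number of samples.
#' @return Numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n) {
  (((0:(n - 1)) + n %/% 2) %% n - n %/% 2) / n
}

# Inverse FFT returning a complex array, normalized.
ifft <- function(x) {
  stats::fft(x, inverse = TRUE) / length(x)
}

#' Radial spatial-frequency grid
#'
#' Magnitude of the spatial frequency (1/Angstrom) at every voxel of a 2D or
#' 3D Fourier grid in the unshifted layout.
#'
#' @param dims Integer vector of grid dimensions (length 2 or 3).
#' @param pixel_size Sampling interval in Angstrom per pixel.
#' @return Array of dimension `dims` with |k| in 1/Angstrom.
#' @export
radial_freq_grid <- function(dims, pixel_size = 1) {
  stopifnot(length(dims) %in% c(2L, 3L), all(dims >= 1), pixel_size > 0)
  f2 <- lapply(dims, function(n) fft_freq(n)^2)
  if (length(dims) == 2L) {
    r2 <- outer(f2[[1]], f2[[2]], "+")
  } else {
    r2 <- outer(outer(f2[[1]], f2[[2]], "+"), f2[[3]], "+")
  }
  sqrt(r2) / pixel_size
}

#' Sub-pixel image shift by Fourier phase ramp
#'
#' Shifts the image content by (`dx`, `dy`) pixels: the output at position
#' `x` equals the input at `x - dx` (periodic boundaries). Integer shifts are
#' exactly circular rolls; fractional shifts interpolate via the phase ramp.
#'
#' @param image Real 2D matrix.
#' @param dx,dy Shift in pixels along the first and second array dimension.
#' @return Shifted real matrix of the same dimension.
#' @export
shift_image <- function(image, dx, dy) {
  stopifnot(is.matrix(image), is.finite(dx), is.finite(dy))
  if (dx == 0 && dy == 0) return(image)
  n1 <- nrow(image); n2 <- ncol(image)
  ramp <- exp(-2i * pi * outer(fft_freq(n1) * dx, fft_freq(n2) * dy, "+"))
  Re(ifft(stats::fft(image) * ramp))
}

# Phase ramp for a shift, applied directly to a Fourier-domain frame.
shift_ramp <- function(n1, n2, dx, dy) {
  exp(-2i * pi * outer(fft_freq(n1) * dx, fft_freq(n2) * dy, "+"))
}

#' Fourier cropping (exact band-limited downsampling)
#'
#' Downsamples an image by truncating its Fourier transform at a lower
#' Nyquist frequency. Content below the new Nyquist is preserved exactly
#' (up to normalization); the real-space mean is preserved.
#'
#' @param image Real 2D matrix.
#' @param factor Integer downsampling factor (>= 1); all image dimensions
#'   must be divisible by it.
#' @return Downsampled matrix of dimension `dim(image) / factor`.
#' @export
fourier_crop <- function(image, factor) {
  stopifnot(is.matrix(image))
  factor <- as.integer(factor)
  if (factor < 1) stop("downsampling factor must be >= 1")
  if (factor == 1) return(image)
  d <- dim(image)
  if (any(d %% factor != 0)) {
    stop(sprintf(
      "image dimensions %s not divisible by factor %d (no silent padding)",
      paste(d, collapse = "x"), factor
    ))
  }
  m <- d %/% factor
  keep <- function(n, m) c(seq_len(m - m %/% 2), if (m %/% 2 > 0) (n - m %/% 2 + 1):n)
  X <- stats::fft(image)
  Y <- X[keep(d[1], m[1]), keep(d[2], m[2]), drop = FALSE] / factor^2
  Re(ifft(Y))
}

#' Radial shell index for a square Fourier grid
#'
#' Assigns every Fourier voxel up to Nyquist to an integer radial shell by
#' rounding its radius in grid units. Shell `s` (0-based) has center
#' frequency `s / (n * pixel_size)` in 1/Angstrom; voxels beyond Nyquist
#' (grid corners) are unassigned.
#'
#' @param dims Dimensions of the (square/cubic) grid, length 2 or 3.
#' @param pixel_size Pixel size in Angstrom.
#' @return An object of class `shell_index` with elements `shell` (integer
#'   array, 0-based shell per voxel, `NA` beyond Nyquist), `freq` (shell
#'   center frequencies, 1/Angstrom), `counts` (voxels per shell), `dims`,
#'   `pixel_size`.
#' @export
shell_index <- function(dims, pixel_size = 1) {
  stopifnot(length(dims) %in% c(2L, 3L), pixel_size > 0)
  n <- dims[1]
  if (!all(dims == n)) stop("shell_index requires a square (or cubic) grid")
  g2 <- lapply(dims, function(nn) (fft_freq(nn) * nn)^2)
  if (length(dims) == 2L) {
    r <- sqrt(outer(g2[[1]], g2[[2]], "+"))
  } else {
    r <- sqrt(outer(outer(g2[[1]], g2[[2]], "+"), g2[[3]], "+"))
  }
  shell <- as.integer(round(r))
  shell[r > n / 2] <- NA_integer_
  dim(shell) <- dims
  smax <- max(shell, na.rm = TRUE)
  counts <- tabulate(shell + 1L, nbins = smax + 1L)
  structure(
    list(
      shell = shell,
      freq = (0:smax) / (n * pixel_size),
      counts = counts,
      dims = dims,
      pixel_size = pixel_size
    ),
    class = "shell_index"
  )
}

#' Per-shell average of a voxelwise quantity
#'
#' Averages a real- or complex-valued quantity defined on a Fourier grid over
#' each radial shell of a [shell_index()].
#'
#' @param x Numeric or complex array with the same dimensions as `shells`.
#' @param shells A `shell_index` object.
#' @return Data frame with columns `freq`, `mean`, `n_voxels`.
#' @export
shell_average <- function(x, shells) {
  stopifnot(inherits(shells, "shell_index"))
  if (!identical(dim(x), as.integer(shells$dims)) &&
      !identical(dim(x), shells$dims)) {
    stop("grid mismatch between data and shell index")
  }
  ok <- !is.na(shells$shell)
  g <- shells$shell[ok] + 1L
  v <- x[ok]
  nb <- length(shells$freq)
  if (is.complex(v)) {
    s <- rowsum_by(Re(v), g, nb) + 1i * rowsum_by(Im(v), g, nb)
  } else {
    s <- rowsum_by(v, g, nb)
  }
  data.frame(
    freq = shells$freq,
    mean = s / shells$counts,
    n_voxels = shells$counts
  )
}

# Sum v grouped by 1-based group id g into nb bins.
rowsum_by <- function(v, g, nb) {
  out <- numeric(nb)
  agg <- rowsum(v, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}
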