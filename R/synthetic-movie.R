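# Synthetic movies and half-map series with known ground truth: rigid drift
# that is fast early and plateaus late, per-shell exponential amplitude
# decay with exposure, and additive Gaussian frame noise of known variance.
# These are the package's validation fixtures; every generator is
# deterministic under a fixed seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(code)
}

#' Deterministic band-rich reference image
#'
#' A mixture of Gaussian blobs (widths from sub-pixel to tens of pixels) and
#' a few concentric rings, centered in the box on a zero background. Sharp
#' blobs guarantee spectral power in every shell up to Nyquist; by default
#' the radial power spectrum is then flattened (whitened) so every shell
#' carries comparable signal and no frequency band of a simulated
#' measurement is starved of signal by the test object itself.
#'
#' @param box Box size in pixels (square image).
#' @param n_blobs Number of Gaussian blobs (0 gives a zero image).
#' @param n_rings Number of ring features.
#' @param whiten Flatten the radial power spectrum and normalize to unit
#'   standard deviation (default `TRUE`).
#' @param seed Random seed; the output is a deterministic function of the
#'   configuration.
#' @return Real `box` x `box` matrix.
#' @export
make_reference <- function(box = 128, n_blobs = 60, n_rings = 3,
                           whiten = TRUE, seed = 1) {
  stopifnot(box >= 8)
  with_seed(seed, {
    img <- matrix(0, box, box)
    xs <- matrix(rep(seq_len(box), box), box, box)
    ys <- t(xs)
    if (n_blobs > 0) {
      cx <- stats::runif(n_blobs, box * 0.15, box * 0.85)
      cy <- stats::runif(n_blobs, box * 0.15, box * 0.85)
      # log-uniform widths: plenty of sharp (high-frequency) features
      sg <- exp(stats::runif(n_blobs, log(0.6), log(box / 16)))
      am <- stats::runif(n_blobs, 0.5, 2)
      for (i in seq_len(n_blobs)) {
        img <- img + am[i] *
          exp(-((xs - cx[i])^2 + (ys - cy[i])^2) / (2 * sg[i]^2))
      }
      for (i in seq_len(n_rings)) {
        r <- sqrt((xs - box / 2)^2 + (ys - box / 2)^2)
        lam <- stats::runif(1, 4, box / 6)
        img <- img + 0.4 * cos(2 * pi * r / lam) *
          exp(-(r / (box * 0.35))^2)
      }
      if (whiten) img <- .whiten_spectrum(img)
    }
    img
  })
}

# Divide each Fourier shell by its root-mean-square amplitude, giving a
# flat radial power spectrum, and rescale to unit pixel variance.
.whiten_spectrum <- function(img) {
  si <- shell_index(dim(img), 1)
  F <- stats::fft(img)
  amp <- sqrt(shell_average(Mod(F)^2, si)$mean)
  if (any(amp == 0)) return(img)
  idx <- si$shell + 1L
  idx[is.na(idx)] <- length(amp)
  W <- 1 / amp[idx]
  dim(W) <- dim(img)
  out <- Re(ifft(F * W))
  out / stats::sd(out)
}

# Ne on a Fourier grid, from a dose model or an Ne(k) lookup table
# (data.frame freq/ne, interpolated; constant extrapolation at the ends).
.ne_grid <- function(kk, params = NULL, ne_table = NULL) {
  if (!is.null(ne_table)) {
    stats::approx(ne_table$freq, ne_table$ne, xout = pmax(kk, min(ne_table$freq)),
                  rule = 2)$y
  } else {
    k <- as.numeric(kk)
    if (any(k == 0) && any(k > 0)) k[k == 0] <- min(k[k > 0])
    critical_exposure(k, params)
  }
}

#' Ground-truth drift trajectory generator
#'
#' Per-frame step sizes decay from `initial_rate` to `plateau_rate`
#' (Angstrom/frame) with an exponential time constant of `decay_frames`
#' frames; the drift direction performs a slow random walk so the path is
#' smooth. Positions are returned as registration shifts (the shift to
#' apply to each frame), centered to zero mean.
#'
#' @param n_frames Number of frames.
#' @param initial_rate,plateau_rate Drift speed at the start / in the
#'   plateau, Angstrom per frame.
#' @param decay_frames Exponential time constant of the slowdown, frames.
#' @param pixel_size Pixel size in Angstrom.
#' @param seed Random seed.
#' @return A `shift_trajectory`.
#' @export
drift_trajectory <- function(n_frames, initial_rate = 2, plateau_rate = 0.2,
                             decay_frames = 16, pixel_size = 1, seed = 1) {
  stopifnot(n_frames >= 1, initial_rate >= 0, plateau_rate >= 0,
            decay_frames > 0)
  with_seed(seed, {
    step <- plateau_rate +
      (initial_rate - plateau_rate) * exp(-(seq_len(n_frames) - 1) / decay_frames)
    theta <- cumsum(c(stats::runif(1, 0, 2 * pi),
                      stats::rnorm(n_frames - 1, 0, 0.15)))
    px <- cumsum(step * cos(theta))   # specimen position, Angstrom
    py <- cumsum(step * sin(theta))
    # registration shift = -position; gauge: zero mean
    sx <- -(px - mean(px)) / pixel_size
    sy <- -(py - mean(py)) / pixel_size
    shift_trajectory(sx, sy, pixel_size, smoothed = FALSE)
  })
}

#' Simulate a movie with known motion, damage and noise
#'
#' Each frame is the reference, attenuated per Fourier shell by
#' `exp(-N_i / (2 Ne(k)))` at the frame's accumulated exposure, displaced
#' along the ground-truth drift trajectory (sub-pixel, Fourier phase ramp),
#' plus i.i.d. Gaussian pixel noise of the configured standard deviation.
#'
#' @param reference Real square matrix (see [make_reference()]).
#' @param n_frames Number of frames.
#' @param exposure_per_frame Exposure per frame, electrons/A^2.
#' @param pre_exposure Exposure before frame 1, electrons/A^2.
#' @param pixel_size Pixel size in Angstrom.
#' @param params Ground-truth [dose_model()]; ignored when `ne_table` is
#'   given.
#' @param ne_table Optional data frame (`freq`, `ne`) giving an arbitrary
#'   ground-truth critical-exposure curve.
#' @param trajectory Optional `shift_trajectory` to use as ground truth;
#'   default generated by [drift_trajectory()] with the remaining
#'   arguments.
#' @param initial_rate,plateau_rate,decay_frames Drift parameters, see
#'   [drift_trajectory()]. Defaults emulate typical beam-induced motion:
#'   fast early drift slowing to a 0.2 Angstrom/frame plateau.
#' @param noise_sd Standard deviation of the additive Gaussian noise per
#'   frame (image units).
#' @param seed Random seed; fixes the output completely.
#' @return List with `stack` (a [movie_stack()]), `trajectory` (ground
#'   truth registration shifts), `schedule` (the [exposure_schedule()]),
#'   `exposures` (accumulated, end-of-frame), `params`, `ne_table`,
#'   `noise_sd`, `seed`.
#' @export
simulate_movie <- function(reference, n_frames = 130,
                           exposure_per_frame = 0.769, pre_exposure = 0,
                           pixel_size = 1, params = dose_model(),
                           ne_table = NULL, trajectory = NULL,
                           initial_rate = 2, plateau_rate = 0.2,
                           decay_frames = 16, noise_sd = 1, seed = 1) {
  stopifnot(is.matrix(reference), n_frames >= 1, exposure_per_frame > 0,
            noise_sd >= 0)
  d <- dim(reference)
  if (is.null(trajectory)) {
    trajectory <- drift_trajectory(n_frames, initial_rate, plateau_rate,
                                   decay_frames, pixel_size,
                                   seed = seed + 1L)
  }
  stopifnot(nrow(trajectory) == n_frames)
  schedule <- exposure_schedule(exposure_per_frame, n_frames, pre_exposure)
  exposures <- accumulated_exposure(schedule, seq_len(n_frames))
  kk <- radial_freq_grid(d, pixel_size)
  ne <- .ne_grid(kk, params, ne_table)
  dim(ne) <- d
  Fref <- stats::fft(reference)
  frames <- array(0, dim = c(d, n_frames))
  with_seed(seed, {
    for (i in seq_len(n_frames)) {
      q <- exp(-exposures[i] / (2 * ne))
      # the frame shows the object displaced by minus the registration shift
      ramp <- shift_ramp(d[1], d[2], -trajectory$x_px[i], -trajectory$y_px[i])
      frames[, , i] <- Re(ifft(Fref * q * ramp)) +
        matrix(stats::rnorm(prod(d), 0, noise_sd), d[1], d[2])
    }
  })
  list(stack = movie_stack(frames, pixel_size), trajectory = trajectory,
       schedule = schedule, exposures = exposures, params = params,
       ne_table = ne_table, noise_sd = noise_sd, seed = seed)
}

#' Simulate an exposure-resolved half-map series
#'
#' For each requested accumulated exposure, two independently noised copies
#' of the damage-attenuated reference are produced (the analogue of
#' half-set reconstructions at increasing exposure). Signal amplitudes
#' decay as `exp(-N / (2 Ne(k)))`, so the per-shell SNR decays as
#' `exp(-N / Ne(k))` and the expected half-map FSC follows
#' `FSC = SNR_half / (SNR_half + 1)`.
#'
#' @param reference Real square matrix (or cubic 3D array).
#' @param exposures Accumulated exposures (electrons/A^2) of the series,
#'   strictly increasing.
#' @param pixel_size Pixel size in Angstrom.
#' @param params Ground-truth [dose_model()]; ignored when `ne_table`
#'   given.
#' @param ne_table Optional ground-truth Ne(k) table (`freq`, `ne`).
#' @param noise_sd Noise standard deviation per half map.
#' @param seed Random seed.
#' @return A `half_map_series`: list with elements `maps` (list of
#'   `list(map_a, map_b, exposure)`), `pixel_size`, `params`, `ne_table`,
#'   `noise_sd`, `seed`.
#' @export
simulate_half_map_series <- function(reference, exposures, pixel_size = 1,
                                     params = dose_model(), ne_table = NULL,
                                     noise_sd = 1, seed = 1) {
  stopifnot(is.array(reference), length(dim(reference)) %in% c(2L, 3L),
            length(exposures) >= 1,
            all(diff(exposures) > 0), all(exposures >= 0), noise_sd >= 0)
  d <- dim(reference)
  kk <- radial_freq_grid(d, pixel_size)
  ne <- .ne_grid(kk, params, ne_table)
  dim(ne) <- d
  Fref <- stats::fft(reference)
  maps <- with_seed(seed, {
    lapply(exposures, function(N) {
      sig <- Re(ifft(Fref * exp(-N / (2 * ne))))
      noise <- function() array(stats::rnorm(prod(d), 0, noise_sd), dim = d)
      list(map_a = sig + noise(), map_b = sig + noise(), exposure = N)
    })
  })
  structure(
    list(maps = maps, pixel_size = pixel_size, params = params,
         ne_table = ne_table, noise_sd = noise_sd, seed = seed),
    class = "half_map_series"
  )
}

#' FSC curves of a simulated half-map series
#'
#' @param series A `half_map_series`.
#' @param mask Optional soft mask passed to [compute_fsc()].
#' @return List of `fsc_curve` objects labelled with their exposures,
#'   ready for [fit_critical_exposure()].
#' @export
half_map_fsc <- function(series, mask = NULL) {
  stopifnot(inherits(series, "half_map_series"))
  lapply(series$maps, function(m) {
    compute_fsc(m$map_a, m$map_b, pixel_size = series$pixel_size,
                mask = mask, exposure = m$exposure)
  })
}

#' Add independent background images to particle images
#'
#' Pixel-wise sum of each particle image with an independent background
#' image (e.g. empty-ice areas). When the background carries noise of the
#' same variance as the particle images' own noise, the spectral SNR is
#' halved in expectation — the standard construction for emulating a
#' particle of lower molecular mass.
#'
#' @param images List of real matrices (or a 3D array) of particle images.
#' @param backgrounds Matching list/array of background images.
#' @return Degraded images in the same shape as `images`.
#' @export
add_background_noise <- function(images, backgrounds) {
  as_list <- function(x) {
    if (is.array(x) && length(dim(x)) == 3) {
      lapply(seq_len(dim(x)[3]), function(i) x[, , i])
    } else if (is.matrix(x)) list(x) else x
  }
  li <- as_list(images); lb <- as_list(backgrounds)
  if (length(li) != length(lb)) stop("image and background counts differ")
  out <- Map(function(a, b) {
    if (!identical(dim(a), dim(b))) stop("image/background dimension mismatch")
    a + b
  }, li, lb)
  if (is.array(images) && length(dim(images)) == 3) {
    array(unlist(out), dim = dim(images))
  } else if (is.matrix(images)) out[[1]] else out
}

#' Write a ground-truth manifest for a simulated movie
#'
#' JSON manifest recording the trajectory, exposure schedule, ground-truth
#' critical-exposure table, noise level and seed.
#'
#' @param sim Result of [simulate_movie()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(sim, path) {
  kk <- seq(1, floor(dim(sim$stack$frames)[1] / 2)) /
    (dim(sim$stack$frames)[1] * sim$stack$pixel_size)
  ne <- if (!is.null(sim$ne_table)) {
    sim$ne_table
  } else {
    data.frame(freq = kk, ne = critical_exposure(kk, sim$params))
  }
  manifest <- list(
    n_frames = sim$stack$n_frames,
    pixel_size = sim$stack$pixel_size,
    exposure_per_frame = sim$schedule$per_frame,
    pre_exposure = sim$schedule$pre_exposure,
    accumulated_exposure = sim$exposures,
    total_exposure = sim$exposures[length(sim$exposures)],
    trajectory = data.frame(frame = sim$trajectory$frame,
                            x_ang = sim$trajectory$x_ang,
                            y_ang = sim$trajectory$y_ang),
    ne_table = ne,
    noise_sd = sim$noise_sd,
    seed = sim$seed
  )
  jsonlite::write_json(manifest, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}
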