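# Iterative rigid frame alignment: each frame is aligned against the
# leave-one-out sum of all other (currently shifted) frames, and the X/Y
# shift trajectories are spline-smoothed after each full pass, until the
# largest per-frame shift change falls below tolerance.

#' Alignment configuration
#'
#' Band-pass and weighting applied to the cross-correlation, plus iteration
#' control. The band-pass suppresses huge-scale intensity gradients (below
#' `lp_freq`) and the noise-dominated high frequencies (above `hp_freq`); a
#' Gaussian B-factor weight `exp(-bfactor * k^2 / 4)` further down-weights
#' high frequencies.
#'
#' @param lp_freq Low-frequency cutoff in 1/Angstrom (default 1/200).
#' @param hp_freq High-frequency cutoff in 1/Angstrom (default 1/8).
#' @param bfactor B-factor in Angstrom^2 applied to the correlation weights
#'   (default 1500).
#' @param max_iter Maximum number of alignment passes (default 20).
#' @param tol Convergence threshold: maximum per-frame shift change in
#'   pixels (default 0.1).
#' @param spline_df Effective degrees of freedom of the smoothing spline
#'   applied to each shift coordinate; default `max(4, n_frames / 4)`.
#' @param max_shift Maximum allowed shift per frame in pixels (default Inf).
#' @return Object of class `alignment_config`.
#' @export
alignment_config <- function(lp_freq = 1 / 200, hp_freq = 1 / 8,
                             bfactor = 1500, max_iter = 20, tol = 0.1,
                             spline_df = NULL, max_shift = Inf) {
  stopifnot(lp_freq >= 0, hp_freq > lp_freq, bfactor >= 0,
            max_iter >= 1, tol > 0, max_shift > 0)
  structure(
    list(lp_freq = lp_freq, hp_freq = hp_freq, bfactor = bfactor,
         max_iter = max_iter, tol = tol, spline_df = spline_df,
         max_shift = max_shift),
    class = "alignment_config"
  )
}

# Correlation weight grid: band-pass + Gaussian B-factor.
.cc_weights <- function(dims, pixel_size, config) {
  k <- radial_freq_grid(dims, pixel_size)
  w <- exp(-config$bfactor * k^2 / 4)
  w[k < config$lp_freq | k > config$hp_freq] <- 0
  w
}

# Parabolic sub-pixel refinement of a 1D triplet (c_minus, c_0, c_plus).
.parabolic_offset <- function(cm, c0, cp) {
  den <- cm - 2 * c0 + cp
  if (den >= 0) return(0)  # not a proper maximum
  off <- 0.5 * (cm - cp) / den
  max(min(off, 0.5), -0.5)
}

# Peak search on a correlation surface in unshifted FFT layout.
# Returns the displacement (dx, dy) and peak height; ties broken towards
# `prev`.
.cc_peak <- function(cc, prev = c(0, 0)) {
  n1 <- nrow(cc); n2 <- ncol(cc)
  mx <- max(cc)
  cand <- which(cc >= mx - 1e-12 * max(abs(mx), 1), arr.ind = TRUE)
  wrap <- function(i, n) ifelse(i - 1 > n / 2, i - 1 - n, i - 1)
  dx <- wrap(cand[, 1], n1)
  dy <- wrap(cand[, 2], n2)
  pick <- which.min((dx - prev[1])^2 + (dy - prev[2])^2)
  i <- cand[pick, 1]; j <- cand[pick, 2]
  im <- if (i == 1) n1 else i - 1
  ip <- if (i == n1) 1 else i + 1
  jm <- if (j == 1) n2 else j - 1
  jp <- if (j == n2) 1 else j + 1
  list(
    dx = unname(wrap(i, n1) + .parabolic_offset(cc[im, j], cc[i, j], cc[ip, j])),
    dy = unname(wrap(j, n2) + .parabolic_offset(cc[i, jm], cc[i, j], cc[i, jp])),
    peak = unname(cc[i, j])
  )
}

#' Sub-pixel cross-correlation of two images
#'
#' Locates the maximum of the band-passed, B-factor-weighted
#' cross-correlation of `a` and `b`, with parabolic 3x3 sub-pixel
#' refinement. The returned displacement `(dx, dy)` satisfies
#' `b ~ shift_image(a, dx, dy)`.
#'
#' @param a,b Real matrices of equal dimension.
#' @param config An [alignment_config()].
#' @param pixel_size Pixel size in Angstrom (for the frequency cutoffs).
#' @param prev Previous shift estimate in pixels; ties between equal maxima
#'   are broken towards it.
#' @return List with `dx`, `dy` (pixels) and `peak` (correlation height).
#' @export
cross_correlate <- function(a, b, config = alignment_config(),
                            pixel_size = 1, prev = c(0, 0)) {
  stopifnot(identical(dim(a), dim(b)))
  if (all(a == 0) || all(b == 0)) stop("all-zero input: correlation peak undefined")
  w <- .cc_weights(dim(a), pixel_size, config)
  cc <- Re(ifft(Conj(stats::fft(a)) * stats::fft(b) * w))
  .cc_peak(cc, prev)
}

#' Smooth a drift trajectory with a cubic smoothing spline
#'
#' Fits a cubic smoothing spline over frame index to each shift coordinate
#' and returns the spline-evaluated shifts. Linear (and constant) inputs are
#' reproduced exactly; i.i.d. jitter around a smooth drift is attenuated.
#' Fewer than 4 frames are returned unchanged (too few points for a cubic
#' fit).
#'
#' @param shifts Numeric vector (one coordinate), or a 2-column matrix of
#'   (x, y) shifts, one row per frame.
#' @param df Effective degrees of freedom of the spline; default
#'   `max(4, n / 4)`, capped at `n - 1`.
#' @return Smoothed shifts in the same shape as the input.
#' @export
smooth_trajectory <- function(shifts, df = NULL) {
  if (is.matrix(shifts)) {
    return(apply(shifts, 2, smooth_trajectory, df = df))
  }
  n <- length(shifts)
  if (n < 4) return(shifts)
  if (is.null(df)) df <- max(4, n / 4)
  df <- min(max(df, 1.5), n - 1)
  stats::predict(stats::smooth.spline(seq_len(n), shifts, df = df),
                 seq_len(n))$y
}

#' Align the frames of a movie
#'
#' Iterative rigid alignment: within each pass, every frame is
#' cross-correlated against the sum of all other currently shifted frames
#' (leaving the frame itself out so it cannot "find itself" in the sum) and
#' its shift is updated; after each pass the X and Y trajectories are
#' centered (mean shift zero) and spline-smoothed. Iteration stops when the
#' maximum per-frame shift change drops below `config$tol` pixels or after
#' `config$max_iter` passes (the latter flags non-convergence with a
#' warning, never silently).
#'
#' @param stack A [movie_stack()] with at least 3 frames.
#' @param config An [alignment_config()].
#' @return A `shift_trajectory`: data frame with columns `frame`, `x_px`,
#'   `y_px`, `x_ang`, `y_ang` (shifts to apply to each frame to register
#'   it), with attributes `pixel_size`, `converged`, `iterations`,
#'   `history` (max shift change per pass) and `smoothed`.
#' @export
align_frames <- function(stack, config = alignment_config()) {
  stopifnot(inherits(stack, "movie_stack"))
  n <- stack$n_frames
  if (n < 3) stop("alignment needs >= 3 frames (leave-one-out sum)")
  d <- dim(stack$frames)[1:2]
  w <- .cc_weights(d, stack$pixel_size, config)
  Fr <- vector("list", n)
  for (i in seq_len(n)) Fr[[i]] <- stats::fft(get_frame(stack, i))
  if (all(vapply(Fr, function(f) all(f == 0), logical(1)))) {
    stop("all-zero movie: alignment undefined")
  }

  sx <- numeric(n); sy <- numeric(n)
  Fs <- Fr                       # shifted spectra (all shifts start at 0)
  total <- Reduce(`+`, Fs)
  history <- numeric(0)
  converged <- FALSE
  iter <- 0

  while (iter < config$max_iter) {
    iter <- iter + 1
    old_x <- sx; old_y <- sy
    for (i in seq_len(n)) {
      loo <- total - Fs[[i]]
      cc <- Re(ifft(Conj(Fr[[i]]) * loo * w))
      pk <- .cc_peak(cc, prev = c(sx[i], sy[i]))
      nx <- pk$dx; ny <- pk$dy
      r <- sqrt(nx^2 + ny^2)
      if (r > config$max_shift) {
        nx <- nx * config$max_shift / r
        ny <- ny * config$max_shift / r
      }
      sx[i] <- nx; sy[i] <- ny
      new_Fi <- Fr[[i]] * shift_ramp(d[1], d[2], sx[i], sy[i])
      total <- total + (new_Fi - Fs[[i]])
      Fs[[i]] <- new_Fi
    }
    # gauge fixing + spline smoothing, then rebuild the shifted spectra
    sx <- sx - mean(sx); sy <- sy - mean(sy)
    sx <- smooth_trajectory(sx, df = config$spline_df)
    sy <- smooth_trajectory(sy, df = config$spline_df)
    for (i in seq_len(n)) {
      Fs[[i]] <- Fr[[i]] * shift_ramp(d[1], d[2], sx[i], sy[i])
    }
    total <- Reduce(`+`, Fs)
    change <- max(sqrt((sx - old_x)^2 + (sy - old_y)^2))
    history <- c(history, change)
    if (change < config$tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf(
      "frame alignment did not converge in %d passes (last change %.3g px)",
      iter, history[length(history)]))
  }
  shift_trajectory(sx, sy, stack$pixel_size, converged = converged,
                   iterations = iter, history = history, smoothed = TRUE)
}

#' Construct a shift trajectory
#'
#' @param x_px,y_px Per-frame shifts in pixels.
#' @param pixel_size Pixel size in Angstrom.
#' @param ... Further attributes (`converged`, `iterations`, `history`,
#'   `smoothed`).
#' @return A `shift_trajectory` data frame.
#' @export
shift_trajectory <- function(x_px, y_px, pixel_size = 1, ...) {
  stopifnot(length(x_px) == length(y_px), all(is.finite(x_px)),
            all(is.finite(y_px)), pixel_size > 0)
  out <- data.frame(
    frame = seq_along(x_px),
    x_px = x_px, y_px = y_px,
    x_ang = x_px * pixel_size, y_ang = y_px * pixel_size
  )
  attr(out, "pixel_size") <- pixel_size
  extra <- list(...)
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("shift_trajectory", "data.frame")
  out
}

#' First frame of stable (plateaued) motion
#'
#' Finds the smallest frame index from which every subsequent per-frame
#' shift magnitude stays below a threshold. Per-frame shift magnitudes are
#' the distances between consecutive trajectory positions (in Angstrom);
#' frame 1 has no preceding frame and counts as zero motion.
#'
#' @param traj A `shift_trajectory`, or a numeric vector of per-frame shift
#'   magnitudes in Angstrom.
#' @param threshold Per-frame shift threshold in Angstrom.
#' @return First stable frame index; `n_frames + 1` (sentinel) if motion
#'   never stabilizes.
#' @export
motion_plateau_onset <- function(traj, threshold) {
  stopifnot(threshold > 0)
  if (inherits(traj, "shift_trajectory")) {
    steps <- c(0, sqrt(diff(traj$x_ang)^2 + diff(traj$y_ang)^2))
  } else {
    steps <- as.numeric(traj)
  }
  n <- length(steps)
  bad <- which(steps >= threshold)
  if (length(bad) == 0) return(1L)
  if (max(bad) == n) return(n + 1L)
  max(bad) + 1L
}

#' Shift selected frames by their trajectory and sum them
#'
#' Applies each frame's (sub-pixel) registration shift and sums over the
#' selected range. No exposure weighting is applied here; see
#' [filtered_sum()] for the SNR-weighted sum.
#'
#' @param stack A [movie_stack()].
#' @param traj A `shift_trajectory` with one row per frame of `stack`.
#' @param frame_range Integer vector of frames to include (default all),
#'   e.g. `4:21`.
#' @return Real matrix: the aligned sum, with attribute `pixel_size`.
#' @export
apply_and_sum <- function(stack, traj, frame_range = NULL) {
  stopifnot(inherits(stack, "movie_stack"))
  if (nrow(traj) != stack$n_frames) {
    stop("trajectory length does not match frame count")
  }
  if (is.null(frame_range)) frame_range <- seq_len(stack$n_frames)
  if (length(frame_range) == 0) stop("empty frame range")
  if (any(frame_range < 1 | frame_range > stack$n_frames)) {
    stop("frame range outside stack")
  }
  d <- dim(stack$frames)[1:2]
  acc <- matrix(0 + 0i, d[1], d[2])
  for (i in frame_range) {
    acc <- acc + stats::fft(get_frame(stack, i)) *
      shift_ramp(d[1], d[2], traj$x_px[i], traj$y_px[i])
  }
  out <- Re(ifft(acc))
  attr(out, "pixel_size") <- stack$pixel_size
  out
}

#' Write / read a shifts file
#'
#' Plain-text shifts: one line per frame, `frame_index dx_A dy_A`, with a
#' commented header recording the pixel size. Readable by [apply_and_sum()]
#' after [read_shifts()] for re-summation of already aligned movies.
#'
#' @param traj A `shift_trajectory`.
#' @param path File path.
#' @return `write_shifts` returns `path` invisibly; `read_shifts` returns a
#'   `shift_trajectory`.
#' @export
write_shifts <- function(traj, path) {
  ps <- attr(traj, "pixel_size")
  lines <- c(
    "# frame shifts (to apply to each frame to register it)",
    sprintf("# pixel_size_A: %.17g", ps),
    "# columns: frame dx_A dy_A",
    sprintf("%d %.10g %.10g", traj$frame, traj$x_ang, traj$y_ang)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_shifts
#' @export
read_shifts <- function(path) {
  lines <- readLines(path)
  hdr <- lines[grepl("^#", lines)]
  ps_line <- grep("pixel_size_A:", hdr, value = TRUE)
  ps <- if (length(ps_line)) {
    as.numeric(sub(".*pixel_size_A:\\s*", "", ps_line[1]))
  } else 1
  dat <- utils::read.table(text = lines[!grepl("^#", lines)],
                           col.names = c("frame", "dx_A", "dy_A"))
  shift_trajectory(dat$dx_A / ps, dat$dy_A / ps, pixel_size = ps)
}
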