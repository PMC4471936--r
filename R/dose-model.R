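# The radiation-damage model: resolution-dependent critical exposure and the
# per-frame amplitude attenuation used by the exposure filter.

#' Radiation-damage model parameters
#'
#' The critical exposure `Ne(k)` — the accumulated electron exposure after
#' which signal at spatial frequency `k` has decayed to 1/e of its starting
#' value — is modelled as the offset power law
#' \deqn{N_e(k) = a k^b + c,}
#' with `k` the SPATIAL FREQUENCY in 1/Angstrom (not the resolution in
#' Angstrom: only the frequency reading yields the strongly
#' resolution-dependent curve observed experimentally, with `Ne` of tens of
#' electrons/A^2 at low resolution dropping to a few at high resolution).
#' Defaults are the published 300 kV calibration `a = 0.245`, `b = -1.665`,
#' `c = 2.81` (exposures in electrons/A^2); they can be replaced by a user's
#' own fit from [fit_critical_exposure()].
#'
#' @param a Power-law prefactor (> 0).
#' @param b Power-law exponent (< 0).
#' @param c Asymptotic critical exposure at high frequency, electrons/A^2
#'   (> 0).
#' @param voltage_kv Accelerating voltage in kV; 300 or 200 (critical
#'   exposure at 200 kV is scaled down by 25%).
#' @param optimal_ratio Ratio of optimal to critical exposure; default 2.5.
#' @return An object of class `dose_model`.
#' @seealso [critical_exposure()], [attenuation_factor()],
#'   [fit_critical_exposure()]
#' @examples
#' m <- dose_model()
#' critical_exposure(1 / 3, m)
#' @export
dose_model <- function(a = 0.245, b = -1.665, c = 2.81,
                       voltage_kv = 300, optimal_ratio = 2.5) {
  if (!(a > 0)) stop("'a' must be positive")
  if (!(b < 0)) stop("'b' must be negative (Ne decreases with frequency)")
  if (!(c > 0)) stop("'c' must be positive")
  if (!(optimal_ratio > 0)) stop("'optimal_ratio' must be positive")
  voltage_scale(voltage_kv)  # validates the voltage
  structure(
    list(a = a, b = b, c = c, voltage_kv = voltage_kv,
         optimal_ratio = optimal_ratio),
    class = "dose_model"
  )
}

#' @export
print.dose_model <- function(x, ...) {
  cat("Critical-exposure model  Ne(k) = s * (a * k^b + c)\n")
  cat(sprintf("  a = %g, b = %g, c = %g e-/A^2\n", x$a, x$b, x$c))
  cat(sprintf("  voltage = %g kV (scale s = %g)\n",
              x$voltage_kv, voltage_scale(x$voltage_kv)))
  cat(sprintf("  optimal/critical exposure ratio = %g\n", x$optimal_ratio))
  invisible(x)
}

#' Voltage scale factor for the critical exposure
#'
#' The critical exposure is referenced to 300 kV; at 200 kV it is about 25%
#' lower. Other voltages are rejected rather than interpolated.
#'
#' @param voltage_kv Accelerating voltage in kV (200 or 300).
#' @return Dimensionless scale factor: 1.0 at 300 kV, 0.75 at 200 kV.
#' @export
voltage_scale <- function(voltage_kv) {
  if (length(voltage_kv) != 1 || !is.numeric(voltage_kv) ||
      !voltage_kv %in% c(200, 300)) {
    stop("unsupported accelerating voltage; supported values: 300 kV, 200 kV")
  }
  if (voltage_kv == 300) 1.0 else 0.75
}

#' Critical exposure at a spatial frequency
#'
#' Evaluates `Ne(k) = s(V) * (a k^b + c)`, the accumulated exposure
#' (electrons/A^2) at which signal at frequency `k` falls to 1/e of its
#' initial value. Strictly decreasing in `k`, approaching `s * c` at high
#' frequency. `k = 0` returns `Inf` (the DC term does not decay under the
#' power law; on sampled grids the filter assigns the DC term the attenuation
#' of the smallest nonzero shell, see [frame_weights()]).
#'
#' @param k Spatial frequency in 1/Angstrom (>= 0); vectorized.
#' @param params A [dose_model()] object.
#' @return Critical exposure(s) in electrons/A^2.
#' @export
critical_exposure <- function(k, params = dose_model()) {
  stopifnot(inherits(params, "dose_model"), is.numeric(k))
  if (any(k < 0, na.rm = TRUE)) stop("spatial frequency k must be >= 0")
  voltage_scale(params$voltage_kv) * (params$a * k^params$b + params$c)
}

#' Optimal exposure at a spatial frequency
#'
#' The exposure maximizing accumulated image signal at frequency `k`,
#' `optimal_ratio` (default 2.5) times the critical exposure.
#'
#' @inheritParams critical_exposure
#' @return Optimal exposure(s) in electrons/A^2.
#' @export
optimal_exposure <- function(k, params = dose_model()) {
  params$optimal_ratio * critical_exposure(k, params)
}

#' Exposure-dependent amplitude attenuation
#'
#' The factor by which signal amplitude at frequency `k` has decayed after an
#' accumulated exposure `N`:
#' \deqn{q(k, N) = \exp(-N / (2 N_e(k))).}
#' Squared amplitudes (hence SNR) decay as `exp(-N / Ne(k))`; at `N = Ne(k)`
#' the amplitude factor is `exp(-1/2)`.
#'
#' @param k Spatial frequency in 1/Angstrom (>= 0).
#' @param N Accumulated exposure in electrons/A^2 (>= 0). Either `k` or `N`
#'   may be a vector (recycled as usual).
#' @param params A [dose_model()] object.
#' @return Attenuation factor(s) in (0, 1].
#' @export
attenuation_factor <- function(k, N, params = dose_model()) {
  if (any(N < 0, na.rm = TRUE)) stop("accumulated exposure N must be >= 0")
  exp(-N / (2 * critical_exposure(k, params)))
}

#' Write / read a dose-model configuration file
#'
#' Serializes the model as a small `key = value` text file (keys `a`, `b`,
#' `c`, `voltage_kv`, `optimal_ratio`).
#'
#' @param params A [dose_model()] object.
#' @param path File path.
#' @return `write_dose_model` returns `path` invisibly; `read_dose_model`
#'   returns a [dose_model()].
#' @export
write_dose_model <- function(params, path) {
  stopifnot(inherits(params, "dose_model"))
  lines <- sprintf("%s = %.17g", names(params), unlist(params))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_dose_model
#' @export
read_dose_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  names(vals) <- keys
  needed <- c("a", "b", "c", "voltage_kv", "optimal_ratio")
  if (!all(needed %in% keys)) {
    stop("dose-model config missing keys: ",
         paste(setdiff(needed, keys), collapse = ", "))
  }
  dose_model(a = vals[["a"]], b = vals[["b"]], c = vals[["c"]],
             voltage_kv = vals[["voltage_kv"]],
             optimal_ratio = vals[["optimal_ratio"]])
}

#' Small-angle rotation arithmetic
#'
#' Helpers for judging whether measured particle rotations matter for
#' translational analysis: the average rotation per sub-sum of frames, and
#' the surface translation that a small rotation causes at a given radius.
#'
#' @param total_deg Total rotation over the whole movie, degrees.
#' @param n_frames Number of frames in the movie.
#' @param frames_per_subsum Frames per sub-sum (e.g. 3).
#' @return `rotation_per_subsum`: average rotation per sub-sum in degrees.
#' @export
rotation_per_subsum <- function(total_deg, n_frames, frames_per_subsum = 3) {
  stopifnot(n_frames >= 1, frames_per_subsum >= 1)
  total_deg * frames_per_subsum / n_frames
}

#' @rdname rotation_per_subsum
#' @param radius_ang Radius in Angstrom at which the translation is evaluated.
#' @param deg Rotation in degrees.
#' @return `rotation_arc`: arc-length translation in Angstrom.
#' @export
rotation_arc <- function(radius_ang, deg) {
  stopifnot(radius_ang >= 0)
  radius_ang * deg * pi / 180
}
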