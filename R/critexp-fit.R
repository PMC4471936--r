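# The critical-exposure estimator: per-shell censored log-linear regression
# of SNR against accumulated exposure, followed by an offset power-law fit
# of Ne against spatial frequency.

#' Per-shell critical exposure from an SNR series
#'
#' Under single-exponential damage, `ln SNR(k, N)` is linear in the
#' accumulated exposure `N` with slope `-1/Ne(k)`. For each shell this
#' performs ordinary least squares of `ln SNR` on `N` over the points from
#' `start_exposure` up to (not including) the first point at which the FSC
#' falls below the pure-noise floor (`noise_sigma_mult` standard deviations
#' of a pure-noise FSC), and sets `Ne = -1/slope`. Truncating at the first
#' crossing, rather than dropping below-floor points individually, avoids
#' retaining only the upward noise fluctuations of the decayed tail, which
#' would bias slopes shallow. Shells with fewer than `min_points` usable
#' points or a non-negative slope are dropped with a recorded reason.
#'
#' @param series An [snr_series()].
#' @param start_exposure Exclude points with accumulated exposure below
#'   this (electrons/A^2); used to skip early frames whose motion has not
#'   yet plateaued. Default 0.
#' @param noise_sigma_mult Censoring multiple of the per-shell pure-noise
#'   FSC standard deviation (default 3).
#' @param min_points Minimum uncensored points per retained shell
#'   (default 3).
#' @param weighted If `TRUE`, weight the regression by the propagated
#'   variance of `ln SNR` (weights `(FSC (1 - FSC))^2 / sigma^2`); default
#'   plain OLS.
#' @return Data frame with one row per shell: `freq`, `ne`, `ne_se`
#'   (standard error of `Ne` propagated from the slope), `slope`,
#'   `intercept`, `n_points`, `r_squared`, `retained`, `reason`.
#' @export
estimate_critical_exposure <- function(series, start_exposure = 0,
                                       noise_sigma_mult = 3,
                                       min_points = 3, weighted = FALSE) {
  stopifnot(inherits(series, "snr_series"), min_points >= 3)
  ns <- length(series$freq)
  out <- data.frame(
    freq = series$freq, ne = NA_real_, ne_se = NA_real_, slope = NA_real_,
    intercept = NA_real_, n_points = 0L, r_squared = NA_real_,
    retained = FALSE, reason = "", stringsAsFactors = FALSE
  )
  for (s in seq_len(ns)) {
    fsc <- series$fsc[s, ]
    snr <- series$snr[s, ]
    keep <- series$exposures >= start_exposure & is.finite(snr) & snr > 0
    floor_hit <- which(keep & fsc <= noise_sigma_mult * series$sigma_noise[s])
    if (length(floor_hit)) keep[floor_hit[1]:length(keep)] <- FALSE
    out$n_points[s] <- sum(keep)
    if (sum(keep) < min_points) {
      out$reason[s] <- sprintf("only %d usable points (< %d)",
                               sum(keep), min_points)
      next
    }
    x <- series$exposures[keep]
    y <- log(snr[keep])
    w <- if (weighted) (fsc[keep] * (1 - fsc[keep]))^2 / series$sigma_noise[s]^2
    fit <- stats::lm(y ~ x, weights = w)
    slope <- unname(stats::coef(fit)[2])
    out$slope[s] <- slope
    out$intercept[s] <- unname(stats::coef(fit)[1])
    ww <- if (is.null(w)) rep(1, length(y)) else w
    sst <- sum(ww * (y - sum(ww * y) / sum(ww))^2)
    out$r_squared[s] <- if (sst > 0) 1 - sum(ww * fit$residuals^2) / sst
                        else NA_real_
    if (!is.finite(slope) || slope >= 0) {
      out$reason[s] <- "non-negative slope (no measurable decay)"
      next
    }
    out$ne[s] <- -1 / slope
    # delta method: Ne = -1/slope  =>  se(Ne) = se(slope) / slope^2
    ww <- if (is.null(w)) rep(1, length(y)) else w
    sxx <- sum(ww * (x - sum(ww * x) / sum(ww))^2)
    sigma2 <- sum(ww * fit$residuals^2) / (length(y) - 2)
    out$ne_se[s] <- sqrt(sigma2 / sxx) / slope^2
    out$retained[s] <- TRUE
  }
  if (!any(out$retained)) {
    stop("no shell yielded a usable critical-exposure regression")
  }
  out
}

#' Offset power-law fit of the critical-exposure curve
#'
#' Nonlinear least squares of `Ne` against `a * k^b + c` with sign
#' constraints `a > 0`, `b < 0`, `c > 0` (bounded Levenberg-Marquardt).
#' Shell estimates of unequal precision can be given inverse-variance
#' weights; `R^2` is computed on the `Ne` values directly (unweighted, not
#' log-transformed).
#'
#' @param freq Shell frequencies in 1/Angstrom (>= 4 values).
#' @param ne Per-shell critical-exposure estimates, electrons/A^2.
#' @param weights Optional non-negative fitting weights (one per shell),
#'   e.g. `1 / ne_se^2` from [estimate_critical_exposure()].
#' @return List with `a`, `b`, `c`, `r_squared`, `fitted`, `degenerate`
#'   (`TRUE` when the prefactor collapsed to its lower bound, i.e. the data
#'   carry no frequency dependence) and the underlying `nls` object `fit`.
#' @export
fit_power_law <- function(freq, ne, weights = NULL) {
  ok <- is.finite(freq) & is.finite(ne) & freq > 0 & ne > 0
  if (!is.null(weights)) {
    stopifnot(length(weights) == length(freq), all(weights[ok] >= 0))
    weights <- weights[ok]
  }
  freq <- freq[ok]; ne <- ne[ok]
  if (length(freq) < 4) stop("power-law fit needs >= 4 shells")
  c0 <- max(0.9 * min(ne), 1e-3)
  b0 <- -1.5
  hi <- which.max(freq)
  a0 <- max((ne[hi] - c0), 1e-3) / freq[hi]^b0
  dat <- data.frame(k = freq, ne = ne)
  if (is.null(weights)) weights <- rep(1, length(freq))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      ne ~ a * k^b + c, data = dat, weights = weights,
      start = list(a = a0, b = b0, c = c0),
      lower = c(a = 1e-8, b = -10, c = 1e-8),
      upper = c(a = Inf, b = -1e-3, c = Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) stop("power-law fit failed to converge: ",
                             conditionMessage(e))
  )
  cf <- stats::coef(fit)
  pred <- stats::predict(fit)
  r2 <- 1 - sum((ne - pred)^2) / sum((ne - mean(ne))^2)
  list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
       r_squared = r2, fitted = pred,
       degenerate = cf["a"] <= 2e-8, fit = fit)
}

#' Fit the critical-exposure curve from exposure-resolved FSC data
#'
#' The full estimation pipeline: FSC curves at increasing accumulated
#' exposure are converted to per-shell SNR, each shell's `ln SNR` is
#' regressed on exposure (censored at the pure-noise floor) to give a
#' critical exposure `Ne = -1/slope`, and the retained shells are fitted
#' with the offset power law `Ne(k) = a k^b + c`, each shell weighted by
#' the inverse variance of its `Ne` estimate (shells measured from thin,
#' noisy Fourier rings carry less weight; set
#' `power_law_weights = FALSE` for a plain fit). The result carries a
#' ready-to-use [dose_model()] with the fitted constants.
#'
#' @param data A list of `fsc_curve` objects (each labelled with its
#'   accumulated exposure) or an [snr_series()].
#' @param start_exposure,noise_sigma_mult,weighted Passed to
#'   [estimate_critical_exposure()].
#' @param freq_range Frequency band (1/Angstrom) of shells entering the
#'   power-law fit; defaults to `c(1/22, Inf)`, excluding the very low
#'   frequency shells where exposure-resolved FSC is typically too noisy.
#' @param voltage_kv Voltage recorded in the returned dose model.
#' @param symmetry Passed to [snr_series()] when `data` is a list of
#'   curves.
#' @param power_law_weights Weight the power-law fit by `1 / ne_se^2`
#'   (default `TRUE`).
#' @return An object of class `critexp` with components `shells` (per-shell
#'   diagnostics), `coefficients` (a, b, c), `r_squared`, `dose_model`,
#'   `freq_range`, `n_exposures`. Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' \donttest{
#' ref <- make_reference(box = 64, seed = 2)
#' hm <- simulate_half_map_series(ref, exposures = seq(1, 40, length.out = 20),
#'                                pixel_size = 1, noise_sd = 2, seed = 3)
#' fit <- fit_critical_exposure(half_map_fsc(hm))
#' coef(fit)
#' predict(fit, k = 0.25)
#' }
#' @export
fit_critical_exposure <- function(data, start_exposure = 0,
                                  noise_sigma_mult = 3,
                                  freq_range = c(1 / 22, Inf),
                                  weighted = FALSE, voltage_kv = 300,
                                  symmetry = 1, power_law_weights = TRUE) {
  series <- if (inherits(data, "snr_series")) data
            else snr_series(data, symmetry = symmetry)
  if (length(series$exposures) < 3) {
    stop("need at least 3 exposure points to regress ln(SNR) on exposure")
  }
  shells <- estimate_critical_exposure(series, start_exposure,
                                       noise_sigma_mult, weighted = weighted)
  infit <- shells$retained & shells$freq >= freq_range[1] &
    shells$freq <= freq_range[2]
  if (sum(infit) < 4) {
    stop(sprintf(
      "only %d retained shells in the frequency band [%.4g, %.4g]; need >= 4.\nShell diagnostics:\n%s",
      sum(infit), freq_range[1], freq_range[2],
      paste(utils::capture.output(print(shells[!shells$retained, c("freq", "n_points", "reason")])),
            collapse = "\n")))
  }
  shells$in_fit <- infit
  # inverse-variance weights; exact (zero-residual) shells get a floor
  w <- if (power_law_weights) {
    1 / pmax(shells$ne_se[infit], 1e-6 * shells$ne[infit])^2
  }
  pl <- fit_power_law(shells$freq[infit], shells$ne[infit], weights = w)
  structure(
    list(
      shells = shells,
      coefficients = c(a = pl$a, b = pl$b, c = pl$c),
      r_squared = pl$r_squared,
      degenerate = pl$degenerate,
      dose_model = dose_model(a = pl$a, b = pl$b, c = pl$c,
                              voltage_kv = voltage_kv),
      freq_range = freq_range,
      n_exposures = length(series$exposures),
      start_exposure = start_exposure,
      noise_sigma_mult = noise_sigma_mult
    ),
    class = "critexp"
  )
}

#' @export
print.critexp <- function(x, ...) {
  cat("Critical-exposure fit  Ne(k) = a * k^b + c\n")
  cat(sprintf("  a = %.4g  b = %.4g  c = %.4g e-/A^2   (R^2 = %.4g)\n",
              x$coefficients["a"], x$coefficients["b"], x$coefficients["c"],
              x$r_squared))
  cat(sprintf("  %d shells fitted (of %d retained) over %d exposure points\n",
              sum(x$shells$in_fit), sum(x$shells$retained), x$n_exposures))
  if (isTRUE(x$degenerate)) {
    cat("  WARNING: degenerate fit (no frequency dependence detected)\n")
  }
  invisible(x)
}

#' @export
summary.critexp <- function(object, ...) {
  print(object)
  cat("\nPer-shell regressions (retained shells):\n")
  sh <- object$shells[object$shells$retained,
                      c("freq", "ne", "slope", "n_points", "r_squared", "in_fit")]
  print(sh, row.names = FALSE, digits = 4)
  dropped <- object$shells[!object$shells$retained, ]
  if (nrow(dropped)) {
    cat(sprintf("\n%d shells dropped (e.g. %s)\n", nrow(dropped),
                dropped$reason[which(nzchar(dropped$reason))[1]]))
  }
  invisible(object)
}

#' @export
coef.critexp <- function(object, ...) object$coefficients

#' Predict critical exposure from a fitted curve
#'
#' @param object A `critexp` fit.
#' @param k Spatial frequencies (1/Angstrom) at which to evaluate the
#'   fitted curve; defaults to the fitted shells.
#' @param what `"critical"` (default) or `"optimal"` exposure.
#' @param ... Unused.
#' @return Exposure(s) in electrons/A^2.
#' @export
predict.critexp <- function(object, k = NULL, what = c("critical", "optimal"),
                            ...) {
  what <- match.arg(what)
  if (is.null(k)) k <- object$shells$freq[object$shells$in_fit]
  if (what == "critical") critical_exposure(k, object$dose_model)
  else optimal_exposure(k, object$dose_model)
}

#' @export
fitted.critexp <- function(object, ...) {
  predict(object, k = object$shells$freq[object$shells$in_fit])
}

#' @export
residuals.critexp <- function(object, ...) {
  sh <- object$shells[object$shells$in_fit, ]
  sh$ne - predict(object, k = sh$freq)
}

#' Plot a critical-exposure fit
#'
#' Per-shell Ne estimates with the fitted power law (log y axis).
#'
#' @param x A `critexp` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.critexp <- function(x, ...) {
  sh <- x$shells[x$shells$retained, ]
  graphics::plot(sh$freq, sh$ne, log = "y",
                 xlab = "spatial frequency (1/A)",
                 ylab = "critical exposure Ne (e-/A^2)",
                 pch = ifelse(sh$in_fit, 19, 1), ...)
  kk <- seq(min(sh$freq), max(sh$freq), length.out = 200)
  graphics::lines(kk, critical_exposure(kk, x$dose_model), col = 2)
  invisible(x)
}

#' Write the per-shell Ne table as CSV
#'
#' @param fit A `critexp` fit.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ne_table <- function(fit, path) {
  stopifnot(inherits(fit, "critexp"))
  sh <- fit$shells
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fitted: a=%.10g b=%.10g c=%.10g r_squared=%.10g",
                     fit$coefficients["a"], fit$coefficients["b"],
                     fit$coefficients["c"], fit$r_squared), con)
  utils::write.csv(sh, con, row.names = FALSE)
  invisible(path)
}
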