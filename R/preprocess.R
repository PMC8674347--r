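#' Preprocessing parameters
#'
#' Holds the common wavenumber grid and the "universal" baseline/smoothing
#' controls applied to every spectrum in a run. Defaults reproduce the
#' working grid 559-1990 cm^-1 sampled every 3 cm^-1 (478 points).
#'
#' @param grid_start,grid_end,grid_step common grid in cm^-1; the span must
#'   be divisible by the step.
#' @param baseline_lambda smoothness of the asymmetric-least-squares
#'   baseline (second-difference penalty weight).
#' @param baseline_p asymmetry: weight given to points above the running
#'   baseline estimate (peaks); points below get weight `1 - baseline_p`.
#' @param baseline_maxit reweighting iterations.
#' @param smooth_spar smoothing-spline strength passed to
#'   [stats::smooth.spline()]; kept deliberately small so a noiseless signal
#'   passes through essentially unchanged.
#' @return An object of class `preprocess_params`.
#' @export
preprocess_params <- function(grid_start = 559, grid_end = 1990,
                              grid_step = 3, baseline_lambda = 1e5,
                              baseline_p = 0.01, baseline_maxit = 10,
                              smooth_spar = 0.25) {
  if (!(grid_start < grid_end) || grid_step <= 0) {
    stop("need grid_start < grid_end and grid_step > 0", call. = FALSE)
  }
  span <- grid_end - grid_start
  if (abs(span / grid_step - round(span / grid_step)) > 1e-9) {
    stop("(grid_end - grid_start) must be divisible by grid_step",
         call. = FALSE)
  }
  structure(
    list(grid_start = grid_start, grid_end = grid_end, grid_step = grid_step,
         baseline_lambda = baseline_lambda, baseline_p = baseline_p,
         baseline_maxit = baseline_maxit, smooth_spar = smooth_spar),
    class = "preprocess_params"
  )
}

#' The common wavenumber grid of a parameter set
#' @param p a [preprocess_params()].
#' @return Numeric vector `grid_start, grid_start + grid_step, ..., grid_end`.
#' @export
common_grid <- function(p = preprocess_params()) {
  seq(p$grid_start, p$grid_end, by = p$grid_step)
}

#' Refit a spectrum onto the common wavenumber grid
#'
#' Cubic-spline interpolation ([stats::splinefun()], natural boundary) onto
#' the exact grid `grid_start, ..., grid_end`. The input axis must cover the
#' target range; the grid is never extrapolated.
#'
#' @param s a [raman_spectrum()].
#' @param p a [preprocess_params()].
#' @return A `raman_spectrum` on the common grid (478 points at defaults).
#' @export
refit_grid <- function(s, p = preprocess_params()) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (min(s$wavenumbers) > p$grid_start || max(s$wavenumbers) < p$grid_end) {
    stop(sprintf(
      "spectrum axis [%g, %g] does not cover the target grid [%g, %g]",
      min(s$wavenumbers), max(s$wavenumbers), p$grid_start, p$grid_end),
      call. = FALSE)
  }
  grid <- common_grid(p)
  f <- stats::splinefun(s$wavenumbers, s$intensities, method = "natural")
  raman_spectrum(grid, f(grid), position = s$position, label = s$label,
                 meta = s$meta)
}

# Asymmetric least squares baseline (Eilers-Boelens style): minimise
# sum w_i (y_i - z_i)^2 + lambda * sum (D2 z)^2 with w_i small where y > z,
# so the smooth curve hugs the lower envelope of the spectrum. The
# pentadiagonal normal equations are solved by a banded Cholesky in C++
# (one O(n) solve per reweighting iteration).
als_baseline <- function(y, lambda, p, maxit) {
  .als_baseline_cpp(as.numeric(y), lambda, p, as.integer(maxit))
}

#' Subtract the fluorescence baseline
#'
#' Estimates a smooth background under the spectrum by asymmetric least
#' squares (a second-difference-penalised fit that down-weights points above
#' the running estimate, so narrow Raman bands do not drag the baseline up)
#' and subtracts it. One fixed "universal" parameter set is the default; the
#' estimated baseline is kept in `meta$baseline` for audit.
#'
#' @param s a `raman_spectrum` on the common grid.
#' @param p a [preprocess_params()].
#' @return Baseline-corrected `raman_spectrum`.
#' @export
correct_baseline <- function(s, p = preprocess_params()) {
  stopifnot(inherits(s, "raman_spectrum"))
  z <- als_baseline(s$intensities, p$baseline_lambda, p$baseline_p,
                    p$baseline_maxit)
  meta <- s$meta
  meta$baseline <- z
  raman_spectrum(s$wavenumbers, s$intensities - z, position = s$position,
                 label = s$label, meta = meta)
}

#' Smooth a spectrum with a signal-preserving spline
#'
#' Fits [stats::smooth.spline()] over all data points (every point is a
#' knot) with a small smoothing parameter, so genuine bands are not degraded
#' while high-frequency noise is attenuated.
#'
#' @param s a `raman_spectrum`.
#' @param p a [preprocess_params()].
#' @return Smoothed `raman_spectrum`.
#' @export
smooth_spectrum <- function(s, p = preprocess_params()) {
  stopifnot(inherits(s, "raman_spectrum"))
  if (max(s$intensities) == min(s$intensities)) return(s)
  fit <- stats::smooth.spline(s$wavenumbers, s$intensities,
                              all.knots = TRUE, spar = p$smooth_spar,
                              keep.data = FALSE)
  raman_spectrum(s$wavenumbers,
                 stats::predict(fit, s$wavenumbers)$y,
                 position = s$position, label = s$label, meta = s$meta)
}

# population standard deviation (divide by n); at n = 478 the difference
# from the sample convention is immaterial but the choice is fixed
sd_pop <- function(v) sqrt(mean((v - mean(v))^2))

#' Scale a spectrum by its standard deviation
#'
#' Divides the intensities by their (population) standard deviation so every
#' spectrum enters the classifier with unit spread. A constant spectrum has
#' zero spread and cannot be scaled: it is flagged degenerate
#' (`meta$degenerate`), bypasses classification downstream and is assigned
#' class NMP with confidence 0.
#'
#' @param s a `raman_spectrum`.
#' @return Scaled `raman_spectrum` with SD 1, or the input flagged
#'   degenerate.
#' @export
scale_sd <- function(s) {
  stopifnot(inherits(s, "raman_spectrum"))
  sdv <- sd_pop(s$intensities)
  meta <- s$meta
  if (sdv == 0) {
    meta$degenerate <- TRUE
    return(raman_spectrum(s$wavenumbers, s$intensities,
                          position = s$position, label = s$label,
                          meta = meta))
  }
  raman_spectrum(s$wavenumbers, s$intensities / sdv, position = s$position,
                 label = s$label, meta = meta)
}

#' Full per-spectrum preprocessing pipeline
#'
#' Applies, in order: grid refit, baseline correction, spline smoothing and
#' SD scaling. Constant (degenerate) inputs skip baseline/smoothing and come
#' out flagged.
#'
#' @param s a [raman_spectrum()] covering the common grid.
#' @param p a [preprocess_params()].
#' @return Preprocessed `raman_spectrum` on the common grid.
#' @export
preprocess_spectrum <- function(s, p = preprocess_params()) {
  s <- refit_grid(s, p)
  if (max(s$intensities) == min(s$intensities)) {
    s$meta$degenerate <- TRUE
    return(scale_sd(s))
  }
  s <- correct_baseline(s, p)
  s <- smooth_spectrum(s, p)
  scale_sd(s)
}

#' Preprocess every pixel of a map
#'
#' @param map a [raman_map()] whose axis covers the common grid.
#' @param p a [preprocess_params()].
#' @return A `raman_map` on the common grid with degenerate pixels flagged.
#' @export
preprocess_map <- function(map, p = preprocess_params()) {
  stopifnot(inherits(map, "raman_map"))
  grid <- common_grid(p)
  n <- nrow(map$intensities)
  out <- matrix(0, n, length(grid))
  degen <- logical(n)
  for (i in seq_len(n)) {
    s <- preprocess_spectrum(
      raman_spectrum(map$wavenumbers, map$intensities[i, ]), p)
    out[i, ] <- s$intensities
    degen[i] <- isTRUE(s$meta$degenerate)
  }
  raman_map(grid, out, map$x, map$y, step = map$step,
            analyzed_fraction = map$analyzed_fraction,
            filter_area = map$filter_area, degenerate = degen)
}

#' Preprocess every entry of a training library
#'
#' @param lib a [raman_library()].
#' @param p a [preprocess_params()].
#' @return A `raman_library` on the common grid. Degenerate (constant)
#'   entries are an error: they carry no class information.
#' @export
preprocess_library <- function(lib, p = preprocess_params()) {
  stopifnot(inherits(lib, "raman_library"))
  grid <- common_grid(p)
  out <- matrix(0, nrow(lib$intensities), length(grid))
  for (i in seq_len(nrow(lib$intensities))) {
    s <- preprocess_spectrum(
      raman_spectrum(lib$wavenumbers, lib$intensities[i, ]), p)
    if (isTRUE(s$meta$degenerate)) {
      stop(sprintf("library entry %d is constant and cannot be scaled", i),
           call. = FALSE)
    }
    out[i, ] <- s$intensities
  }
  raman_library(lib$labels, out, grid)
}
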