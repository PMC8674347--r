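# counts are integers in the analytical report: round half away from zero
round_count <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Extrapolate a particle count from the analyzed sub-area to the whole
#' filter
#'
#' When only a fraction of the filtration area is mapped (typically 50%,
#' giving the factor-2 rule), the whole-filter count is estimated as
#' observed / analyzed_fraction, rounded to the nearest integer.
#'
#' @param observed observed particle count (vector allowed).
#' @param analyzed_fraction fraction of the filter area analyzed, in (0, 1].
#' @return Extrapolated integer count(s).
#' @export
extrapolate <- function(observed, analyzed_fraction) {
  if (!(analyzed_fraction > 0 && analyzed_fraction <= 1)) {
    stop("analyzed_fraction must lie in (0, 1]", call. = FALSE)
  }
  round_count(observed / analyzed_fraction)
}

#' Subtract method-blank counts per class
#'
#' Laboratory contamination measured in a method blank is removed class by
#' class; counts are clamped at zero (a blank can exceed a sample count but
#' a negative particle number is meaningless). Classes absent from the blank
#' pass through unchanged.
#'
#' @param sample named numeric vector of per-class counts.
#' @param blank named numeric vector of per-class blank counts.
#' @return Named vector of blank-subtracted counts.
#' @export
subtract_blank <- function(sample, blank) {
  if (length(blank) == 0L) return(sample)
  out <- sample
  shared <- intersect(names(sample), names(blank))
  out[shared] <- pmax(sample[shared] - blank[shared], 0)
  out
}

#' Convert a count to the per-100-mL reporting convention
#'
#' @param count particle count(s) in the analyzed sample.
#' @param sample_volume_mL volume of sample filtered (default 25 mL).
#' @return Integer count(s) per 100 mL.
#' @export
to_per_100mL <- function(count, sample_volume_mL = 25) {
  if (sample_volume_mL <= 0) stop("sample volume must be positive",
                                  call. = FALSE)
  round_count(count * 100 / sample_volume_mL)
}

#' Rough mass concentration from a particle count
#'
#' Order-of-magnitude mass estimate under the convention that all particles
#' are spheres of a common diameter and density: mass per particle is
#' (pi/6) d^3 rho. The count per 100 mL serving is converted to micrograms
#' per kilogram of product assuming the serving has unit density (100 mL of
#' milk is taken as 100 g).
#'
#' @param n_per_100mL particle count per 100 mL serving.
#' @param diameter_um assumed sphere diameter in micrometers (default 10).
#' @param density_g_cm3 assumed polymer density in g/cm^3 (default 1).
#' @param serving_mass_g mass of the 100 mL serving in grams (default 100).
#' @return Mass concentration in micrograms per kg of product
#'   (1000 particles at defaults give about 5.24).
#' @export
mass_estimate <- function(n_per_100mL, diameter_um = 10, density_g_cm3 = 1,
                          serving_mass_g = 100) {
  vol_um3 <- pi / 6 * diameter_um^3           # per sphere
  mass_ug <- n_per_100mL * vol_um3 * 1e-12 * density_g_cm3 * 1e6
  mass_ug / (serving_mass_g / 1000)           # per kg of product
}

#' Digestion / contamination quality-control verdict
#'
#' A procedural blank passes when fewer than 300 retained particles per mm^2
#' of filtration area are present and at most 5% of the surface is covered.
#' A digested sample passes when the density is at most 600 per mm^2 and the
#' coverage at most 30% (an overloaded filter can hide microplastics under
#' organic residue). Boundary semantics follow that wording: the blank
#' density limit is strict, the sample limit inclusive.
#'
#' @param particles_per_mm2 retained-particle density on the filter.
#' @param surface_covered_pct percentage of filter surface covered.
#' @param kind `"blank"` or `"sample"`.
#' @return A list with `pass` (logical), `failed` (character vector naming
#'   the violated criteria, empty on pass) and the inputs.
#' @export
qc_check <- function(particles_per_mm2, surface_covered_pct,
                     kind = c("sample", "blank")) {
  kind <- match.arg(kind)
  failed <- character(0)
  if (kind == "blank") {
    if (!(particles_per_mm2 < 300)) failed <- c(failed, "density")
    if (!(surface_covered_pct <= 5)) failed <- c(failed, "coverage")
  } else {
    if (!(particles_per_mm2 <= 600)) failed <- c(failed, "density")
    if (!(surface_covered_pct <= 30)) failed <- c(failed, "coverage")
  }
  list(kind = kind, pass = length(failed) == 0L, failed = failed,
       particles_per_mm2 = particles_per_mm2,
       surface_covered_pct = surface_covered_pct)
}

#' Fraction of small particles
#'
#' Percentage of particles with a measured surface area strictly below
#' 50 um^2 (about 7 um square-equivalent size). With no particles the
#' fraction is undefined and `NA` is returned, not 0.
#'
#' @param particles a `raman_particles` list (or data.frame with an `area`
#'   column).
#' @return Percentage in [0, 100], or `NA_real_` for an empty input.
#' @export
size_fraction <- function(particles) {
  areas <- if (is.data.frame(particles)) particles$area else
    vapply(particles, `[[`, 0, "area")
  if (length(areas) == 0L) return(NA_real_)
  100 * mean(areas < 50)
}

#' Acquisition-cost ratio between two mapping resolutions
#'
#' Point-by-point mapping time scales with the lattice point count, so
#' changing the step from `step_a` to `step_b` over a fixed area multiplies
#' the number of acquisitions (and the analysis time) by (step_a/step_b)^2
#' — a factor 25 from 5 um to 1 um.
#'
#' @param step_a,step_b lattice steps in micrometers.
#' @return The point-count ratio.
#' @export
scan_point_factor <- function(step_a, step_b) {
  if (step_a <= 0 || step_b <= 0) stop("steps must be positive",
                                       call. = FALSE)
  (step_a / step_b)^2
}

#' Monte-Carlo check of the half-area extrapolation factor
#'
#' Places `n_particles` points uniformly at random on the disc-shaped
#' filtration area, counts them on the full disc and on a randomly oriented
#' half-disc, and averages the full/half count ratio over replicates. For a
#' uniform deposit the expected ratio is close to 2, which justifies the
#' factor-2 extrapolation from a 50% map.
#'
#' @param n_particles particles per replicate (default 200).
#' @param n_reps replicates (default 100).
#' @param seed integer seed.
#' @return A list with `mean_ratio`, the per-replicate `ratios`,
#'   `n_particles` and `n_reps`.
#' @export
extrapolation_factor_sim <- function(n_particles = 200, n_reps = 100,
                                     seed = 1L) {
  set.seed(as.integer(seed))
  ratios <- vapply(seq_len(n_reps), function(r) {
    # uniform on the unit disc
    th <- stats::runif(n_particles, 0, 2 * pi)
    rad <- sqrt(stats::runif(n_particles))
    x <- rad * cos(th); y <- rad * sin(th)
    # half-plane through the centre at a random orientation
    phi <- stats::runif(1, 0, 2 * pi)
    half <- sum(x * cos(phi) + y * sin(phi) >= 0)
    if (half == 0L) return(NA_real_)
    n_particles / half
  }, numeric(1))
  list(mean_ratio = mean(ratios, na.rm = TRUE), ratios = ratios,
       n_particles = n_particles, n_reps = n_reps)
}

#' Build the full quantification report
#'
#' Aggregates a particle list into the analytical report: observed per-class
#' counts, whole-filter extrapolated counts, blank subtraction, per-100-mL
#' figures, the small-size fraction, the QC verdict, the spherical-mass
#' estimate and a provenance block.
#'
#' @param particles a `raman_particles` list.
#' @param analyzed_fraction fraction of the filter area mapped (default 0.5).
#' @param sample_volume_mL filtered sample volume (default 25 mL).
#' @param blank named per-class counts of a method blank, already on the
#'   whole-filter scale; `NULL` for no subtraction.
#' @param filter_area filtration area in mm^2 (default 14), used for the QC
#'   density.
#' @param qc_kind `"sample"` or `"blank"` (selects the QC thresholds).
#' @param surface_covered_pct measured residue coverage for QC; if `NA`, the
#'   particle footprint itself is used as a lower bound.
#' @param drop_review drop review-flagged low-confidence particles (whose
#'   mean confidence is below `review_confidence`) before counting.
#' @param review_confidence confidence cut used with `drop_review`.
#' @param config,seeds free-form provenance recorded in the report.
#' @return An object of class `quant_report`.
#' @export
quantify_particles <- function(particles, analyzed_fraction = 0.5,
                               sample_volume_mL = 25, blank = NULL,
                               filter_area = 14,
                               qc_kind = c("sample", "blank"),
                               surface_covered_pct = NA_real_,
                               drop_review = FALSE,
                               review_confidence = 0.5,
                               config = list(), seeds = list()) {
  qc_kind <- match.arg(qc_kind)
  if (drop_review && length(particles) > 0L) {
    keep <- vapply(particles, function(p) {
      is.na(p$mean_confidence) || p$mean_confidence >= review_confidence
    }, logical(1))
    particles <- structure(particles[keep], class = "raman_particles")
  }
  cls <- vapply(particles, `[[`, "", "class")
  observed <- table(factor(cls, levels = sort(unique(cls))))
  observed <- stats::setNames(as.numeric(observed), names(observed))
  extrapolated <- extrapolate(observed, analyzed_fraction)
  after_blank <- subtract_blank(extrapolated,
                                if (is.null(blank)) numeric(0) else blank)
  per_100 <- to_per_100mL(after_blank, sample_volume_mL)
  total_100 <- sum(per_100)

  footprint_mm2 <- sum(vapply(particles, `[[`, 0, "area")) / 1e6
  analyzed_mm2 <- filter_area * analyzed_fraction
  density <- length(particles) / analyzed_mm2
  coverage <- if (is.na(surface_covered_pct)) {
    100 * footprint_mm2 / analyzed_mm2
  } else surface_covered_pct

  structure(
    list(
      per_class_counts = as.list(observed),
      extrapolated_counts = as.list(extrapolated),
      per_100mL = as.list(per_100),
      total_per_100mL = total_100,
      pct_small = size_fraction(particles),
      mass_estimate_ug_per_kg = mass_estimate(total_100),
      qc = qc_check(density, coverage, qc_kind),
      particles = lapply(particles, unclass),
      sample_volume_mL = sample_volume_mL,
      analyzed_fraction = analyzed_fraction,
      filter_area_mm2 = filter_area,
      provenance = list(config = config, seeds = seeds)
    ),
    class = "quant_report"
  )
}

#' @export
print.quant_report <- function(x, ...) {
  cat("<quant_report>\n")
  cat(sprintf("  particles observed: %d (analyzed fraction %.2f)\n",
              length(x$particles), x$analyzed_fraction))
  cat(sprintf("  total per 100 mL: %d\n", as.integer(x$total_per_100mL)))
  if (length(x$per_100mL) > 0L) {
    cat("  per class (per 100 mL):",
        paste(sprintf("%s=%d", names(x$per_100mL),
                      as.integer(unlist(x$per_100mL))), collapse = ", "),
        "\n")
  }
  cat(sprintf("  small (< 50 um2): %s\n",
              if (is.na(x$pct_small)) "undefined (no particles)"
              else sprintf("%.1f%%", x$pct_small)))
  cat(sprintf("  mass estimate: %.2f ug/kg (10 um spheres, density 1)\n",
              x$mass_estimate_ug_per_kg))
  cat(sprintf("  QC (%s): %s\n", x$qc$kind,
              if (x$qc$pass) "pass"
              else paste("fail:", paste(x$qc$failed, collapse = ", "))))
  invisible(x)
}
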