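#' Default Raman band tables for the 11 classes
#'
#' One table per class: band center (cm^-1), full width (cm^-1, Gaussian
#' sigma) and relative height. Band positions are canonical literature-style
#' polymer Raman bands (e.g. the 1001 cm^-1 polystyrene ring breathing, the
#' 1295/1440 cm^-1 polyethylene CH2 twist/bend pair, the 732 cm^-1 PTFE CF2
#' stretch); they are a generator design choice, user-overridable, and not
#' claimed to reproduce any instrument library. The stearate table is
#' derived from the polyethylene table (shared aliphatic backbone, bands
#' slightly shifted plus a carboxylate band near 1100 cm^-1), which makes
#' stearate the deliberately PE-confusable decoy class. NMP is broad, weak
#' humps emulating fluorescent organic residue; its silicon-background
#' variant is handled by [generate_spectrum()].
#'
#' @return Named list of data.frames with columns `center`, `width`,
#'   `height`.
#' @export
default_peak_table <- function() {
  pe <- data.frame(
    center = c(1062, 1130, 1296, 1418, 1440),
    width  = c(6, 6, 7, 8, 9),
    height = c(0.55, 0.75, 1.0, 0.35, 0.9))
  stearate <- pe
  stearate$center <- pe$center + c(4, 4, 6, 5, 8)
  stearate$height <- pe$height * c(0.9, 1.0, 0.8, 0.5, 1.0)
  stearate <- rbind(stearate,
                    data.frame(center = 1102, width = 8, height = 0.7))
  list(
    NMP = data.frame(
      center = c(900, 1080, 1350, 1590),
      width  = c(90, 70, 80, 70),
      height = c(0.4, 0.5, 0.9, 1.0)),
    PA = data.frame(
      center = c(930, 1080, 1128, 1300, 1442, 1635),
      width  = c(8, 7, 6, 8, 9, 10),
      height = c(0.5, 0.6, 0.8, 0.7, 1.0, 0.65)),
    PE = pe,
    PES = data.frame(
      center = c(632, 702, 857, 1096, 1117, 1289, 1614, 1730),
      width  = c(7, 7, 8, 7, 7, 8, 7, 10),
      height = c(0.45, 0.35, 0.5, 0.6, 0.55, 0.65, 1.0, 0.75)),
    PLA = data.frame(
      center = c(873, 1043, 1128, 1293, 1454, 1768),
      width  = c(7, 7, 7, 8, 9, 10),
      height = c(1.0, 0.55, 0.45, 0.5, 0.6, 0.55)),
    PMMA = data.frame(
      center = c(600, 813, 988, 1450, 1730),
      width  = c(8, 8, 8, 10, 10),
      height = c(0.6, 1.0, 0.4, 0.7, 0.65)),
    PP = data.frame(
      center = c(809, 841, 973, 998, 1152, 1330, 1458),
      width  = c(6, 6, 6, 6, 7, 8, 9),
      height = c(1.0, 0.8, 0.6, 0.55, 0.5, 0.45, 0.7)),
    PS = data.frame(
      center = c(620, 795, 1001, 1031, 1155, 1583, 1602),
      width  = c(7, 7, 5, 6, 7, 7, 6),
      height = c(0.4, 0.3, 1.0, 0.5, 0.3, 0.35, 0.7)),
    PTFE = data.frame(
      center = c(732, 1216, 1302, 1381),
      width  = c(6, 8, 8, 8),
      height = c(1.0, 0.35, 0.4, 0.3)),
    PU = data.frame(
      center = c(863, 1313, 1444, 1535, 1617, 1730),
      width  = c(8, 8, 9, 9, 8, 10),
      height = c(0.4, 0.6, 0.7, 0.55, 1.0, 0.8)),
    stearate = stearate
  )
}

#' The acquisition wavenumber axis
#'
#' The raw instrument axis spans 550-2000 cm^-1, slightly wider than the
#' 559-1990 cm^-1 working grid so that regridding never extrapolates.
#'
#' @param by sampling interval in cm^-1 (default 2.5).
#' @return Numeric axis.
#' @export
acquisition_axis <- function(by = 2.5) seq(550, 2000, by = by)

#' Generate one labeled synthetic spectrum
#'
#' A class spectrum is the sum of its table's Gaussian bands, on top of a
#' broad polynomial fluorescence baseline, with shot-like noise whose
#' variance scales with the local intensity; `snr` is the ratio of the
#' strongest band height to the noise standard deviation at that point. At
#' infinite snr and zero baseline the pure band sum is returned.
#'
#' @param class one of [mp_classes()].
#' @param snr peak signal-to-noise ratio (default 20; `Inf` for noiseless).
#' @param baseline polynomial coefficients (intercept first) evaluated on
#'   the axis rescaled to [0, 1]; default a gentle fluorescence slope.
#' @param seed optional integer seed (draws are reproducible given it).
#' @param peak_table band table list (default [default_peak_table()]).
#' @param wavenumbers acquisition axis (default [acquisition_axis()]).
#' @param amplitude height of the strongest band in detector counts.
#' @return A labeled [raman_spectrum()].
#' @export
generate_spectrum <- function(class, snr = 20,
                              baseline = c(50, 30, -20), seed = NULL,
                              peak_table = default_peak_table(),
                              wavenumbers = acquisition_axis(),
                              amplitude = 100) {
  if (!class %in% names(peak_table)) {
    stop(sprintf("no peak table for class '%s'", class), call. = FALSE)
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  bands <- peak_table[[class]]
  signal <- band_sum(wavenumbers, bands) * amplitude
  u <- (wavenumbers - min(wavenumbers)) /
    (max(wavenumbers) - min(wavenumbers))
  bg <- rep(0, length(u))
  for (k in seq_along(baseline)) bg <- bg + baseline[k] * u^(k - 1)
  total <- signal + bg
  if (is.finite(snr)) {
    # shot-like: variance proportional to local intensity, normalised so
    # the sd at the strongest band top equals amplitude / snr
    ref <- max(total)
    sd_i <- (amplitude / snr) * sqrt(pmax(total, 0) / max(ref, 1e-12))
    total <- total + stats::rnorm(length(total), 0, sd_i)
  }
  raman_spectrum(wavenumbers, total, label = class,
                 meta = list(snr = snr, class = class))
}

band_sum <- function(wn, bands) {
  out <- rep(0, length(wn))
  for (b in seq_len(nrow(bands))) {
    out <- out + bands$height[b] *
      exp(-0.5 * ((wn - bands$center[b]) / bands$width[b])^2)
  }
  out
}

#' Generate a balanced labeled training library
#'
#' Each entry draws its snr uniformly from `snr_range` (spanning a wide
#' range of signal quality, from clean reference-like spectra to noisy
#' in-matrix ones) and a random fluorescence baseline.
#'
#' @param classes class labels to include (default all 11).
#' @param n_per_class spectra per class (default 50).
#' @param snr_range range of peak signal-to-noise (default c(15, 40)).
#' @param seed integer seed; the library is a pure function of the
#'   arguments and the seed.
#' @param peak_table band table list.
#' @param wavenumbers acquisition axis.
#' @return A raw (unpreprocessed) [raman_library()].
#' @export
generate_training_library <- function(classes = mp_classes(),
                                      n_per_class = 50,
                                      snr_range = c(15, 40), seed = 1L,
                                      peak_table = default_peak_table(),
                                      wavenumbers = acquisition_axis()) {
  set.seed(as.integer(seed))
  n <- length(classes) * n_per_class
  intens <- matrix(0, n, length(wavenumbers))
  labels <- character(n)
  i <- 0L
  for (cl in classes) {
    for (k in seq_len(n_per_class)) {
      i <- i + 1L
      s <- generate_spectrum(
        cl, snr = stats::runif(1, snr_range[1], snr_range[2]),
        baseline = c(stats::runif(1, 20, 120), stats::runif(1, -40, 60),
                     stats::runif(1, -40, 40)),
        peak_table = peak_table, wavenumbers = wavenumbers)
      intens[i, ] <- s$intensities
      labels[i] <- cl
    }
  }
  raman_library(labels, intens, wavenumbers)
}

#' Describe a synthetic filter scene
#'
#' The scene emulates the mapped portion of a digested-sample filter: a
#' rectangular window of a 5-um lattice carrying polymer particles (discs),
#' elongated cellulose-like fibers (NMP), organic residue blobs (NMP) and a
#' silicon-background floor, with a dropout probability for missed
#' acquisitions. Defaults mirror the reference geometry (14 mm^2 filter,
#' half mapped, 5 um step); tests use smaller windows.
#'
#' @param width_um,height_um mapped window size in micrometers.
#' @param step lattice pitch (default 5 um).
#' @param particles data.frame with columns `class`, `diameter` (um) and
#'   optionally `x`, `y` (um; NA = place at random). `NULL` for none.
#' @param n_random_particles particles to place uniformly at random when
#'   `particles` is NULL (classes drawn from `random_classes`).
#' @param random_classes classes sampled for random particles.
#' @param diameter_range diameter range (um) for random particles; at least
#'   one lattice step.
#' @param n_fibers elongated NMP fiber objects.
#' @param n_residue broad NMP residue blobs.
#' @param dropout_prob probability that a pixel's acquisition is missed
#'   (recorded as a constant, degenerate spectrum), in [0, 1). Dropout is
#'   constrained so no ground-truth particle is split under the gap-2 rule
#'   nor erased entirely.
#' @param snr_range per-pixel signal quality range.
#' @param baseline_ranges list of length-2 ranges for the polynomial
#'   baseline coefficients.
#' @param min_separation_steps minimum pairwise center distance between
#'   particles, in lattice steps beyond the sum of radii (default 4, so
#'   distinct ground-truth particles stay distinct under gap-2 clustering).
#' @param analyzed_fraction,filter_area filter geometry metadata.
#' @param seed integer seed.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(width_um = 500, height_um = 500, step = 5,
                       particles = NULL, n_random_particles = 20,
                       random_classes = polymer_classes(),
                       diameter_range = c(8, 25),
                       n_fibers = 2, n_residue = 3,
                       dropout_prob = 0.1,
                       snr_range = c(15, 40),
                       baseline_ranges = list(c(20, 120), c(-40, 60),
                                              c(-40, 40)),
                       min_separation_steps = 4,
                       analyzed_fraction = 0.5, filter_area = 14,
                       seed = 1L) {
  if (!(dropout_prob >= 0 && dropout_prob < 1)) {
    stop("dropout_prob must lie in [0, 1)", call. = FALSE)
  }
  if (diameter_range[1] < step) {
    stop("particle diameters must be at least one lattice step",
         call. = FALSE)
  }
  structure(
    list(width_um = width_um, height_um = height_um, step = step,
         particles = particles, n_random_particles = n_random_particles,
         random_classes = random_classes, diameter_range = diameter_range,
         n_fibers = n_fibers, n_residue = n_residue,
         dropout_prob = dropout_prob, snr_range = snr_range,
         baseline_ranges = baseline_ranges,
         min_separation_steps = min_separation_steps,
         analyzed_fraction = analyzed_fraction, filter_area = filter_area,
         seed = as.integer(seed)),
    class = "scene_spec"
  )
}

# a pixel belongs to a disc iff its center lies strictly inside
rasterize_disc <- function(cx, cy, diameter, gx, gy) {
  which((gx - cx)^2 + (gy - cy)^2 < (diameter / 2)^2)
}

#' Generate a synthetic filter map with ground truth
#'
#' Rasterizes the scene's particles onto the lattice (a pixel belongs to a
#' disc iff its center lies inside), draws one synthetic spectrum per pixel
#' (polymer, fiber/residue NMP, or silicon background), applies dropout as
#' degenerate constant spectra, and returns the map together with the exact
#' ground truth. Random particle placement snaps centers to lattice points
#' and enforces the scene's minimum separation, so every ground-truth
#' particle rasterizes to at least one pixel and distinct particles remain
#' distinct under gap-2 clustering; overlapping particles of different
#' classes are rejected as an ambiguous scene.
#'
#' @param scene a [scene_spec()].
#' @return A list with `map` (raw [raman_map()]), `truth` (data.frame of
#'   per-pixel labels: `x`, `y`, `label`, `dropout`) and `particles`
#'   (ground-truth list: class, center, diameter, pixel indices, area).
#' @export
generate_map <- function(scene) {
  stopifnot(inherits(scene, "scene_spec"))
  set.seed(scene$seed)
  step <- scene$step
  gx_v <- seq(0, scene$width_um - step, by = step) + step / 2
  gy_v <- seq(0, scene$height_um - step, by = step) + step / 2
  grid <- expand.grid(x = gx_v, y = gy_v)
  gx <- grid$x; gy <- grid$y
  n_pix <- length(gx)

  parts <- scene$particles
  if (is.null(parts)) {
    parts <- place_random_particles(scene, gx_v, gy_v)
  } else {
    parts$x <- as.numeric(parts$x); parts$y <- as.numeric(parts$y)
    miss <- is.na(parts$x) | is.na(parts$y)
    if (any(miss)) {
      filled <- place_random_particles(scene, gx_v, gy_v,
                                       n = sum(miss),
                                       classes = parts$class[miss],
                                       diameters = parts$diameter[miss],
                                       existing = parts[!miss, , drop = FALSE])
      parts[miss, c("x", "y")] <- filled[, c("x", "y")]
    }
  }

  label <- rep("background", n_pix)
  owner <- rep(NA_integer_, n_pix)
  truth_particles <- list()
  for (pidx in seq_len(nrow(parts))) {
    pix <- rasterize_disc(parts$x[pidx], parts$y[pidx],
                          parts$diameter[pidx], gx, gy)
    if (length(pix) == 0L) {
      # snap to the nearest lattice point; with diameter >= step the center
      # pixel is then strictly inside the disc
      j <- which.min((gx - parts$x[pidx])^2 + (gy - parts$y[pidx])^2)
      parts$x[pidx] <- gx[j]; parts$y[pidx] <- gy[j]
      pix <- rasterize_disc(parts$x[pidx], parts$y[pidx],
                            parts$diameter[pidx], gx, gy)
    }
    clash <- pix[!is.na(owner[pix]) &
                 parts$class[owner[pix]] != parts$class[pidx]]
    if (length(clash) > 0L) {
      stop("scene error: overlapping particles of different classes (ambiguous ground truth)",
           call. = FALSE)
    }
    owner[pix] <- pidx
    label[pix] <- parts$class[pidx]
    truth_particles[[pidx]] <- list(
      class = parts$class[pidx],
      center = c(parts$x[pidx], parts$y[pidx]),
      diameter = parts$diameter[pidx],
      pixels = pix, n_pixels = length(pix),
      area = length(pix) * step^2)
  }

  # fibers: thick random polylines of NMP; residue: broad NMP discs
  is_fiber <- rep(FALSE, n_pix)
  for (f in seq_len(scene$n_fibers)) {
    fib <- rasterize_fiber(scene, gx, gy)
    fib <- fib[label[fib] == "background"]
    is_fiber[fib] <- TRUE
    label[fib] <- "NMP"
  }
  for (rb in seq_len(scene$n_residue)) {
    cx <- stats::runif(1, 0, scene$width_um)
    cy <- stats::runif(1, 0, scene$height_um)
    d <- stats::runif(1, 3 * step, 8 * step)
    pix <- rasterize_disc(cx, cy, d, gx, gy)
    pix <- pix[label[pix] == "background"]
    label[pix] <- "NMP"
  }

  dropout <- draw_dropout(scene, truth_particles, gx, gy, n_pix)

  ptab <- default_peak_table()
  axis <- acquisition_axis()
  intens <- matrix(0, n_pix, length(axis))
  for (i in seq_len(n_pix)) {
    if (dropout[i]) {
      # a desynchronized acquisition still records a frame: constant level
      intens[i, ] <- stats::runif(1, 0, 50)
      next
    }
    snr <- stats::runif(1, scene$snr_range[1], scene$snr_range[2])
    bl <- vapply(scene$baseline_ranges,
                 function(rg) stats::runif(1, rg[1], rg[2]), numeric(1))
    cl <- if (label[i] == "background") "NMP" else label[i]
    amp <- if (label[i] == "background") 30 else 100
    s <- generate_spectrum(cl, snr = snr, baseline = bl, amplitude = amp,
                           peak_table = ptab, wavenumbers = axis)
    intens[i, ] <- s$intensities
  }

  map <- raman_map(acquisition_axis(), intens, gx, gy, step = step,
                   analyzed_fraction = scene$analyzed_fraction,
                   filter_area = scene$filter_area)
  list(
    map = map,
    truth = data.frame(x = gx, y = gy, label = label, dropout = dropout,
                       stringsAsFactors = FALSE),
    particles = truth_particles
  )
}

place_random_particles <- function(scene, gx_v, gy_v, n = NULL,
                                   classes = NULL, diameters = NULL,
                                   existing = NULL) {
  if (is.null(n)) n <- scene$n_random_particles
  if (is.null(classes)) {
    classes <- sample(scene$random_classes, n, replace = TRUE)
  }
  if (is.null(diameters)) {
    diameters <- stats::runif(n, scene$diameter_range[1],
                              scene$diameter_range[2])
  }
  placed_x <- if (is.null(existing)) numeric(0) else existing$x
  placed_y <- if (is.null(existing)) numeric(0) else existing$y
  placed_d <- if (is.null(existing)) numeric(0) else existing$diameter
  xs <- numeric(n); ys <- numeric(n)
  sep_extra <- scene$min_separation_steps * scene$step
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(2000L)) {
      cx <- sample(gx_v, 1); cy <- sample(gy_v, 1)   # lattice-point centers
      need <- (diameters[i] + placed_d) / 2 + sep_extra
      if (length(placed_x) == 0L ||
          all(sqrt((cx - placed_x)^2 + (cy - placed_y)^2) >= need)) {
        ok <- TRUE; break
      }
    }
    if (!ok) {
      stop("could not place particles with the required separation; enlarge the scene or reduce the count",
           call. = FALSE)
    }
    xs[i] <- cx; ys[i] <- cy
    placed_x <- c(placed_x, cx); placed_y <- c(placed_y, cy)
    placed_d <- c(placed_d, diameters[i])
  }
  data.frame(class = classes, diameter = diameters, x = xs, y = ys,
             stringsAsFactors = FALSE)
}

rasterize_fiber <- function(scene, gx, gy) {
  x0 <- stats::runif(1, 0, scene$width_um)
  y0 <- stats::runif(1, 0, scene$height_um)
  ang <- stats::runif(1, 0, pi)
  len <- stats::runif(1, 0.3, 0.9) * max(scene$width_um, scene$height_um)
  hw <- stats::runif(1, 0.6, 1.2) * scene$step    # half-width
  x1 <- x0 + len * cos(ang); y1 <- y0 + len * sin(ang)
  # distance from each pixel center to the segment
  vx <- x1 - x0; vy <- y1 - y0
  t <- pmin(pmax(((gx - x0) * vx + (gy - y0) * vy) / (vx^2 + vy^2), 0), 1)
  d2 <- (gx - (x0 + t * vx))^2 + (gy - (y0 + t * vy))^2
  which(d2 <= hw^2)
}

# dropout that never splits a ground-truth particle under the gap-2 rule
# and never erases one: candidate pixels are drawn everywhere, then dropped
# particle pixels are restored (in draw order) until the particle's
# remaining pixels are gap-2 connected and non-empty
draw_dropout <- function(scene, truth_particles, gx, gy, n_pix) {
  dropout <- stats::runif(n_pix) < scene$dropout_prob
  if (!any(dropout) || length(truth_particles) == 0L) return(dropout)
  step <- scene$step
  for (tp in truth_particles) {
    pix <- tp$pixels
    repeat {
      kept <- pix[!dropout[pix]]
      if (length(kept) > 0L && gap_connected(gx[kept], gy[kept], step)) break
      dropped <- pix[dropout[pix]]
      dropout[dropped[1L]] <- FALSE
    }
  }
  dropout
}

# TRUE iff the pixel set forms one component under Chebyshev gap 2
gap_connected <- function(x, y, step) {
  if (length(x) <= 1L) return(TRUE)
  comp <- lattice_components(x, y, step, max_gap = 2, metric = "chebyshev")
  length(unique(comp)) == 1L
}
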