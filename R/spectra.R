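#' The closed polymer class inventory
#'
#' The eleven classes the pixel classifier knows: nine polymers, the stearate
#' decoy class (glove-derived fatty-acid salts whose Raman signal closely
#' resembles polyethylene), and the non-microplastic class NMP (organic
#' digestion residue, cellulose fiber, silicon filter background).
#'
#' @return Character vector of the 11 allowed class labels.
#' @export
mp_classes <- function() {
  c("NMP", "PA", "PE", "PES", "PLA", "PMMA", "PP", "PS", "PTFE", "PU",
    "stearate")
}

#' Microplastic classes (everything except NMP)
#' @param merge_stearate_nmp if TRUE, stearate is treated as non-microplastic.
#' @return Character vector of particle-forming class labels.
#' @export
polymer_classes <- function(merge_stearate_nmp = FALSE) {
  cls <- setdiff(mp_classes(), "NMP")
  if (merge_stearate_nmp) cls <- setdiff(cls, "stearate")
  cls
}

#' Construct a single Raman spectrum
#'
#' @param wavenumbers numeric vector of Raman shifts (cm^-1), strictly
#'   increasing.
#' @param intensities numeric vector of detector counts, same length; all
#'   values must be finite.
#' @param position optional numeric length-2 vector (x, y) in micrometers.
#' @param label optional class label.
#' @param meta free-form named list of metadata.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, position = NULL,
                           label = NULL, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2L) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("non-finite intensities are not allowed", call. = FALSE)
  }
  if (!is.null(position)) {
    position <- as.numeric(position)
    if (length(position) != 2L || any(!is.finite(position))) {
      stop("position must be a finite (x, y) pair in micrometers",
           call. = FALSE)
    }
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         position = position, label = label, meta = meta),
    class = "raman_spectrum"
  )
}

#' @export
print.raman_spectrum <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm-1",
              length(x$wavenumbers), rng[1], rng[2]))
  if (!is.null(x$position)) {
    cat(sprintf(", at (%.1f, %.1f) um", x$position[1], x$position[2]))
  }
  if (!is.null(x$label)) cat(sprintf(", label %s", x$label))
  if (isTRUE(x$meta$degenerate)) cat(" [degenerate]")
  cat("\n")
  invisible(x)
}

#' Construct a regular-grid spectral map
#'
#' A map holds one spectrum per occupied lattice position. All spectra share
#' one wavenumber axis; intensities are stored as a pixels x wavenumbers
#' matrix. Positions must lie on the lattice `origin + k * step` (tolerance
#' 1e-6 * step) with no duplicates; the lattice may be arbitrarily masked
#' (pixels can be missing).
#'
#' @param wavenumbers shared wavenumber axis (cm^-1), strictly increasing.
#' @param intensities numeric matrix, one row per pixel.
#' @param x,y pixel coordinates in micrometers.
#' @param step lattice pitch in micrometers; if NULL, inferred as the minimal
#'   positive coordinate difference.
#' @param analyzed_fraction fraction of the total filter area covered by the
#'   map(s), in (0, 1].
#' @param filter_area total filtration area in mm^2 (default 14).
#' @param degenerate optional logical vector flagging constant (zero
#'   spectral variance) pixels, e.g. missed acquisitions.
#' @return An object of class `raman_map`.
#' @export
raman_map <- function(wavenumbers, intensities, x, y, step = NULL,
                      analyzed_fraction = 0.5, filter_area = 14,
                      degenerate = NULL) {
  wavenumbers <- as.numeric(wavenumbers)
  if (any(diff(wavenumbers) <= 0)) {
    stop("wavenumbers must be strictly increasing", call. = FALSE)
  }
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensity matrix must have one column per wavenumber",
         call. = FALSE)
  }
  x <- as.numeric(x); y <- as.numeric(y)
  n <- nrow(intensities)
  if (length(x) != n || length(y) != n) {
    stop("x and y must have one entry per pixel", call. = FALSE)
  }
  if (any(!is.finite(intensities))) {
    stop("non-finite intensities are not allowed", call. = FALSE)
  }
  if (is.null(step)) step <- infer_step(x, y)
  check_lattice(x, y, step)
  if (anyDuplicated(paste(round((x - min(x)) / step),
                          round((y - min(y)) / step)))) {
    stop("duplicate pixel positions in map", call. = FALSE)
  }
  if (!(analyzed_fraction > 0 && analyzed_fraction <= 1)) {
    stop("analyzed_fraction must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(degenerate)) {
    degenerate <- apply(intensities, 1L, function(v) max(v) == min(v))
  }
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         x = x, y = y, step = step,
         analyzed_fraction = analyzed_fraction, filter_area = filter_area,
         degenerate = as.logical(degenerate)),
    class = "raman_map"
  )
}

#' @export
print.raman_map <- function(x, ...) {
  cat(sprintf(
    "<raman_map> %d pixels, step %.3g um, %d spectral points (%.0f-%.0f cm-1)\n",
    nrow(x$intensities), x$step, length(x$wavenumbers),
    min(x$wavenumbers), max(x$wavenumbers)))
  cat(sprintf("  analyzed fraction %.2f of %.3g mm2 filter; %d degenerate pixel(s)\n",
              x$analyzed_fraction, x$filter_area, sum(x$degenerate)))
  invisible(x)
}

#' Extract one pixel of a map as a spectrum
#' @param map a `raman_map`.
#' @param i pixel index.
#' @return A `raman_spectrum` with the pixel's position attached.
#' @export
map_spectrum <- function(map, i) {
  raman_spectrum(map$wavenumbers, map$intensities[i, ],
                 position = c(map$x[i], map$y[i]),
                 meta = list(degenerate = map$degenerate[i]))
}

# smallest positive difference among sorted unique coordinates of both axes
infer_step <- function(x, y) {
  d <- c(diff(sort(unique(x))), diff(sort(unique(y))))
  d <- d[d > 0]
  if (length(d) == 0L) return(1)
  min(d)
}

check_lattice <- function(x, y, step) {
  tol <- 1e-6 * step
  ox <- min(x); oy <- min(y)
  kx <- (x - ox) / step
  ky <- (y - oy) / step
  bad <- abs(kx - round(kx)) > tol / step | abs(ky - round(ky)) > tol / step
  if (any(bad)) {
    stop(sprintf("position (%g, %g) does not lie on the %g um lattice",
                 x[which(bad)[1]], y[which(bad)[1]], step), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a labeled spectral training library
#'
#' @param labels character vector of class labels, each in [mp_classes()].
#' @param intensities numeric matrix, one row per entry.
#' @param wavenumbers shared wavenumber axis.
#' @return An object of class `raman_library`.
#' @export
raman_library <- function(labels, intensities, wavenumbers) {
  labels <- as.character(labels)
  intensities <- as.matrix(intensities)
  wavenumbers <- as.numeric(wavenumbers)
  if (nrow(intensities) != length(labels)) {
    stop("one label per spectrum required", call. = FALSE)
  }
  if (ncol(intensities) != length(wavenumbers)) {
    stop("intensity matrix must match the wavenumber axis", call. = FALSE)
  }
  bad <- setdiff(unique(labels), mp_classes())
  if (length(bad) > 0L) {
    stop(sprintf("unknown class label(s) %s; allowed classes are: %s",
                 paste(bad, collapse = ", "),
                 paste(mp_classes(), collapse = ", ")), call. = FALSE)
  }
  tab <- table(labels)
  if (length(tab) < 2L) {
    stop("a training library needs at least 2 classes", call. = FALSE)
  }
  if (any(tab < 2L)) {
    stop("every present class needs at least 2 spectra", call. = FALSE)
  }
  structure(
    list(labels = labels, intensities = intensities,
         wavenumbers = wavenumbers, classes = sort(unique(labels))),
    class = "raman_library"
  )
}

#' @export
print.raman_library <- function(x, ...) {
  cat(sprintf("<raman_library> %d spectra, %d classes, %d spectral points\n",
              length(x$labels), length(x$classes), length(x$wavenumbers)))
  print(table(x$labels))
  invisible(x)
}
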