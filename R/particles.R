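#' Group classified pixels into particles with the gap-tolerant rule
#'
#' For each polymer class independently, a graph is built on that class's
#' pixels and two pixels are joined when their lattice distance is at most
#' `max_gap` (default 2, in lattice units). Connected components of this
#' graph are the particles: a gap of one missed or misclassified pixel
#' between two same-class pixels does not split a particle. Classes in
#' `exclude` (NMP by default) never form particles.
#'
#' The default metric is Chebyshev distance in lattice steps (diagonal
#' neighbours at distance 1), the natural 8-connectivity generalisation;
#' Euclidean-in-steps is available as an alternative.
#'
#' @param pixels data.frame of pixel classifications as returned by
#'   [predict.raman_classifier()] (columns `x`, `y`, `class`, and optionally
#'   `confidence`).
#' @param step lattice pitch in micrometers.
#' @param max_gap maximum lattice distance joining two same-class pixels.
#' @param exclude classes that form no particles (default `"NMP"`).
#' @param metric `"chebyshev"` (default) or `"euclidean"` lattice distance.
#' @param map optional preprocessed [raman_map()]; when supplied, each
#'   particle carries the spectrum of its highest-confidence member pixel as
#'   `representative_spectrum`.
#' @return A list of particles (class `raman_particles`); each particle is a
#'   list with `class`, `pixels` (n x 2 matrix of x, y in um), `n_pixels`,
#'   `area` (um^2), `size` (um, square-equivalent side), `diameter_equiv`
#'   (um, circular-equivalent), `small` (area < 50 um^2), `centroid`,
#'   `mean_confidence`, `max_confidence` and optionally
#'   `representative_spectrum`.
#' @export
cluster_particles <- function(pixels, step, max_gap = 2,
                              exclude = "NMP",
                              metric = c("chebyshev", "euclidean"),
                              map = NULL) {
  metric <- match.arg(metric)
  stopifnot(is.data.frame(pixels), all(c("x", "y", "class") %in% names(pixels)))
  if (nrow(pixels) > 0L) check_lattice(pixels$x, pixels$y, step)
  keep <- !(pixels$class %in% exclude)
  px <- pixels[keep, , drop = FALSE]
  particles <- list()
  for (cl in sort(unique(px$class))) {
    sub <- px[px$class == cl, , drop = FALSE]
    comp <- lattice_components(sub$x, sub$y, step, max_gap, metric)
    for (k in sort(unique(comp))) {
      members <- sub[comp == k, , drop = FALSE]
      particles[[length(particles) + 1L]] <-
        build_particle(cl, members, step, map)
    }
  }
  structure(particles, class = "raman_particles")
}

# connected components under the gap rule; neighbour search is bucketed on
# integer lattice coordinates so only the (2*max_gap+1)^2 offset window is
# scanned per pixel (linear in pixels for fixed max_gap)
lattice_components <- function(x, y, step, max_gap, metric) {
  n <- length(x)
  if (n == 0L) return(integer(0))
  ix <- round((x - min(x)) / step)
  iy <- round((y - min(y)) / step)
  key <- paste(ix, iy)
  lookup <- split(seq_len(n), key)
  g <- max_gap
  offsets <- expand.grid(dx = -g:g, dy = -g:g)
  offsets <- offsets[!(offsets$dx == 0 & offsets$dy == 0), ]
  if (metric == "euclidean") {
    offsets <- offsets[sqrt(offsets$dx^2 + offsets$dy^2) <= g + 1e-9, ]
  }
  from <- integer(0); to <- integer(0)
  for (r in seq_len(nrow(offsets))) {
    nb_key <- paste(ix + offsets$dx[r], iy + offsets$dy[r])
    hit <- match(nb_key, names(lookup))
    found <- which(!is.na(hit))
    for (i in found) {
      j <- lookup[[hit[i]]]
      from <- c(from, rep.int(i, length(j)))
      to <- c(to, j)
    }
  }
  gr <- igraph::graph_from_edgelist(
    cbind(from, to), directed = FALSE)
  gr <- igraph::add_vertices(gr, max(0L, n - igraph::vcount(gr)))
  igraph::components(gr)$membership[seq_len(n)]
}

build_particle <- function(cl, members, step, map = NULL) {
  n <- nrow(members)
  area <- n * step^2
  conf <- if ("confidence" %in% names(members)) members$confidence else
    rep(NA_real_, n)
  p <- list(
    class = cl,
    pixels = cbind(x = members$x, y = members$y),
    n_pixels = n,
    area = area,
    size = sqrt(area),
    diameter_equiv = sqrt(4 * area / pi),
    small = area < 50,
    centroid = c(mean(members$x), mean(members$y)),
    mean_confidence = mean(conf),
    max_confidence = if (all(is.na(conf))) NA_real_ else max(conf)
  )
  if (!is.null(map)) {
    best <- if (all(is.na(conf))) 1L else which.max(conf)
    i <- which(abs(map$x - members$x[best]) < 1e-9 * step &
               abs(map$y - members$y[best]) < 1e-9 * step)
    if (length(i) == 1L) {
      p$representative_spectrum <- list(
        wavenumbers = map$wavenumbers,
        intensities = as.numeric(map$intensities[i, ]))
    }
  }
  class(p) <- "raman_particle"
  p
}

#' Recompute the size metrics of a particle
#'
#' Area is pixel count times step squared; the reported size is the
#' square-equivalent side sqrt(area), so the `small` flag (area strictly
#' below 50 um^2) corresponds to a size below about 7 um. A
#' circular-equivalent diameter sqrt(4A/pi) is also filled for comparability
#' with optical sizing.
#'
#' @param p a `raman_particle`.
#' @param step lattice pitch in micrometers.
#' @return The particle with `area`, `size`, `diameter_equiv` and `small`
#'   refilled.
#' @export
particle_metrics <- function(p, step) {
  stopifnot(inherits(p, "raman_particle"))
  p$area <- p$n_pixels * step^2
  p$size <- sqrt(p$area)
  p$diameter_equiv <- sqrt(4 * p$area / pi)
  p$small <- p$area < 50
  p
}

#' @export
print.raman_particles <- function(x, ...) {
  cat(sprintf("<raman_particles> %d particle(s)\n", length(x)))
  if (length(x) > 0L) print(table(vapply(x, `[[`, "", "class")))
  invisible(x)
}

#' Flatten a particle list into a data.frame
#' @param particles a `raman_particles` list.
#' @return One row per particle with class, pixel count, area, size,
#'   equivalent diameter, small flag, centroid and confidence summaries.
#' @export
particles_df <- function(particles) {
  if (length(particles) == 0L) {
    return(data.frame(class = character(0), n_pixels = integer(0),
                      area = numeric(0), size = numeric(0),
                      diameter_equiv = numeric(0), small = logical(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      mean_confidence = numeric(0)))
  }
  do.call(rbind, lapply(particles, function(p) {
    data.frame(class = p$class, n_pixels = p$n_pixels, area = p$area,
               size = p$size, diameter_equiv = p$diameter_equiv,
               small = p$small, centroid_x = p$centroid[1],
               centroid_y = p$centroid[2],
               mean_confidence = p$mean_confidence,
               stringsAsFactors = FALSE)
  }))
}
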