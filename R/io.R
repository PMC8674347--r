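#' Read a spectral map from a text export
#'
#' Two dialects are supported. `csv`: header `x,y,<wn1>,...,<wnN>` where the
#' wavenumber columns are named by their cm^-1 value, one pixel per row.
#' `labspec_ascii`: tab-separated; the first row carries the wavenumber axis
#' with its first two cells empty, each following row is x, y, then the
#' intensities.
#'
#' @param path file to read.
#' @param dialect `"csv"` or `"labspec_ascii"`.
#' @param analyzed_fraction,filter_area map geometry metadata (see
#'   [raman_map()]).
#' @return A [raman_map()] whose step is inferred as the minimal positive
#'   coordinate difference.
#' @export
read_map <- function(path, dialect = c("csv", "labspec_ascii"),
                     analyzed_fraction = 0.5, filter_area = 14) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  if (dialect == "csv") {
    parsed <- parse_delim_map(path, sep = ",", header_axis = FALSE)
  } else {
    parsed <- parse_delim_map(path, sep = "\t", header_axis = TRUE)
  }
  raman_map(parsed$wavenumbers, parsed$intensities, parsed$x, parsed$y,
            analyzed_fraction = analyzed_fraction, filter_area = filter_area)
}

# shared line-wise parser; header_axis = TRUE is the LabSpec-style layout
parse_delim_map <- function(path, sep, header_axis) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("map file has no data rows", call. = FALSE)
  head_cells <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  if (header_axis) {
    if (length(head_cells) < 4L || nzchar(trimws(head_cells[1])) ||
        nzchar(trimws(head_cells[2]))) {
      stop("format error at line 1: expected two empty cells then the wavenumber axis",
           call. = FALSE)
    }
    wn <- suppressWarnings(as.numeric(head_cells[-(1:2)]))
  } else {
    if (length(head_cells) < 4L || tolower(head_cells[1]) != "x" ||
        tolower(head_cells[2]) != "y") {
      stop("format error at line 1: expected header x,y,<wavenumbers>",
           call. = FALSE)
    }
    wn <- suppressWarnings(as.numeric(head_cells[-(1:2)]))
  }
  if (any(is.na(wn))) {
    stop("format error at line 1: non-numeric wavenumber column", call. = FALSE)
  }
  ncell <- length(wn) + 2L
  n <- length(lines) - 1L
  x <- numeric(n); y <- numeric(n)
  intens <- matrix(NA_real_, n, length(wn))
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1]]
    if (length(cells) != ncell) {
      stop(sprintf("format error at line %d: expected %d cells, found %d",
                   i + 1L, ncell, length(cells)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals))) {
      stop(sprintf("format error at line %d: non-numeric cell", i + 1L),
           call. = FALSE)
    }
    x[i] <- vals[1]; y[i] <- vals[2]
    intens[i, ] <- vals[-(1:2)]
  }
  list(wavenumbers = wn, intensities = intens, x = x, y = y)
}

#' Write a spectral map
#'
#' Inverse of [read_map()]. The csv round-trip is lossless: coordinates and
#' intensities are written with full precision (`format(..., digits = 17)`).
#'
#' @param map a [raman_map()].
#' @param path destination file.
#' @param dialect `"csv"` or `"labspec_ascii"`.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, path, dialect = c("csv", "labspec_ascii")) {
  dialect <- match.arg(dialect)
  fmt <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  if (dialect == "csv") {
    header <- paste(c("x", "y", fmt(map$wavenumbers)), collapse = ",")
    rows <- vapply(seq_along(map$x), function(i) {
      paste(c(fmt(map$x[i]), fmt(map$y[i]), fmt(map$intensities[i, ])),
            collapse = ",")
    }, character(1))
  } else {
    header <- paste(c("", "", fmt(map$wavenumbers)), collapse = "\t")
    rows <- vapply(seq_along(map$x), function(i) {
      paste(c(fmt(map$x[i]), fmt(map$y[i]), fmt(map$intensities[i, ])),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a labeled training library from csv
#'
#' Expected layout: a `label` column followed by one intensity column per
#' wavenumber, the columns named by their cm^-1 value.
#'
#' @param path csv file.
#' @return A [raman_library()].
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df)) {
    stop("library csv must have a 'label' column", call. = FALSE)
  }
  wn_cols <- setdiff(names(df), "label")
  wn <- suppressWarnings(as.numeric(wn_cols))
  if (any(is.na(wn))) {
    stop("library csv intensity columns must be named by wavenumber",
         call. = FALSE)
  }
  raman_library(df$label, as.matrix(df[, wn_cols, drop = FALSE]), wn)
}

#' Write a training library to csv
#' @param lib a [raman_library()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_library <- function(lib, path) {
  fmt <- function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE)
  header <- paste(c("label", fmt(lib$wavenumbers)), collapse = ",")
  rows <- vapply(seq_along(lib$labels), function(i) {
    paste(c(lib$labels[i], fmt(lib$intensities[i, ])), collapse = ",")
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write an analytical report as JSON
#'
#' The report embeds per-class counts, the particle table (class, area,
#' centroid, confidence, and per particle the representative spectrum — the
#' member pixel of highest classification confidence), the QC block and the
#' provenance block (configuration and seeds), so a reviewer can audit every
#' reported particle.
#'
#' @param report a `quant_report` (see [quantify_particles()]).
#' @param path destination file.
#' @param include_spectra embed per-particle representative spectra
#'   (default TRUE); disable to shrink reports from large runs.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, include_spectra = TRUE) {
  out <- unclass(report)
  if (!include_spectra && !is.null(out$particles)) {
    out$particles <- lapply(out$particles, function(p) {
      p$representative_spectrum <- NULL
      p
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' Read back a JSON analytical report
#' @param path report file written by [write_report()].
#' @return The report as a list of class `quant_report`.
#' @export
read_report <- function(path) {
  out <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = FALSE)
  class(out) <- "quant_report"
  out
}
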