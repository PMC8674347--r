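test_that("spectrum constructor enforces its invariants", {
  expect_s3_class(raman_spectrum(1:5, c(1, 2, 3, 2, 1)), "raman_spectrum")
  expect_error(raman_spectrum(1:4, 1:5), "equal length")
  expect_error(raman_spectrum(c(1, 3, 2), c(1, 1, 1)), "increasing")
  expect_error(raman_spectrum(1:3, c(1, NA, 2)), "non-finite")
  expect_error(raman_spectrum(1:3, c(1, Inf, 2)), "non-finite")
})

test_that("map constructor checks lattice, duplicates and geometry", {
  wn <- c(100, 200, 300, 400)
  ints <- matrix(1:12, 3, 4)
  m <- raman_map(wn, ints, x = c(0, 5, 10), y = c(0, 0, 0), step = 5)
  expect_equal(m$step, 5)
  expect_error(
    raman_map(wn, ints, x = c(0, 5, 7.3), y = c(0, 0, 0), step = 5),
    "lattice")
  expect_error(
    raman_map(wn, ints, x = c(0, 5, 5), y = c(0, 0, 0), step = 5),
    "duplicate")
  expect_error(
    raman_map(wn, ints, x = c(0, 5, 10), y = c(0, 0, 0), step = 5,
              analyzed_fraction = 0),
    "analyzed_fraction")
  # half-step-offset pixel centers are a valid lattice
  m2 <- raman_map(wn, ints, x = c(2.5, 7.5, 12.5), y = c(2.5, 2.5, 2.5),
                  step = 5)
  expect_equal(m2$step, 5)
})

test_that("step is inferred as the minimal positive coordinate difference", {
  wn <- c(100, 200, 300)
  m <- raman_map(wn, matrix(0, 3, 3), x = c(0, 10, 20), y = c(0, 0, 5))
  expect_equal(m$step, 5)
})

test_that("csv maps parse, and malformed rows are reported by line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,100,200,300,400",
               "0,0,1,2,3,4",
               "5,0,5,6,7,8",
               "0,5,9,10,11,12"), path)
  m <- read_map(path, dialect = "csv")
  expect_equal(nrow(m$intensities), 3L)
  expect_equal(m$step, 5)
  expect_equal(m$wavenumbers, c(100, 200, 300, 400))

  writeLines(c("x,y,100,200,300,400",
               "0,0,1,2,3,4",
               "5,0,5,6,7"), path)
  expect_error(read_map(path, dialect = "csv"), "line 3")
})

test_that("labspec ascii dialect parses the axis-header layout", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("\t\t100\t200\t300",
               "0\t0\t1\t2\t3",
               "5\t0\t4\t5\t6"), path)
  m <- read_map(path, dialect = "labspec_ascii")
  expect_equal(m$wavenumbers, c(100, 200, 300))
  expect_equal(m$intensities[2, ], c(4, 5, 6))
  expect_equal(m$x, c(0, 5))
})

test_that("csv map round-trip is bit-identical", {
  sim <- generate_map(scene_spec(width_um = 50, height_um = 50,
                                 n_random_particles = 1,
                                 diameter_range = c(8, 10), n_fibers = 0,
                                 n_residue = 0, dropout_prob = 0,
                                 seed = 7L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_map(sim$map, path)
  back <- read_map(path)
  expect_identical(back$x, sim$map$x)
  expect_identical(back$y, sim$map$y)
  expect_identical(back$wavenumbers, sim$map$wavenumbers)
  expect_identical(back$intensities, sim$map$intensities)
})

test_that("library round-trip is lossless and labels are validated", {
  lib <- generate_training_library(classes = c("PE", "PP"),
                                   n_per_class = 3, seed = 5L)
  expect_setequal(lib$classes, c("PE", "PP"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_library(lib, path)
  back <- read_library(path)
  expect_identical(back$labels, lib$labels)
  expect_identical(back$intensities, lib$intensities,
                   ignore_attr = "dimnames")
  expect_identical(back$wavenumbers, lib$wavenumbers)

  expect_error(
    raman_library(c("PET", "PET", "PE", "PE"), matrix(0, 4, 3), 1:3),
    "PET")
  expect_error(
    raman_library(rep("PE", 4), matrix(0, 4, 3), 1:3),
    "at least 2 classes")
})

test_that("report writer produces valid JSON, including the empty case", {
  empty <- quantify_particles(structure(list(), class = "raman_particles"))
  path <- withr::local_tempfile(fileext = ".json")
  write_report(empty, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$total_per_100mL, 0)
  expect_length(back$particles, 0)
  expect_null(back$pct_small)  # undefined, not 0

  # a populated report embeds per-particle representative spectra
  px <- data.frame(x = c(0, 5), y = c(0, 0), class = "PE",
                   confidence = c(0.9, 0.7), review = FALSE,
                   degenerate = FALSE)
  map <- raman_map(c(100, 200, 300), matrix(seq_len(6), 2, 3),
                   x = c(0, 5), y = c(0, 0), step = 5)
  parts <- cluster_particles(px, step = 5, map = map)
  rep2 <- quantify_particles(parts, analyzed_fraction = 0.5)
  write_report(rep2, path)
  back2 <- jsonlite::read_json(path)
  expect_length(back2$particles, 1)
  spec <- back2$particles[[1]]$representative_spectrum
  expect_equal(unlist(spec$intensities), c(1, 3, 5))  # highest-confidence pixel
  write_report(rep2, path, include_spectra = FALSE)
  back3 <- jsonlite::read_json(path)
  expect_null(back3$particles[[1]]$representative_spectrum)
})
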