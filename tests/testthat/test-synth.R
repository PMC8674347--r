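test_that("peak tables cover all 11 classes with in-range positive bands", {
  tab <- default_peak_table()
  expect_setequal(names(tab), mp_classes())
  for (cl in names(tab)) {
    expect_true(all(tab[[cl]]$center >= 559 & tab[[cl]]$center <= 1990))
    expect_true(all(tab[[cl]]$height > 0))
    expect_true(all(tab[[cl]]$width > 0))
  }
})

test_that("noiseless zero-baseline draws equal the pure band sum", {
  wn <- acquisition_axis()
  s <- generate_spectrum("PS", snr = Inf, baseline = c(0, 0, 0))
  tab <- default_peak_table()$PS
  manual <- rep(0, length(wn))
  for (b in seq_len(nrow(tab))) {
    manual <- manual + 100 * tab$height[b] *
      exp(-0.5 * ((wn - tab$center[b]) / tab$width[b])^2)
  }
  expect_equal(s$intensities, manual, tolerance = 1e-9)
  expect_identical(s$label, "PS")
})

test_that("spectrum draws are a pure function of the seed", {
  a <- generate_spectrum("PE", snr = 10, seed = 12L)
  b <- generate_spectrum("PE", snr = 10, seed = 12L)
  c <- generate_spectrum("PE", snr = 10, seed = 13L)
  expect_identical(a$intensities, b$intensities)
  expect_false(identical(a$intensities, c$intensities))
})

test_that("a generated PE spectrum is recognised by the default-trained model", {
  m <- get_small_model()
  s <- generate_spectrum("PE", snr = 20, seed = 55L)
  sp <- preprocess_spectrum(s)
  map <- raman_map(sp$wavenumbers, matrix(sp$intensities, 1),
                   x = 0, y = 0, step = 5)
  px <- predict(m, map)
  expect_identical(px$class, "PE")
})

test_that("library generation is balanced, seeded and trainable", {
  lib <- generate_training_library(n_per_class = 4, seed = 3L)
  expect_length(lib$labels, 44L)
  expect_equal(unname(c(table(lib$labels))), rep(4L, 11L))
  lib2 <- generate_training_library(n_per_class = 4, seed = 3L)
  expect_identical(lib$intensities, lib2$intensities)
  lib3 <- generate_training_library(n_per_class = 4, seed = 4L)
  expect_false(identical(lib$intensities, lib3$intensities))
})

test_that("disc rasterization matches the brute-force center-in rule", {
  # one 10 um PE disc centered on a cell corner at 5 um step: 4 pixels
  scene <- scene_spec(width_um = 100, height_um = 100, step = 5,
                      particles = data.frame(class = "PE", diameter = 10,
                                             x = 50, y = 50),
                      n_fibers = 0, n_residue = 0, dropout_prob = 0,
                      seed = 8L)
  sim <- generate_map(scene)
  expect_length(sim$particles, 1L)
  expect_equal(sim$particles[[1]]$n_pixels, 4L)
  expect_equal(sim$particles[[1]]$area, 100)

  # brute-force oracle over all pixel centers for random discs
  set.seed(9)
  for (k in 1:5) {
    d <- runif(1, 6, 22); cx <- runif(1, 20, 80); cy <- runif(1, 20, 80)
    scene_k <- scene_spec(width_um = 100, height_um = 100, step = 5,
                          particles = data.frame(class = "PP", diameter = d,
                                                 x = cx, y = cy),
                          n_fibers = 0, n_residue = 0, dropout_prob = 0,
                          seed = k)
    sim_k <- generate_map(scene_k)
    centers <- expand.grid(x = seq(2.5, 97.5, 5), y = seq(2.5, 97.5, 5))
    inside <- which((centers$x - cx)^2 + (centers$y - cy)^2 < (d / 2)^2)
    if (length(inside) == 0L) next  # generator snaps such discs; skip oracle
    expect_setequal(
      paste(sim_k$truth$x[sim_k$particles[[1]]$pixels],
            sim_k$truth$y[sim_k$particles[[1]]$pixels]),
      paste(centers$x[inside], centers$y[inside]))
  }
})

test_that("overlapping particles of different classes are a scene error", {
  scene <- scene_spec(width_um = 60, height_um = 60,
                      particles = data.frame(class = c("PE", "PP"),
                                             diameter = c(20, 20),
                                             x = c(30, 35), y = c(30, 30)),
                      n_fibers = 0, n_residue = 0, dropout_prob = 0,
                      seed = 1L)
  expect_error(generate_map(scene), "scene error")
})

test_that("dropout control: none at 0, flagged and gap-safe when positive", {
  scene0 <- scene_spec(width_um = 80, height_um = 80,
                       n_random_particles = 2, diameter_range = c(8, 12),
                       n_fibers = 0, n_residue = 0, dropout_prob = 0,
                       seed = 2L)
  sim0 <- generate_map(scene0)
  expect_false(any(sim0$map$degenerate))
  expect_false(any(sim0$truth$dropout))

  scene1 <- scene_spec(width_um = 80, height_um = 80,
                       n_random_particles = 2, diameter_range = c(10, 14),
                       n_fibers = 0, n_residue = 0, dropout_prob = 0.3,
                       seed = 3L)
  sim1 <- generate_map(scene1)
  expect_true(any(sim1$map$degenerate))
  expect_identical(sim1$map$degenerate, sim1$truth$dropout)
  # no ground-truth particle is erased or split under the gap-2 rule
  for (tp in sim1$particles) {
    kept <- tp$pixels[!sim1$truth$dropout[tp$pixels]]
    expect_gt(length(kept), 0L)
    px <- data.frame(x = sim1$truth$x[kept], y = sim1$truth$y[kept],
                     class = tp$class, stringsAsFactors = FALSE)
    expect_length(cluster_particles(px, step = 5), 1L)
  }
})

test_that("ground truth conserves the labelled pixel partition", {
  scene <- scene_spec(width_um = 150, height_um = 150,
                      n_random_particles = 4, diameter_range = c(8, 18),
                      n_fibers = 1, n_residue = 1, dropout_prob = 0,
                      seed = 4L)
  sim <- generate_map(scene)
  particle_pix <- sort(unlist(lapply(sim$particles, `[[`, "pixels")))
  polymer_pix <- sort(which(!(sim$truth$label %in% c("background", "NMP"))))
  expect_identical(particle_pix, polymer_pix)
})

test_that("whole-map generation is reproducible from the scene seed", {
  scene <- scene_spec(width_um = 60, height_um = 60,
                      n_random_particles = 1, diameter_range = c(8, 10),
                      seed = 6L)
  a <- generate_map(scene)
  b <- generate_map(scene)
  expect_identical(a$map$intensities, b$map$intensities)
  expect_identical(a$truth, b$truth)
})
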