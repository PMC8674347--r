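test_that("parameter object validates the grid definition", {
  p <- preprocess_params()
  expect_length(common_grid(p), 478L)
  expect_error(preprocess_params(grid_start = 2000, grid_end = 1990),
               "grid_start")
  expect_error(preprocess_params(grid_start = 559, grid_end = 1990,
                                 grid_step = 7),
               "divisible")
})

test_that("grid refit hits the exact target axis and refuses extrapolation", {
  # exact-grid input passes through at the knots
  grid <- common_grid()
  s <- raman_spectrum(grid, sin(grid / 100) + 2)
  out <- refit_grid(s)
  expect_identical(out$wavenumbers, grid)
  expect_equal(out$intensities, s$intensities, tolerance = 1e-9)

  # a straight line on an irregular axis is reproduced exactly at grid points
  set.seed(3)
  ax <- sort(runif(200, 540, 2005))
  ax <- c(540, ax, 2005)
  a <- 4.2; b <- 0.31
  s2 <- raman_spectrum(ax, a + b * ax)
  out2 <- refit_grid(s2)
  expect_equal(out2$intensities, a + b * grid, tolerance = 1e-6)

  # input not covering the target range is a coverage error
  ax3 <- seq(600, 2000, 10)
  s3 <- raman_spectrum(ax3, rep_len(c(1, 2), length(ax3)))
  expect_error(refit_grid(s3), "cover")
})

test_that("baseline correction removes backgrounds and preserves peaks", {
  grid <- common_grid()
  # pure constant offset comes out near zero
  s <- refit_grid(raman_spectrum(acquisition_axis(),
                                 rep(100, length(acquisition_axis())) +
                                   1e-9 * acquisition_axis()))
  out <- correct_baseline(s)
  expect_lt(mean(abs(out$intensities)), 1)   # < 1% of the 100-count offset

  # known decomposition: Gaussian peak on a quadratic background
  wn <- acquisition_axis()
  peak <- 80 * exp(-0.5 * ((wn - 1100) / 8)^2)
  bg <- 50 + 0.00005 * (wn - 550)^2
  sc <- correct_baseline(refit_grid(raman_spectrum(wn, peak + bg)))
  expect_lt(abs(max(sc$intensities) - 80) / 80, 0.05)
  expect_length(sc$meta$baseline, 478L)

  # all-zero input stays all-zero
  z <- correct_baseline(raman_spectrum(grid, rep(0, 478)))
  expect_equal(z$intensities, rep(0, 478), tolerance = 1e-9)
})

test_that("compiled ALS agrees with an independent sparse-matrix solver", {
  skip_if_not_installed("Matrix")
  set.seed(11)
  for (k in 1:5) {
    y <- cumsum(rnorm(478)) + 60 * exp(-0.5 * ((1:478 - 200) / 10)^2)
    z_pkg <- ramanmp:::als_baseline(y, 1e5, 0.01, 10)
    z_ref <- als_reference(y, 1e5, 0.01, 10)
    expect_equal(z_pkg, z_ref, tolerance = 1e-7)
  }
})

test_that("baseline correction is insensitive to a constant shift", {
  set.seed(12)
  wn <- acquisition_axis()
  s <- generate_spectrum("PP", snr = 30, seed = 13)
  s <- refit_grid(s)
  shifted <- raman_spectrum(s$wavenumbers, s$intensities + 500)
  a <- correct_baseline(s)$intensities
  b <- correct_baseline(shifted)$intensities
  expect_lt(max(abs(a - b)), 0.01 * 500)
})

test_that("smoothing preserves noiseless signal and attenuates noise", {
  s <- generate_spectrum("PE", snr = Inf, baseline = c(20, 10, 0))
  s <- refit_grid(s)
  sm <- smooth_spectrum(s)
  amp <- diff(range(s$intensities))
  expect_lt(max(abs(sm$intensities - s$intensities)), 0.01 * amp)

  # Monte-Carlo: residual variance against the clean truth shrinks
  set.seed(99)
  wins <- replicate(20, {
    noisy <- raman_spectrum(s$wavenumbers,
                            s$intensities + rnorm(478, 0, 2))
    smn <- smooth_spectrum(noisy)
    var_before <- mean((noisy$intensities - s$intensities)^2)
    var_after <- mean((smn$intensities - s$intensities)^2)
    var_after < var_before
  })
  expect_true(all(wins))

  # constant input is returned unchanged
  cs <- raman_spectrum(common_grid(), rep(3, 478))
  expect_identical(smooth_spectrum(cs)$intensities, cs$intensities)
})

test_that("SD scaling yields unit spread, idempotently and scale-invariantly", {
  set.seed(21)
  s <- raman_spectrum(common_grid(), rnorm(478, 50, 7))
  out <- scale_sd(s)
  sd_pop <- function(v) sqrt(mean((v - mean(v))^2))
  expect_equal(sd_pop(out$intensities), 1, tolerance = 1e-12)
  expect_equal(scale_sd(out)$intensities, out$intensities, tolerance = 1e-12)
  s10 <- raman_spectrum(s$wavenumbers, s$intensities * 10)
  expect_equal(scale_sd(s10)$intensities, out$intensities, tolerance = 1e-12)

  # a constant spectrum is flagged degenerate rather than divided by zero
  cs <- scale_sd(raman_spectrum(common_grid(), rep(5, 478)))
  expect_true(isTRUE(cs$meta$degenerate))
})

test_that("full pipeline lands on the common grid and keeps band positions", {
  s <- generate_spectrum("PE", snr = 60, seed = 31)
  out <- preprocess_spectrum(s)
  expect_length(out$intensities, 478L)
  expect_identical(out$wavenumbers, common_grid())

  # the three strongest generating bands stay put within one grid step
  tab <- default_peak_table()$PE
  top3 <- tab$center[order(tab$height, decreasing = TRUE)][1:3]
  for (ctr in top3) {
    win <- which(abs(out$wavenumbers - ctr) <= 15)
    found <- out$wavenumbers[win][which.max(out$intensities[win])]
    expect_lte(abs(found - ctr), 3)
  }

  # degenerate constant input propagates its flag
  cs <- preprocess_spectrum(raman_spectrum(acquisition_axis(),
                                           rep(7, length(acquisition_axis()))))
  expect_true(isTRUE(cs$meta$degenerate))
})

test_that("every preprocessed spectrum in a run shares one axis", {
  sim <- generate_map(scene_spec(width_um = 40, height_um = 40,
                                 n_random_particles = 1, n_fibers = 0,
                                 n_residue = 0, dropout_prob = 0,
                                 diameter_range = c(8, 10), seed = 41L))
  mp <- preprocess_map(sim$map)
  expect_identical(mp$wavenumbers, common_grid())
  lp <- preprocess_library(generate_training_library(
    classes = c("PE", "PS"), n_per_class = 2, seed = 42L))
  expect_identical(lp$wavenumbers, common_grid())
})
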