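test_that("depletion law has the saturation-power semantics", {
  expect_equal(depletion_efficiency(0, 5), 1)
  expect_equal(depletion_efficiency(0.864, 0.864), 0.5)
  expect_equal(depletion_efficiency(3 * 0.864, 0.864), 0.25)
  expect_error(depletion_efficiency(1, 0), "Is")
  expect_error(depletion_efficiency(-1, 1), ">= 0")
})

test_that("effective FWHM follows the square-root law", {
  expect_equal(effective_fwhm(250, 0, 0.864), 250)
  expect_equal(effective_fwhm(200, 3 * 0.864, 0.864), 100)
  # strictly decreasing in depletion power, d0 limit exact
  I <- seq(0, 50, by = 0.5)
  v <- effective_fwhm(250, I, 0.864)
  expect_true(all(diff(v) < 0))
  expect_identical(v[1], 250)
  expect_gte(resolution_enhancement(34.7, 0.864), 6)
})

test_that("acquisition conserves energy and is seed-deterministic", {
  zero <- mito_image(matrix(0, 32, 32), 20)
  st0 <- acquisition_settings(background = 0, read_noise_sd = 0)
  expect_true(all(simulate_acquisition(zero, st0, seed = 1) == 0))

  dens <- fixture_network()$density
  st <- acquisition_settings(background = 0, shot_noise = FALSE)
  img <- simulate_acquisition(dens, st, seed = 1)
  m <- unclass(dens)
  blurred_scale <- st$photon_budget / max(mitosted:::blur_gaussian(
    mitosted:::img_matrix(dens),
    effective_fwhm(st$d0, st$I_dep, 0.864) / 2.3548 / 20))
  expect_equal(sum(img), sum(m) * blurred_scale, tolerance = 1e-4)

  stn <- acquisition_settings()
  a <- simulate_acquisition(dens, stn, seed = 42)
  b <- simulate_acquisition(dens, stn, seed = 42)
  expect_identical(unclass(a), unclass(b))
})

test_that("a point source images at the effective PSF width", {
  m <- matrix(0, 128, 128)
  m[64, 64] <- 1
  dens <- mito_image(m, 20)
  st <- acquisition_settings(I_dep = 34.7, shot_noise = FALSE,
                             background = 0)
  img <- simulate_acquisition(dens, st, Is = 0.864, seed = 1)
  fw <- measure_fwhm_profile(img, c(0.3, 64 * 0.02 - 0.01),
                             c(2.3, 64 * 0.02 - 0.01))
  expect_equal(fw$fwhm_nm, effective_fwhm(250, 34.7, 0.864),
               tolerance = 10 / effective_fwhm(250, 34.7, 0.864))
})

test_that("depletion series follow the model and subtract cleanly", {
  s <- simulate_depletion_series(0.864, noise = 0, seed = 1,
                                 secondary_per_mw = 0)
  expect_equal(s$on_mean, 1 / (1 + s$power_mW / 0.864))
  expect_true(all(s$off_mean == 0))

  s2 <- simulate_depletion_series(0.864, powers = c(0, 0.432, 0.864, 2, 5,
                                                    10, 20, 40),
                                  noise = 0, seed = 1)
  at_is <- which(s2$power_mW == 0.864)
  expect_equal(s2$on_mean[at_is] - s2$off_mean[at_is], 0.5)

  expect_identical(simulate_depletion_series(1, seed = 3),
                   simulate_depletion_series(1, seed = 3))
  expect_error(simulate_depletion_series(1, powers = c(1, 2, 3)), "start")
})

test_that("saturation power is recovered from noise-free series", {
  for (is_true in c(0.864, 3.069)) {
    fit <- fit_saturation_power(simulate_depletion_series(is_true,
                                                          noise = 0))
    expect_equal(fit$Is_mW, is_true, tolerance = 1e-6)
    expect_identical(fit$method, "model_fit")
  }
  flat <- data.frame(power_mW = seq(0, 40, length.out = 8),
                     on_mean = rep(2, 8), off_mean = rep(2, 8))
  expect_error(fit_saturation_power(flat), "all zero")
  shallow <- data.frame(power_mW = seq(0, 2, length.out = 8),
                        on_mean = 1 / (1 + seq(0, 2, length.out = 8) / 50),
                        off_mean = 0)
  expect_error(fit_saturation_power(shallow), "saturation")
})

test_that("FRC flags identical frames and pure noise instead of guessing", {
  img <- fixture_network()$image
  same <- estimate_frc_resolution(img, img)
  expect_true(same$limited)
  expect_equal(same$resolution_nm, 2 * pixel_size_nm(img))

  withr::with_seed(5, {
    n1 <- mito_image(matrix(rpois(256^2, 10), 256, 256), 20)
    n2 <- mito_image(matrix(rpois(256^2, 10), 256, 256), 20)
  })
  pure <- estimate_frc_resolution(n1, n2)
  expect_true(pure$no_signal)
  expect_true(is.na(pure$resolution_nm))
})

test_that("FRC resolution degrades monotonically with photon budget", {
  dens <- fixture_network()$density
  res <- vapply(c(400, 40, 8), function(pb) {
    st <- acquisition_settings(photon_budget = pb)
    a <- simulate_acquisition(dens, st, seed = 11)
    b <- simulate_acquisition(dens, st, seed = 22)
    estimate_frc_resolution(a, b)$resolution_nm
  }, 1)
  expect_true(all(diff(res) >= 0))
})

test_that("Gaussian profile FWHM is exact on an analytic ridge", {
  sig_px <- 3
  m <- exp(-(matrix(rep(1:200, 60), 200) - 100)^2 / (2 * sig_px^2))
  img <- mito_image(m, 20)
  fw <- measure_fwhm_profile(img, c(1.0, 0.6), c(3.0, 0.6))
  expect_equal(fw$fwhm_nm, 2 * sqrt(2 * log(2)) * sig_px * 20,
               tolerance = 0.01)
  flat <- mito_image(matrix(1, 50, 50), 20)
  expect_error(measure_fwhm_profile(flat, c(0.1, 0.5), c(0.9, 0.5)), "flat")
  expect_error(measure_fwhm_profile(img, c(-1, 0.5), c(1, 0.5)), "outside")
})
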