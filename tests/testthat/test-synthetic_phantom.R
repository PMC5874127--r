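test_that("phantom regions match a brute-force membership scan", {
  spec <- phantom_spec(rows = 64, cols = 64, pixel_spacing_mm = 4,
                       outer_semiaxes_mm = c(100, 80),
                       module_radius_mm = 50)
  img <- generate_phantom_image(spec)
  counts <- table(factor(img, levels = c(-1000, -100, 40)))

  brute <- c(air = 0, annulus = 0, module = 0)
  for (r in 1:64) {
    for (cc in 1:64) {
      x <- (cc - 32.5) * 4
      y <- (r - 32.5) * 4
      if (x^2 + y^2 <= 50^2) brute["module"] <- brute["module"] + 1
      else if ((x / 100)^2 + (y / 80)^2 <= 1) {
        brute["annulus"] <- brute["annulus"] + 1
      } else brute["air"] <- brute["air"] + 1
    }
  }
  expect_equal(as.numeric(counts), as.numeric(brute))
  expect_equal(img[32, 32], 40)  # pixel at the center is module material
})

test_that("degenerate and invalid phantom geometries behave as specified", {
  spec0 <- phantom_spec(rows = 64, cols = 64, pixel_spacing_mm = 4,
                        outer_semiaxes_mm = c(100, 80),
                        module_radius_mm = 0)
  img <- generate_phantom_image(spec0)
  expect_false(any(img == 40))
  expect_true(any(img == -100))
  expect_error(phantom_spec(rows = 64, cols = 64, pixel_spacing_mm = 1,
                            outer_semiaxes_mm = c(100, 80)),
               "exceed the half image")
  expect_error(phantom_spec(module_radius_mm = 200), "inside the annulus")
})

test_that("the phantom mask covers exactly the non-air pixels", {
  spec <- phantom_spec(rows = 64, cols = 64, pixel_spacing_mm = 4,
                       outer_semiaxes_mm = c(100, 80), module_radius_mm = 50)
  expect_equal(phantom_mask(spec), generate_phantom_image(spec) != -1000)
})

test_that("spectral synthesis honours zero, flat and invalid targets", {
  zero <- synthesize_noise_field(matrix(0, 32, 32), 0.703125, seed = 1)
  expect_equal(zero, matrix(0, 32, 32))
  flat <- matrix(100 * 0.703125^2, 64, 64)
  f <- synthesize_noise_field(flat, 0.703125, seed = 2)
  expect_equal(var(as.vector(f)), 100, tolerance = 0.1)
  expect_error(synthesize_noise_field(-flat, 0.703125), "nonnegative")
  asym <- flat
  asym[2, 1] <- asym[2, 1] * 2  # breaks (f) -> (-f) symmetry
  expect_error(synthesize_noise_field(asym, 0.703125), "conjugate-symmetric")
})

test_that("the ensemble periodogram of synthesized noise matches its target", {
  tgt <- nps_target(16, 16, 0.703125, "lowpass_gaussian",
                    sigma = 10, width = 0.5)
  pats <- synth_patches(tgt, 500, seed = 3)
  nps <- nps2d_from_patches(pats, 0.703125)
  expect_lt(mean(abs(nps$power / tgt - 1)), 0.05)
  # the synthesis is deterministic under a fixed seed
  expect_identical(synthesize_noise_field(tgt, 0.703125, seed = 9),
                   synthesize_noise_field(tgt, 0.703125, seed = 9))
})

test_that("all spectrum families integrate to the pixel variance", {
  for (fam in c("white", "lowpass_gaussian", "bandpass",
                "anisotropic_gaussian")) {
    tgt <- nps_target(32, 32, 0.703125, fam, sigma = 10,
                      f0 = 0.3, width = 0.4, axis_ratio = 2)
    expect_gte(min(tgt), 0)
    expect_equal(sum(tgt) / (32 * 0.703125)^2, 100, tolerance = 1e-10,
                 label = paste(fam, "integral"))
  }
  expect_error(nps_target(16, 16, 0.703125, "bandpass", f0 = 0.8),
               "Nyquist")
})

test_that("radial profiles modulate variance by the squared multiplier", {
  prof <- radial_profile(g_center = 2, r_edge_px = 128)
  set.seed(4)
  noise <- matrix(rnorm(256^2, 0, 10), 256, 256)
  expect_equal(apply_radial_profile(noise, function(r) rep(1, length(r))),
               noise)
  mod <- apply_radial_profile(noise, prof)
  centre <- mod[121:136, 121:136]
  corner <- mod[1:32, 1:32]  # corner is beyond r_edge, so multiplier 1
  expect_equal(var(as.vector(centre)) / var(as.vector(corner)), 4,
               tolerance = 0.35)
  expect_error(apply_radial_profile(noise, function(r) r - 1e9), "positive")
})

test_that("scan series are reproducible, dose-scaled and z-correlatable", {
  rec <- series_recipe(phantom = NULL, noise = noise_model("white", 10),
                       n_scans = 3, dose_mGy = 18.88, seed = 31,
                       rows = 64, cols = 64)
  s1 <- generate_scan_series(rec)
  s2 <- generate_scan_series(rec)
  expect_identical(s1$pixels, s2$pixels)
  expect_equal(s1$labels$dose_mGy, 18.88)

  # halving the dose doubles the noise variance (sigma ~ 1/sqrt(D))
  half <- generate_scan_series(series_recipe(
    phantom = NULL, noise = noise_model("white", 10), n_scans = 3,
    dose_mGy = 18.88 / 2, seed = 31, rows = 64, cols = 64))
  expect_equal(var(as.vector(half$pixels)) / var(as.vector(s1$pixels)), 2,
               tolerance = 0.15)

  zc <- generate_scan_series(series_recipe(
    phantom = NULL, noise = noise_model("white", 10, z_correlated = TRUE),
    n_scans = 3, dose_mGy = 18.88, seed = 31, rows = 64, cols = 64))
  expect_identical(zc$pixels[, , 1], zc$pixels[, , 2])

  quiet <- generate_scan_series(series_recipe(
    phantom = phantom_spec(rows = 64, cols = 64, pixel_spacing_mm = 4,
                           outer_semiaxes_mm = c(100, 80),
                           module_radius_mm = 50),
    noise = noise_model("white", 0), n_scans = 2, seed = 31))
  expect_identical(quiet$pixels[, , 1], quiet$pixels[, , 2])
  expect_equal(sort(unique(as.vector(quiet$pixels))), c(-1000, -100, 40))
})

test_that("ring-sampled variance follows a center-elevated radial profile", {
  rec <- series_recipe(
    phantom = NULL,
    noise = noise_model("white", 10,
                        radial = radial_profile(g_center = 2,
                                                r_edge_px = 128)),
    n_scans = 4, dose_mGy = 18.88, seed = 13, rows = 256, cols = 256)
  st <- generate_scan_series(rec)
  ip <- vapply(c(25, 45, 65, 90), function(r) {
    integrated_power(nps2d_from_patches(
      build_noise_ensemble(st, ring_spec(c(128.5, 128.5), r))))
  }, numeric(1))
  expect_true(all(diff(ip) < 0))  # nonincreasing toward the edge
})
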