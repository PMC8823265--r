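test_that("a point source projects to a single peak at gradient * (r . d)", {
  v <- volume_image(array(0, c(24, 24, 24)), 37.5)
  v$data[17, 9, 13] <- 1
  fa <- field_axis(phantom_protocol())
  for (s in 1:3) {
    d <- random_directions(1, s)$vectors[1, ]
    prof <- plane_projection(v, d, fa, 40)
    r0 <- c(voxel_coords(v, 1)[17], voxel_coords(v, 2)[9],
            voxel_coords(v, 3)[13])
    b_true <- 40 / 1000 * sum(r0 * d)
    expect_lt(abs(fa[which.max(prof)] - b_true), fa[2] - fa[1])
  }
})

test_that("a spherically symmetric object projects identically along any direction", {
  ## smooth Gaussian blob (binary balls carry percent-level voxelisation
  ## anisotropy); profiles are compared after lineshape smoothing because the
  ## raw 0.073 mm field bins sub-sample the 1.2 mm voxel comb
  p <- phantom_protocol()
  m <- default_lineshape()
  v0 <- volume_image(array(0, c(32, 32, 32)), 37.5)
  x <- voxel_coords(v0, 1)
  r2 <- outer(outer(x^2, x^2, "+"), x^2, "+")
  blob <- exp(-r2 / (2 * 3^2))
  blob[blob < 1e-8] <- 0                 # keep all mass inside the sweep
  v <- volume_image(array(blob, c(32, 32, 32)), 37.5)
  ds <- random_directions(4, 10)
  y <- simulate_spectra(v, ds, m, p, 0)
  s1 <- y$spectra[1, ]
  for (i in 2:4) {
    expect_lt(sqrt(sum((y$spectra[i, ] - s1)^2) / sum(s1^2)), 1e-3)
  }
})

test_that("projection matches the brute-force voxel-binning oracle and conserves mass", {
  ph <- pillar_phantom(24, 37.5)
  fa <- field_axis(phantom_protocol())
  dirs <- list(c(0, 0, 1), c(1, 0, 0), c(1, 1, 1) / sqrt(3))
  for (d in dirs) {
    fast <- plane_projection(ph, d, fa, 40)
    slow <- brute_force_projection(ph, d, fa, 40)
    expect_lt(max(abs(fast - slow)) / max(slow), 1e-6)
  }
  mass <- sum(ph$data) * voxel_volume(ph) * 40
  db <- fa[2] - fa[1]
  prof <- plane_projection(ph, golden_mean_directions(16), fa, 40)
  expect_lt(max(abs(rowSums(prof) * db / mass - 1)), 0.005)
})

test_that("mass projected outside the sweep raises an FOV-overflow warning", {
  v <- volume_image(array(1, c(16, 16, 16)), 60)   # 60 mm object, 37.5 mm FOV
  fa <- field_axis(phantom_protocol())
  expect_warning(plane_projection(v, c(1, 0, 0), fa, 40), "FOV overflow")
  expect_error(plane_projection(v, c(1, 0, 0), fa, -40), "positive")
})

test_that("simulated spectra: linear, delta gives the shifted lineshape, seeded noise reproduces", {
  p <- phantom_protocol()
  m <- default_lineshape()
  ds <- golden_mean_directions(6)
  empty <- volume_image(array(0, c(16, 16, 16)), 37.5)
  y0 <- simulate_spectra(empty, ds, m, p, noise_sd = 0)
  expect_true(all(y0$spectra == 0))

  ## point mass: the spectrum is the lineshape shifted to the source's field
  ## offset, linearly split between the two bracketing field bins
  fa <- field_axis(p)
  v <- volume_image(array(0, c(16, 16, 16)), 37.5)
  v$data[9, 9, 9] <- 1
  dz <- direction_set(matrix(c(0, 0, 1), 1))
  b0 <- 40 / 1000 * voxel_coords(v, 3)[9]
  db <- fa[2] - fa[1]
  u <- (b0 - fa[1]) / db
  i0 <- floor(u); w <- u - i0
  ysim <- simulate_spectra(v, dz, m, p, noise_sd = 0)
  scale <- voxel_volume(v) * 40
  direct <- ((1 - w) * lineshape_profile(m, fa - fa[i0 + 1]) +
               w * lineshape_profile(m, fa - fa[i0 + 2])) * scale
  ## exact agreement within the convolution kernel's support; beyond it the
  ## simulated sweep (necessarily) truncates the Lorentzian far tail
  ker_half <- (length(eprredox:::lineshape_kernel(m, fa)) - 1) / 2 * db
  support <- abs(fa - b0) <= ker_half - 2 * db
  expect_lt(max(abs(ysim$spectra[1, support] - direct[support])) /
              max(abs(direct)), 1e-9)

  ## linearity at zero noise
  ph <- pillar_phantom(16, 37.5)
  y1 <- simulate_spectra(ph, ds, m, p, 0)
  vsum <- volume_image(2 * ph$data + 3 * v$data, ph$fov)
  ysum <- simulate_spectra(vsum, ds, m, p, 0)
  ypt <- simulate_spectra(v, ds, m, p, 0)
  expect_equal(ysum$spectra, 2 * y1$spectra + 3 * ypt$spectra,
               tolerance = 1e-9)

  ## seeded noise is bitwise reproducible and leaves the caller's RNG alone
  set.seed(123); before <- rnorm(1)
  set.seed(123)
  ya <- simulate_spectra(ph, ds, m, p, noise_sd = 0.1, seed = 42)
  yb <- simulate_spectra(ph, ds, m, p, noise_sd = 0.1, seed = 42)
  expect_identical(ya$spectra, yb$spectra)
  expect_identical(rnorm(1), before)
})

test_that("zero-gradient spectrum carries the total object mass at the line centre", {
  p <- scan_protocol()                   # includes the zero-gradient scan
  m <- default_lineshape()
  ph <- pillar_phantom(16, 37.5)
  y <- simulate_spectra(ph, golden_mean_directions(4), m, p, 0)
  mass <- sum(ph$data) * voxel_volume(ph) * p$gradient_magnitude
  expect_equal(y$zero_gradient_spectrum,
               lineshape_profile(m, field_axis(p)) * mass, tolerance = 1e-12)
})

test_that("projection-set invariants are enforced", {
  p <- phantom_protocol()
  ds <- golden_mean_directions(4)
  fa <- field_axis(p)
  expect_error(projection_set(matrix(0, 3, 512), ds, fa, p), "row count")
  expect_error(projection_set(matrix(0, 4, 100), ds, fa, p), "column count")
  expect_error(projection_set(matrix(0, 4, 512), ds, fa * 2, p),
               "sweep width")
  s <- projection_set(matrix(rnorm(4 * 512), 4), ds, fa, p)
  s2 <- subset_projections(s, 2)
  expect_equal(s2$spectra, s$spectra[1:2, ])
  expect_error(subset_projections(s, 9), "out of range")
})
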