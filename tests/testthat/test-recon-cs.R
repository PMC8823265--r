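make_geom <- function(n_dirs = 32, n = 16) {
  p <- phantom_protocol()
  recon_geometry(golden_mean_directions(n_dirs), field_axis(p),
                 p$gradient_magnitude, default_lineshape(), n, 37.5)
}

test_that("forward and adjoint operators pass the dot-product test", {
  geom <- make_geom(32, 16)
  set.seed(11)
  x <- array(rnorm(16^3), c(16, 16, 16))
  y <- matrix(rnorm(32 * 512), 32, 512)
  lhs <- sum(forward_op(x, geom) * y)
  rhs <- sum(x * adjoint_op(y, geom)$data)
  expect_lt(abs(lhs - rhs) / abs(lhs), 1e-8)
  expect_true(all(forward_op(array(0, c(16, 16, 16)), geom) == 0))
  expect_true(all(adjoint_op(matrix(0, 32, 512), geom)$data == 0))
  expect_error(adjoint_op(matrix(0, 5, 512), geom), "mismatch")
})

test_that("soft thresholding solves the scalar L1 proximal problem", {
  expect_equal(soft_threshold(c(-2, 0.5, 3), 0), c(-2, 0.5, 3))
  expect_equal(soft_threshold(0.5, 0.2), 0.3)
  expect_equal(soft_threshold(-0.1, 0.2), 0)
  ## brute-force scalar oracle: grid search of (u - v)^2/2 + tau |u|
  grid <- seq(-3, 3, by = 1e-4)
  for (v in c(-1.7, -0.2, 0.08, 0.9, 2.5)) {
    for (tau in c(0.05, 0.3, 1)) {
      u_star <- grid[which.min(0.5 * (grid - v)^2 + tau * abs(grid))]
      expect_lt(abs(soft_threshold(v, tau) - u_star), 1e-3)
    }
  }
  v <- volume_image(array(c(-1, 0.1, 0.6), c(3, 1, 1)), 3)
  expect_equal(soft_threshold(v, 0.2)$data,
               array(c(-0.8, 0, 0.4), c(3, 1, 1)))
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("TV denoising reduces energy and approaches the converged solution", {
  ## 1D step embedded in 3D
  a <- array(0, c(24, 8, 8))
  a[13:24, , ] <- 1
  set.seed(5)
  noisy <- a + array(rnorm(length(a), sd = 0.2), dim(a))
  w <- 0.1
  energy <- function(u) 0.5 * sum((u - noisy)^2) + w * total_variation(u)
  prev <- Inf
  for (ni in c(1, 2, 5, 10, 20, 50)) {
    u <- tv_denoise(noisy, w, ni)
    e <- energy(u)
    expect_lte(e, prev + 1e-9)
    prev <- e
  }
  u50 <- tv_denoise(noisy, w, 50)
  expect_lt(total_variation(u50), total_variation(noisy))
  ## long-run reference
  uref <- tv_denoise(noisy, w, 500)
  expect_lt(sqrt(sum((u50 - uref)^2) / sum(uref^2)), 0.01)
  ## identities
  expect_identical(tv_denoise(noisy, 0, 10), noisy)
  const <- array(3, c(6, 6, 6))
  expect_equal(tv_denoise(const, 0.5, 20), const, tolerance = 1e-12)
  expect_equal(total_variation(const), 0)
})

test_that("FISTA recovers a sparse source support from noiseless data", {
  p <- phantom_protocol()
  arr <- array(0, c(16, 16, 16))
  pts <- rbind(c(4, 4, 4), c(12, 5, 9), c(8, 13, 6), c(5, 10, 12),
               c(13, 12, 13))
  set.seed(3)
  for (i in 1:5) arr[pts[i, 1], pts[i, 2], pts[i, 3]] <- runif(1, 0.5, 1)
  v <- volume_image(arr, 37.5)
  y <- simulate_spectra(v, golden_mean_directions(256), default_lineshape(),
                        p, 0)
  cfg <- recon_config(lambda1 = 1e-4, lambda2 = 1e-4, n_iter = 30,
                      matrix = 16, fov = 37.5)
  rec <- fista_reconstruct(y, cfg, default_lineshape())
  top5 <- order(rec$data, decreasing = TRUE)[1:5]
  truth <- apply(pts, 1, function(q) q[1] + (q[2] - 1) * 16 + (q[3] - 1) * 256)
  expect_setequal(top5, truth)
  expect_lt(sort(rec$data, decreasing = TRUE)[6], 0.05)
})

test_that("an overwhelming L1 weight suppresses the whole image", {
  p <- phantom_protocol()
  v <- ball_volume(16, 37.5, 6)
  ds <- golden_mean_directions(32)
  y <- simulate_spectra(v, ds, default_lineshape(), p, 0)
  geom <- make_geom(32, 16)
  yn <- y$spectra / max(abs(y$spectra))
  lam_kill <- max(abs(adjoint_op(yn, geom)$data)) * 1.01
  cfg <- recon_config(lambda1 = lam_kill, lambda2 = 0, n_iter = 4,
                      matrix = 16, fov = 37.5)
  rec <- fista_reconstruct(y, cfg, default_lineshape())
  expect_true(all(rec$data == 0))
})

test_that("the objective is non-increasing over the four configured iterations", {
  p <- phantom_protocol()
  ph <- pillar_phantom(24, 37.5)
  y <- simulate_spectra(ph, golden_mean_directions(64), default_lineshape(),
                        p, noise_sd = 0, seed = 1)
  for (preset in c("phantom", "invivo")) {
    cfg <- recon_config(preset = preset, matrix = 24, fov = 37.5)
    rec <- fista_reconstruct(y, cfg, default_lineshape())
    expect_equal(cfg$n_iter, 4L)
    expect_true(all(diff(attr(rec, "objective")) <= 1e-12))
  }
})

test_that("with no regularisation FISTA approaches the least-squares solution", {
  ## tiny 8^3 problem solved directly through the pseudo-inverse
  p <- phantom_protocol()
  geom <- recon_geometry(golden_mean_directions(24), field_axis(p),
                         p$gradient_magnitude, default_lineshape(), 8, 37.5)
  set.seed(21)
  xt <- array(0, c(8, 8, 8)); xt[sample(512, 10)] <- runif(10)
  yt <- forward_op(xt, geom)
  A <- vapply(seq_len(512), function(j) {
    e <- numeric(512); e[j] <- 1
    as.numeric(forward_op(array(e, c(8, 8, 8)), geom))
  }, numeric(length(yt)))
  xls <- MASS::ginv(A, tol = 1e-10) %*% as.numeric(yt)
  res_ls <- sqrt(sum((A %*% xls - as.numeric(yt))^2))
  cfg <- recon_config(lambda1 = 0, lambda2 = 0, n_iter = 300, nonneg = FALSE,
                      matrix = 8, fov = 37.5)
  ps <- projection_set(yt, geom$directions, geom$field_axis, p)
  rec <- fista_reconstruct(ps, cfg, default_lineshape())
  ## undo the solver's max-normalisation: optimal scale in closed form
  Ax <- forward_op(rec$data, geom)
  a_star <- sum(Ax * yt) / sum(Ax^2)
  res_fista <- sqrt(sum((a_star * Ax - yt)^2))
  expect_lt(res_fista, res_ls + 0.05 * sqrt(sum(yt^2)))
})

test_that("all-zero observations return a zero volume with a warning", {
  p <- phantom_protocol()
  ds <- golden_mean_directions(8)
  y <- projection_set(matrix(0, 8, 512), ds, field_axis(p), p)
  expect_warning(rec <- fista_reconstruct(y, recon_config(matrix = 8),
                                          default_lineshape()), "zero")
  expect_true(all(rec$data == 0))
})

test_that("series renormalisation restores inter-frame amplitude ratios", {
  p <- phantom_protocol()
  m <- default_lineshape()
  ds <- golden_mean_directions(16)
  ball <- ball_volume(16, 37.5, 6)
  y1 <- simulate_spectra(ball, ds, m, p, 0)
  half <- volume_image(ball$data * 0.5, ball$fov)
  y2 <- simulate_spectra(half, ds, m, p, 0)
  ## two identical (normalised) frames whose spectra differ by a factor 2
  frames <- image_series(list(ball, ball), c(0, 1), unit = "min")
  out <- renormalize_series(frames, list(y1, y2))
  expect_equal(out$frames[[1]]$data, 2 * out$frames[[2]]$data,
               tolerance = 1e-9)
  ## noiseless uniform decay: frame-mean ratios recover exp(-k dt)
  k <- 0.71; dt <- 0.5
  frames2 <- list(ball, ball, ball)
  sets <- lapply(0:2, function(f) {
    vf <- volume_image(ball$data * exp(-k * f * dt), ball$fov)
    simulate_spectra(vf, ds, m, p, 0)
  })
  out2 <- renormalize_series(image_series(frames2, dt * (0:2), unit = "min"),
                             sets)
  means <- vapply(out2$frames, function(f) mean(f$data), numeric(1))
  expect_equal(means[2] / means[1], exp(-k * dt), tolerance = 0.02)
  expect_equal(means[3] / means[2], exp(-k * dt), tolerance = 0.02)
  ## single-frame series: output proportional to input
  one <- renormalize_series(image_series(list(ball), 0, unit = "min"),
                            list(y1))
  expect_equal(one$frames[[1]]$data / max(one$frames[[1]]$data),
               ball$data / max(ball$data), tolerance = 1e-12)
  expect_error(renormalize_series(frames, list(y1)), "differ")
})
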