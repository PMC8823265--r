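## shared small fixtures built in code

default_lineshape <- function() lineshape_model("lorentzian", 0.073)

phantom_protocol <- function() scan_protocol(includes_zero_gradient = FALSE)

## uniform ball of given radius (mm) on an n^3 grid
ball_volume <- function(n = 32, fov = 37.5, radius = 8) {
  v0 <- volume_image(array(0, rep(n, 3)), fov)
  x <- voxel_coords(v0, 1); y <- voxel_coords(v0, 2); z <- voxel_coords(v0, 3)
  r2 <- outer(outer(x^2, y^2, "+"), z^2, "+")
  volume_image(array(as.numeric(r2 <= radius^2), rep(n, 3)), fov)
}

## seeded uniform-random direction set
random_directions <- function(n, seed) {
  set.seed(seed)
  v <- matrix(rnorm(n * 3), n, 3)
  direction_set(v / sqrt(rowSums(v^2)))
}

## independently coded brute-force plane-binning oracle: for each voxel,
## split its mass between the two field bins bracketing g * (r . d)
brute_force_projection <- function(v, d, fa, gradient) {
  g <- gradient / 1000
  db <- fa[2] - fa[1]
  out <- numeric(length(fa))
  xs <- voxel_coords(v, 1); ys <- voxel_coords(v, 2); zs <- voxel_coords(v, 3)
  vv <- voxel_volume(v)
  for (k in seq_along(zs)) for (j in seq_along(ys)) for (i in seq_along(xs)) {
    val <- v$data[i, j, k]
    if (val == 0) next
    b <- g * (xs[i] * d[1] + ys[j] * d[2] + zs[k] * d[3])
    u <- (b - fa[1]) / db
    i0 <- floor(u)
    w <- u - i0
    if (i0 >= 0 && i0 <= length(fa) - 1) {
      out[i0 + 1] <- out[i0 + 1] + val * vv * gradient / db * (1 - w)
      if (i0 + 2 <= length(fa)) {
        out[i0 + 2] <- out[i0 + 2] + val * vv * gradient / db * w
      }
    }
  }
  out
}
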