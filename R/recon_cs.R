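#' Reconstruction configuration for the FISTA solver
#'
#' The solver minimises
#' \deqn{\|C R x - y\|_2^2 + \lambda_1 \|x\|_1 + \lambda_2 \|x\|_{TV}}
#' where C is convolution with the first-derivative lineshape and R the 3D
#' Radon transform. Presets: `"phantom"` uses (0.1, 0.01); `"invivo"` uses
#' (0.01, 0.01), the smaller L1 weight suiting the lower SNR and softer
#' signal edges of animal data.
#'
#' @param lambda1 L1 (sparsity) weight.
#' @param lambda2 total-variation weight.
#' @param n_iter outer FISTA iterations (default 4).
#' @param matrix,fov reconstruction grid (voxels; mm).
#' @param nonneg clamp the iterates to non-negative intensities.
#' @param step gradient step size, or "auto" for 0.95 / L with L estimated by
#'   10 power iterations on the normal operator.
#' @param tv_inner_iter inner iterations of the TV proximal solver.
#' @param prox_order "tv_l1" (TV denoising then soft-thresholding, default)
#'   or "l1_tv".
#' @param seed seed for the power-iteration start vector.
#' @param preset "phantom" or "invivo"; fills lambda1/lambda2 when they are
#'   not given.
#' @return Object of class `recon_config`.
#' @export
recon_config <- function(lambda1 = NULL, lambda2 = NULL, n_iter = 4,
                         matrix = 64, fov = 37.5, nonneg = TRUE,
                         step = "auto", tv_inner_iter = 10,
                         prox_order = c("tv_l1", "l1_tv"), seed = 0L,
                         preset = c("phantom", "invivo")) {
  preset <- match.arg(preset)
  defaults <- list(phantom = c(0.1, 0.01), invivo = c(0.01, 0.01))[[preset]]
  if (is.null(lambda1)) lambda1 <- defaults[1]
  if (is.null(lambda2)) lambda2 <- defaults[2]
  if (lambda1 < 0 || lambda2 < 0) stop("lambda weights must be non-negative")
  if (n_iter < 1) stop("n_iter must be at least 1")
  structure(list(lambda1 = lambda1, lambda2 = lambda2,
                 n_iter = as.integer(n_iter),
                 matrix = rep_len(as.integer(matrix), 3L),
                 fov = rep_len(as.numeric(fov), 3L),
                 nonneg = isTRUE(nonneg), step = step,
                 tv_inner_iter = as.integer(tv_inner_iter),
                 prox_order = match.arg(prox_order),
                 seed = as.integer(seed), preset = preset),
            class = "recon_config")
}

#' Reconstruction geometry
#'
#' Bundles the voxel grid, field axis, gradient, direction set and lineshape
#' kernel shared by the forward and adjoint operators.
#'
#' @param directions a [direction_set].
#' @param field_axis uniform field axis, mT.
#' @param gradient gradient magnitude, mT/m.
#' @param m a [lineshape_model].
#' @param matrix,fov voxel grid.
#' @return Object of class `recon_geometry`.
#' @export
recon_geometry <- function(directions, field_axis, gradient, m,
                           matrix = 64, fov = 37.5) {
  stopifnot(inherits(directions, "direction_set"),
            inherits(m, "lineshape_model"))
  template <- volume_image(array(0, rep_len(as.integer(matrix), 3L)),
                           rep_len(as.numeric(fov), 3L))
  structure(list(directions = directions, field_axis = field_axis,
                 gradient = gradient, kernel = lineshape_kernel(m, field_axis),
                 template = template),
            class = "recon_geometry")
}

#' Forward operator of the CS model
#'
#' `A x = C R x`: plane-integral projection of the volume along every
#' direction, then convolution with the first-derivative lineshape.
#'
#' @param x a [volume_image] on the geometry's grid (or a bare 3D array).
#' @param geom a [recon_geometry].
#' @return Spectra matrix, n_directions x n_field_points.
#' @export
forward_op <- function(x, geom) {
  stopifnot(inherits(geom, "recon_geometry"))
  if (!inherits(x, "volume_image")) {
    x <- volume_image(array(x, geom$template$matrix), geom$template$fov,
                      geom$template$origin)
  }
  if (!same_geometry(x, geom$template)) stop("volume/geometry mismatch")
  prof <- suppressWarnings(
    plane_projection(x, geom$directions, geom$field_axis, geom$gradient))
  conv_same_rows(prof, geom$kernel)
}

#' Adjoint operator of the CS model
#'
#' Exact numerical transpose of [forward_op]: correlation with the lineshape
#' kernel along the field axis, then back-projection. Satisfies the
#' dot-product identity `<Ax, y> = <x, A'y>` to near machine precision.
#'
#' @param y spectra matrix, n_directions x n_field_points.
#' @param geom a [recon_geometry].
#' @return A [volume_image].
#' @export
adjoint_op <- function(y, geom) {
  stopifnot(inherits(geom, "recon_geometry"))
  if (nrow(y) != geom$directions$n) stop("spectra/geometry mismatch")
  prof <- corr_same_rows(y, geom$kernel)
  plane_backprojection(prof, geom$directions, geom$field_axis, geom$gradient,
                       geom$template)
}

#' Soft-thresholding (proximal operator of the L1 norm)
#'
#' Elementwise `sign(v) * max(|v| - tau, 0)`; the exact minimiser of
#' `(u - v)^2 / 2 + tau * |u|`.
#'
#' @param x a [volume_image] or numeric array.
#' @param tau threshold, >= 0.
#' @return Same type as `x`.
#' @export
soft_threshold <- function(x, tau) {
  if (tau < 0) stop("tau must be non-negative")
  if (inherits(x, "volume_image")) {
    x$data <- sign(x$data) * pmax(abs(x$data) - tau, 0)
    x
  } else {
    sign(x) * pmax(abs(x) - tau, 0)
  }
}

## forward differences with reflective (Neumann) boundary: last slice 0
shift_diff <- function(a, axis) {
  d <- dim(a); n <- d[axis]
  idx <- lapply(d, seq_len)
  ip <- idx; ip[[axis]] <- c(2:n, n)
  do.call(`[`, c(list(a), ip)) - a
}

## discrete divergence (negative transpose of shift_diff) from backward
## differences; assumes the dual field vanishes on the trailing boundary,
## which the projected-gradient iteration preserves
divergence3 <- function(px, py, pz) {
  d <- dim(px)
  bdiff <- function(p, axis) {
    n <- d[axis]
    idx <- lapply(d, seq_len)
    im <- idx; im[[axis]] <- c(1, 1:(n - 1))
    pm <- do.call(`[`, c(list(p), im))
    out <- p - pm
    ## boundary handling of the transpose of shift_diff
    first <- idx; first[[axis]] <- 1
    last <- idx; last[[axis]] <- n
    out_first <- do.call(`[`, c(list(p), first))
    arr_assign(out, first, out_first)
  }
  bdiff(px, 1) + bdiff(py, 2) + bdiff(pz, 3)
}

arr_assign <- function(a, idx, value) {
  do.call(`[<-`, c(list(a), idx, list(value)))
}

#' Total variation of a volume
#'
#' Isotropic TV with 3D forward differences and reflective boundaries:
#' the sum over voxels of the Euclidean norm of the discrete gradient.
#'
#' @param x a [volume_image] or 3D array.
#' @return Non-negative scalar.
#' @export
total_variation <- function(x) {
  a <- if (inherits(x, "volume_image")) x$data else as.array(x)
  gx <- shift_diff(a, 1); gy <- shift_diff(a, 2); gz <- shift_diff(a, 3)
  sum(sqrt(gx^2 + gy^2 + gz^2))
}

#' Total-variation denoising (approximate proximal operator)
#'
#' Approximately solves `min_u 0.5 ||u - x||^2 + weight * TV(u)` by a fixed
#' number of dual projected-gradient iterations (Chambolle's scheme, step
#' 1/12 for the 3D operator norm bound). The primal energy is non-increasing
#' as the inner iteration count grows.
#'
#' @param x a [volume_image] or 3D array.
#' @param weight TV weight, >= 0.
#' @param n_inner dual iterations (default 10).
#' @return Same type as `x`.
#' @export
tv_denoise <- function(x, weight, n_inner = 10) {
  if (weight < 0) stop("weight must be non-negative")
  isvol <- inherits(x, "volume_image")
  a <- if (isvol) x$data else as.array(x)
  if (weight == 0 || n_inner < 1) return(x)
  tau <- 1 / 12
  px <- array(0, dim(a)); py <- px; pz <- px
  for (i in seq_len(n_inner)) {
    u <- divergence3(px, py, pz) - a / weight
    gx <- shift_diff(u, 1); gy <- shift_diff(u, 2); gz <- shift_diff(u, 3)
    den <- 1 + tau * sqrt(gx^2 + gy^2 + gz^2)
    px <- (px + tau * gx) / den
    py <- (py + tau * gy) / den
    pz <- (pz + tau * gz) / den
  }
  out <- a - weight * divergence3(px, py, pz)
  if (isvol) { x$data <- out; x } else out
}

#' Estimate the Lipschitz constant of the normal operator
#'
#' Power iteration on `A' A` (10 iterations, seeded start), returning the
#' largest eigenvalue estimate, i.e. the Lipschitz constant of the gradient
#' of `0.5 ||Ax - y||^2`.
#'
#' @param geom a [recon_geometry].
#' @param n_iter power iterations.
#' @param seed RNG seed for the start vector.
#' @return Positive scalar.
#' @export
estimate_lipschitz <- function(geom, n_iter = 10, seed = 0L) {
  v <- with_seed(seed,
    array(stats::rnorm(prod(geom$template$matrix)), geom$template$matrix))
  v <- v / sqrt(sum(v^2))
  lam <- 1
  for (i in seq_len(n_iter)) {
    w <- adjoint_op(forward_op(v, geom), geom)$data
    lam <- sqrt(sum(w^2))
    if (lam == 0) return(1)
    v <- w / lam
  }
  lam
}

#' FISTA compressed-sensing reconstruction
#'
#' Monotone FISTA on the L1 + TV regularised least-squares problem. Each
#' iteration takes a gradient step on `0.5 ||CRx - y||^2` with step `0.95/L`,
#' applies TV denoising with weight `lambda2 * step` and soft-thresholding
#' with threshold `lambda1 * step` (order per config), optionally clamps to
#' non-negative values, and keeps the best iterate so the objective is
#' non-increasing. Spectra are normalised to unit maximum absolute value
#' internally; the returned volume is max-normalised to 1, so a series of
#' frames must be rescaled afterwards with [renormalize_series].
#'
#' @param y a [projection_set] (or bare spectra matrix).
#' @param cfg a [recon_config].
#' @param m a [lineshape_model]; defaults to the 0.073 mT Lorentzian.
#' @param geom optional precomputed [recon_geometry] (overrides `cfg$matrix`
#'   and `cfg$fov` sources).
#' @return A [volume_image] with attributes `objective` (per-iteration values
#'   of the internally scaled objective) and `step`.
#' @export
fista_reconstruct <- function(y, cfg = recon_config(), m = lineshape_model(),
                              geom = NULL) {
  stopifnot(inherits(cfg, "recon_config"))
  if (inherits(y, "projection_set")) {
    if (is.null(geom)) {
      geom <- recon_geometry(y$directions, y$field_axis,
                             y$protocol$gradient_magnitude, m,
                             cfg$matrix, cfg$fov)
    }
    ymat <- y$spectra
  } else {
    if (is.null(geom)) stop("geom is required when y is a bare matrix")
    ymat <- as.matrix(y)
  }
  if (nrow(ymat) != geom$directions$n) stop("spectra/direction count mismatch")
  ymax <- max(abs(ymat))
  if (ymax == 0) {
    warning("all-zero observations: returning a zero volume")
    out <- geom$template
    attr(out, "objective") <- 0
    return(out)
  }
  yn <- ymat / ymax
  L <- if (identical(cfg$step, "auto")) {
    estimate_lipschitz(geom, 10, cfg$seed)
  } else 0.95 / as.numeric(cfg$step)
  step <- 0.95 / L
  prox <- function(a) {
    if (cfg$prox_order == "tv_l1") {
      a <- tv_denoise(a, cfg$lambda2 * step, cfg$tv_inner_iter)
      a <- soft_threshold(a, cfg$lambda1 * step)
    } else {
      a <- soft_threshold(a, cfg$lambda1 * step)
      a <- tv_denoise(a, cfg$lambda2 * step, cfg$tv_inner_iter)
    }
    if (cfg$nonneg) a[a < 0] <- 0
    a
  }
  obj <- function(a) {
    r <- forward_op(a, geom) - yn
    0.5 * sum(r^2) + cfg$lambda1 * sum(abs(a)) + cfg$lambda2 * total_variation(a)
  }
  x <- array(0, geom$template$matrix)
  xprev <- x
  z <- x
  tk <- 1
  fx <- obj(x)
  trace <- numeric(cfg$n_iter)
  yk <- x
  for (it in seq_len(cfg$n_iter)) {
    g <- adjoint_op(forward_op(yk, geom) - yn, geom)$data
    zk <- prox(yk - step * g)
    fz <- obj(zk)
    if (fz <= fx) { xnew <- zk; fnew <- fz } else { xnew <- x; fnew <- fx }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    yk <- xnew + (tk / tk1) * (zk - xnew) + ((tk - 1) / tk1) * (xnew - x)
    x <- xnew; fx <- fnew; tk <- tk1
    trace[it] <- fx
  }
  mx <- max(x)
  if (mx > 0) x <- x / mx
  out <- volume_image(x, geom$template$fov, geom$template$origin)
  attr(out, "objective") <- trace
  attr(out, "step") <- step
  out
}

#' Restore inter-frame amplitudes of a reconstructed series
#'
#' CS reconstruction max-normalises every frame, destroying the decay
#' profile. Each frame is rescaled by the mean double-integrated amplitude of
#' its own spectral projections, which is proportional to the spin count in
#' the sensitive volume at that time point.
#'
#' @param frames an [image_series] of reconstructed (normalised) volumes.
#' @param spectra_sets list of [projection_set]s, one per frame, in order.
#' @return An [image_series] with recovered relative amplitudes.
#' @export
renormalize_series <- function(frames, spectra_sets) {
  stopifnot(inherits(frames, "image_series"))
  if (length(frames$frames) != length(spectra_sets)) {
    stop("frame count and spectra-set count differ")
  }
  scales <- vapply(spectra_sets, function(s) {
    stopifnot(inherits(s, "projection_set"))
    mean(apply(s$spectra, 1L, double_integral, field_axis = s$field_axis))
  }, numeric(1))
  newf <- lapply(seq_along(frames$frames), function(i) {
    f <- frames$frames[[i]]
    volume_image(f$data * scales[i], f$fov, f$origin)
  })
  image_series(newf, frames$times, unit = frames$unit, meta = frames$meta)
}
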