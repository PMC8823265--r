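#' Spectral projection set
#'
#' The observation container of EPR imaging: one first-derivative spectrum per
#' gradient direction, with the common field axis and acquisition protocol.
#'
#' @param spectra numeric matrix, n_directions x n_field_points.
#' @param directions a [direction_set] with matching row count.
#' @param field_axis strictly increasing field offsets, mT, spanning the
#'   protocol sweep width.
#' @param protocol a [scan_protocol].
#' @param zero_gradient_spectrum optional reference spectrum acquired without
#'   gradient.
#' @param timestamp frame start time, s.
#' @return Object of class `projection_set`.
#' @export
projection_set <- function(spectra, directions, field_axis, protocol,
                           zero_gradient_spectrum = NULL, timestamp = 0) {
  stopifnot(inherits(directions, "direction_set"),
            inherits(protocol, "scan_protocol"))
  spectra <- as.matrix(spectra)
  if (nrow(spectra) != directions$n) {
    stop("spectra row count must equal the number of directions")
  }
  if (ncol(spectra) != length(field_axis)) {
    stop("spectra column count must equal the field axis length")
  }
  if (any(diff(field_axis) <= 0)) stop("field_axis must be strictly increasing")
  span <- field_axis[length(field_axis)] - field_axis[1]
  if (abs(span - protocol$sweep_width) > 1e-9) {
    stop("field_axis span must equal the protocol sweep width")
  }
  structure(list(spectra = spectra, directions = directions,
                 field_axis = field_axis, protocol = protocol,
                 zero_gradient_spectrum = zero_gradient_spectrum,
                 timestamp = timestamp),
            class = "projection_set")
}

#' @export
print.projection_set <- function(x, ...) {
  cat(sprintf("<projection_set> %d spectra x %d field points, sweep %.3g mT, gradient %.3g mT/m\n",
              nrow(x$spectra), ncol(x$spectra),
              x$protocol$sweep_width, x$protocol$gradient_magnitude))
  invisible(x)
}

#' Keep the first n directions of a projection set
#'
#' Golden-mean schedules are nested, so truncating an acquired set to a prefix
#' emulates a shorter acquisition.
#'
#' @param s a [projection_set].
#' @param n number of leading projections to keep.
#' @export
subset_projections <- function(s, n) {
  stopifnot(inherits(s, "projection_set"))
  if (n < 1 || n > s$directions$n) stop("n out of range")
  projection_set(s$spectra[seq_len(n), , drop = FALSE],
                 direction_set(s$directions$vectors[seq_len(n), , drop = FALSE],
                               scheme = s$directions$scheme),
                 s$field_axis, s$protocol,
                 s$zero_gradient_spectrum, s$timestamp)
}

field_step <- function(field_axis) {
  db <- diff(field_axis)
  if (any(abs(db - db[1]) > 1e-9 * abs(db[1]))) {
    stop("field_axis must be uniformly spaced")
  }
  db[1]
}

#' Plane-integral projection of a volume
#'
#' The 3D Radon transform used in EPR imaging: for field offset `b`, the
#' integral of the volume over the plane `gradient * (r . d) = b`. Voxel mass
#' is split linearly between the two nearest field bins, which conserves total
#' mass: `sum(out) * db = sum(v) * voxel_volume * gradient` for objects fully
#' inside the field of view. Mass projected outside the axis raises a warning
#' (no wrap-around).
#'
#' @param v a [volume_image] with isotropic voxels.
#' @param d unit 3-vector, or a [direction_set] (all rows projected at once).
#' @param field_axis uniform, strictly increasing field offsets, mT.
#' @param gradient gradient magnitude, mT/m (> 0).
#' @return Numeric vector (single direction) or matrix n_dir x n_field.
#' @export
plane_projection <- function(v, d, field_axis, gradient) {
  stopifnot(inherits(v, "volume_image"))
  if (gradient <= 0) stop("gradient must be positive")
  if (max(abs(v$spacing - v$spacing[1])) > 1e-9) {
    stop("plane_projection requires isotropic voxels")
  }
  single <- !inherits(d, "direction_set")
  dirs <- if (single) matrix(as.numeric(d), 1, 3) else d$vectors
  db <- field_step(field_axis)
  prof <- radon_project_cpp(as.numeric(v$data), as.integer(v$matrix),
                            v$spacing, v$origin, dirs,
                            field_axis[1], db, length(field_axis), gradient)
  if (attr(prof, "overflow") > 0) {
    warning("object mass projected outside the field axis (FOV overflow)")
  }
  if (single) as.numeric(prof) else prof
}

#' Back-projection (adjoint of [plane_projection])
#'
#' Spreads projection profiles back over the volume along their planes. This
#' is the exact numerical transpose of [plane_projection] and is the
#' workhorse of both FBP and the FISTA gradient.
#'
#' @param prof matrix n_dir x n_field (or vector for one direction).
#' @param d a [direction_set] or unit 3-vector.
#' @param field_axis,gradient as in [plane_projection].
#' @param geom a [volume_image] providing the target voxel grid (its data are
#'   ignored).
#' @return A [volume_image] on the grid of `geom`.
#' @export
plane_backprojection <- function(prof, d, field_axis, gradient, geom) {
  stopifnot(inherits(geom, "volume_image"))
  dirs <- if (inherits(d, "direction_set")) d$vectors else matrix(as.numeric(d), 1, 3)
  if (is.null(dim(prof))) prof <- matrix(prof, nrow = 1)
  db <- field_step(field_axis)
  vol <- radon_backproject_cpp(prof, as.integer(geom$matrix), geom$spacing,
                               geom$origin, dirs, field_axis[1], db,
                               length(field_axis), gradient)
  volume_image(array(vol, geom$matrix), geom$fov, geom$origin)
}

## --- convolution along the field axis -------------------------------------
## The lineshape kernel is evaluated on a centred odd-length offset axis so
## that "same"-mode convolution is zero-phase and self-transposable (the
## adjoint is convolution with the reversed kernel at the same crop).

lineshape_kernel <- function(m, field_axis) {
  db <- field_step(field_axis)
  nf <- length(field_axis)
  h <- if (nf %% 2 == 1) (nf - 1) / 2 else nf / 2 - 1
  ka <- (-h:h) * db
  ## lineshape_profile evaluates at ka - center_offset, so a nonzero line
  ## centre shifts the kernel (and hence every spectrum) by that offset
  lineshape_profile(m, ka) * db
}

conv_same_rows <- function(mat, kernel) {
  nf <- ncol(mat); mk <- length(kernel); h <- (mk - 1) / 2
  L <- stats::nextn(nf + mk - 1, 2)
  K <- stats::fft(c(kernel, numeric(L - mk)))
  X <- stats::mvfft(t(cbind(mat, matrix(0, nrow(mat), L - nf))))
  Z <- Re(stats::mvfft(X * K, inverse = TRUE)) / L
  t(Z)[, h + seq_len(nf), drop = FALSE]
}

corr_same_rows <- function(mat, kernel) conv_same_rows(mat, rev(kernel))

#' Simulate CW-EPR spectral projections of a volume
#'
#' Each spectrum is the plane-integral projection of the volume along its
#' gradient direction, convolved along the field axis with the
#' first-derivative lineshape ("same" mode, zero padded), plus optional i.i.d.
#' Gaussian noise. When the protocol includes a zero-gradient scan, that
#' reference spectrum is the lineshape carrying the object's total mass at the
#' line centre.
#'
#' @param v a [volume_image].
#' @param ds a [direction_set].
#' @param m a [lineshape_model].
#' @param p a [scan_protocol].
#' @param noise_sd standard deviation of additive spectral noise (same units
#'   as the spectra); 0 for noiseless.
#' @param seed integer seed making the noise reproducible.
#' @param timestamp frame start time, s.
#' @return A [projection_set].
#' @export
simulate_spectra <- function(v, ds, m, p, noise_sd = 0, seed = 1L,
                             timestamp = 0) {
  stopifnot(inherits(v, "volume_image"), inherits(ds, "direction_set"),
            inherits(m, "lineshape_model"), inherits(p, "scan_protocol"))
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  fa <- field_axis(p)
  prof <- plane_projection(v, ds, fa, p$gradient_magnitude)
  ker <- lineshape_kernel(m, fa)
  spectra <- conv_same_rows(prof, ker)
  zg <- NULL
  if (p$includes_zero_gradient) {
    mass <- sum(v$data) * voxel_volume(v) * p$gradient_magnitude
    zg <- lineshape_profile(m, fa) * mass
  }
  if (noise_sd > 0) {
    noise <- with_seed(seed, {
      n1 <- matrix(stats::rnorm(length(spectra), sd = noise_sd),
                   nrow(spectra), ncol(spectra))
      n2 <- if (is.null(zg)) NULL else stats::rnorm(length(zg), sd = noise_sd)
      list(n1, n2)
    })
    spectra <- spectra + noise[[1]]
    if (!is.null(zg)) zg <- zg + noise[[2]]
  }
  projection_set(spectra, ds, fa, p, zg, timestamp)
}
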