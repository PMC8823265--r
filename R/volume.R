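#' 3D volume image
#'
#' Container for a 3D scalar field of EPR signal intensity together with its
#' physical geometry. Voxels are cube-shaped; the field of view is centred on
#' the origin of the laboratory frame unless `origin` says otherwise, so the
#' centre of voxel `(i, j, k)` sits at `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param fov physical field of view in mm, length 1 (isotropic) or 3.
#' @param origin mm coordinate of the first voxel centre; default centres the
#'   FOV on (0,0,0).
#' @return Object of class `volume_image` with fields `data`, `fov`, `matrix`
#'   (voxel counts), `spacing` (mm), `origin` (mm).
#' @export
volume_image <- function(data, fov, origin = NULL) {
  data <- as.array(data)
  if (length(dim(data)) != 3L) stop("data must be a 3D array")
  m <- dim(data)
  fov <- rep_len(as.numeric(fov), 3L)
  if (any(fov <= 0)) stop("fov must be positive")
  spacing <- fov / m
  if (is.null(origin)) origin <- -fov / 2 + spacing / 2
  origin <- rep_len(as.numeric(origin), 3L)
  structure(list(data = data, fov = fov, matrix = m,
                 spacing = spacing, origin = origin),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, FOV %s mm, range [%.4g, %.4g]\n",
              paste(x$matrix, collapse = "x"),
              paste(signif(x$fov, 4), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Voxel-centre coordinates of a volume
#'
#' @param v a [volume_image].
#' @param axis 1, 2 or 3.
#' @return Numeric vector of voxel-centre coordinates (mm) along `axis`.
#' @export
voxel_coords <- function(v, axis) {
  stopifnot(inherits(v, "volume_image"))
  v$origin[axis] + (seq_len(v$matrix[axis]) - 1) * v$spacing[axis]
}

#' Voxel volume in mm^3
#' @param v a [volume_image].
#' @export
voxel_volume <- function(v) prod(v$spacing)

same_geometry <- function(a, b, tol = 1e-9) {
  all(a$matrix == b$matrix) &&
    all(abs(a$fov - b$fov) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

#' Check two volumes share a voxel grid
#' @param a,b [volume_image] objects.
#' @return TRUE/FALSE.
#' @export
compatible_volumes <- function(a, b) same_geometry(a, b)
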