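## Golden-mean sampling of gradient directions on the unit sphere.
##
## The two 3D golden means drive a pair of coupled fractional-part sequences:
## phi2 is the real root of x^3 + x - 1 = 0 and phi1 = phi2^2.  Index i (from 1)
## maps to z = 2*frac(i*phi1) - 1 and azimuth 2*pi*frac(i*phi2), covering the
## full sphere quasi-uniformly; every prefix of the sequence is itself a
## quasi-uniform set, which is what makes retrospective undersampling of an
## acquired projection schedule possible.

#' 3D golden-mean constants
#'
#' `GOLDEN_MEAN_2` is the real root of \eqn{x^3 + x - 1 = 0};
#' `GOLDEN_MEAN_1` is its square. These are the two "golden means" of the
#' modified-Fibonacci (3x3 matrix) eigen-construction used for quasi-uniform
#' direction schedules on the sphere.
#'
#' @format Numeric scalars.
#' @export
GOLDEN_MEAN_2 <- local({
  f <- function(x) x^3 + x - 1
  uniroot(f, c(0.5, 1), tol = .Machine$double.eps)$root
})

#' @rdname GOLDEN_MEAN_2
#' @export
GOLDEN_MEAN_1 <- GOLDEN_MEAN_2^2

#' Construct a direction set
#'
#' A `direction_set` is an ordered list of unit vectors on the sphere, one per
#' magnetic-field-gradient direction of a projection acquisition.
#'
#' @param vectors numeric matrix, n x 3, rows are direction vectors (need not
#'   be normalised; they are checked, not rescaled).
#' @param scheme label for how the set was generated.
#' @return An object of class `direction_set` with fields `n`, `vectors`,
#'   `scheme`.
#' @export
direction_set <- function(vectors, scheme = "explicit") {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3L) stop("direction vectors must have 3 components")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-12)) {
    stop("all direction vectors must have unit norm (within 1e-12)")
  }
  structure(list(n = nrow(vectors), vectors = vectors, scheme = scheme),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  cat(sprintf("<direction_set> %d directions (%s)\n", x$n, x$scheme))
  invisible(x)
}

#' Golden-mean gradient-direction schedule
#'
#' Generates `n` unit vectors on the full sphere by the two-golden-means
#' construction: for index \eqn{i = 1..n}, \eqn{z_i = 2\,\mathrm{frac}(i\phi_1)-1}
#' and azimuth \eqn{\theta_i = 2\pi\,\mathrm{frac}(i\phi_2)}. The sequence is
#' deterministic and nested: the first `m` directions of
#' `golden_mean_directions(n)` equal `golden_mean_directions(m)` exactly, so a
#' long acquisition can be retrospectively truncated to any shorter schedule.
#'
#' @param n number of directions (positive integer).
#' @return A [direction_set] with `scheme = "golden_mean"`.
#' @examples
#' d <- golden_mean_directions(64)
#' range(sqrt(rowSums(d$vectors^2)))  # all 1
#' @export
golden_mean_directions <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1) {
    stop("n must be a positive integer")
  }
  n <- as.integer(n)
  i <- seq_len(n)
  z <- 2 * ((i * GOLDEN_MEAN_1) %% 1) - 1
  th <- 2 * pi * ((i * GOLDEN_MEAN_2) %% 1)
  s <- sqrt(pmax(0, 1 - z^2))
  v <- cbind(s * cos(th), s * sin(th), z)
  ## rows are unit vectors by construction; renormalise to keep the norm
  ## invariant exact against accumulated rounding
  v <- v / sqrt(rowSums(v^2))
  direction_set(v, scheme = "golden_mean")
}

#' Angular uniformity score of a direction set
#'
#' Coefficient of variation of the nearest-neighbour angular distances
#' (radians) between directions. 0 means perfectly even nearest-neighbour
#' spacing; larger values indicate clumping. Used to compare sampling schemes:
#' golden-mean schedules score well below uniform-random sets of the same size.
#'
#' @param d a [direction_set] with at least 2 directions.
#' @return Non-negative scalar.
#' @export
uniformity_score <- function(d) {
  stopifnot(inherits(d, "direction_set"))
  if (d$n < 2) stop("uniformity_score requires at least 2 directions")
  g <- tcrossprod(d$vectors)           # cosines of pairwise angles
  g[g > 1] <- 1; g[g < -1] <- -1
  ang <- acos(g)
  diag(ang) <- Inf
  nn <- apply(ang, 1L, min)
  if (mean(nn) == 0) return(0)
  stats::sd(nn) / mean(nn)
}

#' Write/read a direction set as CSV
#'
#' Plain-text serialisation: three columns `x,y,z`, one row per direction,
#' full double precision.
#'
#' @param d a [direction_set].
#' @param path file path.
#' @return `read_directions_csv` returns a [direction_set];
#'   `write_directions_csv` returns `path` invisibly.
#' @export
write_directions_csv <- function(d, path) {
  stopifnot(inherits(d, "direction_set"))
  df <- as.data.frame(d$vectors)
  names(df) <- c("x", "y", "z")
  utils::write.table(df, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' @rdname write_directions_csv
#' @param scheme scheme label to attach on read.
#' @export
read_directions_csv <- function(path, scheme = "explicit") {
  df <- utils::read.csv(path)
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("direction CSV must have columns x,y,z")
  }
  v <- as.matrix(df[, c("x", "y", "z")])
  v <- v / sqrt(rowSums(v^2))  # re-normalise after decimal round trip
  direction_set(v, scheme = scheme)
}
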