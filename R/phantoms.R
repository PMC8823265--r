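## Digital phantoms: the multiple-pillar solution phantom used to benchmark
## reconstruction, and a two-compartment decaying object for end-to-end
## decay-rate recovery experiments.

## Cross-section layout of the 10 solution pillars: a triangular 1-2-3-4
## packing at the printed 5.0 mm centre-to-centre pitch, centred in the
## 21.8 mm housing.  The published drawing fixes count, pitch, diameter and
## length; the exact row arrangement is approximate.
PILLAR_PITCH_MM <- 5.0
PILLAR_DIAMETER_MM <- 3.0
PILLAR_LENGTH_MM <- 15.0
PILLAR_HOUSING_DIAMETER_MM <- 21.8

pillar_centers <- function() {
  pitch <- PILLAR_PITCH_MM
  rows <- list(1L, 2L, 3L, 4L)
  ys <- (seq_along(rows) - 2.5) * pitch * sqrt(3) / 2
  xy <- do.call(rbind, lapply(seq_along(rows), function(r) {
    k <- rows[[r]]
    x <- (seq_len(k) - (k + 1) / 2) * pitch
    cbind(x, rep(ys[r], k))
  }))
  xy - matrix(colMeans(xy), nrow(xy), 2, byrow = TRUE)
}

#' Multiple-pillar solution phantom
#'
#' Digital twin of a cylindrical solution phantom: ten parallel pillars of
#' radical solution, 3.0 mm diameter and 15.0 mm long at 5.0 mm
#' centre-to-centre spacing inside a 21.8 mm housing (total filled volume
#' about 1.06 mL). Intensity is 1 inside the solution and 0 outside, with
#' partial-volume anti-aliasing: 8x8 in-plane supersampling of the curved
#' walls and exact fractional overlap at the flat end caps.
#'
#' @param matrix voxel counts per axis (scalar or length 3).
#' @param fov field of view in mm (scalar or length 3); must be at least the
#'   21.8 mm housing diameter.
#' @return A [volume_image]. Pillars run along the z axis.
#' @export
pillar_phantom <- function(matrix = 64, fov = 37.5) {
  m <- rep_len(as.integer(matrix), 3L)
  fov <- rep_len(as.numeric(fov), 3L)
  if (any(fov < PILLAR_HOUSING_DIAMETER_MM)) {
    stop("fov must be at least the 21.8 mm housing diameter")
  }
  centers <- pillar_centers()
  r <- PILLAR_DIAMETER_MM / 2
  halfL <- PILLAR_LENGTH_MM / 2
  spacing <- fov / m
  ## partial-volume anti-aliasing: 8x8 in-plane supersampling for the curved
  ## cylinder walls; the flat end caps get the exact per-voxel overlap
  off8 <- (seq_len(8) - 4.5) / 8
  sub <- as.matrix(expand.grid(ox = off8, oy = off8))
  x0 <- -fov / 2 + spacing / 2
  z <- x0[3] + (seq_len(m[3]) - 1) * spacing[3]
  zcov <- pmin(pmax((pmin(z + spacing[3] / 2, halfL) -
                       pmax(z - spacing[3] / 2, -halfL)) / spacing[3], 0), 1)
  sl <- matrix(0, m[1], m[2])
  for (s in seq_len(nrow(sub))) {
    x <- x0[1] + (seq_len(m[1]) - 1 + sub[s, 1]) * spacing[1]
    y <- x0[2] + (seq_len(m[2]) - 1 + sub[s, 2]) * spacing[2]
    hit <- matrix(0, m[1], m[2])
    for (p in seq_len(nrow(centers))) {
      d2 <- outer((x - centers[p, 1])^2, (y - centers[p, 2])^2, "+")
      hit <- hit + (d2 <= r^2)
    }
    sl <- sl + pmin(hit, 1)
  }
  volume_image(outer(sl / nrow(sub), zcov), fov)
}

#' Decay phantom specification
#'
#' A base intensity volume (the initial amplitude field A0) plus a voxelwise
#' decay-rate field and the frame times of an imaging series.
#'
#' @param base [volume_image] of initial amplitudes A0.
#' @param rate_map 3D array of decay rates k, 1/min, same dimensions.
#' @param frame_times strictly increasing frame times, minutes.
#' @return Object of class `decay_phantom_spec`.
#' @export
decay_phantom_spec <- function(base, rate_map, frame_times) {
  stopifnot(inherits(base, "volume_image"))
  rate_map <- as.array(rate_map)
  if (!all(dim(rate_map) == base$matrix)) stop("rate_map dimensions mismatch")
  if (any(rate_map < 0)) stop("decay rates must be non-negative")
  if (any(diff(frame_times) <= 0)) {
    stop("frame_times must be strictly increasing")
  }
  structure(list(base = base, rate_map = rate_map, frame_times = frame_times),
            class = "decay_phantom_spec")
}

#' Default frame times of a redox-mapping series
#'
#' Image frames acquired back-to-back every 16.8 s (128 projections plus the
#' zero-gradient scan at 130 ms per scan) starting 30 s after probe
#' injection; the timestamp of a frame is its mid-acquisition time.
#'
#' @param n_frames number of frames.
#' @param frame_duration_s seconds per frame.
#' @param start_s series start after injection, s.
#' @param unit "min" (default, matching decay rates in 1/min) or "s".
#' @return Numeric vector of frame mid-scan times.
#' @export
series_frame_times <- function(n_frames = 5, frame_duration_s = 16.8,
                               start_s = 30, unit = c("min", "s")) {
  unit <- match.arg(unit)
  t <- start_s + (seq_len(n_frames) - 1) * frame_duration_s +
    frame_duration_s / 2
  if (unit == "min") t / 60 else t
}

#' Two-compartment leg phantom with distinct decay rates
#'
#' Synthetic stand-in for a tumor-bearing leg: an ellipsoidal "leg" of uniform
#' initial amplitude with an embedded spherical "tumor". The tumor compartment
#' carries `rate_tumor`, the remaining leg tissue `rate_normal`. Defaults are
#' 1.00 and 1.36 1/min, the normal/tumor group means the mapping experiment
#' is designed to distinguish.
#'
#' @param matrix,fov voxel counts and field of view (mm) per axis.
#' @param rate_normal,rate_tumor decay rates, 1/min.
#' @param frame_times frame times (minutes); default [series_frame_times()].
#' @return A [decay_phantom_spec]. The element `tumor_mask` attribute of the
#'   rate map marks the tumor compartment.
#' @export
two_compartment_leg_phantom <- function(matrix = 48, fov = 37.5,
                                        rate_normal = 1.00, rate_tumor = 1.36,
                                        frame_times = series_frame_times()) {
  if (rate_normal < 0 || rate_tumor < 0) stop("rates must be non-negative")
  m <- rep_len(as.integer(matrix), 3L)
  fov <- rep_len(as.numeric(fov), 3L)
  spacing <- fov / m
  x <- -fov[1] / 2 + (seq_len(m[1]) - 0.5) * spacing[1]
  y <- -fov[2] / 2 + (seq_len(m[2]) - 0.5) * spacing[2]
  z <- -fov[3] / 2 + (seq_len(m[3]) - 0.5) * spacing[3]
  ## leg: ellipsoid semi-axes 8 x 8 x 12 mm; tumor: 4 mm sphere offset in +x
  ax <- c(8, 8, 12); tc <- c(3.5, 0, 0); tr <- 4
  X <- array(rep(x, times = m[2] * m[3]), m)
  Y <- array(rep(rep(y, each = m[1]), times = m[3]), m)
  Z <- array(rep(z, each = m[1] * m[2]), m)
  leg <- (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1
  tumor <- (X - tc[1])^2 + (Y - tc[2])^2 + (Z - tc[3])^2 <= tr^2
  tumor <- tumor & leg
  base <- volume_image(array(as.numeric(leg), m), fov)
  rates <- array(0, m)
  rates[leg] <- rate_normal
  rates[tumor] <- rate_tumor
  attr(rates, "tumor_mask") <- tumor
  decay_phantom_spec(base, rates, frame_times)
}

#' Generate the decaying image series of a decay phantom
#'
#' Frame f is `base * exp(-rate_map * frame_times[f])`, voxelwise: a clean,
#' noiseless exponential decay; realistic degradation enters later through
#' spectral noise in the forward simulation.
#'
#' @param spec a [decay_phantom_spec].
#' @return An [image_series].
#' @export
decay_series <- function(spec) {
  stopifnot(inherits(spec, "decay_phantom_spec"))
  frames <- lapply(spec$frame_times, function(t) {
    f <- array(spec$base$data * exp(-spec$rate_map * t), spec$base$matrix)
    volume_image(f, spec$base$fov, spec$base$origin)
  })
  image_series(frames, spec$frame_times, unit = "min")
}
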