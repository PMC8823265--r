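#' CW-EPR acquisition protocol
#'
#' Scan parameters of a continuous-wave EPR imaging acquisition. Defaults are
#' a 1.5 mT sweep scanned in 100 ms with 30 ms field flyback, 512 field points
#' and a 40 mT/m gradient, giving a reconstruction field of view of
#' sweep_width / gradient = 37.5 mm.
#'
#' @param sweep_width magnetic field sweep, mT.
#' @param scan_duration duration of one field scan, ms.
#' @param flyback_duration time to return the field between scans, ms.
#' @param gradient_magnitude field gradient, mT/m.
#' @param n_field_points samples per scan.
#' @param includes_zero_gradient whether a zero-gradient reference spectrum is
#'   acquired in addition to the gradient projections.
#' @return Object of class `scan_protocol`.
#' @export
scan_protocol <- function(sweep_width = 1.5,
                          scan_duration = 100,
                          flyback_duration = 30,
                          gradient_magnitude = 40,
                          n_field_points = 512,
                          includes_zero_gradient = TRUE) {
  if (sweep_width <= 0) stop("sweep_width must be positive")
  if (scan_duration <= 0) stop("scan_duration must be positive")
  if (n_field_points < 2) stop("n_field_points must be at least 2")
  if (gradient_magnitude < 0) stop("gradient_magnitude must be non-negative")
  structure(list(sweep_width = sweep_width,
                 scan_duration = scan_duration,
                 flyback_duration = flyback_duration,
                 gradient_magnitude = gradient_magnitude,
                 n_field_points = as.integer(n_field_points),
                 includes_zero_gradient = isTRUE(includes_zero_gradient)),
            class = "scan_protocol")
}

#' Field axis of a protocol
#'
#' Centred, strictly increasing axis of field offsets spanning the sweep
#' width, in mT.
#'
#' @param p a [scan_protocol].
#' @export
field_axis <- function(p) {
  stopifnot(inherits(p, "scan_protocol"))
  seq(-p$sweep_width / 2, p$sweep_width / 2, length.out = p$n_field_points)
}

#' Total acquisition time of an image scan
#'
#' One spectral projection takes `scan_duration + flyback_duration`; the
#' zero-gradient reference spectrum, when acquired, costs one extra scan.
#'
#' @param n_projections number of gradient projections.
#' @param p a [scan_protocol].
#' @return Seconds.
#' @examples
#' acquisition_time(256, scan_protocol())  # 33.41 s
#' @export
acquisition_time <- function(n_projections, p) {
  stopifnot(inherits(p, "scan_protocol"))
  if (n_projections < 1) stop("n_projections must be at least 1")
  n_scans <- n_projections + as.integer(p$includes_zero_gradient)
  n_scans * (p$scan_duration + p$flyback_duration) / 1000
}

#' Intrinsic spatial resolution of a CW-EPR image
#'
#' The gradient maps field offsets to positions, so the peak-to-peak linewidth
#' sets the intrinsic resolution: `width / gradient`, converted to mm.
#'
#' @param peak_to_peak_width linewidth, mT.
#' @param gradient field gradient, mT/m.
#' @return Millimetres.
#' @examples
#' resolution_estimate(0.073, 40)  # 1.825 mm, prints as 1.8 at 2 s.f.
#' @export
resolution_estimate <- function(peak_to_peak_width, gradient) {
  if (peak_to_peak_width <= 0 || gradient <= 0) {
    stop("both arguments must be positive")
  }
  peak_to_peak_width / gradient * 1000
}
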