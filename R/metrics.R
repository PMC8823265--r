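#' Normalised root-mean-square error
#'
#' RMS difference over all voxels divided by the dynamic range
#' (max - min) of the reference image. Lower is better; 0 means identical.
#'
#' @param ref,recon [volume_image]s (or arrays) of identical geometry.
#' @return Non-negative scalar.
#' @export
nrmse <- function(ref, recon) {
  ab <- metric_arrays(ref, recon)
  rng <- max(ab$a) - min(ab$a)
  if (rng == 0) stop("reference image is constant: NRMSE undefined")
  sqrt(mean((ab$a - ab$b)^2)) / rng
}

#' Mean absolute error after per-image max-normalisation
#'
#' Both images are divided by their own maximum before taking the mean
#' absolute voxel difference, so MAE is invariant to a positive global scale
#' of either image.
#'
#' @param ref,recon [volume_image]s (or arrays) of identical geometry with
#'   positive maxima.
#' @return Non-negative scalar.
#' @export
mae <- function(ref, recon) {
  ab <- metric_arrays(ref, recon)
  ma <- max(ab$a); mb <- max(ab$b)
  if (ma <= 0 || mb <= 0) stop("both images must have a positive maximum")
  mean(abs(ab$a / ma - ab$b / mb))
}

metric_arrays <- function(ref, recon) {
  if (inherits(ref, "volume_image") && inherits(recon, "volume_image")) {
    if (!same_geometry(ref, recon)) stop("image geometries differ")
    list(a = ref$data, b = recon$data)
  } else {
    a <- as.array(if (inherits(ref, "volume_image")) ref$data else ref)
    b <- as.array(if (inherits(recon, "volume_image")) recon$data else recon)
    if (!all(dim(a) == dim(b))) stop("image dimensions differ")
    list(a = a, b = b)
  }
}

## separable Gaussian filtering along each array axis with a truncated,
## renormalised kernel (window half-width 5, sigma 1.5 by default)
gauss_filter3 <- function(a, sigma = 1.5, half = 5) {
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  d <- dim(a)
  for (axis in 1:3) {
    n <- d[axis]
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      kk <- k[j - i + half + 1]
      W[i, j] <- kk / sum(kk)
    }
    a <- apply_along(a, axis, W)
  }
  a
}

apply_along <- function(a, axis, W) {
  d <- dim(a)
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- W %*% matrix(ap, d[axis])
  aperm(array(m, d[perm]), order(perm))
}

#' Structural similarity index
#'
#' Windowed SSIM with 3D Gaussian weighting (sigma 1.5, 11-voxel support) and
#' stabilisers `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2`, where `L` is the dynamic
#' range of the image pair; the mean of the local SSIM map is returned. The
#' single-window global-statistics formula is available with
#' `method = "global"` (there `L` defaults the same way; pass `c1`/`c2` to
#' override, e.g. ~0 for the pure correlation limit).
#'
#' @param ref,recon [volume_image]s (or arrays) of identical geometry.
#' @param method "windowed" (default) or "global".
#' @param dynamic_range value range L; default `max - min` over both images.
#' @param c1,c2 optional explicit stabiliser constants.
#' @return Scalar in `[-1, 1]` (up to stabiliser effects).
#' @export
ssim <- function(ref, recon, method = c("windowed", "global"),
                 dynamic_range = NULL, c1 = NULL, c2 = NULL) {
  method <- match.arg(method)
  ab <- metric_arrays(ref, recon)
  a <- ab$a; b <- ab$b
  if (is.null(dynamic_range)) {
    dynamic_range <- max(a, b) - min(a, b)
    if (dynamic_range == 0) dynamic_range <- 1
  }
  if (is.null(c1)) c1 <- (0.01 * dynamic_range)^2
  if (is.null(c2)) c2 <- (0.03 * dynamic_range)^2
  if (method == "global") {
    mu1 <- mean(a); mu2 <- mean(b)
    v1 <- mean((a - mu1)^2); v2 <- mean((b - mu2)^2)
    cov <- mean((a - mu1) * (b - mu2))
    return(((2 * mu1 * mu2 + c1) * (2 * cov + c2)) /
             ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2)))
  }
  mu1 <- gauss_filter3(a); mu2 <- gauss_filter3(b)
  s11 <- gauss_filter3(a * a) - mu1^2
  s22 <- gauss_filter3(b * b) - mu2^2
  s12 <- gauss_filter3(a * b) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + c1) * (2 * s12 + c2)) /
    ((mu1^2 + mu2^2 + c1) * (s11 + s22 + c2))
  mean(map)
}

#' Estimate the Gaussian PSF width from a 1D profile
#'
#' Models the measured profile of a structure of known ideal width (e.g. a
#' 3.0 mm rod) as the convolution of a boxcar with a Gaussian point spread
#' function, and fits amplitude, centre, baseline and PSF sigma by least
#' squares. The reported figure of merit is the Gaussian's full width at
#' half maximum, the operational spatial resolution.
#'
#' @param profile 1D intensity vector through the structure.
#' @param spacing sample spacing, mm.
#' @param true_width ideal structure width, mm.
#' @return FWHM in mm, or NA (with a warning) if the fit fails.
#' @export
psf_fwhm_estimate <- function(profile, spacing, true_width) {
  n <- length(profile)
  x <- (seq_len(n) - (n + 1) / 2) * spacing
  w2 <- true_width / 2
  model <- function(p) {
    amp <- p[1]; cen <- p[2]; lsig <- p[3]; base <- p[4]
    sig <- exp(lsig)
    amp * (stats::pnorm((x - cen + w2) / sig) -
             stats::pnorm((x - cen - w2) / sig)) + base
  }
  obj <- function(p) sum((model(p) - profile)^2)
  cen0 <- sum(x * pmax(profile, 0)) / max(sum(pmax(profile, 0)), 1e-12)
  best <- NULL
  for (sig0 in c(0.05, 0.2, 0.5, 1, 2) * max(spacing, true_width / 4)) {
    p0 <- c(max(profile) - min(profile), cen0, log(sig0), min(profile))
    fit <- tryCatch(stats::optim(p0, obj, method = "Nelder-Mead",
                                 control = list(maxit = 2000, reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    warning("PSF fit failed")
    return(NA_real_)
  }
  2 * sqrt(2 * log(2)) * exp(best$par[3])
}
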