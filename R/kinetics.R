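#' Time-ordered series of volume images
#'
#' @param frames list of [volume_image] objects on a common grid.
#' @param times frame times (mid-scan), strictly increasing.
#' @param unit time unit of `times`: "min" or "s". Decay rates fitted from a
#'   series are expressed in 1/unit.
#' @param meta optional free-form acquisition description.
#' @return Object of class `image_series`.
#' @export
image_series <- function(frames, times, unit = c("min", "s"), meta = NULL) {
  unit <- match.arg(unit)
  if (length(frames) != length(times)) stop("frames and times lengths differ")
  if (length(frames) < 1) stop("empty series")
  stopifnot(all(vapply(frames, inherits, TRUE, "volume_image")))
  if (length(frames) > 1) {
    ok <- vapply(frames[-1], same_geometry, TRUE, b = frames[[1]])
    if (!all(ok)) stop("all frames must share the same geometry")
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  structure(list(frames = frames, times = as.numeric(times), unit = unit,
                 meta = meta),
            class = "image_series")
}

#' @export
print.image_series <- function(x, ...) {
  cat(sprintf("<image_series> %d frames, t = %s %s\n", length(x$frames),
              paste(signif(x$times, 4), collapse = ", "), x$unit))
  invisible(x)
}

#' Convert the time unit of a series
#' @param s an [image_series].
#' @param unit target unit, "min" or "s".
#' @export
convert_series_unit <- function(s, unit = c("min", "s")) {
  unit <- match.arg(unit)
  if (unit == s$unit) return(s)
  f <- if (unit == "min") 1 / 60 else 60
  image_series(s$frames, s$times * f, unit = unit, meta = s$meta)
}

#' Intensity threshold mask
#'
#' TRUE where the intensity is at least `fraction` times the volume's global
#' maximum. Background suppression before display uses 15%; decay-rate
#' computation uses 25%.
#'
#' @param v a [volume_image].
#' @param fraction threshold as a fraction of the maximum, in `[0, 1)`.
#' @return Logical 3D array.
#' @export
threshold_mask <- function(v, fraction) {
  stopifnot(inherits(v, "volume_image"))
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  v$data >= fraction * max(v$data)
}

## Vectorised Gauss-Newton for S(t) = A0 * exp(-k t), all voxels at once.
## Damped steps (halving) with a per-voxel convergence flag.
fit_exp_gn <- function(S, t, A0, k, max_iter = 200, tol = 1e-12) {
  nvox <- nrow(S)
  nt <- length(t)
  Tm <- matrix(t, nvox, nt, byrow = TRUE)
  sse_rows <- function(A0, k, rows) {
    E <- exp(-outer(k, t))
    rowSums((A0 * E - S[rows, , drop = FALSE])^2)
  }
  f0 <- sse_rows(A0, k, seq_len(nvox))
  active <- rep(TRUE, nvox)
  for (it in seq_len(max_iter)) {
    E <- exp(-outer(k, t))          # nvox x nt
    M <- A0 * E                     # model values
    R <- M - S                      # residuals
    MT <- M * Tm
    ## normal equations of the 2-parameter Jacobian [E, -t*M]
    g1 <- rowSums(R * E)
    g2 <- -rowSums(R * MT)
    h11 <- rowSums(E * E)
    h12 <- -rowSums(E * MT)
    h22 <- rowSums(MT * MT)
    det <- h11 * h22 - h12^2
    ok <- is.finite(det) & abs(det) > 1e-300
    dA <- ifelse(ok, (h22 * g1 - h12 * g2) / det, 0)
    dk <- ifelse(ok, (h11 * g2 - h12 * g1) / det, 0)
    dA[!active] <- 0; dk[!active] <- 0
    step <- rep(1, nvox)
    A1 <- A0 - dA
    k1 <- pmax(k - dk, 0)
    f1 <- sse_rows(A1, k1, seq_len(nvox))
    for (h in 1:10) {
      worse <- which(active & (!is.finite(f1) | f1 > f0))
      if (!length(worse)) break
      step[worse] <- step[worse] / 2
      A1[worse] <- A0[worse] - step[worse] * dA[worse]
      k1[worse] <- pmax(k[worse] - step[worse] * dk[worse], 0)
      f1[worse] <- sse_rows(A1[worse], k1[worse], worse)
    }
    move <- active & is.finite(f1) & f1 <= f0
    done <- move & (f0 - f1 <= tol * (f0 + 1e-300))
    A0[move] <- A1[move]; k[move] <- k1[move]; f0[move] <- f1[move]
    active <- active & !done & move   # stalled voxels (no improvement) stop
    if (!any(active)) break
  }
  list(A0 = A0, k = k, sse = f0)
}

#' Voxelwise exponential decay-rate map
#'
#' Fits `S(t) = A0 * exp(-k t)` per voxel over an image series by nonlinear
#' least squares, initialised from the log-linear ordinary least-squares
#' solution on the positive samples (non-positive samples are clipped for the
#' initialisation only). Only voxels passing the intensity threshold on the
#' first frame are fitted.
#'
#' @param s an [image_series] with at least 2 frames.
#' @param fraction threshold fraction applied to the first frame
#'   (see [threshold_mask]); default 0.25.
#' @param n_frames number of leading frames used (default all). Early frames
#'   carry the most signal; later frames of a decaying probe mostly add noise.
#' @param method "nls" (nonlinear, default) or "loglinear".
#' @return Object of class `decay_rate_map`: fields `rates` (1/unit of the
#'   series times), `amplitudes`, `mask`, `fit_quality` (R^2), `unit`.
#' @export
fit_decay_map <- function(s, fraction = 0.25, n_frames = NULL,
                          method = c("nls", "loglinear")) {
  stopifnot(inherits(s, "image_series"))
  method <- match.arg(method)
  if (!is.null(n_frames)) {
    n_frames <- min(n_frames, length(s$frames))
    s <- image_series(s$frames[seq_len(n_frames)], s$times[seq_len(n_frames)],
                      unit = s$unit, meta = s$meta)
  }
  if (length(s$frames) < 2) stop("need at least 2 frames to fit a decay")
  t <- s$times
  if (max(t) - min(t) <= 0) stop("degenerate series: all frame times equal")
  mask <- threshold_mask(s$frames[[1]], fraction)
  idx <- which(mask)
  if (!length(idx)) stop("threshold mask is empty")
  S <- vapply(s$frames, function(f) f$data[idx], numeric(length(idx)))
  S <- matrix(S, nrow = length(idx))
  ## log-linear init on clipped samples
  eps <- 1e-12 * max(S)
  L <- log(pmax(S, eps))
  tb <- t - mean(t)
  beta <- (L %*% tb) / sum(tb^2)
  kk <- pmax(-as.numeric(beta), 0)
  aa <- exp(rowMeans(L) + kk * mean(t))
  if (method == "nls") {
    fit <- fit_exp_gn(S, t, aa, kk)
    aa <- fit$A0; kk <- fit$k; sse <- fit$sse
  } else {
    sse <- rowSums((aa * exp(-outer(kk, t)) - S)^2)
  }
  sst <- rowSums((S - rowMeans(S))^2)
  r2 <- 1 - sse / pmax(sst, 1e-300)
  geom <- s$frames[[1]]
  rates <- array(NA_real_, geom$matrix)
  amps <- array(NA_real_, geom$matrix)
  fq <- array(NA_real_, geom$matrix)
  bad <- !is.finite(kk) | !is.finite(aa)
  mask[idx[bad]] <- FALSE
  keep <- !bad
  rates[idx[keep]] <- kk[keep]
  amps[idx[keep]] <- aa[keep]
  fq[idx[keep]] <- r2[keep]
  structure(list(rates = rates, amplitudes = amps, mask = mask,
                 fit_quality = fq,
                 unit = paste0("1/", s$unit),
                 fov = geom$fov, origin = geom$origin),
            class = "decay_rate_map")
}

#' @export
print.decay_rate_map <- function(x, ...) {
  r <- x$rates[x$mask]
  cat(sprintf("<decay_rate_map> %d valid voxels, median k = %.3g %s\n",
              sum(x$mask), stats::median(r), x$unit))
  invisible(x)
}

#' Histogram and summary statistics of a decay-rate map
#'
#' @param m a [decay_rate_map] with a nonempty mask.
#' @param bins number of histogram bins or a vector of breakpoints
#'   (passed to [hist][graphics::hist]).
#' @return List with `histogram` (counts/breaks), `median`, `mean`,
#'   `variance`, `n`.
#' @export
decay_histogram_stats <- function(m, bins = 30) {
  stopifnot(inherits(m, "decay_rate_map"))
  r <- m$rates[m$mask]
  if (!length(r)) stop("no valid voxels in the decay-rate map")
  h <- graphics::hist(r, breaks = bins, plot = FALSE)
  list(histogram = h, median = stats::median(r), mean = mean(r),
       variance = if (length(r) > 1) stats::var(r) else 0, n = length(r))
}

#' Mean decay rate in box regions of interest
#'
#' Default ROI shape in redox mapping is a 5 x 5 in-plane box on a chosen
#' slice; any axis-aligned box is accepted.
#'
#' @param m a [decay_rate_map].
#' @param rois list of ROIs, each a list with integer index ranges `x`, `y`,
#'   `z` (each length-2 `c(from, to)`).
#' @return Data frame with one row per ROI: `mean_rate` (NA when the ROI
#'   contains no valid voxel) and `n_valid`.
#' @export
roi_mean_rates <- function(m, rois) {
  stopifnot(inherits(m, "decay_rate_map"))
  dm <- dim(m$rates)
  out <- lapply(seq_along(rois), function(i) {
    r <- rois[[i]]
    ix <- r$x[1]:r$x[2]; iy <- r$y[1]:r$y[2]; iz <- r$z[1]:r$z[2]
    if (min(ix) < 1 || max(ix) > dm[1] || min(iy) < 1 || max(iy) > dm[2] ||
        min(iz) < 1 || max(iz) > dm[3]) {
      stop("ROI ", i, " outside volume bounds")
    }
    vals <- m$rates[ix, iy, iz]
    msk <- m$mask[ix, iy, iz]
    v <- vals[msk & is.finite(vals)]
    data.frame(roi = i,
               mean_rate = if (length(v)) mean(v) else NA_real_,
               n_valid = length(v))
  })
  do.call(rbind, out)
}
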