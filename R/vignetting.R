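## Flat-field vignetting model: robust per-epoch flats, smooth unit-level
## multiplicative gains, master gain across epochs, stability diagnostics,
## log-domain temporal interpolation, and correction by elementwise
## division. All gain estimation happens in the radiometric domain, before
## the non-linear temperature inversion.

## Pixelwise median over a list of same-shaped matrices. Even counts use
## the mean of the two central order statistics (stats::median).
pixelwiseMedian <- function(mats) {
  if (length(mats) == 1L) return(mats[[1L]])
  arr <- array(unlist(mats), dim = c(dim(mats[[1L]]), length(mats)))
  apply(arr, c(1L, 2L), median)
}

#' Robust flat image from one flat-field epoch
#'
#' Pixelwise median over the epoch's frames (robust to hot pixels and
#' transient reflections), followed by a symmetric quantile clamp of the
#' median image computed over all pixels.
#'
#' @param seq a \linkS4class{FlatFieldSequence}.
#' @param qlo,qhi clamp quantiles, 0 <= qlo < qhi <= 1 (defaults 0.02,
#'   0.98); set \code{clamp = FALSE} to disable.
#' @param clamp logical; apply the quantile clamp (default TRUE).
#' @return numeric matrix, the robust flat image.
#' @export
robustFlat <- function(seq, qlo = 0.02, qhi = 0.98, clamp = TRUE) {
  if (!is(seq, "FlatFieldSequence")) stop("seq must be a FlatFieldSequence")
  if (length(seq@frames) < 1L) stop("empty flat-field sequence")
  if (qlo < 0 || qhi > 1 || qlo >= qhi) stop("need 0 <= qlo < qhi <= 1")
  flat <- pixelwiseMedian(lapply(seq@frames, function(f) f@counts))
  if (clamp) {
    q <- quantile(flat, c(qlo, qhi), names = FALSE)
    flat <- pmin(pmax(flat, q[1]), q[2])
    dim(flat) <- dim(seq@frames[[1L]]@counts)
  }
  flat
}

## Gaussian smoothing with replicate padding; avoids the darkened borders
## circular convolution would introduce (which would masquerade as
## vignetting at the frame edge). The kernel is truncated to fit inside
## the image when sigma is large relative to the frame.
gaussianSmooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  maxSize <- 2L * ((min(dim(x)) - 1L) %/% 2L) + 1L
  EBImage::gblur(x, sigma = sigma, radius = min(size, maxSize),
                 boundary = "replicate")
}

#' Build a unit-level multiplicative gain field from a flat image
#'
#' Gaussian-smooths the flat (sigma 3-6 px preserves the spatial structure
#' of the vignetting while suppressing noise), divides by its central
#' tendency so the gain has unit level, and floors it at a small epsilon.
#'
#' @param flat numeric matrix, robust flat image (strictly positive).
#' @param sigma Gaussian smoothing scale in pixels (default 4).
#' @param normalizer "median" (default) or "mean".
#' @param floor small positive lower bound (default 1e-6).
#' @param epoch numeric timestamp carried by the gain.
#' @return a \linkS4class{GainField} with central tendency 1.
#' @export
buildGain <- function(flat, sigma = 4, normalizer = c("median", "mean"),
                      floor = 1e-6, epoch = 0) {
  normalizer <- match.arg(normalizer)
  if (min(flat) < 0) stop("flat image must be non-negative")
  if (max(flat) <= 0) stop("flat image is identically zero")
  sm <- gaussianSmooth(flat, sigma)
  ref <- if (normalizer == "median") median(sm) else mean(sm)
  g <- sm / ref
  g <- pmax(g, floor)
  dim(g) <- dim(flat)
  new("GainField", values = g, epoch = as.numeric(epoch),
      normalizer = normalizer, floor = floor)
}

#' Master gain across epochs
#'
#' Pixelwise median across per-epoch gain fields; appropriate when the
#' vignetting pattern is temporally stable (see
#' \code{\link{stabilityReport}}).
#'
#' @param gains list of \linkS4class{GainField} with identical shapes.
#' @return a \linkS4class{GainField} (epoch = median of input epochs).
#' @export
masterGain <- function(gains) {
  if (length(gains) < 1L) stop("need at least one gain field")
  dims <- vapply(gains, function(g) dim(g@values), integer(2))
  if (any(dims != dims[, 1])) stop("gain shapes must match")
  flo <- max(vapply(gains, function(g) g@floor, numeric(1)))
  v <- pixelwiseMedian(lapply(gains, function(g) g@values))
  v <- pmax(v, flo)
  new("GainField", values = v,
      epoch = median(vapply(gains, function(g) g@epoch, numeric(1))),
      normalizer = gains[[1L]]@normalizer, floor = flo)
}

#' Inter-epoch gain stability report
#'
#' RMS over pixels of the log-gain differences log(Gi/Gj) for every epoch
#' pair; the natural discrepancy measure for multiplicative fields. Small
#' off-diagonal RMS indicates stable vignetting and licenses the master
#' gain.
#'
#' @param gains list of >= 2 \linkS4class{GainField}.
#' @return a \linkS4class{GainStabilityReport}.
#' @export
stabilityReport <- function(gains) {
  K <- length(gains)
  if (K < 2L) stop("need at least two gain fields")
  dims <- vapply(gains, function(g) dim(g@values), integer(2))
  if (any(dims != dims[, 1])) stop("gain shapes must match")
  logs <- lapply(gains, function(g) log(g@values))
  rms <- matrix(0, K, K)
  for (i in seq_len(K - 1L)) for (j in (i + 1L):K) {
    rms[i, j] <- rms[j, i] <- sqrt(mean((logs[[i]] - logs[[j]])^2))
  }
  new("GainStabilityReport", rms = rms,
      epochs = vapply(gains, function(g) g@epoch, numeric(1)))
}

#' Temporal gain interpolation in the log domain
#'
#' Geometric interpolation G(t) = Gj^(1-w) * Gj1^w with
#' w = (t - tj)/(tj1 - tj): linear interpolation of the log-gains,
#' preserving positivity and the multiplicative structure. No
#' extrapolation: t must lie within [tj, tj1].
#'
#' @param gj,gj1 bracketing \linkS4class{GainField}s (gj@epoch <= gj1@epoch).
#' @param t target timestamp, gj@epoch <= t <= gj1@epoch.
#' @return a \linkS4class{GainField} at time t.
#' @export
interpolateGain <- function(gj, gj1, t) {
  if (gj@epoch > gj1@epoch) stop("gj must not be later than gj1")
  if (t < gj@epoch || t > gj1@epoch)
    stop("t outside [gj@epoch, gj1@epoch]: no extrapolation")
  if (!all(dim(gj@values) == dim(gj1@values))) stop("gain shapes must match")
  w <- if (gj1@epoch == gj@epoch) 0
       else (t - gj@epoch) / (gj1@epoch - gj@epoch)
  v <- exp((1 - w) * log(gj@values) + w * log(gj1@values))
  flo <- max(gj@floor, gj1@floor)
  new("GainField", values = pmax(v, flo), epoch = as.numeric(t),
      normalizer = gj@normalizer, floor = flo)
}

#' Select a gain model for a measurement time
#'
#' Automatic rule: use the master gain when the maximum off-diagonal
#' inter-epoch RMS is at most \code{rmsMax} (stable vignetting), otherwise
#' interpolate between the bracketing epochs in the log domain.
#'
#' @param gains list of per-epoch \linkS4class{GainField}, sorted or not.
#' @param t measurement timestamp.
#' @param rmsMax stability threshold on the log-gain RMS (default 0.01).
#' @return list with elements \code{gain} (GainField), \code{method}
#'   ("master" or "interpolated") and \code{report}
#'   (\linkS4class{GainStabilityReport} or NULL for a single epoch).
#' @export
selectGain <- function(gains, t, rmsMax = 0.01) {
  if (length(gains) == 1L)
    return(list(gain = gains[[1L]], method = "master", report = NULL))
  ord <- order(vapply(gains, function(g) g@epoch, numeric(1)))
  gains <- gains[ord]
  rep <- stabilityReport(gains)
  maxRms <- max(rep@rms[upper.tri(rep@rms)])
  if (maxRms <= rmsMax)
    return(list(gain = masterGain(gains), method = "master", report = rep))
  ep <- vapply(gains, function(g) g@epoch, numeric(1))
  j <- findInterval(t, ep, rightmost.closed = TRUE)
  if (j < 1L || t > ep[length(ep)])
    stop("t outside calibration epochs: cannot interpolate")
  j <- min(j, length(ep) - 1L)
  list(gain = interpolateGain(gains[[j]], gains[[j + 1L]], t),
       method = "interpolated", report = rep)
}

#' Correct a radiometric frame for vignetting
#'
#' Elementwise division of the counts by the gain field; scale-equivariant
#' and exactly invertible for a noiseless frame.
#'
#' @param frame a \linkS4class{RadiometricFrame}.
#' @param gain a \linkS4class{GainField} with matching shape.
#' @return a corrected \linkS4class{RadiometricFrame} (timestamp and camera
#'   identity preserved).
#' @export
applyGainCorrection <- function(frame, gain) {
  if (!all(dim(frame@counts) == dim(gain@values)))
    stop("frame and gain shapes must match")
  new("RadiometricFrame", counts = frame@counts / gain@values,
      timestamp = frame@timestamp, cameraId = frame@cameraId)
}
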