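## Detection of the white 10 mm marker disks in visible images: local
## disk/ring contrast score, local maxima, and per-candidate geometric
## validation (area, circularity, axis ratio) on an adaptively thresholded
## neighbourhood.

## Luma conversion for RGB arrays; grayscale matrices pass through.
toGray <- function(image) {
  if (length(dim(image)) == 3L)
    0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  else image
}

#' Remove slowly varying illumination
#'
#' Estimates the background with a large-scale Gaussian filter and
#' subtracts it, compensating low-frequency illumination variations while
#' preserving small bright structures. The background scale should be well
#' above the marker radius (sigmaBg >= 4 r keeps the disk contrast within
#' about 10 percent).
#'
#' @param gray numeric matrix (grayscale image).
#' @param sigmaBg Gaussian scale of the background estimate, pixels.
#' @return background-subtracted image (approximately zero-mean
#'   background).
#' @export
subtractIllumination <- function(gray, sigmaBg = 20) {
  gray - gaussianSmooth(gray, sigmaBg)
}

#' Disk/ring contrast score map
#'
#' S(x, y) = mean inside a disk of radius r minus mean inside the
#' surrounding annulus of width w: large positive for a bright disk on a
#' darker local background. Border pixels whose ring exits the image are
#' NA.
#'
#' @param image numeric matrix.
#' @param r disk radius, pixels (default 5, the expected marker radius).
#' @param w annulus width, pixels (default 5).
#' @return numeric matrix of scores (NA at the border).
#' @export
diskRingScore <- function(image, r = 5, w = 5) {
  if (r <= 0 || w <= 0) stop("r and w must be > 0")
  rr <- ceiling(r + w)
  off <- -rr:rr
  d2 <- outer(off^2, off^2, "+")
  diskK <- (d2 <= r^2) * 1
  ringK <- (d2 > r^2 & d2 <= (r + w)^2) * 1
  diskK <- diskK / sum(diskK)
  ringK <- ringK / sum(ringK)
  S <- as.matrix(EBImage::filter2(image, diskK, boundary = "replicate")) -
    as.matrix(EBImage::filter2(image, ringK, boundary = "replicate"))
  dim(S) <- dim(image)
  h <- nrow(S); w2 <- ncol(S)
  b <- rr
  if (2 * b >= min(h, w2)) stop("ring radius too large for the image")
  S[c(seq_len(b), (h - b + 1):h), ] <- NA
  S[, c(seq_len(b), (w2 - b + 1):w2)] <- NA
  S
}

#' Configuration for visible-marker detection
#'
#' Defaults: marker radius 5 px, ring width 5 px, background scale 4 r;
#' score threshold 5 robust (MAD) noise levels of the score map;
#' area within [0.4, 2.5] times the nominal disk area; circularity >= 0.7;
#' minor/major axis ratio >= 0.75. Thresholds are deliberately exposed:
#' the circularity and axis-ratio tolerances are engineering choices.
#'
#' @param r,w disk radius and ring width, pixels.
#' @param sigmaBg illumination-subtraction scale, pixels.
#' @param scoreThreshMad score threshold in robust noise units.
#' @param areaFactorMin,areaFactorMax admissible area range as multiples of
#'   pi r^2.
#' @param minCircularity minimum 4 pi A / P^2.
#' @param minAxisRatio minimum minor/major axis ratio.
#' @param roiHalf half-size of the validation region of interest (default
#'   2 r, i.e. a (4 r)^2 window).
#' @return named list of settings.
#' @export
visDetectConfig <- function(r = 5, w = 5, sigmaBg = 4 * r,
                            scoreThreshMad = 5, areaFactorMin = 0.4,
                            areaFactorMax = 2.5, minCircularity = 0.7,
                            minAxisRatio = 0.75, roiHalf = ceiling(2 * r)) {
  list(r = r, w = w, sigmaBg = sigmaBg, scoreThreshMad = scoreThreshMad,
       areaFactorMin = areaFactorMin, areaFactorMax = areaFactorMax,
       minCircularity = minCircularity, minAxisRatio = minAxisRatio,
       roiHalf = roiHalf)
}

## Local maxima of a score map above a threshold, with non-maximum
## suppression over a (2 radius + 1) disc window.
localMaxima <- function(S, thresh, radius) {
  Sf <- S
  Sf[is.na(Sf)] <- -Inf
  lo <- min(Sf[is.finite(Sf)]); hi <- max(Sf[is.finite(Sf)])
  if (hi - lo < .Machine$double.eps) return(NULL)
  sn <- (pmax(Sf, lo) - lo) / (hi - lo)
  size <- 2L * as.integer(ceiling(radius)) + 1L
  mx <- as.matrix(EBImage::dilate(sn, EBImage::makeBrush(size, "disc")))
  isMax <- sn >= mx - 1e-12 & Sf >= thresh & is.finite(Sf)
  which(isMax, arr.ind = TRUE)
}

#' Detect white marker disks in a visible image
#'
#' Pipeline: grayscale conversion, illumination subtraction, disk/ring
#' score, local maxima above an adaptive threshold, then per-candidate
#' validation: the score neighbourhood is segmented with Otsu's threshold,
#' the component containing the candidate must have an area consistent
#' with the expected disk, sufficient circularity, and a near-unity axis
#' ratio. Centres are component centroids (sub-pixel); the radius comes
#' from the equivalent-disk area.
#'
#' @param image numeric matrix (grayscale) or height x width x 3 RGB array.
#' @param config settings from \code{\link{visDetectConfig}}.
#' @param validMask optional logical matrix; detections whose centre falls
#'   on an invalid pixel (e.g. outside the undistortion domain) are
#'   dropped.
#' @return data.frame with columns x, y, radius_px, score, modality
#'   (possibly empty).
#' @export
detectVisMarkers <- function(image, config = visDetectConfig(),
                             validMask = NULL) {
  gray <- toGray(image)
  gray[is.na(gray)] <- median(gray, na.rm = TRUE)
  flat <- subtractIllumination(gray, config$sigmaBg)
  S <- diskRingScore(flat, config$r, config$w)
  noise <- stats::mad(S[!is.na(S)])
  thresh <- config$scoreThreshMad * noise
  cand <- localMaxima(S, thresh, config$r)
  empty <- data.frame(x = numeric(0), y = numeric(0),
                      radius_px = numeric(0), score = numeric(0),
                      modality = character(0))
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  h <- nrow(gray); w <- ncol(gray)
  rh <- config$roiHalf
  nominalArea <- pi * config$r^2
  out <- empty
  for (i in seq_len(nrow(cand))) {
    r0 <- cand[i, 1]; c0 <- cand[i, 2]
    rows <- max(1, r0 - rh):min(h, r0 + rh)
    cols <- max(1, c0 - rh):min(w, c0 + rh)
    roi <- flat[rows, cols, drop = FALSE]
    rng <- range(roi)
    if (diff(rng) < .Machine$double.eps) next
    roiN <- (roi - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(roiN), range = c(0, 1))
    mask <- roiN > th
    lab <- label8(mask)
    lcand <- lab[r0 - rows[1] + 1L, c0 - cols[1] + 1L]
    if (lcand == 0L) next
    st <- componentStats(lab)[[lcand]]
    if (st$area < config$areaFactorMin * nominalArea ||
        st$area > config$areaFactorMax * nominalArea) next
    per <- st$perimeter
    if (4 * pi * st$area / per^2 < config$minCircularity) next
    if (st$major <= 0 || st$minor / st$major < config$minAxisRatio) next
    cx <- st$ucx + (cols[1] - 1L)   # back to full-image 0-based coords
    cy <- st$ucy + (rows[1] - 1L)
    if (!is.null(validMask) &&
        !isTRUE(validMask[round(cy) + 1L, round(cx) + 1L])) next
    out <- rbind(out, data.frame(
      x = cx, y = cy, radius_px = st$eqDiameter / 2,
      score = S[r0, c0], modality = "VIS"))
  }
  ## NMS across accepted components that collapsed onto the same disk
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(-out$score)
    for (a in seq_along(ord)) {
      if (!keep[ord[a]]) next
      for (b in ord[seq_along(ord) > a]) {
        if (keep[b] &&
            sqrt((out$x[ord[a]] - out$x[b])^2 +
                 (out$y[ord[a]] - out$y[b])^2) < config$r) keep[b] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
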