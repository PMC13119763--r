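## Final VIS -> LWIR anamorphosis: transform fitting in three families
## (affine, projective, degree-2 polynomial), inverse-mapped warping of
## the VIS image onto the LWIR grid, display fusion, and the metric scale
## derived from the 10 mm markers.

## A fitted geometric transform. Coefficients always describe the forward
## map named by `direction`; the inverse map needed for warping is fitted
## alongside from the same pairs.
#' @exportClass GeomTransform
setClass("GeomTransform",
  representation(family = "character", forward = "matrix",
                 inverse = "matrix", residuals = "numeric"))

polyBasis <- function(pts, family) {
  x <- pts[, 1]; y <- pts[, 2]
  switch(family,
    affine = cbind(x, y, 1),
    projective = cbind(x, y, 1),
    poly2 = cbind(1, x, y, x * y, x^2, y^2))
}

fitDirection <- function(src, dst, family) {
  if (family == "projective") {
    # DLT: rows [x y 1 0 0 0 -x'x -x'y -x'] ; [0 0 0 x y 1 -y'x -y'y -y']
    n <- nrow(src)
    A <- matrix(0, 2 * n, 9)
    for (i in seq_len(n)) {
      x <- src[i, 1]; y <- src[i, 2]; u <- dst[i, 1]; v <- dst[i, 2]
      A[2 * i - 1, ] <- c(x, y, 1, 0, 0, 0, -u * x, -u * y, -u)
      A[2 * i, ] <- c(0, 0, 0, x, y, 1, -v * x, -v * y, -v)
    }
    h <- svd(A)$v[, 9]
    H <- matrix(h, 3, 3, byrow = TRUE)
    H / H[3, 3]
  } else {
    X <- polyBasis(src, family)
    if (qr(X)$rank < ncol(X)) stop("degenerate point configuration")
    qr.solve(X, dst)      # basis x 2 coefficient matrix
  }
}

applyDirection <- function(coefs, pts, family) {
  pts <- rbind(pts)
  if (family == "projective") {
    P <- coefs %*% rbind(t(pts), 1)
    t(P[1:2, , drop = FALSE] / rep(P[3, ], each = 2))
  } else {
    polyBasis(pts, family) %*% coefs
  }
}

#' Fit the registration transform from matched marker centres
#'
#' Least squares in the chosen family, mapping VIS coordinates to LWIR
#' coordinates (the warp direction keeps the thermal raster untouched).
#' The inverse map (LWIR to VIS), needed for inverse-mapped warping, is
#' fitted from the same pairs.
#'
#' @param visPts,lwirPts n x 2 matrices of corresponding marker centres,
#'   e.g. the detections selected by a \linkS4class{CorrespondenceSet}'s
#'   pair indices.
#' @param family "affine" (default, >= 3 pairs), "projective" (>= 4) or
#'   "poly2" (>= 6).
#' @return a \code{GeomTransform}; residuals are per-pair distances in
#'   LWIR pixels.
#' @export
fitTransform <- function(visPts, lwirPts,
                         family = c("affine", "projective", "poly2")) {
  family <- match.arg(family)
  visPts <- rbind(visPts); lwirPts <- rbind(lwirPts)
  need <- c(affine = 3, projective = 4, poly2 = 6)[family]
  if (nrow(visPts) < need)
    stop(sprintf("family '%s' needs at least %d pairs", family, need))
  fwd <- fitDirection(visPts, lwirPts, family)
  inv <- fitDirection(lwirPts, visPts, family)
  pred <- applyDirection(fwd, visPts, family)
  res <- sqrt(rowSums((pred - lwirPts)^2))
  new("GeomTransform", family = family, forward = fwd, inverse = inv,
      residuals = res)
}

#' Map points through a fitted transform
#'
#' @param transform a \code{GeomTransform}.
#' @param pts n x 2 matrix of VIS points (forward direction).
#' @export
setMethod("mapPoints", "GeomTransform", function(transform, pts) {
  applyDirection(transform@forward, pts, transform@family)
})

#' Warp the VIS image onto the LWIR grid
#'
#' Inverse mapping: every LWIR output pixel samples the VIS image at its
#' back-projected position (bilinear). Out-of-domain pixels are NA and
#' flagged in the validity mask.
#'
#' @param visImage numeric matrix or height x width x channels array.
#' @param transform a \code{GeomTransform} fitted VIS -> LWIR.
#' @param lwirShape c(height, width) of the target grid.
#' @return list with \code{image} and \code{valid}.
#' @export
warpVisToLwir <- function(visImage, transform, lwirShape) {
  h <- lwirShape[1]; w <- lwirShape[2]
  grid <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
  src <- applyDirection(transform@inverse, grid, transform@family)
  if (any(!is.finite(src)))
    stop("transform not invertible over the target domain")
  s <- bilinearSample(visImage, src[, 1], src[, 2])
  chans <- if (length(dim(visImage)) == 3L) dim(visImage)[3] else 1L
  if (chans == 1L) img <- matrix(s$values, h, w)
  else {
    img <- array(NA_real_, c(h, w, chans))
    for (ch in seq_len(chans)) img[, , ch] <- s$values[, ch]
  }
  list(image = img, valid = matrix(s$valid, h, w))
}

#' Fuse temperature and warped VIS for display
#'
#' Pure visualization; the stored temperature raster is never altered.
#' "alpha" blends a grayscale temperature rendering with the warped VIS;
#' "edges" superimposes the VIS edge magnitude (Sobel) onto the
#' temperature rendering.
#'
#' @param T a \linkS4class{TemperatureImage} or matrix (degC).
#' @param warpedVis warped VIS image (matrix or array; NA allowed).
#' @param mode "edges" or "alpha".
#' @param alpha blend weight in [0, 1] (alpha mode); 0 = pure temperature,
#'   1 = pure VIS.
#' @return height x width x 3 display array in [0, 1].
#' @export
fuseOverlay <- function(T, warpedVis, mode = c("edges", "alpha"),
                        alpha = 0.5) {
  mode <- match.arg(mode)
  tm <- if (is(T, "TemperatureImage")) T@values else T
  vis <- toGray(warpedVis)
  vis[is.na(vis)] <- 0
  rngT <- range(tm)
  tn <- if (diff(rngT) > 0) (tm - rngT[1]) / diff(rngT) else tm * 0
  rngV <- range(vis)
  vn <- if (diff(rngV) > 0) (vis - rngV[1]) / diff(rngV) else vis * 0
  if (mode == "alpha") {
    out <- (1 - alpha) * tn + alpha * vn
    array(rep(out, 3), c(dim(tm), 3))
  } else {
    sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
    gx <- as.matrix(EBImage::filter2(vn, sx, boundary = "replicate"))
    gy <- as.matrix(EBImage::filter2(vn, t(sx), boundary = "replicate"))
    edge <- sqrt(gx^2 + gy^2)
    if (max(edge) > 0) edge <- edge / max(edge)
    out <- array(0, c(dim(tm), 3))
    out[, , 1] <- pmin(tn + edge, 1)   # temperature in red + edges
    out[, , 2] <- edge
    out[, , 3] <- 1 - tn
    out
  }
}

#' Millimetres per pixel from detected markers
#'
#' The registration markers expose a 10 mm circular hole; the median
#' detected diameter therefore yields the metric scale of the modality's
#' image plane at the marker plane.
#'
#' @param detections data.frame with a radius_px column.
#' @param trueDiameterMm physical marker diameter (default 10 mm).
#' @return scale in mm per pixel.
#' @export
mmPerPixel <- function(detections, trueDiameterMm = 10) {
  if (is.null(detections) || nrow(detections) == 0L)
    stop("no detections: cannot derive a scale")
  trueDiameterMm / median(2 * detections$radius_px)
}
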