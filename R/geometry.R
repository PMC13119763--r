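## Lens distortion (Brown-Conrady radial-tangential model) and generic
## inverse-mapped bilinear resampling. Intrinsic estimation is out of
## scope: intrinsics come from any standard planar calibration, via JSON.

#' Bilinear sampling of an image at fractional coordinates
#'
#' Samples \code{img} (matrix, or height x width x channels array) at
#' 0-based (x, y) positions. Positions outside the source domain yield NA
#' and are flagged in the validity mask.
#'
#' @param img numeric matrix or 3D array.
#' @param x,y numeric vectors of 0-based sample coordinates.
#' @return list with \code{values} (vector or matrix n x channels) and
#'   \code{valid} (logical vector).
#' @export
bilinearSample <- function(img, x, y) {
  chans <- if (length(dim(img)) == 3L) dim(img)[3] else 1L
  h <- dim(img)[1]; w <- dim(img)[2]
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  valid <- x >= 0 & y >= 0 & x <= w - 1 & y <= h - 1 &
    is.finite(x) & is.finite(y)
  # clamp the integer corners so indexing stays legal; invalid entries are
  # overwritten with NA below
  x0c <- pmin(pmax(x0, 0), w - 1); x1c <- pmin(x0c + 1, w - 1)
  y0c <- pmin(pmax(y0, 0), h - 1); y1c <- pmin(y0c + 1, h - 1)
  out <- matrix(NA_real_, length(x), chans)
  for (ch in seq_len(chans)) {
    plane <- if (chans == 1L) img else img[, , ch]
    i00 <- plane[cbind(y0c + 1, x0c + 1)]
    i01 <- plane[cbind(y0c + 1, x1c + 1)]
    i10 <- plane[cbind(y1c + 1, x0c + 1)]
    i11 <- plane[cbind(y1c + 1, x1c + 1)]
    v <- (1 - fy) * ((1 - fx) * i00 + fx * i01) +
      fy * ((1 - fx) * i10 + fx * i11)
    v[!valid] <- NA_real_
    out[, ch] <- v
  }
  list(values = if (chans == 1L) out[, 1L] else out, valid = valid)
}

#' Apply the forward distortion model to ideal points
#'
#' Maps undistorted (ideal pinhole) pixel coordinates to their distorted
#' observed positions under the radial (k1, k2, k3) and tangential (p1, p2)
#' model.
#'
#' @param pts n x 2 matrix of 0-based undistorted (x, y) pixel coordinates.
#' @param intr a \linkS4class{CameraIntrinsics}.
#' @return n x 2 matrix of distorted pixel coordinates.
#' @export
distortPoints <- function(pts, intr) {
  pts <- rbind(pts)
  xn <- (pts[, 1] - intr@cx) / intr@fx
  yn <- (pts[, 2] - intr@cy) / intr@fy
  r2 <- xn^2 + yn^2
  rad <- 1 + intr@k1 * r2 + intr@k2 * r2^2 + intr@k3 * r2^3
  xd <- xn * rad + 2 * intr@p1 * xn * yn + intr@p2 * (r2 + 2 * xn^2)
  yd <- yn * rad + intr@p1 * (r2 + 2 * yn^2) + 2 * intr@p2 * xn * yn
  cbind(xd * intr@fx + intr@cx, yd * intr@fy + intr@cy)
}

#' Undistort observed points (iterative inversion)
#'
#' Fixed-point inversion of the distortion model: starting from the
#' observed normalized coordinates, repeatedly divides out the radial
#' factor and subtracts the tangential terms.
#'
#' @param pts n x 2 matrix of 0-based distorted (x, y) pixel coordinates.
#' @param intr a \linkS4class{CameraIntrinsics}.
#' @param iterations fixed-point iterations (default 10).
#' @return n x 2 matrix of undistorted pixel coordinates.
#' @export
undistortPoints <- function(pts, intr, iterations = 10L) {
  pts <- rbind(pts)
  xd <- (pts[, 1] - intr@cx) / intr@fx
  yd <- (pts[, 2] - intr@cy) / intr@fy
  xn <- xd; yn <- yd
  for (i in seq_len(iterations)) {
    r2 <- xn^2 + yn^2
    rad <- 1 + intr@k1 * r2 + intr@k2 * r2^2 + intr@k3 * r2^3
    dx <- 2 * intr@p1 * xn * yn + intr@p2 * (r2 + 2 * xn^2)
    dy <- intr@p1 * (r2 + 2 * yn^2) + 2 * intr@p2 * xn * yn
    xn <- (xd - dx) / rad
    yn <- (yd - dy) / rad
  }
  cbind(xn * intr@fx + intr@cx, yn * intr@fy + intr@cy)
}

#' Undistort an image
#'
#' Standard inverse-mapped unwarping: for every pixel of the undistorted
#' output, the forward distortion model gives the source position in the
#' observed image, sampled bilinearly. Pixels whose source falls outside
#' the observed image are invalid (NA) and flagged in the mask so
#' downstream detection can ignore them.
#'
#' @param image numeric matrix (height x width) or 3D array.
#' @param intr a \linkS4class{CameraIntrinsics} matching the image size.
#' @return list with \code{image} (same shape, NA outside the source
#'   domain) and \code{valid} (logical matrix).
#' @export
undistortImage <- function(image, intr) {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (w != intr@width || h != intr@height)
    stop(sprintf("intrinsics are %dx%d but image is %dx%d",
                 intr@width, intr@height, w, h))
  grid <- cbind(rep(0:(w - 1), each = h), rep(0:(h - 1), times = w))
  src <- distortPoints(grid, intr)
  s <- bilinearSample(image, src[, 1], src[, 2])
  valid <- matrix(s$valid, h, w)
  if (length(dim(image)) == 3L) {
    out <- array(NA_real_, dim(image))
    for (ch in seq_len(dim(image)[3])) out[, , ch] <- s$values[, ch]
  } else {
    out <- matrix(s$values, h, w)
  }
  list(image = out, valid = valid)
}

#' Read / write camera intrinsics JSON
#'
#' Plain JSON schema mirroring the \linkS4class{CameraIntrinsics} fields
#' (fx, fy, cx, cy, k1, k2, k3, p1, p2, width, height), as produced by any
#' standard planar calibration toolbox.
#'
#' @param path file path.
#' @return a \linkS4class{CameraIntrinsics} (for the reader).
#' @export
readIntrinsics <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  CameraIntrinsics(fx = x$fx, fy = x$fy, cx = x$cx, cy = x$cy,
                   width = x$width, height = x$height,
                   k1 = x$k1 %||% 0, k2 = x$k2 %||% 0, k3 = x$k3 %||% 0,
                   p1 = x$p1 %||% 0, p2 = x$p2 %||% 0)
}

#' @rdname readIntrinsics
#' @param intr a \linkS4class{CameraIntrinsics} to serialize.
#' @export
writeIntrinsics <- function(intr, path) {
  write_json(list(fx = intr@fx, fy = intr@fy, cx = intr@cx, cy = intr@cy,
                  k1 = intr@k1, k2 = intr@k2, k3 = intr@k3,
                  p1 = intr@p1, p2 = intr@p2,
                  width = intr@width, height = intr@height),
             path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
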