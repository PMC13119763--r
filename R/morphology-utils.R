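## Shared low-level binary/grayscale morphology helpers.
##
## EBImage's bwlabel is 4-connected and its grayscale morphology assumes
## intensities in [0, 1]; the wrappers here provide the 8-connectivity and
## arbitrary-range behaviour the detection algorithms need.

## 8-connected labelling: 4-connected bwlabel, then merge labels touching
## diagonally (union-find over the label graph).
label8 <- function(mask) {
  mask <- matrix(as.numeric(mask != 0), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(round(lab)), nrow(lab), ncol(lab))
  n <- max(lab)
  if (n <= 1L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  parent <- seq_len(n)
  findRoot <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  unite <- function(a, b) {
    ra <- findRoot(a); rb <- findRoot(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # diagonal adjacencies: (r, c) with (r+1, c+1) and (r+1, c-1)
  a <- lab[-h, -w]; b <- lab[-1, -1]
  keep <- which(a > 0 & b > 0 & a != b)
  for (k in keep) unite(a[k], b[k])
  a <- lab[-h, -1]; b <- lab[-1, -w]
  keep <- which(a > 0 & b > 0 & a != b)
  for (k in keep) unite(a[k], b[k])
  roots <- vapply(seq_len(n), findRoot, integer(1))
  remap <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- remap[lab[lab > 0]]
  out
}

## Remove connected components smaller than minArea (8-connectivity).
areaOpen <- function(mask, minArea) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minArea)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

## Grayscale morphological operation on an arbitrary-range image: affine
## min-max normalization to [0, 1], replicate padding by the SE radius
## (so boundary pixels see a full neighbourhood), EBImage op with a flat
## disc brush, crop and rescale back. Valid because flat-SE morphology
## commutes with increasing affine maps.
grayMorph <- function(x, radius, op = c("open", "close", "erode", "dilate")) {
  op <- match.arg(op)
  rad <- as.integer(ceiling(radius))
  brush <- EBImage::makeBrush(2L * rad + 1L, shape = "disc")
  lo <- min(x); hi <- max(x)
  if (hi - lo < .Machine$double.eps) return(x)
  xn <- (x - lo) / (hi - lo)
  h <- nrow(xn); w <- ncol(xn)
  ri <- c(rep(1L, rad), seq_len(h), rep(h, rad))
  ci <- c(rep(1L, rad), seq_len(w), rep(w, rad))
  xp <- xn[ri, ci]
  yp <- switch(op,
    open = EBImage::opening(xp, brush),
    close = EBImage::closing(xp, brush),
    erode = EBImage::erode(xp, brush),
    dilate = EBImage::dilate(xp, brush))
  out <- as.matrix(yp)[rad + seq_len(h), rad + seq_len(w)] * (hi - lo) + lo
  dim(out) <- dim(x)
  out
}

## Binary closing with a disc structuring element.
binaryClose <- function(mask, radius) {
  size <- 2L * as.integer(ceiling(radius)) + 1L
  brush <- EBImage::makeBrush(size, shape = "disc")
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::closing(m, brush)) > 0.5
}

## Fill holes in a binary mask.
fillHoles <- function(mask) {
  m <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  as.matrix(EBImage::fillHull(m)) > 0.5
}

## Moore-neighbour boundary tracing; returns the cyclic sequence of chain
## directions (indices into the W,NW,N,NE,E,SE,S,SW table) around the
## outer boundary. Single-pixel components return integer(0).
traceContour <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) <= 1L) return(integer(0))
  # pad so neighbourhood lookups never leave the matrix
  pm <- matrix(FALSE, h + 2L, w + 2L)
  pm[2:(h + 1L), 2:(w + 1L)] <- mask
  # start: topmost pixel of the leftmost column containing foreground; its
  # west neighbour is background by construction
  ord <- order(idx[, 2L], idx[, 1L])
  start <- idx[ord[1L], ] + 1L
  # Moore neighbourhood, clockwise on screen (row grows downward):
  # W, NW, N, NE, E, SE, S, SW
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  p <- start; b <- start + nb[1L, ]  # initial backtrack: west of start
  dirs <- integer(0)
  # cycle detection on the (pixel, entry-direction) state: the walk is
  # deterministic, so the first repeated state closes the contour exactly
  seen <- new.env(hash = TRUE)
  maxSteps <- 8L * nrow(idx) + 16L
  for (step in seq_len(maxSteps)) {
    db <- b - p
    i0 <- which(nb[, 1L] == db[1L] & nb[, 2L] == db[2L])
    found <- FALSE
    for (k in seq_len(8L)) {
      d <- ((i0 - 1L + k) %% 8L) + 1L
      q <- p + nb[d, ]
      if (pm[q[1L], q[2L]]) {
        dPrev <- ((i0 - 1L + k - 1L) %% 8L) + 1L
        b <- p + nb[dPrev, ]
        key <- paste(q[1L], q[2L], d)
        prev <- seen[[key]]
        if (!is.null(prev)) return(dirs[(prev + 1L):length(dirs)])
        dirs <- c(dirs, d)
        seen[[key]] <- length(dirs)
        p <- q
        found <- TRUE
        break
      }
    }
    if (!found) return(dirs)
  }
  dirs
}

## Perimeter estimate from the chain code with the Vossepoel-Smeulders
## corner correction (the regionprops-style estimator): isothetic steps
## weigh 0.980, diagonal steps 1.406, and each direction change subtracts
## 0.091. Near-unbiased for smooth digitized outlines; single pixels get
## the unit-square circumference.
componentPerimeter <- function(mask) {
  dirs <- traceContour(mask)
  if (length(dirs) == 0L) return(4)
  diagSteps <- dirs %% 2L == 0L  # NW, NE, SE, SW are even indices
  nc <- sum(dirs != c(dirs[-1L], dirs[1L]))
  0.980 * sum(!diagSteps) + 1.406 * sum(diagSteps) - 0.091 * nc
}

## Per-component statistics for a label image. weights (same shape) feed
## the weighted centroid; NULL means unweighted.
componentStats <- function(labels, weights = NULL) {
  n <- max(labels)
  out <- vector("list", n)
  if (n == 0L) return(out)
  h <- nrow(labels); w <- ncol(labels)
  pix <- which(labels > 0)
  labv <- labels[pix]
  rows <- ((pix - 1L) %% h) + 1L
  cols <- ((pix - 1L) %/% h) + 1L
  for (k in seq_len(n)) {
    sel <- labv == k
    r <- rows[sel]; cc <- cols[sel]
    x <- cc - 1; y <- r - 1            # 0-based coordinates
    area <- length(r)
    wk <- if (is.null(weights)) rep(1, area) else weights[cbind(r, cc)]
    sw <- sum(wk)
    if (sw <= 0) wk <- rep(1, area)    # fallback to unweighted
    cx <- sum(x * wk) / sum(wk); cy <- sum(y * wk) / sum(wk)
    ux <- mean(x); uy <- mean(y)
    # second moments (+1/12 pixel variance) for axis lengths
    vxx <- mean((x - ux)^2) + 1 / 12
    vyy <- mean((y - uy)^2) + 1 / 12
    vxy <- mean((x - ux) * (y - uy))
    tr <- vxx + vyy; det <- vxx * vyy - vxy^2
    disc <- sqrt(max(tr^2 / 4 - det, 0))
    l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
    major <- 4 * sqrt(max(l1, 0)); minor <- 4 * sqrt(max(l2, 0))
    sub <- matrix(FALSE, max(r) - min(r) + 3L, max(cc) - min(cc) + 3L)
    sub[cbind(r - min(r) + 2L, cc - min(cc) + 2L)] <- TRUE
    per <- componentPerimeter(sub)
    out[[k]] <- list(area = area, perimeter = per,
                     cx = cx, cy = cy, ucx = ux, ucy = uy,
                     major = major, minor = minor,
                     eqDiameter = 2 * sqrt(area / pi),
                     maxWeight = if (is.null(weights)) NA_real_ else max(wk),
                     bbox = c(xmin = min(x), xmax = max(x),
                              ymin = min(y), ymax = max(y)),
                     weightedFallback = sw <= 0)
  }
  out
}
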