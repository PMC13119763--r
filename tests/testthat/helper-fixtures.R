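## Shared fixture builders for the test suite. Everything is generated in
## code; no binary fixtures.

## Anti-aliased bright disk on a constant background (0-based centre).
renderDisk <- function(h, w, cx, cy, r, fg = 0.95, bg = 0.1) {
  img <- matrix(bg, h, w)
  rows <- max(1, floor(cy - r - 2) + 1):min(h, ceiling(cy + r + 2) + 1)
  cols <- max(1, floor(cx - r - 2) + 1):min(w, ceiling(cx + r + 2) + 1)
  dd <- sqrt(outer((rows - 1 - cy)^2, (cols - 1 - cx)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - dd, 0), 1)
  img[rows, cols] <- img[rows, cols] * (1 - cov) + fg * cov
  img
}

## Gaussian thermal hill added onto a base temperature matrix.
addHill <- function(tm, cx, cy, amp, sigma) {
  h <- nrow(tm); w <- ncol(tm)
  px <- matrix(rep(0:(w - 1), each = h), h, w)
  py <- matrix(rep(0:(h - 1), times = w), h, w)
  tm + amp * exp(-((px - cx)^2 + (py - cy)^2) / (2 * sigma^2))
}

## Minimum distance from each query point to a set of reference points.
nearestDist <- function(query, ref) {
  apply(rbind(query), 1, function(p)
    min(sqrt(rowSums((t(t(rbind(ref)) - as.numeric(p)))^2))))
}

## Brute-force optimal one-to-one assignment with distance cap, by
## enumeration over all injective row -> column maps (oracle for the
## Hungarian solver). Cost of a map = matched costs + cap per unmatched
## row/column.
bruteAssignment <- function(cost, cap) {
  m <- nrow(cost); n <- ncol(cost)
  cols <- seq_len(n)
  bestVal <- Inf; bestPairs <- NULL
  # enumerate subsets of rows and injective assignments
  rowSets <- unlist(lapply(0:m, function(k)
    combn(m, k, simplify = FALSE)), recursive = FALSE)
  for (rows in rowSets) {
    k <- length(rows)
    if (k > n) next
    perms <- if (k == 0) list(list(integer(0))) else
      combn(n, k, function(s) lapply(asplit(permMatrix(s), 1), identity),
            simplify = FALSE)
    for (pl in perms) for (p in pl) {
      cc <- cost[cbind(rows, p)]
      if (any(cc > cap)) next
      val <- sum(cc) + cap * (m - k) + cap * (n - k)
      if (val < bestVal - 1e-12) {
        bestVal <- val
        bestPairs <- cbind(row = rows, col = p)
      }
    }
  }
  list(value = bestVal, pairs = bestPairs)
}

## All permutations of a vector, as a matrix (rows = permutations).
permMatrix <- function(v) {
  n <- length(v)
  if (n == 1) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permMatrix(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}
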