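## Optimal one-to-one assignment (Hungarian algorithm with dual
## potentials, O(n^3)), plus the distance-capped rectangular wrapper the
## matcher uses. Written in-package: problem sizes are tiny (tens of
## markers), so plain R loops are ample.

## Square minimization: returns ans with ans[row] = assigned column.
hungarianSquare <- function(C) {
  n <- nrow(C)
  stopifnot(ncol(C) == n)
  u <- numeric(n)            # row potentials
  v <- numeric(n + 1L)       # column potentials, slot j+1 (j = 0 virtual)
  p <- integer(n + 1L)       # p[j+1] = row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- C[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Distance-capped one-to-one assignment
#'
#' Optimal assignment between two point-associated cost sets with explicit
#' non-assignment: every row/column may stay unassigned at cost \code{cap},
#' and pairs costlier than \code{cap} are never matched. Solved exactly on
#' the (m+n) x (m+n) augmented matrix; a greedy alternative (repeatedly
#' take the cheapest remaining admissible pair) is available for speed.
#'
#' @param cost m x n matrix of pair costs (e.g. distances).
#' @param cap non-assignment cost; pairs with cost > cap stay unmatched.
#' @param method "optimal" (Hungarian) or "greedy".
#' @return integer matrix with columns \code{row}, \code{col}: the matched
#'   pairs (possibly zero rows).
#' @export
solveAssignment <- function(cost, cap, method = c("optimal", "greedy")) {
  method <- match.arg(method)
  m <- nrow(cost); n <- ncol(cost)
  if (m == 0L || n == 0L)
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("row", "col"))))
  if (method == "greedy") {
    pairs <- NULL
    usedR <- logical(m); usedC <- logical(n)
    admissible <- which(cost <= cap)
    ord <- admissible[order(cost[admissible])]
    for (k in ord) {
      i <- ((k - 1L) %% m) + 1L
      j <- ((k - 1L) %/% m) + 1L
      if (!usedR[i] && !usedC[j]) {
        usedR[i] <- TRUE; usedC[j] <- TRUE
        pairs <- rbind(pairs, c(i, j))
      }
    }
    out <- if (is.null(pairs)) matrix(integer(0), 0, 2) else pairs
    colnames(out) <- c("row", "col")
    return(out)
  }
  big <- cap * (m + n + 2) + sum(cost[is.finite(cost) & cost <= cap]) + 1
  N <- m + n
  C <- matrix(big, N, N)
  sub <- pmin(cost, big)
  sub[cost > cap] <- big
  C[seq_len(m), seq_len(n)] <- sub
  for (i in seq_len(m)) C[i, n + i] <- cap       # row i unassigned
  for (j in seq_len(n)) C[m + j, j] <- cap       # col j unassigned
  C[(m + 1):N, (n + 1):N] <- 0                   # dummy-dummy
  ans <- hungarianSquare(C)
  keep <- which(ans[seq_len(m)] >= 1L & ans[seq_len(m)] <= n)
  keep <- keep[cost[cbind(keep, ans[keep])] <= cap]
  out <- cbind(row = keep, col = ans[keep])
  colnames(out) <- c("row", "col")
  out
}
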