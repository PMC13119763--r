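## One-to-one IR <-> VIS marker correspondence: scale-invariant
## neighbour-distance signatures, shortlisting, constrained RANSAC over
## triplets (orientation sign, positive determinant, rank monotonicity),
## optimal distance-capped assignment, and strict refinement.

#' Neighbour-distance signatures
#'
#' For each point, the sorted distances to its k nearest neighbours within
#' the same modality, divided by their mean: invariant to global scale by
#' construction, which makes signatures comparable across sensors of very
#' different resolution.
#'
#' @param points n x 2 matrix of (x, y) coordinates.
#' @param k number of neighbours (default 4); needs at least k+1 points.
#' @return n x k matrix of normalized signatures.
#' @export
neighborSignature <- function(points, k = 4) {
  points <- rbind(points)
  n <- nrow(points)
  if (n < k + 1) stop(sprintf("need at least %d points for k = %d", k + 1, k))
  D <- as.matrix(stats::dist(points))
  t(vapply(seq_len(n), function(i) {
    d <- sort(D[i, -i])[seq_len(k)]
    d / mean(d)
  }, numeric(k)))
}

#' Shortlist candidate VIS partners per IR point
#'
#' @param sigIr,sigVis signature matrices with the same number of columns.
#' @param m shortlist size (default 5); capped at the number of VIS points.
#' @return integer matrix, one row per IR point, the m most
#'   signature-similar VIS indices in increasing distance order.
#' @export
shortlistCandidates <- function(sigIr, sigVis, m = 5) {
  if (ncol(sigIr) != ncol(sigVis)) stop("signatures must share k")
  m <- min(m, nrow(sigVis))
  t(vapply(seq_len(nrow(sigIr)), function(i) {
    d <- sqrt(colSums((t(sigVis) - sigIr[i, ])^2))
    order(d)[seq_len(m)]
  }, integer(m)))
}

#' Sign of the oriented triangle area
#'
#' Sign of the cross product (p2 - p1) x (p3 - p1): encodes the triplet's
#' handedness. Any consistent convention serves, provided it is the same
#' in both modalities; mirrored triplets flip the sign, collinear triplets
#' return 0.
#'
#' @param p1,p2,p3 length-2 numeric (x, y).
#' @return -1, 0 or 1.
#' @export
orientedAreaSign <- function(p1, p2, p3) {
  sign((p2[1] - p1[1]) * (p3[2] - p1[2]) -
       (p2[2] - p1[2]) * (p3[1] - p1[1]))
}

#' Least-squares affine estimate from point pairs
#'
#' Minimizes sum || A p_ir + t - p_vis ||^2; exact for three
#' non-collinear pairs.
#'
#' @param irPts,visPts n x 2 matrices of corresponding points (n >= 3).
#' @return an \linkS4class{Affine2D} mapping IR to VIS coordinates.
#' @export
estimateAffine <- function(irPts, visPts) {
  irPts <- rbind(irPts); visPts <- rbind(visPts)
  n <- nrow(irPts)
  if (n < 3) stop("need at least 3 pairs")
  X <- cbind(irPts[, 1], irPts[, 2], 1)
  if (qr(X)$rank < 3) stop("degenerate (collinear) point configuration")
  theta <- qr.solve(X, visPts)           # 3 x 2
  Affine2D(linear = t(theta[1:2, ]), translation = theta[3, ])
}

#' Matching configuration
#'
#' Values unstated by the method description and chosen here as defaults:
#' k = 4 signature neighbours, shortlist 5, up to 2000 RANSAC iterations
#' (with early exit once every point is matched), permissive inlier radius
#' 5 and strict radius 2 -- both expressed in LWIR pixels and scaled into
#' the VIS frame by the hypothesis' linear scale sqrt(det A) -- and
#' Spearman thresholds 0.8 (search) / 0.95 (strict).
#'
#' @param k signature neighbours.
#' @param shortlist candidates retained per IR point.
#' @param maxIter RANSAC iteration cap.
#' @param inlierRadius permissive assignment cap, LWIR pixels.
#' @param strictRadius strict assignment cap, LWIR pixels.
#' @param rhoMin,rhoMinStrict Spearman rank-correlation thresholds.
#' @param minInliers absolute minimum pairs for a valid hypothesis (>= 3).
#' @param minInlierFrac minimum consensus as a fraction of min(M, N);
#'   guards against partial matches onto self-similar sub-patterns (e.g.
#'   one marker strip of a mirrored scene) while still tolerating
#'   missing/spurious detections.
#' @param assignment "optimal" or "greedy" one-to-one assignment.
#' @return named list of settings.
#' @export
matchConfig <- function(k = 4, shortlist = 5, maxIter = 2000,
                        inlierRadius = 5, strictRadius = 2,
                        rhoMin = 0.8, rhoMinStrict = 0.95,
                        minInliers = 3, minInlierFrac = 0.8,
                        assignment = "optimal") {
  list(k = k, shortlist = shortlist, maxIter = maxIter,
       inlierRadius = inlierRadius, strictRadius = strictRadius,
       rhoMin = rhoMin, rhoMinStrict = rhoMinStrict,
       minInliers = minInliers, minInlierFrac = minInlierFrac,
       assignment = assignment)
}

requiredInliers <- function(config, M, N) {
  frac <- config$minInlierFrac
  if (is.null(frac)) frac <- 0
  max(config$minInliers, ceiling(frac * min(M, N)))
}

#' Rank-monotonicity check on matched pairs
#'
#' Nearly parallel image axes imply that the relative ordering of matched
#' targets along x and along y is preserved across modalities. Quantified
#' by Spearman rank correlations computed independently per axis (average
#' ranks under ties).
#'
#' @param pairs matrix with columns (ir, vis) indices.
#' @param irPts,visPts the detection coordinate matrices.
#' @param rhoMin threshold both correlations must reach.
#' @param tieTol length-2 numeric c(irTol, visTol). With the default 0 the
#'   pass criterion is Spearman rho >= rhoMin per axis. With a positive
#'   tolerance, order between points whose coordinates differ by less than
#'   the detection noise is physically meaningless, so the pass criterion
#'   becomes a tolerant Kendall-type concordance: only point pairs
#'   separated by more than the tolerance in both modalities vote, and
#'   (concordant - discordant) / voting must reach rhoMin per axis.
#'   Spearman rho is reported either way.
#' @return list with rhoX, rhoY (Spearman), pass.
#' @export
monotonicityCheck <- function(pairs, irPts, visPts, rhoMin = 0.8,
                              tieTol = c(0, 0)) {
  if (nrow(pairs) < 3) stop("need at least 3 pairs")
  a <- irPts[pairs[, 1], , drop = FALSE]
  b <- visPts[pairs[, 2], , drop = FALSE]
  rho <- function(u, v) {
    r <- suppressWarnings(cor(u, v, method = "spearman"))
    if (is.na(r)) 0 else r
  }
  rhoX <- rho(a[, 1], b[, 1])
  rhoY <- rho(a[, 2], b[, 2])
  if (all(tieTol <= 0)) {
    return(list(rhoX = rhoX, rhoY = rhoY,
                pass = rhoX >= rhoMin && rhoY >= rhoMin))
  }
  gamma <- function(u, v) {
    du <- outer(u, u, "-"); dv <- outer(v, v, "-")
    # a pair votes when its separation is significant in either
    # modality: a clear separation on one side with reversed (even
    # small) separation on the other is real evidence of an ordering
    # violation, whereas pairs tied on both sides carry no information
    vote <- upper.tri(du) & (abs(du) > tieTol[1] | abs(dv) > tieTol[2])
    if (!any(vote)) return(1)
    mean(sign(du[vote]) == sign(dv[vote])) * 2 - 1
  }
  gX <- gamma(a[, 1], b[, 1])
  gY <- gamma(a[, 2], b[, 2])
  list(rhoX = rhoX, rhoY = rhoY, pass = gX >= rhoMin && gY >= rhoMin)
}

## Evaluate one affine hypothesis: project IR points into the VIS frame,
## assign one-to-one under the scaled distance cap, return pairs and
## residuals.
evaluateHypothesis <- function(A, irPts, visPts, radiusLwir, method) {
  proj <- mapPoints(A, irPts)
  scale <- sqrt(max(det(A@linear), .Machine$double.eps))
  cap <- radiusLwir * scale
  cost <- sqrt(outer(proj[, 1], visPts[, 1], "-")^2 +
               outer(proj[, 2], visPts[, 2], "-")^2)
  pairs <- solveAssignment(cost, cap, method)
  res <- if (nrow(pairs)) cost[pairs] else numeric(0)
  list(pairs = pairs, residuals = res, cap = cap)
}

noMatch <- function(seed, diagnostics) {
  new("CorrespondenceSet",
      pairs = matrix(integer(0), 0, 2, dimnames = list(NULL, c("ir", "vis"))),
      transform = Affine2D(), residuals = numeric(0),
      seed = as.numeric(seed), diagnostics = diagnostics)
}

#' RANSAC matching of IR and VIS marker sets
#'
#' Randomly samples IR triplets paired with signature-shortlisted VIS
#' candidates; hypotheses are discarded when the triplet orientations
#' disagree, the affine determinant is non-positive (a reflection,
#' physically impossible for rigidly mounted nearly parallel cameras), or
#' the matched pairs violate rank monotonicity. Each surviving hypothesis
#' is scored by inlier count under an optimal distance-capped one-to-one
#' assignment (ties broken by total residual). The best hypothesis is then
#' refined with strict thresholds (\code{\link{refineAndFinalize}}).
#' Deterministic given (inputs, seed).
#'
#' @param irPts M x 2 LWIR marker centres (M >= 3).
#' @param visPts N x 2 VIS marker centres (N >= 3).
#' @param config settings from \code{\link{matchConfig}}.
#' @param seed integer RNG seed, recorded in the result.
#' @return a \linkS4class{CorrespondenceSet}; zero pairs signal "no match"
#'   with rejection counters in \code{@diagnostics}.
#' @export
ransacMatch <- function(irPts, visPts, config = matchConfig(), seed = 1) {
  irPts <- rbind(irPts); visPts <- rbind(visPts)
  M <- nrow(irPts); N <- nrow(visPts)
  diag0 <- list(iterations = 0, degenerate = 0, orientationRejected = 0,
                detRejected = 0, monotonicityRejected = 0,
                tooFewInliers = 0)
  if (M < 3 || N < 3) {
    diag0$reason <- "fewer than 3 points in one modality"
    return(noMatch(seed, diag0))
  }
  k <- min(config$k, M - 1, N - 1)
  short <- shortlistCandidates(neighborSignature(irPts, k),
                               neighborSignature(visPts, k),
                               config$shortlist)
  oldSeed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(seed)
  best <- NULL
  bestScore <- c(-1, Inf)   # (inliers, total residual)
  diag <- diag0
  searchPhase <- function(candidates, maxIter) {
    for (it in seq_len(maxIter)) {
      diag$iterations <<- diag$iterations + 1
      triIr <- sample.int(M, 3)
      triVis <- vapply(triIr, function(i) {
        cands <- candidates[i, ]
        cands[sample.int(length(cands), 1)]
      }, integer(1))
      if (anyDuplicated(triVis)) {
        diag$degenerate <<- diag$degenerate + 1; next
      }
      sIr <- orientedAreaSign(irPts[triIr[1], ], irPts[triIr[2], ],
                              irPts[triIr[3], ])
      sVis <- orientedAreaSign(visPts[triVis[1], ], visPts[triVis[2], ],
                               visPts[triVis[3], ])
      if (sIr == 0 || sVis == 0) {
        diag$degenerate <<- diag$degenerate + 1; next
      }
      if (sIr != sVis) {
        diag$orientationRejected <<- diag$orientationRejected + 1; next
      }
      A <- tryCatch(estimateAffine(irPts[triIr, ], visPts[triVis, ]),
                    error = function(e) NULL)
      if (is.null(A)) { diag$degenerate <<- diag$degenerate + 1; next }
      if (det(A@linear) <= 0) {
        diag$detRejected <<- diag$detRejected + 1; next
      }
      ## greedy assignment while searching (cheap); the optimal solver
      ## re-scores the winning hypothesis during refinement
      ev <- evaluateHypothesis(A, irPts, visPts, config$inlierRadius,
                               "greedy")
      if (nrow(ev$pairs) < requiredInliers(config, M, N)) {
        diag$tooFewInliers <<- diag$tooFewInliers + 1; next
      }
      scl <- sqrt(max(det(A@linear), .Machine$double.eps))
      mono <- monotonicityCheck(ev$pairs, irPts, visPts, config$rhoMin,
                                tieTol = config$strictRadius * c(1, scl))
      if (!mono$pass) {
        diag$monotonicityRejected <<- diag$monotonicityRejected + 1; next
      }
      score <- c(nrow(ev$pairs), sum(ev$residuals))
      if (score[1] == min(M, N)) {
        ## every possible point matched: try to finalize right away; a
        ## failure (e.g. a spurious point slipped in and the strict pass
        ## rejects it) just discards this hypothesis and keeps searching
        if (tryFinalize(list(A = A, pairs = ev$pairs))) break
        next
      }
      if (score[1] > bestScore[1] ||
          (score[1] == bestScore[1] && score[2] < bestScore[2])) {
        bestScore <<- score
        best <<- list(A = A, pairs = ev$pairs)
      }
    }
  }
  finalResult <- NULL
  tryFinalize <- function(cand) {
    res <- refineAndFinalize(cand, irPts, visPts, config, seed = seed,
                             diagnostics = diag)
    if (nrow(res@pairs) > 0) { finalResult <<- res; TRUE } else FALSE
  }
  searchPhase(short, config$maxIter)
  if (is.null(finalResult)) {
    ## progressive relaxation: spurious points can contaminate the k-NN
    ## signatures badly enough that true partners drop out of every
    ## shortlist. Enumerate IR triplets (seeded random order) against all
    ## ordered VIS triplets -- exhaustive, so any admissible hypothesis is
    ## found -- stopping at the first full match.
    diag$relaxedShortlist <- TRUE
    triples <- utils::combn(M, 3)
    triples <- triples[, sample.int(ncol(triples)), drop = FALSE]
    visIdx <- seq_len(N)
    evalOne <- function(triIr, triVis) {
      sIr <- orientedAreaSign(irPts[triIr[1], ], irPts[triIr[2], ],
                              irPts[triIr[3], ])
      sVis <- orientedAreaSign(visPts[triVis[1], ], visPts[triVis[2], ],
                               visPts[triVis[3], ])
      if (sIr == 0 || sVis == 0 || sIr != sVis) return(invisible())
      A <- tryCatch(estimateAffine(irPts[triIr, ], visPts[triVis, ]),
                    error = function(e) NULL)
      if (is.null(A) || det(A@linear) <= 0) return(invisible())
      ev <- evaluateHypothesis(A, irPts, visPts, config$inlierRadius,
                               "greedy")
      if (nrow(ev$pairs) < requiredInliers(config, M, N)) return(invisible())
      scl <- sqrt(det(A@linear))
      mono <- monotonicityCheck(ev$pairs, irPts, visPts, config$rhoMin,
                                tieTol = config$strictRadius * c(1, scl))
      if (!mono$pass) return(invisible())
      score <- c(nrow(ev$pairs), sum(ev$residuals))
      if (score[1] == min(M, N)) {
        tryFinalize(list(A = A, pairs = ev$pairs))
        return(invisible())
      }
      if (score[1] > bestScore[1] ||
          (score[1] == bestScore[1] && score[2] < bestScore[2])) {
        bestScore <<- score
        best <<- list(A = A, pairs = ev$pairs)
      }
      invisible()
    }
    for (t in seq_len(ncol(triples))) {
      triIr <- triples[, t]
      for (a in visIdx) for (b in visIdx) {
        if (b == a) next
        for (cc in visIdx) {
          if (cc == a || cc == b) next
          evalOne(triIr, c(a, b, cc))
          if (!is.null(finalResult)) break
        }
        if (!is.null(finalResult)) break
      }
      if (!is.null(finalResult)) break
    }
  }
  if (!is.null(finalResult)) return(finalResult)
  if (is.null(best)) {
    diag$reason <- "no hypothesis satisfied the constraints"
    return(noMatch(seed, diag))
  }
  refineAndFinalize(best, irPts, visPts, config, seed = seed,
                    diagnostics = diag)
}

#' Refine the best hypothesis with strict thresholds
#'
#' Re-fits the affine map on all inliers, re-assigns with the strict
#' distance cap and monotonicity threshold, and iterates to a fixed point
#' (the pair set stops changing). Collapse below the minimum pair count
#' yields a no-match result.
#'
#' @param best list with elements A (\linkS4class{Affine2D}) and pairs.
#' @param irPts,visPts coordinate matrices.
#' @param config settings from \code{\link{matchConfig}}.
#' @param seed seed recorded in the result.
#' @param diagnostics counters carried from the search phase.
#' @return a \linkS4class{CorrespondenceSet}.
#' @export
refineAndFinalize <- function(best, irPts, visPts, config = matchConfig(),
                              seed = NA, diagnostics = list()) {
  pairs <- best$pairs
  A <- best$A
  need <- requiredInliers(config, nrow(rbind(irPts)), nrow(rbind(visPts)))
  for (pass in 1:20) {
    if (nrow(pairs) < need) {
      diagnostics$reason <- "inlier collapse during refinement"
      return(noMatch(seed, diagnostics))
    }
    A2 <- estimateAffine(irPts[pairs[, 1], ], visPts[pairs[, 2], ])
    if (det(A2@linear) <= 0) {
      diagnostics$reason <- "refined transform became a reflection"
      return(noMatch(seed, diagnostics))
    }
    ev <- evaluateHypothesis(A2, irPts, visPts, config$strictRadius,
                             config$assignment)
    if (nrow(ev$pairs) < need) {
      diagnostics$reason <- "inlier collapse during refinement"
      return(noMatch(seed, diagnostics))
    }
    scl <- sqrt(max(det(A2@linear), .Machine$double.eps))
    mono <- monotonicityCheck(ev$pairs, irPts, visPts, config$rhoMinStrict,
                              tieTol = config$strictRadius * c(1, scl))
    if (!mono$pass) {
      diagnostics$reason <- "strict monotonicity violated"
      return(noMatch(seed, diagnostics))
    }
    a <- ev$pairs[order(ev$pairs[, 1]), , drop = FALSE]
    b <- pairs[order(pairs[, 1]), , drop = FALSE]
    stable <- nrow(a) == nrow(b) && all(a == b)
    A <- A2
    pairs <- ev$pairs
    if (stable) {
      colnames(pairs) <- c("ir", "vis")
      return(new("CorrespondenceSet", pairs = pairs, transform = A,
                 residuals = ev$residuals, rhoX = mono$rhoX,
                 rhoY = mono$rhoY, seed = as.numeric(seed),
                 diagnostics = diagnostics))
    }
  }
  diagnostics$reason <- "refinement did not reach a fixed point"
  noMatch(seed, diagnostics)
}
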