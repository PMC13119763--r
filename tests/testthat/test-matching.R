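square4 <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("neighbour signatures are scale-invariant and discriminative", {
  sig <- neighborSignature(square4, k = 2)
  # every corner sees two side-length-1 neighbours: signature (1, 1)
  expect_equal(sig, matrix(1, 4, 2), ignore_attr = TRUE)
  # a 10x rescale changes nothing
  expect_equal(neighborSignature(10 * square4, k = 2), sig)
  # the centre of a square has a distinct signature from the corners
  plus <- rbind(square4, c(0.5, 0.5))
  sig5 <- neighborSignature(plus, k = 3)
  # brute-force oracle for the centre point: three nearest of four equal
  # distances sqrt(0.5)
  expect_equal(sig5[5, ], rep(1, 3), ignore_attr = TRUE)
  expect_gt(max(abs(sig5[1, ] - sig5[5, ])), 0.05)
  expect_error(neighborSignature(square4, k = 4), "at least")
})

test_that("shortlists rank true partners first on clean copies", {
  set.seed(61)
  pts <- cbind(runif(9, 0, 100), runif(9, 0, 100))
  sig <- neighborSignature(pts, k = 4)
  short <- shortlistCandidates(sig, sig, m = 3)
  expect_equal(short[, 1], 1:9)
  # m >= N returns every candidate
  shortAll <- shortlistCandidates(sig, sig, m = 99)
  expect_equal(ncol(shortAll), 9)
  # permuted noisy copy at a different scale: true partner in top 3
  hits <- 0
  for (s in 1:20) {
    set.seed(400 + s)
    perm <- sample(9)
    scale <- 37
    noisy <- pts[perm, ] * scale +
      matrix(rnorm(18, sd = 0.01 * 100 * scale), ncol = 2)
    sh <- shortlistCandidates(sig, neighborSignature(noisy, k = 4), m = 3)
    ok <- all(vapply(1:9, function(i) which(perm == i) %in% sh[i, ],
                     logical(1)))
    hits <- hits + ok
  }
  expect_equal(hits, 20)
})

test_that("oriented area sign flips under reflection, zero when collinear", {
  expect_equal(orientedAreaSign(c(0, 0), c(1, 0), c(0, 1)), 1)
  expect_equal(orientedAreaSign(c(0, 0), c(0, 1), c(1, 0)), -1)
  # reflecting any triplet flips the sign
  set.seed(62)
  for (i in 1:10) {
    tri <- matrix(runif(6, -5, 5), 3, 2)
    s <- orientedAreaSign(tri[1, ], tri[2, ], tri[3, ])
    mir <- tri; mir[, 1] <- -mir[, 1]
    expect_equal(orientedAreaSign(mir[1, ], mir[2, ], mir[3, ]), -s)
  }
  expect_equal(orientedAreaSign(c(0, 0), c(1, 1), c(2, 2)), 0)
})

test_that("affine estimation is exact on exact data, errors on degenerate", {
  ir <- rbind(c(10, 10), c(50, 12), c(30, 40), c(60, 60))
  A0 <- Affine2D(1.3 * rbind(c(cos(pi / 18), -sin(pi / 18)),
                             c(sin(pi / 18), cos(pi / 18))),
                 c(40, -15))
  vis <- mapPoints(A0, ir)
  est <- estimateAffine(ir, vis)
  expect_lt(max(abs(est@linear - A0@linear)), 1e-9)
  expect_lt(max(abs(est@translation - A0@translation)), 1e-9)
  # identity pairs
  id <- estimateAffine(ir, ir)
  expect_equal(id@linear, diag(2), tolerance = 1e-12)
  expect_error(estimateAffine(rbind(c(0, 0), c(1, 1), c(2, 2)),
                              rbind(c(0, 0), c(1, 1), c(2, 2))),
               "degenerate")
  # noisy overdetermined fit: residual shrinks with the dof correction
  set.seed(63)
  resids <- replicate(40, {
    irn <- cbind(runif(6, 0, 100), runif(6, 0, 100))
    visn <- mapPoints(A0, irn) + matrix(rnorm(12, sd = 0.3), ncol = 2)
    estn <- estimateAffine(irn, visn)
    sqrt(mean(rowSums((mapPoints(estn, irn) - visn)^2)))
  })
  # E[residual RMS] ~ sigma * sqrt(1 - p/n) with p = 3 per axis
  expect_lt(abs(mean(resids) - 0.3 * sqrt(1 - 3 / 6) * sqrt(2)) , 0.12)
})

test_that("monotonicity: crossing swaps lower rho, reversal fails", {
  ir <- cbind(seq(0, 70, by = 10), seq(0, 35, by = 5))
  vis <- ir * 3 + 5
  pairs <- cbind(1:8, 1:8)
  m0 <- monotonicityCheck(pairs, ir, vis, rhoMin = 0.95)
  expect_equal(m0$rhoX, 1); expect_equal(m0$rhoY, 1); expect_true(m0$pass)
  # one crossing swap: rho from the exact rank formula 1 - 6*2/(8*63)
  visSwap <- vis; visSwap[c(3, 4), ] <- visSwap[c(4, 3), ]
  m1 <- monotonicityCheck(pairs, ir, visSwap, rhoMin = 0.99)
  expect_equal(m1$rhoX, 1 - 12 / (8 * 63), tolerance = 1e-12)
  expect_false(m1$pass)
  # full reversal
  m2 <- monotonicityCheck(pairs, ir, vis[8:1, ], rhoMin = 0.8)
  expect_equal(m2$rhoX, -1)
  expect_false(m2$pass)
  # near-tied coordinates with a tolerance: noise-level swaps don't fail
  irT <- cbind(c(10, 10.2, 9.9, 10.1, 50, 50.3, 49.8, 50.1),
               seq(0, 70, by = 10))
  visT <- cbind(c(30.3, 30, 30.6, 30.2, 150.1, 150, 150.8, 150.2),
                seq(5, 215, by = 30))
  mT <- monotonicityCheck(cbind(1:8, 1:8), irT, visT, rhoMin = 0.95,
                          tieTol = c(2, 6))
  expect_true(mT$pass)
})

test_that("matcher: identity sets, determinism, diagnostics on no-match", {
  set.seed(64)
  pts <- cbind(runif(8, 10, 150), runif(8, 10, 110))
  vis <- pts * 3 + 10
  m <- ransacMatch(pts, vis, seed = 7)
  expect_equal(nrow(m@pairs), 8)
  expect_equal(unname(m@pairs[order(m@pairs[, 1]), 2]), 1:8)
  expect_equal(m@rhoX, 1); expect_equal(m@rhoY, 1)
  expect_gt(det(m@transform@linear), 0)
  # exactly reproducible under the same seed
  m2 <- ransacMatch(pts, vis, seed = 7)
  expect_identical(m@pairs, m2@pairs)
  expect_equal(m@transform@linear, m2@transform@linear)
  # too few points: structured no-match
  nm <- ransacMatch(pts[1:2, ], vis, seed = 1)
  expect_equal(nrow(nm@pairs), 0)
  expect_match(nm@diagnostics$reason, "fewer than 3")
})

test_that("matcher recovers known affine maps with spurious points", {
  set.seed(65)
  recovered <- 0
  for (s in 1:10) {
    sc <- makeBimodalScene(nMarkers = 8, seed = 70 + s)
    ir <- sc$truth@irCenters +
      matrix(rnorm(16, sd = 0.3), ncol = 2)
    vis <- rbind(sc$truth@visCenters + matrix(rnorm(16, sd = 0.3), ncol = 2),
                 cbind(runif(2, 100, 540), runif(2, 100, 380)))
    m <- ransacMatch(ir, vis, seed = s)
    ok <- nrow(m@pairs) == 8 && all(m@pairs[, 2] <= 8) &&
      all(m@pairs[order(m@pairs[, 1]), 2] == 1:8)
    recovered <- recovered + ok
    # accepted transforms always preserve orientation
    if (nrow(m@pairs) > 0) expect_gt(det(m@transform@linear), 0)
  }
  expect_gte(recovered, 9)
})

test_that("mirrored scenes are refused", {
  for (s in 1:5) {
    sc <- makeBimodalScene(nMarkers = 8, seed = 80 + s)
    vis <- sc$truth@visCenters
    vis[, 1] <- max(vis[, 1]) + min(vis[, 1]) - vis[, 1]
    m <- ransacMatch(sc$truth@irCenters, vis, seed = s)
    expect_equal(nrow(m@pairs), 0)
  }
})

test_that("refinement is a fixed point and never increases the residual", {
  set.seed(66)
  sc <- makeBimodalScene(nMarkers = 8, seed = 90)
  ir <- sc$truth@irCenters
  vis <- sc$truth@visCenters
  # noiseless: refinement reproduces the RANSAC result
  m <- ransacMatch(ir, vis, seed = 3)
  again <- refineAndFinalize(list(A = m@transform, pairs = m@pairs),
                             ir, vis, matchConfig(), seed = 3)
  expect_equal(again@pairs[order(again@pairs[, 1]), ],
               m@pairs[order(m@pairs[, 1]), ], ignore_attr = TRUE)
  # noisy: the refined fit's residual does not exceed the 3-point
  # hypothesis residual
  irn <- ir + matrix(rnorm(16, sd = 0.4), ncol = 2)
  visn <- vis + matrix(rnorm(16, sd = 0.4), ncol = 2)
  mn <- ransacMatch(irn, visn, seed = 4)
  expect_gt(nrow(mn@pairs), 5)
  A3 <- estimateAffine(irn[mn@pairs[1:3, 1], ], visn[mn@pairs[1:3, 2], ])
  resOf <- function(A) {
    proj <- mapPoints(A, irn[mn@pairs[, 1], ])
    sqrt(mean(rowSums((proj - visn[mn@pairs[, 2], ])^2)))
  }
  expect_lte(resOf(mn@transform), resOf(A3) + 1e-9)
})
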