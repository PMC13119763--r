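test_that("water vapour pressure follows the stated polynomial", {
  expect_equal(waterVapourPressure(25, 0), 0)
  # independent scalar evaluation of the polynomial at the protocol's
  # ambient conditions
  Ta <- 22.4
  expected <- 0.58 * exp(1.5587 + 0.06939 * Ta - 0.00027816 * Ta^2 +
                         0.00000068455 * Ta^3)
  expect_equal(waterVapourPressure(22.4, 0.58), expected)
  expect_equal(round(expected, 2), 11.43)
  # strictly increasing in RH at fixed temperature (linear in RH)
  rh <- seq(0.1, 1, by = 0.1)
  wp <- waterVapourPressure(30, rh)
  expect_true(all(diff(wp) > 0))
  expect_error(waterVapourPressure(20, 1.2), "RH")
})

test_that("atmospheric transmission: unit at zero path, decays with distance", {
  expect_equal(atmTransmission(radiometricParams(distanceM = 0)), 1)
  # monotone non-increasing in distance at fixed vapour pressure
  taus <- vapply(seq(0, 5, by = 0.5), function(d)
    atmTransmission(radiometricParams(distanceM = d)), numeric(1))
  expect_true(all(diff(taus) <= 0))
  expect_true(all(taus > 0 & taus <= 1))
  # independent scalar oracle at the protocol distance
  p <- radiometricParams(distanceM = 0.5, TaC = 22.4, RH = 0.58)
  Wp <- waterVapourPressure(22.4, 0.58)
  oracle <- p@Xatm * exp(-sqrt(0.5) * (p@alpha1 + p@beta1 * sqrt(Wp))) +
    (1 - p@Xatm) * exp(-sqrt(0.5) * (p@alpha2 + p@beta2 * sqrt(Wp)))
  expect_equal(atmTransmission(p), oracle)
  # the switchable literal-product variant differs from the default
  pl <- radiometricParams(distanceM = 0.5, TaC = 22.4, RH = 0.58,
                          atmFormula = "linear")
  oracleL <- p@Xatm * exp(-0.5 * (p@alpha1 + p@beta1 * Wp)) +
    (1 - p@Xatm) * exp(-0.5 * (p@alpha2 + p@beta2 * Wp))
  expect_equal(atmTransmission(pl), min(oracleL, 1))
})

test_that("path radiances vanish with their prefactors", {
  expect_equal(pathRadiances(radiometricParams(emissivity = 1))$Rrefl, 0)
  expect_equal(pathRadiances(radiometricParams(Wt = 1))$Ropt, 0)
  p0 <- radiometricParams(distanceM = 0)   # tau = 1
  expect_equal(pathRadiances(p0, tau = 1)$Ratm, 0)
  r <- pathRadiances(radiometricParams(Wt = 0.9, emissivity = 0.95))
  expect_true(all(is.finite(unlist(r))))
})

test_that("object radiance is affine in counts and matches a scalar oracle", {
  p <- radiometricParams()
  tau <- atmTransmission(p)
  rads <- pathRadiances(p, tau)
  # identity configuration: all path terms vanish
  pid <- radiometricParams(emissivity = 1, Wt = 1, distanceM = 0)
  expect_equal(countsToObjectRadiance(c(100, 5000), pid, tau = 1),
               c(100, 5000))
  # linearity in counts
  c1 <- countsToObjectRadiance(1000, p, tau, rads)
  c2 <- countsToObjectRadiance(3000, p, tau, rads)
  cmid <- countsToObjectRadiance(2000, p, tau, rads)
  expect_equal(cmid, (c1 + c2) / 2)
  # scalar oracle per the measurement equation
  oracle <- 2500 / (p@emissivity * tau * p@Wt) -
    rads$Ratm - rads$Ropt - rads$Rrefl
  expect_equal(countsToObjectRadiance(2500, p, tau, rads), oracle)
})

test_that("Planck inversion is exact, monotone, and reports bad pixels", {
  p <- radiometricParams()
  # analytic spot check: radiance constructed for an exact 25.00 degC
  TK <- 298.15
  Robj <- p@PR1 / (p@PR2 * (exp(p@PB / TK) - p@PF)) - p@PO
  expect_equal(planckInvert(Robj, p), 25, tolerance = 1e-12)
  # strictly increasing in radiance
  rr <- seq(1000, 6000, length.out = 50)
  expect_true(all(diff(planckInvert(rr, p)) > 0))
  # offending pixels are reported, not clipped
  expect_error(planckInvert(c(3000, -1e9), p), "out-of-range")
})

test_that("forward/inverse chain round-trips to 1e-9 over random params", {
  set.seed(71)
  for (i in 1:100) {
    p <- radiometricParams(
      PB = runif(1, 1300, 1600), PR1 = runif(1, 14000, 22000),
      PR2 = runif(1, 0.01, 0.08), PO = runif(1, -9000, -100),
      PF = runif(1, 0.5, 2.5), emissivity = runif(1, 0.8, 1),
      Wt = runif(1, 0.85, 1), distanceM = runif(1, 0.1, 2),
      TaC = runif(1, 15, 30), RH = runif(1, 0.2, 0.9))
    Ts <- seq(-20, 60, length.out = 17)
    back <- planckInvert(
      countsToObjectRadiance(planckForward(Ts, p), p), p)
    expect_lt(max(abs(back - Ts)), 1e-9)
  }
})

test_that("frame-to-temperature composes the whole chain", {
  p <- radiometricParams()
  # uniform scene with unit gain comes back exactly
  counts <- matrix(planckForward(33, p), 40, 50)
  g1 <- new("GainField", values = matrix(1, 40, 50), epoch = 0,
            normalizer = "median", floor = 1e-6)
  tI <- frameToTemperature(RadiometricFrame(counts), g1, p)
  expect_equal(max(abs(tI@values - 33)), 0, tolerance = 1e-9)
  expect_true(tI@vignetteCorrected)
  # vignetted scene: correction recovers the truth; skipping the
  # correction leaves a spatial gradient far above the noise floor
  gain <- makeGain(shape = c(40, 50), amplitude = 0.1, seed = 2)
  vc <- counts * gain@values
  tCorr <- frameToTemperature(RadiometricFrame(vc), gain, p)
  expect_lt(max(abs(tCorr@values - 33)), 1e-6)
  tRaw <- frameToTemperature(RadiometricFrame(vc), NULL, p)
  expect_false(tRaw@vignetteCorrected)
  expect_gt(diff(range(tRaw@values)), 1)   # several degC of false gradient
})

test_that("counts-per-degree sensitivity is positive and finite", {
  p <- radiometricParams()
  s <- countsPerDegree(c(20, 30, 40), p)
  expect_true(all(s > 0 & is.finite(s)))
})
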