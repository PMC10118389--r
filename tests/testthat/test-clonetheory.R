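test_that("establishment probability from the branching rates", {
  p <- defaultParams()
  ## at the no-CRISPR bacterial total, s0 = 0 exactly: alpha nB (BpV-1) = F
  est <- establishmentProbability(p, nB = 0.15 * p@C0)
  expect_equal(est$s0, 0, tolerance = 1e-15)
  expect_equal(est$Pest, 0)
  est2 <- establishmentProbability(p, nB = 0.2 * p@C0)
  expect_equal(est2$s0, 2.4e-3, tolerance = 1e-10)
  expect_equal(est2$delta0, 1.112e-2, tolerance = 1e-10)
  expect_equal(est2$Pest, 2.0884e-3, tolerance = 1e-4)
  ## steady-state form vanishes with e
  expect_equal(establishmentProbability(p, 1000, e = 0, nu = 0.3,
                                        m = 5)$PestSteadyState, 0)
})

test_that("branching oracle agrees with closed forms", {
  ## subcritical process never survives
  expect_equal(branchingExtinctionOracle(1e-3, 1e-2, B = 5)[["survival"]], 0)
  ## B = 2: extinction probability is delta0/beta0 exactly
  b0 <- 2e-3; d0 <- 1.5e-3
  expect_equal(branchingExtinctionOracle(b0, d0, B = 2)[["extinction"]],
               d0 / b0, tolerance = 1e-10)
  ## n independent founders: survival complement compounds
  one <- branchingExtinctionOracle(b0, d0, B = 2)[["extinction"]]
  expect_equal(branchingExtinctionOracle(b0, d0, B = 2, n = 5)[["extinction"]],
               one^5, tolerance = 1e-12)
})

test_that("establishment formula matches the oracle when s0 << delta0", {
  p <- defaultParams()
  ## grid of bacterial totals giving 0 < s0 <= 0.2 delta0
  nBgrid <- seq(1520, 1930, length.out = 20)
  for (nB in nBgrid) {
    est <- establishmentProbability(p, nB)
    expect_lte(est$s0, 0.2 * est$delta0 + 1e-12)
    orc <- branchingExtinctionOracle(est$beta0, est$delta0, p@B)
    expect_equal(est$Pest, orc[["survival"]], tolerance = 0.05)
  }
})

test_that("large-clone extinction time: full and approximate forms", {
  p <- defaultParams()
  m <- 10
  expect_equal(textApprox(p, m), 2023.2, tolerance = 1e-3)
  ## full form at the deterministic clone sizes agrees to O(1/B)
  ss <- steadyState(p, p@e / m)
  nB <- ss@xStar * p@C0; nV <- ss@yStar * p@C0
  nBs <- ss@nuStar * nB
  full <- largeCloneExtinctionTime(p, nV / m, nV, nB, nBs / m)
  ## identity: 2 beta + delta = alpha pV nB (1 - e nu/m)(B + 1) at the
  ## steady state, so full/approx = B/(B+1) up to the e/m expansion
  expect_lt(abs(full$generations - textApprox(p, m)) / full$generations,
            2 / p@B + 0.05)
  ## nVi -> nV removes the log term
  al <- adsorptionRate(p); FF <- outflowRate(p)
  beta <- al * p@pV * (nB - p@e * nBs / m)
  delta <- FF + al * nB * (1 - p@pV) + al * p@pV * p@e * nBs / m
  f2 <- largeCloneExtinctionTime(p, nV, nV, nB, nBs / m)
  expect_equal(f2$minutes, 2 * nV / ((p@B - 1) * (2 * beta + delta)),
               tolerance = 1e-12)
  expect_error(largeCloneExtinctionTime(p, 10, 5, nB, 1), "nVi")
})

test_that("effective mutation rate scales with the burst mutation odds", {
  p <- defaultParams()
  expect_equal(effectiveMutationRate(simParams(mu = 0), 1e5, 1e3), 0)
  ## the per-offspring factor 1 - e^{-mu L} at the largest mutation rate
  r1 <- effectiveMutationRate(simParams(mu = 1e-4), 1e5, 1e3)
  r2 <- effectiveMutationRate(simParams(mu = 1e-8), 1e5, 1e3)
  expect_equal(r1 / r2, (1 - exp(-1e-4 * 30)) / (1 - exp(-1e-8 * 30)),
               tolerance = 1e-9)
  ## zeroth-order (no-CRISPR totals) within 10% of the full rate at e/m
  pd <- predictDiversity(p)
  full <- pd$details$muBar
  z <- effectiveMutationRate(p, zerothOrder = TRUE)
  expect_equal(z / full, 1, tolerance = 0.1)
})

test_that("diversity parameter and closed-form m", {
  p <- defaultParams()
  a <- diversityParameter(p)
  expect_equal(a[["approx"]], 5966.8, tolerance = 1e-3)
  pd <- predictDiversity(p)
  expect_equal(pd$mClosedForm, 29.70, tolerance = 1e-3)
  expect_equal(pd$mPerturbative, pd$mClosedForm, tolerance = 0.01)
  ## a is proportional to mu; m gains the 1/3 exponent with log correction
  a10 <- diversityParameter(simParams(mu = 1e-4))
  expect_equal(a10[["approx"]] / a[["approx"]], 10, tolerance = 1e-9)
  m10 <- predictDiversity(simParams(mu = 1e-4))$mClosedForm
  expect_gt(m10 / pd$mClosedForm, 10^(1/3) * 0.98)
  expect_lt(m10 / pd$mClosedForm, 10^(1/3) * 1.25)
  ## mu -> 0 flags the sub-1 regime
  tiny <- predictDiversity(simParams(mu = 1e-12))
  expect_true(tiny$subOne)
  expect_lt(tiny$mClosedForm, 1)
})

test_that("closed-form exponent d ln m / d ln a tends to 1/3", {
  h <- 1e-4
  for (a in c(1e2, 1e4, 1e8)) {
    .solveM <- function(a) {
      g <- function(m) m^3 - a * (1 + log(m))
      uniroot(g, c(1, 10 * a^(1/3) + 10), tol = 1e-12)$root
    }
    mv <- .solveM(a)
    slope <- (log(.solveM(a * exp(h))) - log(mv)) / h
    expect_equal(slope, 1 / (3 - 1 / (1 + log(mv))), tolerance = 1e-3)
  }
  expect_equal(1 / (3 - 1 / (1 + log(1e6))), 1/3, tolerance = 0.03)
})

test_that("self-consistent m solves the establishment-extinction balance", {
  p <- defaultParams()
  pd <- predictDiversity(p)
  expect_true(pd$mFound)
  with(pd$details, expect_equal(Pest * muBar * Text, pd$m,
                                tolerance = 1e-6))
  ## fed-back residual: recompute the product at the solution
  pd3 <- predictDiversity(defaultParams(C0 = 1e3))
  expect_true(pd3$mFound)
  with(pd3$details, expect_equal(Pest * muBar * Text, pd3$m,
                                 tolerance = 1e-6))
})

test_that("closed-form Pest composes from nu, m and a", {
  p <- defaultParams()
  pcf <- pestClosedForm(p)
  ## composition of 2 e nu/(m(B-1)) with the same approximations used for
  ## the closed-form a: nu ~ etahat alpha nVtilde / r with
  ## nVtilde ~ gC0(1-f)/(alpha pV), m ~ a^(1/3), B-1 ~ B
  etah <- p@eta * (1 - p@pV)
  nuA <- etah * (p@gC0 * (1 - p@f) / p@pV) / lossRate(p)
  a <- diversityParameter(p)[["approx"]]
  expect_equal(pcf, 2 * p@e * nuA / (p@B * a^(1/3)), tolerance = 1e-10)
  ## decreases with mutation rate
  expect_lt(pestClosedForm(simParams(mu = 1e-4)), pcf)
})

test_that("deterministic clone dynamics and fixed points", {
  p <- defaultParams()
  m <- 10
  ss <- steadyState(p, p@e / m)
  tot <- c(nB = ss@xStar * p@C0, nB0 = (1 - ss@nuStar) * ss@xStar * p@C0,
           nV = ss@yStar * p@C0, C = ss@cStar * p@C0)
  cd <- cloneDynamics(p, tot, horizon = 400, nVi0 = 1, nBi0 = 0)
  ## early growth follows exp(s0 t) while nBi is negligible
  tr <- cd$trajectory
  early <- tr[tr$time <= 400, ]
  expect_equal(early$nVi, exp(cd$s0 * early$time), tolerance = 0.01)
  ## fixed points reduce to the per-clone shares of the totals
  nBs <- ss@nuStar * tot[["nB"]]
  expect_equal(cd$fixedPoint[["nBiStar"]], nBs / m, tolerance = 0.03)
  expect_equal(cd$fixedPoint[["nViStar"]], tot[["nV"]] / m, tolerance = 0.03)
})

test_that("first-acquisition timing from the growing-clone density", {
  p <- defaultParams()
  s0 <- 0.01
  nB0 <- 1e-4 / (adsorptionRate(p) * p@eta * (1 - p@pV))
  at <- acquisitionTime(p, s0, nB0)
  expect_equal(at$aAcq, 1e-4, tolerance = 1e-10)
  ## density has unit mass
  expect_equal(integrate(at$density, 0, Inf, rel.tol = 1e-8)$value, 1,
               tolerance = 1e-6)
  ## worked values via E1(0.01) = 4.0379
  expect_equal(at$meanTime, 407.85, tolerance = 1e-4)
  expect_equal(at$sizeAtMean, 59.06, tolerance = 1e-3)
  ## slow acquisition: first acquisition after the drift-escape time 1/s0
  expect_gt(at$meanTime, 1 / s0)
  expect_error(acquisitionTime(p, -0.01, 1000), "positive")
})

test_that("speed prediction is clone turnover in disguise", {
  p <- defaultParams()
  sp <- predictSpeed(p, Text = 2023.2)
  expect_equal(sp$v, 1 / 2023.2)
  expect_equal(sp$v * 2023.2, 1)
  ## closed form scales as mu^(1/3)
  r10 <- predictSpeed(simParams(mu = 1e-4))$vClosedForm /
    predictSpeed(p)$vClosedForm
  expect_equal(r10, 10^(1/3), tolerance = 1e-9)
  ## Text route from m matches textApprox
  expect_equal(predictSpeed(p, m = 10)$v, 1 / textApprox(p, 10))
})

test_that("theory bundle is internally consistent", {
  p <- defaultParams()
  tb <- theoryBundle(p)
  expect_equal(tb@A, 14 / 3, tolerance = 1e-12)
  expect_true(tb@mFound)
  expect_equal(tb@Pest * tb@muBar * tb@Text, tb@mPred, tolerance = 1e-6)
  expect_equal(tb@vPred * tb@Text, 1, tolerance = 1e-9)
  expect_true(tb@Pest >= 0 && tb@Pest <= 1)
})
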