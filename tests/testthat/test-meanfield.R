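test_that("phage viability index and extinction threshold", {
  p <- defaultParams()
  th <- phageThreshold(p)
  expect_equal(th[["A"]], 14 / 3, tolerance = 1e-12)
  expect_equal(th[["pV0"]], ((0.3 / 0.7) / (2e-2 / 2.4e-2) + 1) / 170,
               tolerance = 1e-12)
  ## at pV = pV0 the index is exactly 1
  pc <- simParams(pV = th[["pV0"]])
  expect_equal(phageThreshold(pc)[["A"]], 1, tolerance = 1e-12)
  expect_gt(phageThreshold(simParams(pV = th[["pV0"]] * 1.01))[["A"]], 1)
})

test_that("no-CRISPR steady state matches the closed forms", {
  p <- defaultParams()
  tot <- noCrisprSteadyState(p)
  expect_equal(tot[["nBTilde"]], 0.15 * p@C0, tolerance = 1e-10)
  expect_equal(tot[["nVTilde"]], 22.0 * p@C0, tolerance = 1e-3)
  ## nB_tilde reduces to C0 f g / ((BpV-1) alpha), independent algebra
  for (f in c(0.2, 0.5)) {
    pf <- simParams(f = f)
    expect_equal(noCrisprSteadyState(pf)[["nBTilde"]],
                 pf@C0 * f * pf@gC0 / ((pf@B * pf@pV - 1) * pf@alphaC0),
                 tolerance = 1e-12)
  }
  expect_error(noCrisprSteadyState(simParams(pV = 0.005)), "extinct")
})

test_that("mean-field RHS vanishes at fixed points", {
  p <- defaultParams()
  tot <- noCrisprSteadyState(p)
  A <- phageThreshold(p)[["A"]]
  ## nutrient level at the no-CRISPR fixed point: C* = f/(f + x*) * C0
  x <- tot[["nBTilde"]] / p@C0
  totals <- c(nBs = 0, nV = tot[["nVTilde"]], nB0 = tot[["nBTilde"]],
              C = p@C0 * p@f / (p@f + x))
  rhs <- odeRHS(totals, p, eEff = 0)
  ## acquisition shuffles bacteria between the naive and spacer classes,
  ## but the totals nB, nV and C are stationary
  expect_lt(abs(rhs[["nBs"]] + rhs[["nB0"]]), 1e-8 * p@gC0 * p@C0)
  expect_lt(abs(rhs[["nV"]]), 1e-8 * p@gC0 * p@C0)
  expect_lt(abs(rhs[["C"]]), 1e-8 * p@gC0 * p@C0)
  ## phage-free bacterial subsystem: nB = C0(1-f), C = f C0
  totals0 <- c(nBs = 0, nV = 0, nB0 = p@C0 * (1 - p@f), C = p@f * p@C0)
  rhs0 <- odeRHS(totals0, p, eEff = 0)
  expect_true(all(abs(rhs0) < 1e-10))
  ## full immunity wipes the spacer-side phage production term
  t1 <- c(nBs = 1000, nV = 1000, nB0 = 0, C = 5000)
  r1 <- odeRHS(t1, p, eEff = 1)
  expect_equal(r1[["nV"]], -(outflowRate(p) + adsorptionRate(p) * 1000) *
                 1000, tolerance = 1e-12)
})

test_that("nu cubic reproduces its limiting closed forms", {
  p <- defaultParams()
  ## independent oracle: nu_tilde = 1/(1 + r/(etahat alpha nV_tilde))
  etah <- 1e-3 * 0.98
  nuT <- 1 / (1 + (0.04 * 2.4e-2) / (etah * 2e-2 * 22.0))
  expect_equal(nuStarCubic(p, 0)$nu, nuT, tolerance = 1e-3)
  ## no acquisition, positive loss: no spacers
  expect_equal(nuStarCubic(simParams(eta = 0), 0.05)$nu, 0)
  ## e -> 1, eta -> 0: root of the eta=0 quadratic factor
  pe <- simParams(eta = 1e-9)
  ap <- nuApproximations(pe, 1)
  expect_equal(nuStarCubic(pe, 1)$nu, ap$largeE, tolerance = 1e-4)
  expect_equal(ap$largeE, 0.5240642, tolerance = 1e-5)
})

test_that("dominant-balance approximations behave per regime", {
  p <- defaultParams()
  ap <- nuApproximations(p, 0)
  expect_equal(ap$nuTilde, 0.30995, tolerance = 1e-4)
  expect_equal(ap$dropCubicQuadratic, ap$nuTilde, tolerance = 0.02)
  ## eta-hat -> infinity saturates nu_tilde at 1
  expect_gt(nuApproximations(simParams(eta = 0.9), 0)$nuTilde, 0.99)
  ## monotonicity: nu_tilde increasing in eta, decreasing in R
  nus <- vapply(c(1e-4, 1e-3, 1e-2),
                function(et) nuApproximations(simParams(eta = et), 0)$nuTilde,
                numeric(1))
  expect_true(all(diff(nus) > 0))
  nur <- vapply(c(0.01, 0.04, 0.16),
                function(R) nuApproximations(simParams(R = R), 0)$nuTilde,
                numeric(1))
  expect_true(all(diff(nur) < 0))
})

test_that("critical effective immunity and its eta threshold", {
  p <- defaultParams()
  ce <- criticalEffectiveE(p)
  ## third denominator term changes sign at eta = 0.0113
  expect_equal(signif(ce$etaSignThreshold, 3), 0.0113)
  ## eta -> 0 series limit: r/(alpha nV_tilde pV) = 0.109
  ce0 <- criticalEffectiveE(simParams(eta = 1e-12))
  expect_equal(ce0$emStarSeries, 9.6e-4 / (0.44 * 0.02), tolerance = 1e-6)
  expect_equal(ce0$emStarFull, ce0$emStarSeries, tolerance = 1e-3)
  ## order of magnitude 1e-1 across mu, e, C0
  for (pp in list(p, simParams(C0 = 1e5), simParams(mu = 1e-7),
                  simParams(e = 0.3)))
    expect_true(criticalEffectiveE(pp)$emStarFull > 0.05 &&
                  criticalEffectiveE(pp)$emStarFull < 0.5)
})

test_that("steady state composes, verifies, and is continuous", {
  p <- defaultParams()
  ss0 <- steadyState(p, 0)
  tot <- noCrisprSteadyState(p)
  expect_equal(ss0@xStar, tot[["nBTilde"]] / p@C0, tolerance = 1e-10)
  expect_equal(ss0@yStar, tot[["nVTilde"]] / p@C0, tolerance = 1e-10)
  grid <- seq(0, 0.09, by = 0.005)    # below the em* singularity (0.173)
  sss <- lapply(grid, function(E) steadyState(p, E))
  expect_true(all(vapply(sss, function(s) s@residual, 1) < 1e-8))
  x <- vapply(sss, function(s) s@xStar, 1)
  expect_true(max(abs(diff(x))) < 0.2 * max(x))   # no jumps on the branch
  ## phage-extinct regime flagged with the bacteria-only fixed point
  se <- steadyState(simParams(pV = 0.005), 0.1)
  expect_true(se@phageExtinct)
  expect_equal(se@xStar, 1 - p@f)
  expect_equal(se@yStar, 0)
})

test_that("phage total is non-monotone in pV with an interior maximum", {
  pVs <- seq(0.01, 0.3, by = 0.01)
  y <- vapply(pVs, function(pv)
    steadyState(simParams(pV = pv), eEff = 0.05)@yStar, numeric(1))
  i <- which.max(y)
  expect_gt(i, 1)
  expect_lt(i, length(pVs))
})

test_that("totals at the critical effective immunity approach no-CRISPR", {
  p <- simParams(eta = 1e-5)
  ce <- criticalEffectiveE(p)
  ss <- steadyState(p, min(ce$emStarFull, 1))
  nBt <- noCrisprSteadyState(p)[["nBTilde"]]
  expect_equal(ss@xStar, nBt / p@C0, tolerance = 0.15)
})
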