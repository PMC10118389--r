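test_that("channel propensities follow the reaction catalogue", {
  p <- defaultParams()
  mk <- function(C, nB0, bs, bc, ps, pc)
    CRISPRcoevo:::.PopulationState(time = 0, C = C, nB0 = nB0,
        bacteriaSeq = as.integer(bs), bacteriaCount = as.numeric(bc),
        phageSeq = as.integer(ps), phageCount = as.numeric(pc))
  ## no phage: every adsorption channel is silent
  s1 <- mk(5000, 100, 3L, 10, integer(0), numeric(0))
  r1 <- channelRates(s1, p)
  expect_equal(r1$adsorptionTotal, 0)
  expect_length(r1$adsorptionNaive, 0)
  ## no nutrients: no growth
  s2 <- mk(0, 100, integer(0), numeric(0), 7L, 50)
  r2 <- channelRates(s2, p)
  expect_equal(r2$growth0, 0)
  ## alpha * nB * nV arithmetic
  s3 <- mk(1000, 100, integer(0), numeric(0), 7L, 50)
  r3 <- channelRates(s3, p)
  expect_equal(r3$adsorptionTotal, 2e-6 * 100 * 50)   # 0.01 per minute
  expect_equal(sum(r3$adsorptionNaive) + 0, r3$adsorptionTotal)
})

test_that("runs are reproducible given a seed", {
  p <- defaultParams(C0 = 1e3)
  r1 <- tauLeapRun(p, tEndGen = 60, seed = 5)
  r2 <- tauLeapRun(p, tEndGen = 60, seed = 5)
  expect_identical(r1@totals, r2@totals)
  expect_identical(r1@clones, r2@clones)
  g1 <- gillespieRun(p, tEndGen = 10, seed = 5)
  g2 <- gillespieRun(p, tEndGen = 10, seed = 5)
  expect_identical(g1@totals, g2@totals)
})

test_that("counts stay non-negative and snapshots are consistent", {
  p <- defaultParams(C0 = 1e3)
  r <- tauLeapRun(p, tEndGen = 150, seed = 3)
  tot <- r@totals
  expect_true(all(tot$C >= 0 & tot$nB0 >= 0 & tot$nBs >= 0 & tot$nV >= 0))
  times <- vapply(r@snapshots, function(s) s@time, numeric(1))
  expect_true(all(diff(times) > 0))
  for (s in r@snapshots) expect_true(validObject(s))
  ## clone records: birth <= extinction, max size positive
  cl <- r@clones
  expect_true(all(is.na(cl$extinction) | cl$extinction >= cl$birth))
  expect_true(all(cl$maxSize >= 1))
})

test_that("without mutation no new phage types appear", {
  p <- defaultParams(C0 = 1e3, mu = 0)
  r <- tauLeapRun(p, tEndGen = 120, seed = 2)
  expect_true(all(diff(r@totals$mPhage) <= 0))
  expect_equal(r@schedule$mutantsCreated, 0)
  g <- gillespieRun(p, tEndGen = 20, seed = 2)
  expect_true(all(g@totals$mPhage <= 1))
})

test_that("phage-free chemostat settles at C0(1-f) bacteria", {
  ## alpha = 0 and r = 0: pure logistic-like growth against outflow
  p <- simParams(C0 = 500, alphaC0 = 0, R = 0, eta = 0, mu = 0)
  init <- CRISPRcoevo:::.PopulationState(time = 0, C = 500, nB0 = 50,
              bacteriaSeq = integer(0), bacteriaCount = numeric(0),
              phageSeq = integer(0), phageCount = numeric(0))
  g <- gillespieRun(p, init = init, tEndGen = 150, seed = 1,
                    stopOnPhageExtinct = FALSE)
  ss <- steadyWindow(g, startGen = 50)
  expect_equal(mean(ss$nB0), 500 * 0.7, tolerance = 0.1)
  ## nutrient balance in expectation: F(C0 - C) = g C nB at steady state
  lhs <- outflowRate(p) * (500 - mean(ss$C))
  rhs <- growthRate(p) * mean(ss$C * ss$nB0)
  expect_equal(lhs, rhs, tolerance = 0.15)
})

test_that("sub-threshold phage die out quickly", {
  p0 <- defaultParams(C0 = 1e3)
  pV0 <- phageThreshold(p0)[["pV0"]]
  p <- defaultParams(C0 = 1e3, pV = 0.8 * pV0)
  for (s in 1:3) {
    r <- tauLeapRun(p, tEndGen = 500, seed = s)
    expect_equal(r@totals$nV[nrow(r@totals)], 0)
  }
})

test_that("clone records carry parentage and establishment", {
  p <- defaultParams(C0 = 1e3)
  r <- tauLeapRun(p, tEndGen = 400, seed = 7)
  cl <- recordClones(r)
  expect_true(all(c("population", "seqString", "parent", "birth",
                    "establishment", "extinction", "maxSize") %in%
                    names(cl)))
  ph <- cl[cl$population == "phage", ]
  ## the founding clone has no parent; mutants point at an existing type
  expect_true(any(is.na(ph$parent)))
  kids <- ph[!is.na(ph$parent), ]
  expect_true(all(kids$parent %in% r@clones$seq))
  ## establishment only between birth and extinction, above threshold
  est <- cl[!is.na(cl$establishment), ]
  expect_true(all(est$establishment >= est$birth))
  expect_true(all(est$maxSize >= attr(cl, "threshold")[["phage"]] |
                    est$population == "bacteria"))
  ## a clone that never crossed the threshold has no establishment time
  small <- cl[cl$population == "phage" &
                cl$maxSize < attr(cl, "threshold")[["phage"]], ]
  expect_true(all(is.na(small$establishment)))
})

test_that("re-created types get separate clone records", {
  p <- defaultParams(C0 = 1e3)
  r <- tauLeapRun(p, tEndGen = 2000, seed = 1)
  cl <- r@clones[r@clones$population == "phage", ]
  dup <- cl[duplicated(cl$seq) | duplicated(cl$seq, fromLast = TRUE), ]
  if (nrow(dup) >= 2) {
    for (sq in unique(dup$seq)) {
      runs <- dup[dup$seq == sq, ]
      runs <- runs[order(runs$birth), ]
      ## lifespans are disjoint: each new record starts after the previous
      ## extinction
      if (nrow(runs) >= 2)
        expect_true(all(runs$birth[-1] >=
                          runs$extinction[-nrow(runs)] - 1e-9))
    }
  }
  expect_gt(nrow(cl), 1)
})

test_that("tau-leap matches the mean-field spacer fraction at C0=1e4", {
  p <- defaultParams(C0 = 1e4)
  r <- tauLeapRun(p, tEndGen = 600, seed = 2)
  ss <- steadyWindow(r, startGen = 250)
  m <- mean(ss$mBacteria)
  nuHat <- mean(ss$nBs / (ss$nB0 + ss$nBs))
  nuTheory <- steadyState(p, min(p@e / m, 1))@nuStar
  expect_equal(nuHat, nuTheory, tolerance = 0.25)
  expect_equal(mean(ss$nV) / p@C0,
               steadyState(p, min(p@e / m, 1))@yStar, tolerance = 0.25)
  ## feeding the *measured* average immunity back as effective e
  ## reproduces the simulated totals
  ai <- vapply(r@snapshots, function(sn) {
    b <- setNames(sn@bacteriaCount, as.character(sn@bacteriaSeq))
    v <- setNames(sn@phageCount, as.character(sn@phageSeq))
    if (!sum(b) || !sum(v)) return(NA_real_)
    averageImmunity(b, v, e = p@e)
  }, numeric(1))
  ssm <- steadyState(p, mean(ai, na.rm = TRUE))
  expect_equal(mean(ss$nB0 + ss$nBs) / p@C0, ssm@xStar, tolerance = 0.15)
  expect_equal(mean(ss$nV) / p@C0, ssm@yStar, tolerance = 0.15)
})

test_that("cross-reactive runs stay within kernel bounds", {
  p <- defaultParams(C0 = 1e3, xr = crossReactivity("step", 1))
  r <- tauLeapRun(p, tEndGen = 150, seed = 4)
  expect_true(all(r@totals$nV >= 0))
  ## immunity of the steady population against itself is within [0, e]
  if (length(r@snapshots)) {
    s <- r@snapshots[[length(r@snapshots)]]
    if (length(s@bacteriaSeq) && length(s@phageSeq)) {
      b <- setNames(s@bacteriaCount, seqToString(s@bacteriaSeq, p@L))
      v <- setNames(s@phageCount, seqToString(s@phageSeq, p@L))
      ai <- averageImmunity(b, v, e = p@e, xr = p@xr)
      expect_gte(ai, 0); expect_lte(ai, p@e)
    }
  }
})
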