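test_that("average immunity: delta-matching and kernels", {
  expect_equal(averageImmunity(c(A = 5), c(A = 3), e = 0.7), 0.7)
  expect_equal(averageImmunity(c(A = 5), c(B = 3)), 0)
  expect_equal(averageImmunity(c(A = 2, B = 1), c(A = 1, C = 3)), 1 / 6)
  expect_error(averageImmunity(c(A = 0), c(A = 1)), "empty")
  ## step kernel: everything within theta counts as matched
  b <- c("000" = 2); v <- c("001" = 3, "011" = 1)
  expect_equal(averageImmunity(b, v, e = 0.95, crossReactivity("step", 1)),
               0.95 * 3 / 4)
  expect_equal(averageImmunity(b, v, e = 0.95, crossReactivity("step", 2)),
               0.95)
  ## exponential kernel interpolates
  ei <- averageImmunity(b, v, e = 1, crossReactivity("exponential", 2))
  expect_equal(ei, (3 * exp(-1/2) + exp(-1)) / 4, tolerance = 1e-12)
})

test_that("average immunity equals e times the Morisita-style overlap", {
  set.seed(5)
  for (i in 1:10) {
    types <- letters[1:8]
    b <- setNames(rpois(8, 20) + 1, types)[sample(8, 5)]
    v <- setNames(rpois(8, 30) + 1, types)[sample(8, 6)]
    common <- intersect(names(b), names(v))
    overlap <- sum(b[common] * v[common]) / (sum(b) * sum(v))
    e <- runif(1)
    expect_equal(averageImmunity(b, v, e = e), e * overlap)
  }
})

test_that("marginal immunity collapses one side to a focal clone", {
  v <- c("000" = 10, "001" = 30)
  expect_equal(marginalImmunity("000", v, e = 0.95), 0.95 * 10 / 40)
  expect_equal(marginalImmunity("110", v, e = 0.95), 0)
  ## a clone matching the entire population
  expect_equal(marginalImmunity("A", c(A = 100), e = 0.95), 0.95)
  ## step kernel theta=1: one mutation away still fully immune
  expect_equal(marginalImmunity("100", v, e = 0.95,
                                crossReactivity("step", 1)), 0.95 * 10 / 40)
})

test_that("time-shift immunity: zero delay equals the unshifted average", {
  times <- 0:4
  b <- abundanceSeries(times, c("a", "b"),
                       rbind(c(4, 3, 2, 1, 2), c(1, 2, 3, 4, 3)),
                       "bacteria", "days")
  v <- abundanceSeries(times, c("a", "c"),
                       rbind(c(2, 2, 4, 4, 2), c(1, 3, 1, 3, 1)),
                       "phage", "days")
  sc <- timeShiftImmunity(b, v)
  tab <- shiftCurveTable(sc)
  manual <- mean(vapply(1:5, function(k)
    averageImmunity(setNames(b@counts[, k], b@types),
                    setNames(v@counts[, k], v@types)), numeric(1)))
  expect_equal(tab$mean[tab$delay == 0], manual, tolerance = 1e-12)
  expect_equal(tab$n[tab$delay == 0], 5)
  ## stationary composition: flat curve
  bs <- abundanceSeries(times, "a", matrix(2, 1, 5), "bacteria", "days")
  vs <- abundanceSeries(times, c("a", "b"),
                        rbind(rep(1, 5), rep(3, 5)), "phage", "days")
  fc <- shiftCurveTable(timeShiftImmunity(bs, vs))
  expect_true(all(abs(fc$mean - fc$mean[1]) < 1e-12))
  ## multiplier scales the curve
  m2 <- shiftCurveTable(timeShiftImmunity(b, v, multiplier = 3))
  expect_equal(m2$mean, tab$mean * 3)
})

test_that("turnover counts surviving types", {
  x <- abundanceSeries(0:1, c("a", "b", "c", "d"),
                       rbind(c(1, 1), c(1, 0), c(1, 1), c(0, 1)),
                       "bacteria", "days")
  tv <- turnover(x)
  expect_equal(tv$mean[tv$delay == 0], 1)
  expect_equal(tv$mean[tv$delay == 1], 2 / 3)
  ## strictly nested loss: non-increasing curve
  y <- abundanceSeries(0:3, letters[1:4],
                       rbind(c(1, 1, 1, 1), c(1, 1, 1, 0),
                             c(1, 1, 0, 0), c(1, 0, 0, 0)),
                       "bacteria", "days")
  ty <- turnover(y)
  expect_true(all(diff(ty$mean) <= 1e-12))
})

test_that("large-clone weighting by survival probability", {
  expect_equal(classifyLargeClones(c(10, 100), 0, 1e4)$estimatedCount, 0)
  w <- classifyLargeClones(1000, 2.09e-3, 1e4)
  expect_equal(w$fractionLarge, 0.8766, tolerance = 1e-3)
  ## sizes above the cutoff count fully
  expect_equal(classifyLargeClones(c(1e9, 2e9), 1e-9, 1e4)$estimatedCount,
               2, tolerance = 1e-6)
})

test_that("centre of mass, distance, speed and spread", {
  ## 20 phages at [0,1] and 10 at [1,1]: centre of mass (1/3, 1)
  s <- abundanceSeries(c(0, 10), c("01", "11"),
                       rbind(c(20, 20), c(10, 10)), "phage", "generations")
  sp <- speedAndSpread(s, ancestor = "00")
  expect_equal(sp$distance$distance, c(4 / 3, 4 / 3), tolerance = 1e-12)
  expect_equal(sp$maxDistance, 4 / 3)
  expect_equal(sp$speed, (4 / 3) / 10)
  ## monomorphic population has zero spread
  mono <- abundanceSeries(0:1, "0110", matrix(7, 1, 2), "phage",
                          "generations")
  expect_equal(speedAndSpread(mono)$spread$spread, c(0, 0))
  expect_lte(sp$maxDistance, 2)
  ## back-mutation balance point: at d = L/2 half the mutations go outward
  expect_equal(outwardMutationFraction(15, 30), 0.5)
  expect_equal(outwardMutationFraction(0, 30), 1)
})

test_that("single-linkage clans under the L1 metric", {
  one <- clusterClans(rep("0000", 3))
  expect_equal(one$nClans, 1)
  cl <- clusterClans(c("000", "001", "011", "110"))
  expect_equal(cl$nClans, 2)
  expect_equal(sort(table(cl$labels)), sort(c(3L, 1L)),
               ignore_attr = TRUE)
  ## chaining: a-b-c with d(a,b)=d(b,c)=1, d(a,c)=2 is one clan
  expect_equal(clusterClans(c("000", "001", "011"))$nClans, 1)
  ## order invariance and abundance independence
  perm <- clusterClans(c("110", "011", "000", "001"),
                       abundances = c(9, 1, 4, 2))
  expect_equal(perm$nClans, 2)
  expect_equal(sum(perm$clanAbundance), 16)
})

test_that("PCA trajectories are fitted on phage and shared with bacteria", {
  times <- 0:3
  ph <- abundanceSeries(times, c("a", "b"),
                        rbind(c(9, 6, 3, 1), c(1, 4, 7, 9)), "phage",
                        "days")
  ba <- abundanceSeries(times, c("a", "c"),
                        rbind(c(5, 5, 5, 5), c(1, 1, 1, 1)), "bacteria",
                        "days")
  tr <- pcaTrajectories(ph, ba)
  php <- tr[tr$population == "phage", ]
  expect_gte(var(php$PC1), var(php$PC2))
  ## two-type seesaw: variation confined to one axis
  expect_lt(max(abs(php$PC2)), 1e-10)
  ## constant composition projects to a single point
  cst <- abundanceSeries(times, c("a", "b"),
                         rbind(rep(3, 4), rep(1, 4)), "phage", "days")
  tc <- pcaTrajectories(cst, ba)
  pcc <- tc[tc$population == "phage", ]
  expect_lt(max(abs(pcc$PC1 - pcc$PC1[1])), 1e-10)
  expect_error(pcaTrajectories(abundanceSeries(0, "a",
    matrix(1, 1, 1), "phage", "days"), ba), "two time points")
})

test_that("Morisita-Horn similarity", {
  expect_equal(morisitaHorn(c(a = 2, b = 4), c(a = 1, b = 2)), 1)
  expect_equal(morisitaHorn(c(a = 2), c(b = 5)), 0)
  ## hand-evaluated case: 2*2 / ((5/9 + 10/16) * 12) = 24/85
  expect_equal(morisitaHorn(c(A = 2, B = 1), c(A = 1, C = 3)), 24 / 85,
               tolerance = 1e-12)
  expect_error(morisitaHorn(c(a = 0), c(a = 1)), "all-zero")
})

test_that("Morisita-Horn matches the vegan implementation", {
  skip_if_not_installed("vegan")
  set.seed(9)
  for (i in 1:5) {
    x <- setNames(rpois(6, 10) + 1, letters[1:6])
    y <- setNames(rpois(6, 10) + 1, letters[1:6])
    d <- vegan::vegdist(rbind(x, y), method = "horn")
    expect_equal(morisitaHorn(x, y), 1 - as.numeric(d), tolerance = 1e-10)
  }
})

test_that("signed-rank asymmetry test", {
  expect_error(shiftAsymmetryTest(1:4, 1:4), "at least 6")
  deg <- shiftAsymmetryTest(rep(1, 8), rep(1, 8))
  expect_true(deg$degenerate)
  ## all shifted strictly below zero-delay: minimal one-sided p for n=10
  set.seed(2)
  z <- runif(10, 0.5, 1)
  res <- shiftAsymmetryTest(z, z * 0.8)
  expect_equal(res$p.value, 2^-10, tolerance = 1e-12)
  ## symmetric noise keeps p roughly uniform
  set.seed(3)
  ps <- replicate(200, {
    z <- runif(8); shiftAsymmetryTest(z, z + rnorm(8, 0, 0.1))$p.value
  })
  expect_gt(mean(ps < 0.5), 0.3)
  expect_lt(mean(ps < 0.05), 0.15)
})
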