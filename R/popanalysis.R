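## Population-level statistics on clone-resolved abundance data.

## pairwise immunity weight in [0,1]: 1 - pV(i,j)/pV, as a function of
## distance; the naive success probability cancels throughout
.immunityWeight <- function(d, e, xr) {
  mode <- xr@mode; theta <- xr@theta
  if (theta == 0) mode <- "none"
  switch(mode,
    none = e * (d == 0),
    exponential = e * exp(-d / theta),
    step = e * (d <= theta))
}

#' Average immunity between two populations
#'
#' The abundance-weighted mean pairwise immunity,
#' \deqn{1 - \frac{\sum_{ij} n_{Bi} n_{Vj}\, p_V(i,j)}{p_V \sum_{ij}
#' n_{Bi} n_{Vj}},}
#' the key population summary ("effective e"). With the all-or-nothing
#' kernel this is \eqn{e \sum_i n_{Bi} n_{Vi} / (N_B N_V)}: labels are
#' matched exactly (delta-matching) and no sequence interpretation is
#' needed. Cross-reactive kernels require labels that parse as equal-width
#' 0/1 strings.
#'
#' @param bacteria,phage named count vectors (type -> count).
#' @param e spacer effectiveness (1 for pure overlap).
#' @param xr a \linkS4class{CrossReactivity} kernel.
#' @return immunity in [0, 1].
#' @examples
#' averageImmunity(c(A = 2, B = 1), c(A = 1, C = 3))  # 1/6
#' @export
averageImmunity <- function(bacteria, phage, e = 1,
                            xr = crossReactivity("none")) {
  NB <- sum(bacteria); NV <- sum(phage)
  if (NB <= 0 || NV <= 0)
    stop("average immunity is undefined for an empty population")
  if (xr@mode == "none" || xr@theta == 0) {
    common <- intersect(names(bacteria), names(phage))
    if (!length(common)) return(0)
    return(e * sum(bacteria[common] * phage[common]) / (NB * NV))
  }
  bSeq <- stringToSeq(names(bacteria))
  pSeq <- stringToSeq(names(phage))
  d <- outer(bSeq, pSeq, hammingDistance)
  w <- .immunityWeight(d, e, xr)
  sum(outer(as.numeric(bacteria), as.numeric(phage)) * w) / (NB * NV)
}

#' Marginal immunity of a single clone
#'
#' The average-immunity formula with one side collapsed to a single focal
#' clone: for a focal bacterial clone, its mean immunity against the whole
#' phage population; for a focal phage clone, the population's mean
#' immunity against it.
#'
#' @param focal type label of the focal clone.
#' @param other named count vector of the opposing population.
#' @inheritParams averageImmunity
#' @return immunity in [0, 1].
#' @export
marginalImmunity <- function(focal, other, e = 1,
                             xr = crossReactivity("none")) {
  N <- sum(other)
  if (N <= 0) stop("marginal immunity is undefined against an empty population")
  if (xr@mode == "none" || xr@theta == 0) {
    hit <- other[names(other) == focal]
    return(e * sum(hit) / N)
  }
  d <- hammingDistance(stringToSeq(rep(focal, length(other))),
                       stringToSeq(names(other)))
  sum(as.numeric(other) * .immunityWeight(d, e, xr)) / N
}

#' Time-shifted average immunity
#'
#' Computes the overlap between bacterial spacers at time \eqn{t} and
#' phage protospacers at time \eqn{t+\Delta}, averaged over all valid
#' \eqn{t}, for every signed delay on a common regular grid (both series
#' are linearly interpolated to the minimum sampling interval). A negative
#' peak delay means bacteria are more immune to phages of the past. When
#' real phages carry many protospacers the raw statistic is multiplied by
#' the average protospacer count per phage (a user-supplied scalar, e.g.
#' 696 or 1956 for the published datasets); products above 1 are reported
#' as-is and only noted.
#'
#' @param bacteria,phage \linkS4class{AbundanceSeries} with overlapping
#'   time ranges (after trimming).
#' @param multiplier protospacers-per-phage scalar.
#' @param trimHead,trimTail points dropped from each series before
#'   interpolation (the published recipe drops the first 1 and last 2).
#' @param interval grid spacing; default the minimum sampling interval of
#'   the two series.
#' @inheritParams averageImmunity
#' @return a \linkS4class{ShiftCurve}.
#' @export
timeShiftImmunity <- function(bacteria, phage, multiplier = 1,
                              trimHead = 0L, trimTail = 0L,
                              interval = NULL, e = 1,
                              xr = crossReactivity("none")) {
  stopifnot(bacteria@population == "bacteria", phage@population == "phage",
            bacteria@units == phage@units)
  if (trimHead > 0 || trimTail > 0) {
    bacteria <- trimSeries(bacteria, trimHead, trimTail)
    phage <- trimSeries(phage, trimHead, trimTail)
  }
  if (is.null(interval))
    interval <- min(min(diff(bacteria@times)), min(diff(phage@times)))
  lo <- max(bacteria@times[1], phage@times[1])
  hi <- min(max(bacteria@times), max(phage@times))
  if (hi <= lo) stop("series do not overlap in time")
  grid <- seq(lo, hi, by = interval)
  regrid <- function(x) {
    cnt <- t(apply(x@counts, 1, function(row)
      stats::approx(x@times, row, xout = grid, rule = 1)$y))
    if (length(grid) == 1L) cnt <- matrix(cnt, ncol = 1)
    cnt
  }
  bC <- regrid(bacteria); pC <- regrid(phage)
  n <- length(grid)
  val <- function(tb, tp) {
    b <- bC[, tb]; names(b) <- bacteria@types
    p <- pC[, tp]; names(p) <- phage@types
    b <- b[!is.na(b) & b > 0]; p <- p[!is.na(p) & p > 0]
    if (!sum(b) || !sum(p)) return(NA_real_)
    averageImmunity(b, p, e, xr)
  }
  delays <- (-(n - 1)):(n - 1)
  meanV <- sdV <- nV <- numeric(length(delays))
  for (k in seq_along(delays)) {
    dk <- delays[k]
    tb <- seq(max(1, 1 - dk), min(n, n - dk))
    vs <- vapply(tb, function(t) val(t, t + dk), numeric(1))
    vs <- vs[!is.na(vs)]
    nV[k] <- length(vs)
    meanV[k] <- if (length(vs)) mean(vs) * multiplier else NA_real_
    sdV[k] <- if (length(vs) > 1) stats::sd(vs) * multiplier else NA_real_
  }
  keep <- nV > 0
  if (multiplier != 1 && any(meanV[keep] > 1))
    message("note: some multiplied immunity values exceed 1")
  new("ShiftCurve", delay = delays[keep] * interval, mean = meanV[keep],
      sd = sdV[keep], n = nV[keep], multiplier = multiplier,
      units = bacteria@units)
}

setMethod("show", "ShiftCurve", function(object) {
  pk <- object@delay[which.max(object@mean)]
  cat(sprintf(
    "ShiftCurve: %d delays [%g..%g %s], peak %.4g at delay %g (multiplier %g)\n",
    length(object@delay), min(object@delay), max(object@delay),
    object@units, max(object@mean), pk, object@multiplier))
})

#' @describeIn timeShiftImmunity the curve as a data.frame
#'   (\code{delay}, \code{mean}, \code{sd}, \code{n}).
#' @param curve a \linkS4class{ShiftCurve}.
#' @export
shiftCurveTable <- function(curve) {
  data.frame(delay = curve@delay, mean = curve@mean, sd = curve@sd,
             n = curve@n)
}

#' Clone-type turnover
#'
#' Fraction of the clone types present at time \eqn{t} that are still
#' present at \eqn{t+\Delta}, averaged over \eqn{t} on the interpolated
#' grid. Presence means count > 0; time points with no types are excluded
#' from the average. Always equals 1 at zero delay.
#'
#' @param series an \linkS4class{AbundanceSeries}.
#' @param delays delays to evaluate (grid units); default every multiple
#'   of the grid interval.
#' @param interval interpolation interval; default the minimum sampling
#'   interval.
#' @return data.frame with \code{delay}, \code{mean}, \code{sd}, \code{n}.
#' @export
turnover <- function(series, delays = NULL, interval = NULL) {
  x <- interpolateSeries(series, interval)
  n <- length(x@times)
  step <- if (n > 1) x@times[2] - x@times[1] else 1
  present <- x@counts > 0
  if (is.null(delays)) delays <- (0:(n - 1)) * step
  ks <- round(delays / step)
  out <- lapply(seq_along(ks), function(i) {
    k <- ks[i]
    ts <- seq_len(n - abs(k))
    if (k < 0) ts <- ts + abs(k)
    fr <- vapply(ts, function(t) {
      a <- present[, t]
      if (!any(a)) return(NA_real_)
      sum(a & present[, t + k]) / sum(a)
    }, numeric(1))
    fr <- fr[!is.na(fr)]
    if (!length(fr)) return(NULL)
    data.frame(delay = delays[i], mean = mean(fr),
               sd = if (length(fr) > 1) stats::sd(fr) else NA_real_,
               n = length(fr))
  })
  do.call(rbind, out)
}

#' Expected number of long-time surviving clones
#'
#' Weights each observed clone of size \eqn{n} by its probability of
#' escaping stochastic extinction, \eqn{1 - (1 - P_{est})^n} below the
#' deterministic size cutoff \code{Nest} and 1 above it, and sums the
#' weights.
#'
#' @param sizes observed clone sizes.
#' @param Pest per-individual establishment probability
#'   (\code{\link{establishmentProbability}}).
#' @param Nest size cutoff (deterministic mean clone size).
#' @return list with \code{fractionLarge} (mean weight) and
#'   \code{estimatedCount} (sum of weights).
#' @export
classifyLargeClones <- function(sizes, Pest, Nest) {
  stopifnot(Pest >= 0, Pest <= 1, all(sizes >= 0))
  w <- ifelse(sizes >= Nest, 1, 1 - (1 - Pest)^sizes)
  list(fractionLarge = mean(w), estimatedCount = sum(w))
}

#' Empirical establishment fraction and rate
#'
#' A phage mutant counts as established when its clone reached the
#' establishment threshold (its exact maximum size is tracked by the
#' engines). The fraction is over all mutants created; the rate counts
#' establishments of mutants born inside the steady-state window, per
#' bacterial generation.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param threshold establishment threshold (phage clone size); default
#'   the measured mean phage clone size over the steady-state snapshots.
#' @return list with \code{fraction}, \code{ratePerGeneration},
#'   \code{established}, \code{mutantsCreated}, \code{threshold}.
#' @export
empiricalEstablishment <- function(result, threshold = NULL) {
  cl <- result@clones
  mutants <- cl[cl$population == "phage" & !is.na(cl$parent), ]
  created <- result@schedule$mutantsCreated
  if (is.null(created) || created == 0)
    created <- nrow(mutants)
  if (created == 0) stop("no phage mutants were created in this run")
  if (is.null(threshold)) {
    pc <- unlist(lapply(result@snapshots, function(s) s@phageCount))
    if (!length(pc)) stop("no snapshots to derive a threshold from")
    threshold <- mean(pc)
  }
  est <- mutants$maxSize >= threshold
  ssStart <- result@schedule$steadyStateStart
  tEnd <- result@schedule$tEnd
  inWin <- mutants$birth >= ssStart
  gens <- (tEnd - ssStart) * result@params@gC0
  list(fraction = sum(est) / created,
       ratePerGeneration = sum(est & inWin) / gens,
       established = sum(est), mutantsCreated = created,
       threshold = threshold)
}

## bit matrix (types x L) from 0/1 type labels
.bitMatrix <- function(types) {
  L <- unique(nchar(types))
  if (length(L) != 1L) stop("types must be equal-width 0/1 strings")
  m <- t(vapply(strsplit(types, "", fixed = TRUE),
                function(x) as.integer(x), integer(L)))
  if (any(is.na(m)) || any(m > 1L)) stop("types must be 0/1 strings")
  m
}

#' Centre-of-mass speed and spread in sequence space
#'
#' The population's centre of mass is the abundance-weighted per-position
#' mean of its sequences (a point in \eqn{[0,1]^L}); distances are L1.
#' Speed uses the long-interval convention: the maximum centre-of-mass
#' distance from the ancestor reached over the series, divided by the
#' elapsed time. Spread is the abundance-weighted mean L1 distance of the
#' population from its own centre of mass.
#'
#' @param series an \linkS4class{AbundanceSeries} whose types are 0/1
#'   strings.
#' @param ancestor ancestor sequence (0/1 string); defaults to all zeros.
#' @return list with \code{distance} (data.frame time, distance),
#'   \code{spread} (data.frame time, spread), \code{maxDistance} and
#'   \code{speed} (distance per time unit of the series).
#' @export
speedAndSpread <- function(series, ancestor = NULL) {
  bits <- .bitMatrix(series@types)
  L <- ncol(bits)
  if (is.null(ancestor)) ancestor <- paste(rep("0", L), collapse = "")
  aBits <- as.integer(strsplit(ancestor, "", fixed = TRUE)[[1]])
  stopifnot(length(aBits) == L)
  nT <- length(series@times)
  dist <- spread <- rep(NA_real_, nT)
  for (k in seq_len(nT)) {
    w <- series@counts[, k]
    W <- sum(w)
    if (W <= 0) next
    com <- colSums(bits * w) / W
    dist[k] <- sum(abs(com - aBits))
    spread[k] <- sum(w * rowSums(abs(sweep(bits, 2, com)))) / W
  }
  ok <- !is.na(dist)
  if (!any(ok)) stop("empty population at every time point")
  elapsed <- max(series@times[ok]) - min(series@times[ok])
  maxD <- max(dist[ok])
  list(distance = data.frame(time = series@times, distance = dist),
       spread = data.frame(time = series@times, spread = spread),
       maxDistance = maxD,
       speed = if (elapsed > 0) maxD / elapsed else NA_real_)
}

#' Fraction of mutations that move away from the ancestor
#'
#' At distance \eqn{d} from the ancestor, \eqn{(L-d)/L} of the possible
#' single-bit mutations increase the distance; at \eqn{d = L/2} outward
#' and backward mutations balance, which caps the centre-of-mass distance
#' a neutrally drifting population maintains from its ancestor.
#'
#' @param d distance(s) from the ancestor.
#' @param L sequence length.
#' @return fraction in [0, 1].
#' @export
outwardMutationFraction <- function(d, L = 30L) {
  stopifnot(all(d >= 0), all(d <= L))
  (L - d) / L
}

#' Single-linkage clans of clone sequences
#'
#' Groups sequences into clans by single-linkage agglomerative clustering
#' under the L1 (mutational) distance, cutting at \code{cut}: clans are
#' the connected components of the graph with edges strictly below
#' \code{cut} (the default 2 links only sequences one mutation apart,
#' chained transitively). Abundances do not affect the partition, only the
#' reported clan abundances.
#'
#' @param types sequences as 0/1 strings (or integer codes with \code{L}).
#' @param abundances optional clone sizes (defaults to 1 each).
#' @param cut distance threshold (default 2).
#' @param L sequence length when \code{types} are integer codes.
#' @return list with \code{labels} (clan index per type), \code{nClans},
#'   \code{meanClanSize} (types per clan), \code{clanAbundance}.
#' @export
clusterClans <- function(types, abundances = NULL, cut = 2, L = 30L) {
  seqs <- if (is.character(types)) stringToSeq(types) else as.integer(types)
  n <- length(seqs)
  if (is.null(abundances)) abundances <- rep(1, n)
  if (n == 1L)
    return(list(labels = 1L, nClans = 1L, meanClanSize = 1,
                clanAbundance = sum(abundances)))
  d <- outer(seqs, seqs, hammingDistance)
  tree <- stats::hclust(stats::as.dist(d), method = "single")
  labels <- stats::cutree(tree, h = cut - sqrt(.Machine$double.eps))
  nClans <- max(labels)
  list(labels = unname(labels), nClans = nClans,
       meanClanSize = n / nClans,
       clanAbundance = as.numeric(tapply(abundances, labels, sum)))
}

#' PCA trajectories of both populations in phage composition space
#'
#' Clone abundances are normalized at each time point; the principal axes
#' are fitted on the phage time series alone, and both populations are
#' projected into the first two components. The shared type universe is
#' the union of types, zero-filled.
#'
#' @param phage,bacteria \linkS4class{AbundanceSeries}.
#' @return data.frame with \code{time}, \code{population}, \code{PC1},
#'   \code{PC2}.
#' @export
pcaTrajectories <- function(phage, bacteria) {
  if (length(phage@times) < 2L)
    stop("need at least two time points")
  types <- union(phage@types, bacteria@types)
  fill <- function(x) {
    m <- matrix(0, length(types), length(x@times))
    m[match(x@types, types), ] <- x@counts
    tot <- colSums(m)
    tot[tot == 0] <- 1
    t(sweep(m, 2, tot, "/"))          # times x types, relative
  }
  P <- fill(phage); Bm <- fill(bacteria)
  pc <- stats::prcomp(P, center = TRUE, scale. = FALSE, rank. = 2)
  proj <- function(M) {
    s <- sweep(M, 2, pc$center) %*% pc$rotation[, 1:2, drop = FALSE]
    if (ncol(s) < 2) s <- cbind(s, 0)
    s
  }
  sp <- proj(P); sb <- proj(Bm)
  rbind(
    data.frame(time = phage@times, population = "phage",
               PC1 = sp[, 1], PC2 = sp[, 2]),
    data.frame(time = bacteria@times, population = "bacteria",
               PC1 = sb[, 1], PC2 = sb[, 2]))
}

#' Morisita-Horn similarity
#'
#' \deqn{\Psi = \frac{2\sum_i x_i y_i}{(\sum_i x_i^2/X^2 +
#' \sum_i y_i^2/Y^2)\, X Y}} with \eqn{X=\sum x_i}, \eqn{Y=\sum y_i};
#' 1 for identical relative abundances, 0 for disjoint supports. Related
#' to average immunity computed from the same abundance tables.
#'
#' @param x,y named count vectors.
#' @return similarity in [0, 1].
#' @export
morisitaHorn <- function(x, y) {
  X <- sum(x); Y <- sum(y)
  if (X <= 0 || Y <= 0) stop("undefined for an all-zero vector")
  types <- union(names(x), names(y))
  xi <- ifelse(is.na(match(types, names(x))), 0, x[match(types, names(x))])
  yi <- ifelse(is.na(match(types, names(y))), 0, y[match(types, names(y))])
  2 * sum(xi * yi) / ((sum(xi^2) / X^2 + sum(yi^2) / Y^2) * X * Y)
}

#' Signed-rank test for time-shift asymmetry
#'
#' One-sided paired Wilcoxon signed-rank test of whether the statistic at
#' zero delay exceeds its value at a chosen delay (zero differences are
#' dropped, the standard convention; n is small in typical use, so the
#' count of informative pairs is returned).
#'
#' @param zero statistic values at zero delay, paired with \code{shifted}.
#' @param shifted values at the probed delay.
#' @param alternative passed to \code{wilcox.test}; the default
#'   \code{"greater"} tests zero > shifted.
#' @return list with \code{statistic}, \code{p.value}, \code{n}
#'   (informative pairs), \code{degenerate}.
#' @export
shiftAsymmetryTest <- function(zero, shifted, alternative = "greater") {
  stopifnot(length(zero) == length(shifted))
  if (length(zero) < 6L) stop("need at least 6 paired observations")
  d <- zero - shifted
  nInf <- sum(d != 0)
  if (nInf == 0)
    return(list(statistic = NA_real_, p.value = NA_real_, n = 0L,
                degenerate = TRUE))
  wt <- suppressWarnings(
    stats::wilcox.test(zero, shifted, paired = TRUE,
                       alternative = alternative))
  list(statistic = unname(wt$statistic), p.value = wt$p.value,
       n = nInf, degenerate = FALSE)
}
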