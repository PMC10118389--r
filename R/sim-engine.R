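## Stochastic engines for the chemostat reaction catalogue.
##
## Reactions (rates per minute): bacterial growth g*C per bacterium
## (consumes one nutrient); outflow F for every bacterium, phage and
## nutrient; nutrient inflow F*C0; spacer loss r per spacer-bearing
## bacterium; adsorption alpha per phage-bacterium pair. Every adsorption
## consumes the infecting phage. Against a naive bacterium the phage wins
## with probability pV (burst of B offspring, mutated per bit with
## probability mu); a surviving naive bacterium acquires the phage's
## protospacer as its spacer with probability eta. Against a spacer-bearing
## bacterium the kill probability is the pairwise kernel pV(i, j);
## spacer-bearing survivors never re-acquire.

#' Per-channel propensities of the reaction catalogue
#'
#' @param state a \linkS4class{PopulationState}.
#' @param params a \linkS4class{SimParams}.
#' @return list of propensities (min^-1): \code{growth0}, \code{growthI}
#'   (per bacterial clone), \code{outflowB0}, \code{outflowBi},
#'   \code{outflowVj}, \code{outflowC}, \code{inflowC}, \code{lossI},
#'   \code{adsorptionNaive} and \code{adsorptionSpacer} (per phage clone),
#'   and the aggregate \code{adsorptionTotal} = \eqn{\alpha n_B n_V}.
#' @export
channelRates <- function(state, params) {
  g <- growthRate(params); FF <- outflowRate(params)
  al <- adsorptionRate(params); r <- lossRate(params)
  nBs <- sum(state@bacteriaCount); nB <- state@nB0 + nBs
  nV <- sum(state@phageCount)
  list(growth0 = g * state@C * state@nB0,
       growthI = g * state@C * state@bacteriaCount,
       outflowB0 = FF * state@nB0,
       outflowBi = FF * state@bacteriaCount,
       outflowVj = FF * state@phageCount,
       outflowC = FF * state@C,
       inflowC = FF * params@C0,
       lossI = r * state@bacteriaCount,
       adsorptionNaive = al * state@nB0 * state@phageCount,
       adsorptionSpacer = al * nBs * state@phageCount,
       adsorptionTotal = al * nB * nV)
}

## --- internal mutable run state ------------------------------------------

.newRun <- function(params, init) {
  e <- new.env(parent = emptyenv())
  e$C <- init@C; e$nB0 <- init@nB0
  e$bSeq <- init@bacteriaSeq; e$bCnt <- init@bacteriaCount
  e$pSeq <- init@phageSeq; e$pCnt <- init@phageCount
  e$t <- init@time
  ## clone log grown in chunks
  e$logN <- 0L
  e$logCap <- 256L
  e$logPop <- character(256L); e$logSeq <- integer(256L)
  e$logParent <- rep(NA_integer_, 256L)
  e$logBirth <- numeric(256L); e$logDeath <- rep(NA_real_, 256L)
  e$logMax <- numeric(256L)
  ## open-record row index per live clone, aligned with bSeq/pSeq
  e$bRow <- integer(0); e$pRow <- integer(0)
  e$mutantsCreated <- 0L
  e$clamps <- 0L
  for (k in seq_along(e$pSeq))
    e$pRow[k] <- .openClone(e, "phage", e$pSeq[k], NA_integer_,
                            init@time, e$pCnt[k])
  for (k in seq_along(e$bSeq))
    e$bRow[k] <- .openClone(e, "bacteria", e$bSeq[k], NA_integer_,
                            init@time, e$bCnt[k])
  e
}

.openClone <- function(e, pop, seq, parent, t, size) {
  if (e$logN == e$logCap) {
    newCap <- e$logCap * 2L
    for (f in c("logPop", "logSeq", "logParent", "logBirth", "logDeath",
                "logMax"))
      length(e[[f]]) <- newCap
    e$logCap <- newCap
  }
  i <- e$logN + 1L
  e$logN <- i
  e$logPop[i] <- pop; e$logSeq[i] <- seq; e$logParent[i] <- parent
  e$logBirth[i] <- t; e$logDeath[i] <- NA_real_; e$logMax[i] <- size
  i
}

## drop clones whose count reached zero, closing their records
.reapClones <- function(e) {
  zb <- which(e$bCnt <= 0)
  if (length(zb)) {
    e$logDeath[e$bRow[zb]] <- e$t
    keep <- -zb
    e$bSeq <- e$bSeq[keep]; e$bCnt <- e$bCnt[keep]; e$bRow <- e$bRow[keep]
  }
  zp <- which(e$pCnt <= 0)
  if (length(zp)) {
    e$logDeath[e$pRow[zp]] <- e$t
    keep <- -zp
    e$pSeq <- e$pSeq[keep]; e$pCnt <- e$pCnt[keep]; e$pRow <- e$pRow[keep]
  }
}

## add k individuals of (possibly new) phage type `seq` descended from
## `parent`; vectorized over new mutant codes
.addPhage <- function(e, seqs, parent) {
  if (!length(seqs)) return(invisible())
  tab <- table(seqs)
  codes <- as.integer(names(tab)); n <- as.numeric(tab)
  hit <- match(codes, e$pSeq)
  old <- !is.na(hit)
  if (any(old)) e$pCnt[hit[old]] <- e$pCnt[hit[old]] + n[old]
  if (any(!old)) {
    for (k in which(!old)) {
      e$pSeq <- c(e$pSeq, codes[k]); e$pCnt <- c(e$pCnt, n[k])
      e$pRow <- c(e$pRow, .openClone(e, "phage", codes[k], parent,
                                     e$t, n[k]))
    }
  }
  invisible()
}

.addBacteria <- function(e, seq, k) {
  hit <- match(seq, e$bSeq)
  if (!is.na(hit)) {
    e$bCnt[hit] <- e$bCnt[hit] + k
  } else {
    e$bSeq <- c(e$bSeq, seq); e$bCnt <- c(e$bCnt, k)
    e$bRow <- c(e$bRow, .openClone(e, "bacteria", seq, NA_integer_,
                                   e$t, k))
  }
  invisible()
}

.updateMax <- function(e) {
  if (length(e$bRow))
    e$logMax[e$bRow] <- pmax(e$logMax[e$bRow], e$bCnt)
  if (length(e$pRow))
    e$logMax[e$pRow] <- pmax(e$logMax[e$pRow], e$pCnt)
}

.snapshotOf <- function(e) {
  .PopulationState(time = e$t, C = e$C, nB0 = e$nB0,
                   bacteriaSeq = e$bSeq, bacteriaCount = e$bCnt,
                   phageSeq = e$pSeq, phageCount = e$pCnt)
}

.totalsOf <- function(e, gC0) {
  c(t = e$t, tGen = e$t * gC0, C = e$C, nB0 = e$nB0, nBs = sum(e$bCnt),
    nV = sum(e$pCnt), mBacteria = length(e$bCnt), mPhage = length(e$pCnt))
}

## kill probability of phage clone j against each bacterial clone
.killProbs <- function(bSeq, pSeqJ, params) {
  if (!length(bSeq)) return(numeric(0))
  infectionSuccess(bSeq, pSeqJ, params@pV, params@e, params@xr)
}

## --- schedules -------------------------------------------------------------

.makeSchedule <- function(params, tEndGen, snapshots, totalsEvery) {
  gC0 <- params@gC0
  if (is.null(tEndGen)) tEndGen <- runLengthRule(params@C0)$generations
  tEnd <- tEndGen / gC0
  ssStart <- tEnd / 5
  snapTimes <- seq(ssStart, tEnd, length.out = snapshots)
  if (is.null(totalsEvery)) totalsEvery <- 10 / gC0
  list(tEnd = tEnd, tEndGen = tEndGen, steadyStateStart = ssStart,
       snapshotTimes = snapTimes, totalsEvery = totalsEvery)
}

.finishResult <- function(e, params, seed, engine, snaps, totals, schedule) {
  ## close all surviving clones with NA extinction
  .updateMax(e)
  n <- e$logN
  clones <- data.frame(
    population = e$logPop[seq_len(n)],
    seq = e$logSeq[seq_len(n)],
    parent = e$logParent[seq_len(n)],
    birth = e$logBirth[seq_len(n)],
    extinction = e$logDeath[seq_len(n)],
    maxSize = e$logMax[seq_len(n)],
    stringsAsFactors = FALSE)
  totals <- as.data.frame(do.call(rbind, totals))
  schedule$mutantsCreated <- e$mutantsCreated
  new("SimulationResult", params = params, seed = as.integer(seed),
      engine = engine, snapshots = snaps, totals = totals, clones = clones,
      schedule = schedule, clampEvents = e$clamps)
}

## --- tau-leaping ------------------------------------------------------------

#' Tau-leaping stochastic simulation
#'
#' Advances the full reaction catalogue in steps of length \eqn{\tau},
#' drawing per-channel event counts from Poisson (with binomial thinning
#' for infection outcomes). The default policy picks \eqn{\tau} each step so
#' that the expected number of consuming events per species stays below
#' \code{epsilon} times that species' count; if an update would drive a
#' count negative the step is halved and redrawn (up to
#' \code{maxHalvings}), after which remaining negatives are clamped to zero
#' and counted in \code{clampEvents}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param init initial \linkS4class{PopulationState}; default
#'   \code{\link{initialState}(params)}.
#' @param tEndGen run length in bacterial generations; default from
#'   \code{\link{runLengthRule}}.
#' @param seed integer seed.
#' @param epsilon leap-condition bound (fraction of a species consumed per
#'   step).
#' @param tauMax,tauMin bounds on the step (minutes).
#' @param snapshots number of full snapshots, evenly spaced over the
#'   steady-state window (final fifth-onward of the run).
#' @param totalsEvery cadence of the totals table (minutes); default every
#'   10 generations.
#' @param maxHalvings redraw attempts before clamping.
#' @param stopOnPhageExtinct end the run early once no phage remain.
#' @return a \linkS4class{SimulationResult}.
#' @export
tauLeapRun <- function(params, init = initialState(params), tEndGen = NULL,
                       seed = 1L, epsilon = 0.1, tauMax = NULL,
                       tauMin = 0.01, snapshots = 15L, totalsEvery = NULL,
                       maxHalvings = 10L, stopOnPhageExtinct = TRUE) {
  set.seed(seed)
  sch <- .makeSchedule(params, tEndGen, snapshots, totalsEvery)
  if (is.null(tauMax)) tauMax <- generationTime(params) / 4
  if (tauMin <= 0 || tauMax <= 0) stop("tau bounds must be positive")
  g <- growthRate(params); FF <- outflowRate(params)
  al <- adsorptionRate(params); r <- lossRate(params)
  pV <- params@pV; B <- params@B; eta <- params@eta
  mu <- params@mu; L <- params@L
  plainKernel <- params@xr@mode == "none" || params@xr@theta == 0

  e <- .newRun(params, init)
  snaps <- list(); totals <- list()
  nextSnap <- 1L; nextTot <- e$t

  while (e$t < sch$tEnd) {
    nBs <- sum(e$bCnt); nB <- e$nB0 + nBs; nV <- sum(e$pCnt)
    if (stopOnPhageExtinct && nV == 0) break
    ## expected consumption rate per species -> leap condition
    consC <- g * e$C * nB + FF * e$C
    cons0 <- FF * e$nB0 + al * e$nB0 * nV * (pV + (1 - pV) * eta)
    tau <- tauMax
    if (consC > 0) tau <- min(tau, epsilon * max(e$C, 1) / consC)
    if (cons0 > 0) tau <- min(tau, epsilon * max(e$nB0, 1) / cons0)
    if (length(e$bCnt)) {
      if (plainKernel) {
        match_j <- match(e$bSeq, e$pSeq)
        nVmatch <- ifelse(is.na(match_j), 0, e$pCnt[match_j])
        killRate <- al * (pV * (nV - nVmatch) + pV * (1 - params@e) * nVmatch)
      } else {
        killRate <- al * vapply(seq_along(e$bSeq), function(i)
          sum(.killProbs(e$bSeq[i], e$pSeq, params) * e$pCnt), numeric(1))
      }
      consB <- FF + r + killRate
      tau <- min(tau, epsilon * min(pmax(e$bCnt, 1) / consB))
    }
    if (nV > 0) {
      consV <- FF + al * nB
      tau <- min(tau, epsilon * min(pmax(e$pCnt, 1)) / consV)
    }
    tau <- max(tau, tauMin)
    tau <- min(tau, sch$tEnd - e$t)

    for (attempt in seq_len(maxHalvings + 1L)) {
      ## draws
      G0 <- stats::rpois(1L, g * e$C * e$nB0 * tau)
      Gi <- if (length(e$bCnt)) stats::rpois(length(e$bCnt),
                                             g * e$C * e$bCnt * tau) else integer(0)
      OC <- stats::rpois(1L, FF * e$C * tau)
      IC <- stats::rpois(1L, FF * params@C0 * tau)
      O0 <- stats::rpois(1L, FF * e$nB0 * tau)
      Ob <- if (length(e$bCnt)) stats::rpois(length(e$bCnt),
                                             FF * e$bCnt * tau) else integer(0)
      Ov <- if (length(e$pCnt)) stats::rpois(length(e$pCnt),
                                             FF * e$pCnt * tau) else integer(0)
      Li <- if (length(e$bCnt)) stats::rpois(length(e$bCnt),
                                             r * e$bCnt * tau) else integer(0)
      nP <- length(e$pCnt)
      A0 <- if (nP) stats::rpois(nP, al * e$nB0 * e$pCnt * tau) else integer(0)
      K0 <- if (nP) stats::rbinom(nP, A0, pV) else integer(0)
      Q  <- if (nP) stats::rbinom(nP, A0 - K0, eta) else integer(0)

      killsB <- numeric(length(e$bCnt))     # bacteria killed per clone
      KS <- integer(nP)                     # spacer-side kills per phage
      AS <- integer(nP)                     # spacer-side adsorptions
      if (nP && length(e$bCnt)) {
        if (plainKernel) {
          AS <- stats::rpois(nP, al * nBs * e$pCnt * tau)
          mi <- match(e$pSeq, e$bSeq)       # matching bacterial clone
          fracMatch <- ifelse(is.na(mi), 0, e$bCnt[pmax(mi, 1L)] / nBs)
          Amatch <- stats::rbinom(nP, AS, fracMatch)
          Kmatch <- stats::rbinom(nP, Amatch, pV * (1 - params@e))
          Kother <- stats::rbinom(nP, AS - Amatch, pV)
          KS <- Kmatch + Kother
          ok <- !is.na(mi) & Kmatch > 0
          if (any(ok)) {
            km <- tapply(Kmatch[ok], mi[ok], sum)
            killsB[as.integer(names(km))] <-
              killsB[as.integer(names(km))] + as.numeric(km)
          }
          totOther <- sum(Kother)
          if (totOther > 0) {
            ## unmatched kills land on clones in proportion to size
            w <- e$bCnt
            alloc <- stats::rmultinom(1L, totOther, w)[, 1]
            killsB <- killsB + alloc
          }
        } else {
          ## cross-reactive kernel: per-pair Poisson kills
          for (j in seq_len(nP)) {
            pk <- .killProbs(e$bSeq, e$pSeq[j], params)
            AS[j] <- stats::rpois(1L, al * nBs * e$pCnt[j] * tau)
            kj <- stats::rpois(length(pk),
                               al * e$bCnt * e$pCnt[j] * pk * tau)
            killsB <- killsB + kj
            KS[j] <- sum(kj)
          }
        }
      }
      Kj <- K0 + KS                          # bursts per phage type

      newC <- e$C + IC - OC - (G0 + sum(Gi))
      newB0 <- e$nB0 + G0 - O0 - sum(K0) - sum(Q) + sum(Li)
      newBi <- e$bCnt + Gi - Ob - Li - killsB
      newVj <- e$pCnt - Ov - A0 - AS + B * Kj

      bad <- (newC < 0) || (newB0 < 0) || any(newBi < 0) || any(newVj < 0)
      if (!bad || attempt > maxHalvings) {
        if (bad) {
          e$clamps <- e$clamps + sum(newC < 0) + sum(newB0 < 0) +
            sum(newBi < 0) + sum(newVj < 0)
          newC <- max(newC, 0); newB0 <- max(newB0, 0)
          newBi <- pmax(newBi, 0); newVj <- pmax(newVj, 0)
        }
        e$t <- e$t + tau
        e$C <- newC; e$nB0 <- newB0
        e$bCnt <- newBi; e$pCnt <- newVj
        ## mutant offspring leave the parental count
        if (mu > 0 && any(Kj > 0)) {
          for (j in which(Kj > 0)) {
            muts <- .drawMutants(e$pSeq[j], Kj[j] * B, mu, L)
            if (length(muts)) {
              e$pCnt[j] <- e$pCnt[j] - length(muts)
              e$mutantsCreated <- e$mutantsCreated + length(muts)
              .addPhage(e, muts, e$pSeq[j])
            }
          }
        }
        ## acquisitions create/extend bacterial clones
        if (any(Q > 0))
          for (j in which(Q > 0)) .addBacteria(e, e$pSeq[j], Q[j])
        break
      }
      tau <- tau / 2
    }

    .updateMax(e)
    .reapClones(e)
    if (e$t >= nextTot) {
      totals[[length(totals) + 1L]] <- .totalsOf(e, params@gC0)
      nextTot <- nextTot + sch$totalsEvery
    }
    while (nextSnap <= length(sch$snapshotTimes) &&
           e$t >= sch$snapshotTimes[nextSnap]) {
      snaps[[length(snaps) + 1L]] <- .snapshotOf(e)
      nextSnap <- nextSnap + 1L
    }
  }
  totals[[length(totals) + 1L]] <- .totalsOf(e, params@gC0)
  .finishResult(e, params, seed, "tau-leap", snaps, totals, sch)
}

## --- Gillespie --------------------------------------------------------------

#' Exact Gillespie simulation
#'
#' Statistically exact realization of the jump process defined by the
#' reaction catalogue. Tractable for small systems (guideline
#' \code{C0 <= 1e4}); used as the oracle against which the tau-leaping
#' engine is validated.
#'
#' @inheritParams tauLeapRun
#' @return a \linkS4class{SimulationResult}.
#' @export
gillespieRun <- function(params, init = initialState(params), tEndGen = NULL,
                         seed = 1L, snapshots = 15L, totalsEvery = NULL,
                         stopOnPhageExtinct = TRUE) {
  set.seed(seed)
  sch <- .makeSchedule(params, tEndGen, snapshots, totalsEvery)
  g <- growthRate(params); FF <- outflowRate(params)
  al <- adsorptionRate(params); r <- lossRate(params)
  pV <- params@pV; B <- params@B; eta <- params@eta
  mu <- params@mu; L <- params@L

  e <- .newRun(params, init)
  snaps <- list(); totals <- list()
  nextSnap <- 1L; nextTot <- e$t

  repeat {
    nBs <- sum(e$bCnt); nB <- e$nB0 + nBs; nV <- sum(e$pCnt)
    if (stopOnPhageExtinct && nV == 0) break
    aGrow <- g * e$C * nB
    aFlow <- FF * (nB + nV + e$C + params@C0)
    aLoss <- r * nBs
    aAds <- al * nB * nV
    aTot <- aGrow + aFlow + aLoss + aAds
    if (aTot <= 0) break
    e$t <- e$t + stats::rexp(1L, aTot)
    if (e$t > sch$tEnd) { e$t <- sch$tEnd; break }

    u <- stats::runif(1L) * aTot
    if (u < aGrow) {
      ## division consumes a nutrient
      if (stats::runif(1L) * nB < e$nB0) e$nB0 <- e$nB0 + 1
      else {
        i <- sample.int(length(e$bCnt), 1L, prob = e$bCnt)
        e$bCnt[i] <- e$bCnt[i] + 1
      }
      e$C <- e$C - 1
    } else if (u < aGrow + aFlow) {
      v <- stats::runif(1L) * (nB + nV + e$C + params@C0)
      if (v < params@C0) e$C <- e$C + 1        # inflow
      else if (v < params@C0 + e$C) e$C <- e$C - 1
      else if (v < params@C0 + e$C + nB) {
        if (stats::runif(1L) * nB < e$nB0) e$nB0 <- e$nB0 - 1
        else {
          i <- sample.int(length(e$bCnt), 1L, prob = e$bCnt)
          e$bCnt[i] <- e$bCnt[i] - 1
        }
      } else {
        j <- sample.int(length(e$pCnt), 1L, prob = e$pCnt)
        e$pCnt[j] <- e$pCnt[j] - 1
      }
    } else if (u < aGrow + aFlow + aLoss) {
      i <- sample.int(length(e$bCnt), 1L, prob = e$bCnt)
      e$bCnt[i] <- e$bCnt[i] - 1
      e$nB0 <- e$nB0 + 1
    } else {
      ## adsorption: phage j meets a uniformly chosen bacterium
      j <- sample.int(length(e$pCnt), 1L, prob = e$pCnt)
      e$pCnt[j] <- e$pCnt[j] - 1               # phage always consumed
      naive <- stats::runif(1L) * nB < e$nB0
      if (naive) {
        if (stats::runif(1L) < pV) {
          e$nB0 <- e$nB0 - 1
          muts <- .drawMutants(e$pSeq[j], B, mu, L)
          e$pCnt[j] <- e$pCnt[j] + B - length(muts)
          if (length(muts)) {
            e$mutantsCreated <- e$mutantsCreated + length(muts)
            .addPhage(e, muts, e$pSeq[j])
          }
        } else if (stats::runif(1L) < eta) {
          e$nB0 <- e$nB0 - 1
          .addBacteria(e, e$pSeq[j], 1)
        }
      } else {
        i <- sample.int(length(e$bCnt), 1L, prob = e$bCnt)
        ps <- .killProbs(e$bSeq[i], e$pSeq[j], params)
        if (stats::runif(1L) < ps) {
          e$bCnt[i] <- e$bCnt[i] - 1
          muts <- .drawMutants(e$pSeq[j], B, mu, L)
          e$pCnt[j] <- e$pCnt[j] + B - length(muts)
          if (length(muts)) {
            e$mutantsCreated <- e$mutantsCreated + length(muts)
            .addPhage(e, muts, e$pSeq[j])
          }
        }
      }
    }

    .updateMax(e)
    .reapClones(e)
    if (e$t >= nextTot) {
      totals[[length(totals) + 1L]] <- .totalsOf(e, params@gC0)
      nextTot <- nextTot + sch$totalsEvery
    }
    while (nextSnap <= length(sch$snapshotTimes) &&
           e$t >= sch$snapshotTimes[nextSnap]) {
      snaps[[length(snaps) + 1L]] <- .snapshotOf(e)
      nextSnap <- nextSnap + 1L
    }
  }
  totals[[length(totals) + 1L]] <- .totalsOf(e, params@gC0)
  .finishResult(e, params, seed, "gillespie", snaps, totals, sch)
}

setMethod("show", "SimulationResult", function(object) {
  tot <- object@totals
  last <- tot[nrow(tot), ]
  cat(sprintf(
    "SimulationResult (%s, seed %d): %d snapshots, %.0f generations\n",
    object@engine, object@seed, length(object@snapshots), last$tGen))
  cat(sprintf(
    " final: C=%.0f nB0=%.0f nBs=%.0f nV=%.0f m=%d; %d clone records, %d mutants created\n",
    last$C, last$nB0, last$nBs, last$nV, last$mBacteria,
    nrow(object@clones), object@schedule$mutantsCreated))
  if (object@clampEvents > 0)
    cat(sprintf(" tau-leap clamps: %d\n", object@clampEvents))
})
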