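#' Construct a parameter set
#'
#' Defaults are the model's representative values for *S. thermophilus* in
#' lab conditions: doubling time \code{1/gC0} = 41.7 min, burst size 170,
#' naive infection success 0.02, normalized outflow 0.3, per-generation
#' spacer loss 0.04, adsorption rate \eqn{2\times 10^{-2}/C_0} per minute.
#'
#' @param C0 inflow nutrient concentration (cell-density units).
#' @param gC0 maximal growth rate (min^-1).
#' @param f normalized outflow in (0, 1).
#' @param alphaC0 adsorption rate times C0 (min^-1).
#' @param B burst size.
#' @param pV naive infection success probability.
#' @param e spacer effectiveness.
#' @param R per-generation spacer-loss probability.
#' @param eta acquisition probability.
#' @param mu per-base per-replication mutation probability.
#' @param L protospacer length in bits (<= 30).
#' @param xr a \linkS4class{CrossReactivity} kernel.
#' @return a \linkS4class{SimParams} object.
#' @examples
#' p <- simParams(C0 = 1e4, e = 0.95, eta = 1e-3, mu = 1e-5)
#' phageThreshold(p)
#' @export
simParams <- function(C0 = 1e4, gC0 = 2.4e-2, f = 0.3, alphaC0 = 2e-2,
                      B = 170, pV = 0.02, e = 0.95, R = 0.04, eta = 1e-3,
                      mu = 1e-5, L = 30L, xr = crossReactivity("none")) {
  new("SimParams", C0 = C0, gC0 = gC0, f = f, alphaC0 = alphaC0, B = B,
      pV = pV, e = e, R = R, eta = eta, mu = mu, L = as.integer(L), xr = xr)
}

#' @describeIn simParams per-nutrient growth rate \eqn{g = gC_0/C_0}
#'   (min^-1 per nutrient).
#' @param params a \linkS4class{SimParams} object.
#' @export
growthRate <- function(params) params@gC0 / params@C0

#' @describeIn simParams chemostat flow rate \eqn{F = f\,gC_0} (min^-1).
#' @export
outflowRate <- function(params) params@f * params@gC0

#' @describeIn simParams adsorption rate \eqn{\alpha} (min^-1 per phage per
#'   bacterium).
#' @export
adsorptionRate <- function(params) params@alphaC0 / params@C0

#' @describeIn simParams spacer loss rate \eqn{r = R\,gC_0} (min^-1).
#' @export
lossRate <- function(params) params@R * params@gC0

#' @describeIn simParams minutes per bacterial generation, \code{1/gC0}.
#' @export
generationTime <- function(params) 1 / params@gC0

setMethod("show", "SimParams", function(object) {
  cat("SimParams:",
      sprintf("C0=%g, gC0=%g/min (doubling %.1f min), f=%g",
              object@C0, object@gC0, 1 / object@gC0, object@f), "\n",
      sprintf(" alpha=%g/min, B=%g, pV=%g, e=%g, R=%g, eta=%g, mu=%g, L=%d",
              adsorptionRate(object), object@B, object@pV, object@e,
              object@R, object@eta, object@mu, object@L), "\n",
      sprintf(" cross-reactivity: %s (theta=%g)", object@xr@mode,
              object@xr@theta), "\n")
})

#' Simulation length and steady-state window for a given system size
#'
#' The run length in bacterial generations is
#' \code{max(10000, round-to-nearest-1000(10000 * (log10(C0) - 3)))}; larger
#' systems interact less often per capita (smaller \eqn{\alpha}) and take
#' longer to equilibrate. The steady-state analysis window starts at one
#' fifth of the run.
#'
#' @param C0 inflow nutrient concentration.
#' @return list with \code{generations} and \code{steadyStateStart}
#'   (generations).
#' @examples
#' runLengthRule(30000)  # 15000 generations, window from 3000
#' @export
runLengthRule <- function(C0) {
  stopifnot(C0 > 0)
  raw <- 10000 * (log10(C0) - 3)
  rounded <- sign(raw) * floor(abs(raw) / 1000 + 0.5) * 1000
  gens <- max(10000, rounded)
  list(generations = gens, steadyStateStart = gens / 5)
}

#' Default initial condition for a simulation
#'
#' Nutrients start at \code{C0}, naive bacteria at the phage-free fixed
#' point \code{C0(1-f)} (rounded), and the phage population is introduced as
#' \code{mInit} clonal types (ancestor sequence 0 and, for
#' \code{mInit > 1}, its single-bit neighbours) totalling \code{nV0}
#' individuals.
#'
#' @param params a \linkS4class{SimParams} object.
#' @param nV0 total initial phage count.
#' @param mInit number of initial phage clones.
#' @return a \linkS4class{PopulationState} at time 0.
#' @export
initialState <- function(params, nV0 = round(params@C0 / 10), mInit = 1L) {
  mInit <- as.integer(mInit)
  stopifnot(mInit >= 1L, mInit <= params@L + 1L, nV0 >= mInit)
  seqs <- if (mInit == 1L) 0L else
    c(0L, bitwShiftL(1L, 0:(mInit - 2L)))
  counts <- rep(nV0 %/% mInit, mInit)
  counts[1] <- counts[1] + nV0 %% mInit
  .PopulationState(time = 0, C = params@C0,
                   nB0 = round(params@C0 * (1 - params@f)),
                   bacteriaSeq = integer(0), bacteriaCount = numeric(0),
                   phageSeq = seqs, phageCount = as.numeric(counts))
}

#' Totals of a population state
#'
#' @param state a \linkS4class{PopulationState}.
#' @return named numeric vector with \code{C}, \code{nB0}, \code{nBs},
#'   \code{nB}, \code{nV}, \code{mBacteria}, \code{mPhage}.
#' @export
stateTotals <- function(state) {
  c(C = state@C, nB0 = state@nB0, nBs = sum(state@bacteriaCount),
    nB = state@nB0 + sum(state@bacteriaCount), nV = sum(state@phageCount),
    mBacteria = sum(state@bacteriaCount > 0),
    mPhage = sum(state@phageCount > 0))
}

setMethod("show", "PopulationState", function(object) {
  tot <- stateTotals(object)
  cat(sprintf(
    "PopulationState t=%.1f min: C=%g nB0=%g nBs=%g (%d clones) nV=%g (%d clones)\n",
    object@time, tot["C"], tot["nB0"], tot["nBs"], tot["mBacteria"],
    tot["nV"], tot["mPhage"]))
})
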