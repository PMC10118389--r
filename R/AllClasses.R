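#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Cross-reactivity kernel specification
#'
#' Describes how spacer--protospacer immunity degrades with mutational
#' distance. With \code{mode = "none"} immunity is all-or-nothing: a spacer
#' protects only against an exactly matching protospacer. With
#' \code{mode = "exponential"} effectiveness decays as
#' \eqn{e\,\exp(-d/\theta)} with distance \eqn{d}; with \code{mode = "step"}
#' a spacer is fully effective against all protospacers within distance
#' \eqn{\theta}. \code{theta = 0} reproduces the all-or-nothing kernel in
#' every mode.
#'
#' @slot mode one of \code{"none"}, \code{"exponential"}, \code{"step"}.
#' @slot theta non-negative radius scale (mutations).
#' @export
setClass("CrossReactivity",
  representation(mode = "character", theta = "numeric"),
  prototype(mode = "none", theta = 0))

setValidity("CrossReactivity", function(object) {
  if (!object@mode %in% c("none", "exponential", "step"))
    return("mode must be 'none', 'exponential' or 'step'")
  if (length(object@theta) != 1L || is.na(object@theta) || object@theta < 0)
    return("theta must be a single non-negative number")
  TRUE
})

#' Construct a cross-reactivity kernel
#'
#' @param mode kernel shape: \code{"none"} (all-or-nothing),
#'   \code{"exponential"} or \code{"step"}.
#' @param theta radius scale in mutations; ignored for \code{"none"}.
#'   \code{theta = 0} with mode \code{"exponential"} is defined as the
#'   all-or-nothing kernel.
#' @return a \linkS4class{CrossReactivity} object.
#' @examples
#' crossReactivity("step", theta = 1)
#' @export
crossReactivity <- function(mode = c("none", "exponential", "step"),
                            theta = 0) {
  mode <- match.arg(mode)
  new("CrossReactivity", mode = mode, theta = as.numeric(theta))
}

#' Model parameters for the chemostat coevolution model
#'
#' Single source of truth for all rate constants. Rates that the model scales
#' with the bacterial growth rate are stored in their dimensionless form
#' (\code{f}, \code{R}) and converted at the accessor boundary; the adsorption
#' rate is stored as \code{alphaC0} = \eqn{\alpha C_0} (min^-1) so that
#' changing \code{C0} rescales \eqn{\alpha} the way the model prescribes.
#'
#' Internally all rates are per minute; one bacterial generation is
#' \code{1/gC0} minutes (41.7 min at the default maximal growth rate).
#'
#' @slot C0 inflow nutrient concentration (bacterial cell-density units).
#' @slot gC0 maximal bacterial growth rate \eqn{g C_0} (min^-1).
#' @slot f normalized chemostat outflow, \eqn{F = f\,g C_0}.
#' @slot alphaC0 phage adsorption rate times \eqn{C_0} (min^-1);
#'   \eqn{\alpha} = \code{alphaC0 / C0}.
#' @slot B phage burst size.
#' @slot pV probability a phage kills a bacterium without a matching spacer.
#' @slot e spacer effectiveness in [0, 1].
#' @slot R per-generation spacer-loss probability, \eqn{r = R\,g C_0}.
#' @slot eta spacer acquisition probability on surviving infection.
#' @slot mu phage mutation probability per base per replication.
#' @slot L protospacer length in bits.
#' @slot xr a \linkS4class{CrossReactivity} kernel.
#' @export
setClass("SimParams",
  representation(C0 = "numeric", gC0 = "numeric", f = "numeric",
                 alphaC0 = "numeric", B = "numeric", pV = "numeric",
                 e = "numeric", R = "numeric", eta = "numeric",
                 mu = "numeric", L = "integer", xr = "CrossReactivity"))

setValidity("SimParams", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && !is.na(x)
  if (!one(object@C0) || object@C0 <= 0) msg <- c(msg, "C0 must be > 0")
  if (!one(object@gC0) || object@gC0 <= 0) msg <- c(msg, "gC0 must be > 0")
  if (!one(object@f) || object@f <= 0 || object@f >= 1)
    msg <- c(msg, "f must lie in (0, 1)")
  if (!one(object@alphaC0) || object@alphaC0 < 0)
    msg <- c(msg, "alphaC0 must be >= 0")
  if (!one(object@B) || object@B < 2) msg <- c(msg, "B must be >= 2")
  for (p in c("pV", "e", "eta")) {
    v <- slot(object, p)
    if (!one(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must lie in [0, 1]", p))
  }
  if (!one(object@R) || object@R < 0) msg <- c(msg, "R must be >= 0")
  if (!one(object@mu) || object@mu < 0 || object@mu > 1)
    msg <- c(msg, "mu must lie in [0, 1]")
  if (!one(object@L) || object@L < 1L || object@L > 30L)
    msg <- c(msg, "L must be an integer in [1, 30]")
  if (length(msg)) msg else TRUE
})

#' Population state at one time point
#'
#' Integer counts of nutrients, naive bacteria, per-spacer bacterial clones
#' and per-protospacer phage clones. Sequences are stored as unsigned
#' integers (bit pattern = type identity); see \code{\link{seqToString}} for
#' the serialized form.
#'
#' @slot time time in minutes.
#' @slot C nutrient count.
#' @slot nB0 count of bacteria without a spacer.
#' @slot bacteriaSeq integer-coded spacer sequences of bacterial clones.
#' @slot bacteriaCount clone sizes matching \code{bacteriaSeq}.
#' @slot phageSeq integer-coded protospacer sequences of phage clones.
#' @slot phageCount clone sizes matching \code{phageSeq}.
#' @export
setClass("PopulationState",
  representation(time = "numeric", C = "numeric", nB0 = "numeric",
                 bacteriaSeq = "integer", bacteriaCount = "numeric",
                 phageSeq = "integer", phageCount = "numeric"))

## internal constructor: the slot named C would otherwise partially match
## new()'s Class argument
.PopulationState <- function(time, C, nB0, bacteriaSeq, bacteriaCount,
                             phageSeq, phageCount) {
  do.call(new, list(Class = "PopulationState", time = time, C = C,
                    nB0 = nB0, bacteriaSeq = bacteriaSeq,
                    bacteriaCount = bacteriaCount, phageSeq = phageSeq,
                    phageCount = phageCount))
}

setValidity("PopulationState", function(object) {
  msg <- character()
  if (object@C < 0 || object@nB0 < 0) msg <- c(msg, "counts must be >= 0")
  if (length(object@bacteriaSeq) != length(object@bacteriaCount))
    msg <- c(msg, "bacteriaSeq and bacteriaCount lengths differ")
  if (length(object@phageSeq) != length(object@phageCount))
    msg <- c(msg, "phageSeq and phageCount lengths differ")
  if (any(object@bacteriaCount < 0) || any(object@phageCount < 0))
    msg <- c(msg, "clone counts must be >= 0")
  if (anyDuplicated(object@bacteriaSeq) || anyDuplicated(object@phageSeq))
    msg <- c(msg, "duplicate clone sequences in one population")
  if (length(msg)) msg else TRUE
})

#' Result of one stochastic simulation run
#'
#' @slot params the \linkS4class{SimParams} used.
#' @slot seed integer seed of the run.
#' @slot engine \code{"gillespie"} or \code{"tau-leap"}.
#' @slot snapshots list of \linkS4class{PopulationState} at recorded times.
#' @slot totals data.frame of population totals
#'   (\code{t}, \code{tGen}, \code{C}, \code{nB0}, \code{nBs}, \code{nV},
#'   \code{mBacteria}, \code{mPhage}) on a denser cadence than snapshots.
#' @slot clones data.frame of clone records (\code{population},
#'   \code{seq}, \code{parent}, \code{birth}, \code{extinction},
#'   \code{maxSize}), one row per clone lifespan; \code{establishment} is
#'   added by \code{\link{recordClones}}.
#' @slot schedule list with the recording schedule and run length actually
#'   used (times in minutes).
#' @slot clampEvents number of tau-leap updates clamped at zero after
#'   step-halving was exhausted (0 for Gillespie).
#' @export
setClass("SimulationResult",
  representation(params = "SimParams", seed = "integer", engine = "character",
                 snapshots = "list", totals = "data.frame",
                 clones = "data.frame", schedule = "list",
                 clampEvents = "integer"))

#' Time-indexed type-by-count abundance table for one population
#'
#' The interchange object between the simulator and the analysis layer.
#' Stored as a types-by-times matrix; rows are clone identifiers (serialized
#' sequences or opaque labels), columns are time points.
#'
#' @slot times strictly increasing time points.
#' @slot types unique clone identifiers.
#' @slot counts numeric matrix, \code{length(types)} rows by
#'   \code{length(times)} columns, non-negative.
#' @slot population \code{"bacteria"} or \code{"phage"}.
#' @slot units time units: \code{"minutes"}, \code{"generations"} or
#'   \code{"days"}.
#' @export
setClass("AbundanceSeries",
  representation(times = "numeric", types = "character", counts = "matrix",
                 population = "character", units = "character"))

setValidity("AbundanceSeries", function(object) {
  msg <- character()
  if (is.unsorted(object@times, strictly = TRUE))
    msg <- c(msg, "times must be strictly increasing")
  if (anyDuplicated(object@types)) msg <- c(msg, "duplicate types")
  if (nrow(object@counts) != length(object@types) ||
      ncol(object@counts) != length(object@times))
    msg <- c(msg, "counts must be types x times")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (!object@population %in% c("bacteria", "phage"))
    msg <- c(msg, "population must be 'bacteria' or 'phage'")
  if (!object@units %in% c("minutes", "generations", "days"))
    msg <- c(msg, "units must be minutes, generations or days")
  if (length(msg)) msg else TRUE
})

#' Time-shift curve of a population statistic
#'
#' @slot delay signed time delays (same units as the input series).
#' @slot mean mean statistic at each delay.
#' @slot sd standard deviation across contributing time points.
#' @slot n number of contributing pairs per delay.
#' @slot multiplier scalar applied to the raw statistic (protospacers per
#'   phage; 1 when not used).
#' @slot units time units of the delays.
#' @export
setClass("ShiftCurve",
  representation(delay = "numeric", mean = "numeric", sd = "numeric",
                 n = "numeric", multiplier = "numeric", units = "character"))

#' Deterministic steady state of the total-population model
#'
#' @slot xStar total bacteria over \code{C0}.
#' @slot yStar total phage over \code{C0}.
#' @slot nuStar fraction of bacteria carrying a spacer.
#' @slot cStar nutrient level over \code{C0}.
#' @slot eEff effective immunity used in place of \eqn{e}.
#' @slot regime root-selection/regime tag.
#' @slot phageExtinct TRUE when the phage-free fixed point is returned.
#' @slot residual maximum relative residual of the ODE right-hand side.
#' @export
setClass("SteadyState",
  representation(xStar = "numeric", yStar = "numeric", nuStar = "numeric",
                 cStar = "numeric", eEff = "numeric", regime = "character",
                 phageExtinct = "logical", residual = "numeric"))

#' Bundle of clone-level theoretical predictions
#'
#' All rates are reported per bacterial generation unless the name says
#' otherwise; \code{s0}, \code{delta0}, \code{beta0} are per minute.
#'
#' @slot A phage viability index; phages persist deterministically iff A > 1.
#' @slot pV0 infection-success extinction threshold.
#' @slot nBTilde,nVTilde no-CRISPR steady-state totals (counts).
#' @slot s0,delta0,beta0 initial mutant growth, death and birth-event rates
#'   (min^-1).
#' @slot Pest establishment probability of a new phage mutant.
#' @slot muBar establishment-eligible mutants per generation.
#' @slot Text large-clone mean extinction time (generations).
#' @slot mPred self-consistent predicted number of clones (NA when no
#'   solution exists).
#' @slot mFound TRUE when the self-consistent solve converged.
#' @slot diversityA combined diversity parameter (closed form).
#' @slot mClosedForm root of \eqn{m^3 = a(1+\ln m)}.
#' @slot vPred predicted speed (mutational distance per generation).
#' @slot emStar critical effective immunity.
#' @slot notes character vector of warnings (e.g. clonal-interference
#'   regime).
#' @export
setClass("TheoryBundle",
  representation(A = "numeric", pV0 = "numeric", nBTilde = "numeric",
                 nVTilde = "numeric", s0 = "numeric", delta0 = "numeric",
                 beta0 = "numeric", Pest = "numeric", muBar = "numeric",
                 Text = "numeric", mPred = "numeric", mFound = "logical",
                 diversityA = "numeric", mClosedForm = "numeric",
                 vPred = "numeric", emStar = "numeric", notes = "character"))

#' Specification for the synthetic abundance-table generator
#'
#' Emulates the statistical shape of experiment-derived clone-count tables:
#' approximately exponential clone-size distributions, partial type overlap
#' between the bacterial and phage populations, and gradual type turnover.
#'
#' @slot nTimes number of time points.
#' @slot dt spacing between time points.
#' @slot units time units of \code{dt}.
#' @slot nBacteriaTypes,nPhageTypes number of clone types alive at any time.
#' @slot meanCloneSize mean of the exponential clone-size law.
#' @slot overlap target fraction of bacterial types matched by a phage type.
#' @slot turnover per-step probability that a type dies and is replaced by a
#'   fresh label.
#' @export
setClass("FixtureSpec",
  representation(nTimes = "integer", dt = "numeric", units = "character",
                 nBacteriaTypes = "integer", nPhageTypes = "integer",
                 meanCloneSize = "numeric", overlap = "numeric",
                 turnover = "numeric"),
  prototype(nTimes = 20L, dt = 1, units = "days", nBacteriaTypes = 40L,
            nPhageTypes = 60L, meanCloneSize = 50, overlap = 0.5,
            turnover = 0.1))

setValidity("FixtureSpec", function(object) {
  msg <- character()
  if (object@nTimes < 2L) msg <- c(msg, "need at least 2 time points")
  if (object@nBacteriaTypes < 1L || object@nPhageTypes < 1L)
    msg <- c(msg, "need at least one type in each population")
  if (object@overlap < 0 || object@overlap > 1)
    msg <- c(msg, "overlap must lie in [0, 1]")
  if (object@turnover < 0 || object@turnover > 1)
    msg <- c(msg, "turnover must lie in [0, 1]")
  if (object@meanCloneSize <= 0) msg <- c(msg, "meanCloneSize must be > 0")
  if (length(msg)) msg else TRUE
})
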