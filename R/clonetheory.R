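## Clone-level analytics: establishment, extinction, effective mutation
## rate, self-consistent diversity, deterministic single-clone dynamics,
## first-acquisition timing, and predicted speed of evolution.
##
## Internal computation is in minutes; rates are converted to bacterial
## generations (via gC0) only at the reporting boundary.

#' Establishment probability of a new phage mutant
#'
#' A new mutant escapes CRISPR targeting entirely, so its early fate is a
#' branching process whose rates depend only on the total bacterial
#' population: birth-event rate \eqn{\beta_0 = \alpha n_B p_V} (each event
#' replaces the phage by \eqn{B} copies), death rate
#' \eqn{\delta_0 = F + \alpha n_B (1-p_V)}, net growth
#' \eqn{s_0 = \beta_0(B-1) - \delta_0 = \alpha n_B(Bp_V-1) - F}. The
#' establishment probability is \eqn{2 s_0 / (B (s_0 + \delta_0))}
#' (0 when \eqn{s_0 \le 0}).
#'
#' When \code{e}, \code{nu} and \code{m} are supplied the steady-state form
#' \eqn{P_{est} = 2 e \nu / (m (B-1))} is also returned.
#'
#' @param params a \linkS4class{SimParams}.
#' @param nB total bacterial population size.
#' @param e,nu,m optional spacer effectiveness, spacer-bearing fraction and
#'   clone number for the steady-state form.
#' @return list with \code{s0}, \code{delta0}, \code{beta0} (min^-1),
#'   \code{Pest}, and \code{PestSteadyState} (NA unless e, nu, m given).
#' @export
establishmentProbability <- function(params, nB, e = NULL, nu = NULL,
                                     m = NULL) {
  stopifnot(nB > 0)
  al <- adsorptionRate(params); FF <- outflowRate(params)
  B <- params@B; pV <- params@pV
  beta0 <- al * nB * pV
  delta0 <- FF + al * nB * (1 - pV)
  s0 <- al * nB * (B * pV - 1) - FF
  stopifnot(s0 + delta0 > 0)
  Pest <- max(0, 2 * s0 / (B * (s0 + delta0)))
  Pss <- if (!is.null(e) && !is.null(nu) && !is.null(m))
    2 * e * nu / (m * (B - 1)) else NA_real_
  list(s0 = s0, delta0 = delta0, beta0 = beta0, Pest = Pest,
       PestSteadyState = Pss)
}

#' Branching-process survival oracle
#'
#' Exact survival probability of a continuous-time branching process in
#' which an individual dies at rate \code{delta0} and at rate \code{beta0}
#' is replaced by \code{B} copies. The per-lineage extinction probability
#' \eqn{q} is the smallest root in [0, 1] of
#' \eqn{\delta_0 + \beta_0 q^B = (\delta_0+\beta_0) q}, found by monotone
#' fixed-point iteration from 0. This is the independent check for the
#' \eqn{2 s_0/(B(s_0+\delta_0))} establishment formula.
#'
#' @param beta0 birth-event rate (min^-1).
#' @param delta0 death rate (min^-1).
#' @param B copies per birth event.
#' @param n initial number of individuals.
#' @return named vector with \code{extinction} (\eqn{q^n}) and
#'   \code{survival}.
#' @export
branchingExtinctionOracle <- function(beta0, delta0, B, n = 1) {
  stopifnot(beta0 >= 0, delta0 >= 0, beta0 + delta0 > 0, B >= 2, n >= 1)
  if (beta0 * (B - 1) <= delta0)
    return(c(extinction = 1, survival = 0))
  q <- 0
  for (i in 1:10000) {
    qNew <- (delta0 + beta0 * q^B) / (delta0 + beta0)
    if (abs(qNew - q) < 1e-15) { q <- qNew; break }
    q <- qNew
  }
  c(extinction = q^n, survival = 1 - q^n)
}

#' Mean time to extinction for a large phage clone
#'
#' Full form (from the backward master equation for a clone fluctuating
#' around size \code{nVi} in a population of total size \code{nV}):
#' \deqn{T_{ext} = \frac{2 n_{Vi} (1 - \ln(n_{Vi}/n_V))}{(B-1)(2\beta+\delta)}
#' \ \mathrm{min}, \quad \beta = \alpha p_V (n_B - e\, n_{Bi}),\
#' \delta = F + \alpha n_B (1-p_V) + \alpha p_V e\, n_{Bi}.}
#' The approximate form evaluates this at the deterministic mean clone size
#' (\eqn{n_{Vi} = \tilde n_V/m}, \eqn{n_{Bi} = n_{Bs}/m}) and drops the
#' CRISPR correction:
#' \eqn{T_{ext} \approx 2(1+\ln m)\,(\tilde n_V/m)(1 - 1/(Bp_V)) / (f(B-1))}
#' generations. The two agree to \eqn{O(1/B)}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param nVi clone size.
#' @param nV total phage population.
#' @param nB total bacterial population.
#' @param nBi matching bacterial clone size.
#' @param e spacer effectiveness (defaults to \code{params@e}).
#' @return list with \code{minutes} and \code{generations}.
#' @export
largeCloneExtinctionTime <- function(params, nVi, nV, nB, nBi,
                                     e = params@e) {
  stopifnot(nVi > 0, nVi <= nV)
  al <- adsorptionRate(params); FF <- outflowRate(params)
  B <- params@B; pV <- params@pV
  beta <- al * pV * (nB - e * nBi)
  delta <- FF + al * nB * (1 - pV) + al * pV * e * nBi
  mins <- 2 * nVi * (1 - log(nVi / nV)) / ((B - 1) * (2 * beta + delta))
  list(minutes = mins, generations = mins * params@gC0)
}

#' @describeIn largeCloneExtinctionTime approximate extinction time
#'   (generations) as a function of the clone number \code{m} only.
#' @param m number of coexisting clones.
#' @export
textApprox <- function(params, m) {
  nVt <- noCrisprSteadyState(params)[["nVTilde"]]
  B <- params@B; pV <- params@pV
  2 * (1 + log(m)) * (nVt / m) * (1 - 1 / (B * pV)) /
    (params@f * (B - 1))
}

#' Effective phage mutation rate
#'
#' New-mutant creation rate
#' \eqn{\bar\mu = \alpha B (1-e^{-\mu L}) p_V n_V n_B (1 - e_\mathrm{eff}\nu)
#' / (g C_0)} (per bacterial generation). With \code{zerothOrder = TRUE}
#' the no-CRISPR totals are used and the immunity factor dropped; across
#' the parameter range this changes the rate only weakly.
#'
#' @param params a \linkS4class{SimParams}.
#' @param nV,nB total population sizes.
#' @param nu spacer-bearing fraction.
#' @param eEff effective immunity (\eqn{e/m} in the theory).
#' @param zerothOrder use the \eqn{e_\mathrm{eff} = 0} approximation.
#' @return mutants per bacterial generation.
#' @export
effectiveMutationRate <- function(params, nV, nB, nu = 0, eEff = 0,
                                  zerothOrder = FALSE) {
  al <- adsorptionRate(params)
  pFlip <- 1 - exp(-params@mu * params@L)
  if (zerothOrder) {
    tot <- noCrisprSteadyState(params)
    nV <- tot[["nVTilde"]]; nB <- tot[["nBTilde"]]; nu <- 0; eEff <- 0
  }
  al * params@B * pFlip * params@pV * nV * nB * (1 - eEff * nu) /
    params@gC0
}

## solve m^3 = a (1 + log m); returns list(m, subOne)
.solveMCubicLog <- function(a) {
  if (!is.finite(a) || a <= 0) return(list(m = 0, subOne = TRUE))
  g <- function(m) m^3 - a * (1 + log(m))
  if (g(1) >= 0) {  # a <= 1: no root at or above 1
    return(list(m = a^(1/3), subOne = TRUE))
  }
  up <- max(10, 10 * a^(1/3))
  list(m = stats::uniroot(g, c(1, up), tol = 1e-10)$root, subOne = FALSE)
}

#' Perturbative solution of \eqn{m^3 = a(1+\ln m)}
#'
#' First-order perturbation around \eqn{z_0 = 1 + \ln(a)/3}:
#' \deqn{m \approx \Big[\frac{a(\ln a+3)\big(\ln a + \ln((\ln a+3)/3) + 2\big)}
#' {3(\ln a+2)}\Big]^{1/3}.}
#'
#' @param a combined diversity parameter.
#' @return approximate m.
#' @export
mPerturbative <- function(a) {
  la <- log(a)
  if (!is.finite(la) || la <= -2) return(NA_real_)  # expansion invalid
  (a * (la + 3) * (la + log((la + 3) / 3) + 2) / (3 * (la + 2)))^(1/3)
}

#' Combined diversity parameter
#'
#' \code{exact}: \eqn{a = 4 e \tilde\nu \tilde n_V^2 (1-e^{-\mu L})/(B-1)^2}
#' with \eqn{\tilde\nu} and \eqn{\tilde n_V} evaluated exactly.
#' \code{approx}: the large-burst, small-\eqn{\eta} closed form
#' \eqn{a \approx 4 e \mu L \hat\eta (g C_0 (1-f))^3 /
#' (B^2 \alpha^2 p_V^3 r)}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return named vector \code{c(exact, approx)}.
#' @export
diversityParameter <- function(params) {
  B <- params@B; pV <- params@pV; e <- params@e
  etah <- params@eta * (1 - pV)
  al <- adsorptionRate(params); r <- lossRate(params)
  nVt <- noCrisprSteadyState(params)[["nVTilde"]]
  nuT <- 1 / (1 + r / (etah * al * nVt))
  pFlip <- 1 - exp(-params@mu * params@L)
  exact <- 4 * e * nuT * nVt^2 * pFlip / (B - 1)^2
  approx <- 4 * e * params@mu * params@L * etah *
    (params@gC0 * (1 - params@f))^3 / (B^2 * al^2 * pV^3 * r)
  c(exact = exact, approx = approx)
}

#' Closed-form establishment probability
#'
#' The fully reduced form obtained by composing the steady-state
#' establishment probability \eqn{2e\nu/(m(B-1))} with
#' \eqn{\tilde\nu \approx \hat\eta\alpha\tilde n_V/r},
#' \eqn{\tilde n_V \approx gC_0(1-f)/(\alpha p_V)} and
#' \eqn{m \approx a^{1/3}} (Eq.-88-level approximations):
#' \eqn{P_{est} \approx [2 (e \hat\eta \alpha)^2 / (\mu L B r^2)]^{1/3}}.
#' It decreases with increasing mutation rate \eqn{\mu L}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return approximate establishment probability.
#' @export
pestClosedForm <- function(params) {
  etah <- params@eta * (1 - params@pV)
  al <- adsorptionRate(params); r <- lossRate(params)
  (2 * (params@e * etah * al)^2 /
     (params@mu * params@L * params@B * r^2))^(1/3)
}

#' Self-consistent prediction of clonal diversity
#'
#' Solves \eqn{m = P_{est}\,\bar\mu\,T_{ext}} for the steady-state number
#' of clones, with all three factors evaluated at the mean-field totals for
#' effective immunity \eqn{e/m} and clone sizes \eqn{n_{Vi} = n_V/m},
#' \eqn{n_{Bi} = n_{Bs}/m}. For several parameter combinations no solution
#' exists (small systems where establishment, mutation or extinction time
#' are too low); this is a flagged return, not an error. Also returns the
#' combined diversity parameter and the closed-form root of
#' \eqn{m^3 = a(1+\ln m)}.
#'
#' A warning note is attached when the predicted extinction time is shorter
#' than the spacer-acquisition timescale (clonal-interference regime at
#' very low \eqn{\eta}, where the self-consistency argument overestimates
#' diversity).
#'
#' @param params a \linkS4class{SimParams}.
#' @param mRange search interval for the self-consistent solve.
#' @return list with \code{m} (NA when none), \code{mFound},
#'   \code{diversityA} (exact and approx), \code{mClosedForm} (from the
#'   approximate a), \code{mClosedFormExact}, \code{mPerturbative},
#'   \code{subOne} flag, \code{details} (Pest, muBar, Text at the
#'   solution) and \code{notes}.
#' @export
predictDiversity <- function(params, mRange = c(1, 1e4)) {
  if (phageThreshold(params)[["A"]] <= 1)
    stop("phage-extinct regime (A <= 1)")
  e <- params@e
  rhs <- function(m) {
    eEff <- min(e / m, 1)
    ss <- steadyState(params, eEff)
    if (ss@phageExtinct) return(NA_real_)
    C0 <- params@C0
    nB <- ss@xStar * C0; nV <- ss@yStar * C0; nu <- ss@nuStar
    est <- establishmentProbability(params, nB)
    muBar <- effectiveMutationRate(params, nV, nB, nu, eEff)
    Text <- largeCloneExtinctionTime(params, nV / m, nV, nB,
                                     nu * nB / m)$generations
    est$Pest * muBar * Text
  }
  h <- function(m) {
    v <- rhs(m)
    if (is.na(v)) return(NA_real_)
    m - v
  }
  grid <- exp(seq(log(mRange[1]), log(mRange[2]), length.out = 60))
  hv <- vapply(grid, h, numeric(1))
  ok <- !is.na(hv)
  mSol <- NA_real_; found <- FALSE
  idx <- which(ok[-length(ok)] & ok[-1] &
                 hv[-length(hv)] * hv[-1] <= 0)
  if (length(idx)) {
    i <- idx[length(idx)]  # largest-m crossing: the self-consistent branch
    mSol <- stats::uniroot(h, c(grid[i], grid[i + 1]), tol = 1e-8)$root
    found <- TRUE
  }
  aBoth <- diversityParameter(params)
  closedApprox <- .solveMCubicLog(aBoth[["approx"]])
  closedExact <- .solveMCubicLog(aBoth[["exact"]])
  notes <- character()
  details <- NULL
  if (found) {
    eEff <- min(e / mSol, 1)
    ss <- steadyState(params, eEff)
    C0 <- params@C0
    nB <- ss@xStar * C0; nV <- ss@yStar * C0; nu <- ss@nuStar
    est <- establishmentProbability(params, nB)
    muBar <- effectiveMutationRate(params, nV, nB, nu, eEff)
    Text <- largeCloneExtinctionTime(params, nV / mSol, nV, nB,
                                     nu * nB / mSol)$generations
    details <- list(Pest = est$Pest, muBar = muBar, Text = Text,
                    nu = nu, nB = nB, nV = nV)
    ## spacer-acquisition timescale (generations)
    etah <- params@eta * (1 - params@pV)
    D <- adsorptionRate(params) * etah * (nV / mSol) * (1 - nu) * nB
    tAcqGen <- params@gC0 / D
    if (is.finite(tAcqGen) && Text < tAcqGen) {
      notes <- c(notes, paste(
        "clonal-interference regime: predicted extinction time is shorter",
        "than the spacer-acquisition timescale; the prediction tends to",
        "overestimate diversity here"))
    }
  }
  list(m = mSol, mFound = found, diversityA = aBoth,
       mClosedForm = closedApprox$m, mClosedFormExact = closedExact$m,
       mPerturbative = mPerturbative(aBoth[["approx"]]),
       subOne = closedApprox$subOne, details = details, notes = notes)
}

#' Deterministic dynamics of a matched clone pair
#'
#' Integrates the coupled clone equations in a fixed background of totals
#' (back-mutation neglected):
#' \deqn{\dot n_{Vi} = -(F+\alpha n_B) n_{Vi} +
#'   \alpha B e^{-\mu L} p_V n_{Vi} (n_B - e\,n_{Bi})}
#' \deqn{\dot n_{Bi} = (gC-F-r) n_{Bi} - \alpha p_V n_{Bi}(n_V - e\,n_{Vi})
#'   + \alpha \hat\eta\, n_{B0}\, n_{Vi}}
#' and reports the 1-D analytic solutions (each clone with the other held
#' fixed) and the steady clone sizes.
#'
#' @param params a \linkS4class{SimParams}.
#' @param totals named vector with \code{nB}, \code{nB0}, \code{nV},
#'   \code{C} (background steady state).
#' @param horizon integration horizon in minutes.
#' @param nVi0,nBi0 initial clone sizes.
#' @param nOut number of output times.
#' @return list with \code{trajectory} (data.frame time, nVi, nBi),
#'   \code{s0} (1-D phage clone growth rate, min^-1, with the
#'   \eqn{B e^{-\mu L}} correction), \code{fixedPoint} (nBiStar, nViStar).
#' @export
cloneDynamics <- function(params, totals, horizon, nVi0 = 1, nBi0 = 0,
                          nOut = 200L) {
  al <- adsorptionRate(params); FF <- outflowRate(params)
  g <- growthRate(params); r <- lossRate(params)
  B <- params@B; pV <- params@pV; e <- params@e
  etah <- params@eta * (1 - pV)
  P0 <- exp(-params@mu * params@L)
  nB <- totals[["nB"]]; nB0 <- totals[["nB0"]]
  nV <- totals[["nV"]]; C <- totals[["C"]]
  rhs <- function(t, y, p) {
    nVi <- y[1]; nBi <- y[2]
    list(c(-(FF + al * nB) * nVi + al * B * P0 * pV * nVi * (nB - e * nBi),
           (g * C - FF - r) * nBi - al * pV * nBi * (nV - e * nVi) +
             al * etah * nB0 * nVi))
  }
  times <- seq(0, horizon, length.out = nOut)
  traj <- as.data.frame(deSolve::ode(c(nVi = nVi0, nBi = nBi0), times,
                                     rhs, NULL))
  s0 <- al * B * P0 * pV * nB - FF - al * nB
  nBiStar <- (nB - (FF + al * nB) / (al * B * P0 * pV)) / e
  nViStar <- nBiStar * (al * pV * nV - (g * C - FF - r)) /
    (al * etah * nB0 + al * pV * e * nBiStar)
  list(trajectory = traj, s0 = s0,
       fixedPoint = c(nBiStar = nBiStar, nViStar = nViStar))
}

#' Timing of the first spacer acquisition against a growing clone
#'
#' A phage clone growing exponentially at rate \code{s0} is sampled for
#' spacer acquisition as an inhomogeneous Poisson process with per-phage
#' rate \eqn{a = \alpha \hat\eta\, n_{B0}}. The first-acquisition time has
#' density \eqn{P(t) = a e^{s_0 t} \exp(-(a/s_0)(e^{s_0 t}-1))} and mean
#' \eqn{\langle t\rangle = (1/s_0)\, e^{a/s_0}\, \Gamma(0, a/s_0)}; the
#' clone size floor at acquisition is \eqn{e^{s_0 \langle t\rangle}}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param s0 clone growth rate (min^-1), must be positive.
#' @param nB0 naive bacterial population size.
#' @return list with \code{density} (a function of t in minutes),
#'   \code{meanTime} (minutes), \code{sizeAtMean}, and the acquisition
#'   rate \code{aAcq} (min^-1).
#' @export
acquisitionTime <- function(params, s0, nB0) {
  if (s0 <= 0) stop("s0 must be positive (no exponential growth phase)")
  aAcq <- adsorptionRate(params) * params@eta * (1 - params@pV) * nB0
  stopifnot(aAcq >= 0)
  ## evaluated in log space so the exp(s0 t) factor cannot overflow into
  ## Inf * 0 at large t
  dens <- function(t) exp(log(aAcq) + s0 * t -
                            (aAcq / s0) * expm1(s0 * t))
  x <- aAcq / s0
  meanTime <- exp(x) * pracma::expint_E1(x) / s0
  list(density = dens, meanTime = meanTime,
       sizeAtMean = exp(s0 * meanTime), aAcq = aAcq)
}

#' Predicted speed of evolution
#'
#' At steady state the population's centre of mass advances one
#' established clone at a time, and the advance rate is set by clone
#' turnover: \eqn{v = 1/T_{ext}} (mutational distance per generation).
#' The closed form applies the same approximations as the closed form for
#' \eqn{m}: \eqn{v \approx (\alpha B / f)\,[e\mu\eta L(1-p_V) /
#' (2\alpha^2B^2 r)]^{1/3}}.
#'
#' @param params a \linkS4class{SimParams}.
#' @param Text large-clone extinction time in generations (optional; when
#'   missing it is derived from \code{m} via \code{\link{textApprox}}).
#' @param m number of clones (used when \code{Text} is missing).
#' @return list with \code{v} (distance per generation; NA when neither
#'   Text nor m given) and \code{vClosedForm}.
#' @export
predictSpeed <- function(params, Text = NULL, m = NULL) {
  if (is.null(Text) && !is.null(m)) Text <- textApprox(params, m)
  v <- if (!is.null(Text)) 1 / Text else NA_real_
  al <- adsorptionRate(params); r <- lossRate(params)
  vcf <- (al * params@B / params@f) *
    (params@e * params@mu * params@eta * params@L * (1 - params@pV) /
       (2 * al^2 * params@B^2 * r))^(1/3)
  list(v = v, vClosedForm = vcf)
}

#' Assemble the full bundle of theoretical predictions
#'
#' @param params a \linkS4class{SimParams}.
#' @return a \linkS4class{TheoryBundle}.
#' @examples
#' theoryBundle(simParams(C0 = 1e4, e = 0.95, eta = 1e-3, mu = 1e-5))
#' @export
theoryBundle <- function(params) {
  th <- phageThreshold(params)
  tot <- if (th[["A"]] > 1) noCrisprSteadyState(params) else
    c(nBTilde = NA_real_, nVTilde = NA_real_)
  pd <- predictDiversity(params)
  mUse <- if (pd$mFound) pd$m else pd$mClosedForm
  det <- pd$details
  if (is.null(det)) {
    eEff <- min(params@e / max(mUse, 1), 1)
    ss <- steadyState(params, eEff)
    nB <- ss@xStar * params@C0; nV <- ss@yStar * params@C0
    det <- list(
      Pest = establishmentProbability(params, nB)$Pest,
      muBar = effectiveMutationRate(params, nV, nB, ss@nuStar, eEff),
      Text = textApprox(params, max(mUse, 1)))
  }
  est <- establishmentProbability(params, if (th[["A"]] > 1)
    tot[["nBTilde"]] else params@C0 * (1 - params@f))
  em <- if (th[["A"]] > 1) criticalEffectiveE(params)$emStarFull else
    NA_real_
  new("TheoryBundle", A = th[["A"]], pV0 = th[["pV0"]],
      nBTilde = tot[["nBTilde"]], nVTilde = tot[["nVTilde"]],
      s0 = est$s0, delta0 = est$delta0, beta0 = est$beta0,
      Pest = det$Pest, muBar = det$muBar, Text = det$Text,
      mPred = if (pd$mFound) pd$m else NA_real_, mFound = pd$mFound,
      diversityA = pd$diversityA[["approx"]],
      mClosedForm = pd$mClosedForm,
      vPred = 1 / det$Text, emStar = em, notes = pd$notes)
}

setMethod("show", "TheoryBundle", function(object) {
  cat("TheoryBundle:\n")
  cat(sprintf("  A=%.4g (pV0=%.4g); nB~=%.4g nV~=%.4g\n", object@A,
              object@pV0, object@nBTilde, object@nVTilde))
  cat(sprintf("  Pest=%.3e muBar=%.3e/gen Text=%.3e gen\n", object@Pest,
              object@muBar, object@Text))
  cat(sprintf("  m(self-consistent)=%s m(closed form)=%.3g a=%.3g\n",
              if (object@mFound) sprintf("%.3g", object@mPred) else
                "no solution", object@mClosedForm, object@diversityA))
  cat(sprintf("  v=%.3e per gen; em*=%.3g\n", object@vPred, object@emStar))
  for (n in object@notes) cat("  note:", n, "\n")
})
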