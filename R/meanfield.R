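## Deterministic total-population layer.
##
## The totals (nBs, nV, nB0, C) obey the mean-field equations obtained by
## summing the clone-size master equations, with the population-averaged
## success probability against spacer-bearing bacteria written as
## pVa = pV(1 - e_eff). Effective immunity e_eff is always an explicit
## argument: the caller passes e/m (theory) or a measured average immunity
## (analysis).

#' Mean-field right-hand side of the total-population model
#'
#' @param totals named numeric vector with \code{nBs}, \code{nV},
#'   \code{nB0}, \code{C} (counts).
#' @param params a \linkS4class{SimParams}.
#' @param eEff effective immunity in [0, 1], used as
#'   \eqn{p_{Va} = p_V(1 - e_\mathrm{eff})}.
#' @return named vector of time derivatives (per minute).
#' @export
odeRHS <- function(totals, params, eEff) {
  stopifnot(eEff >= 0, eEff <= 1, all(totals >= 0))
  g <- growthRate(params); FF <- outflowRate(params)
  al <- adsorptionRate(params); r <- lossRate(params)
  pV <- params@pV; B <- params@B; eta <- params@eta
  nBs <- totals[["nBs"]]; nV <- totals[["nV"]]
  nB0 <- totals[["nB0"]]; C <- totals[["C"]]
  nB <- nB0 + nBs
  pVa <- pV * (1 - eEff)
  c(nBs = (g * C - FF - r) * nBs + al * (1 - pV) * eta * nB0 * nV -
      al * nBs * nV * pVa,
    nV = -(FF + al * nB) * nV + al * B * (pVa * nBs + pV * nB0) * nV,
    nB0 = (g * C - FF) * nB0 - al * pV * nB0 * nV -
      al * (1 - pV) * eta * nB0 * nV + r * nBs,
    C = FF * (params@C0 - C) - g * C * nB)
}

#' Integrate the total-population mean-field model
#'
#' @inheritParams odeRHS
#' @param times output times in minutes.
#' @return data.frame from \code{deSolve::ode} with columns \code{time},
#'   \code{nBs}, \code{nV}, \code{nB0}, \code{C}.
#' @export
meanfieldTrajectory <- function(totals, params, eEff, times) {
  out <- deSolve::ode(y = totals[c("nBs", "nV", "nB0", "C")], times = times,
                      func = function(t, y, p) list(odeRHS(pmax(y, 0),
                                                           params, eEff)),
                      parms = NULL)
  as.data.frame(out)
}

#' Phage viability index and extinction threshold
#'
#' Phages persist deterministically iff \eqn{A > 1}, where
#' \eqn{A = (B p_V - 1)(1-f)\alpha/(f g)}; equivalently iff
#' \eqn{p_V > p_{V0} = (g f /((1-f)\alpha) + 1)/B}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return named vector \code{c(A, pV0)}.
#' @examples
#' phageThreshold(simParams())  # A = 4.667, pV0 = 8.908e-3
#' @export
phageThreshold <- function(params) {
  ratio <- adsorptionRate(params) / growthRate(params)  # alpha/g
  A <- (params@B * params@pV - 1) * (1 - params@f) * ratio / params@f
  pV0 <- (params@f / ((1 - params@f) * ratio) + 1) / params@B
  c(A = A, pV0 = pV0)
}

#' No-CRISPR steady-state totals
#'
#' Fixed point of the totals with \eqn{e = 0}:
#' \eqn{\tilde n_B = C_0(1-f)/A} and
#' \eqn{\tilde n_V = g C_0 f (1-f)(A-1) / (\alpha p_V (1-f+Af))}.
#'
#' @param params a \linkS4class{SimParams}.
#' @return named vector \code{c(nBTilde, nVTilde)} (counts).
#' @export
noCrisprSteadyState <- function(params) {
  A <- phageThreshold(params)[["A"]]
  if (A <= 1)
    stop("phage-extinct regime (A <= 1): no-CRISPR phage total undefined")
  f <- params@f
  nB <- params@C0 * (1 - f) / A
  nV <- params@gC0 * params@C0 * f * (1 - f) * (A - 1) /
    (adsorptionRate(params) * params@pV * params@C0 * (1 - f + A * f))
  c(nBTilde = nB, nVTilde = nV)
}

## Coefficients (descending powers) of the cubic in nu obtained by
## eliminating x*, y*, C* from the steady-state conditions and clearing
## denominators: P(nu) = nu*w*(f*gC0*G - r*H) +
## f*gC0*G*(etahat/pV - nu*(etahat/pV + 1 - E)), with w = 1 - E*nu,
## q = B*pV*w - 1, K = f*g/alpha, G = (1-f)*q - K, H = f*q + K. The factor
## w contributes a spurious root at nu = 1/E.
.nuCubicCoeffs <- function(params, eEff, eta = params@eta) {
  C0 <- params@C0; gC0 <- params@gC0; f <- params@f
  al <- adsorptionRate(params); pV <- params@pV; B <- params@B
  r <- lossRate(params); E <- eEff
  K <- f * (gC0 / C0) / al
  etah <- eta * (1 - pV)
  q0 <- B * pV - 1; q1 <- B * pV * E
  G0 <- (1 - f) * q0 - K; G1 <- (1 - f) * q1
  H0 <- f * q0 + K;       H1 <- f * q1
  S0 <- f * gC0 * G0 - r * H0
  S1 <- f * gC0 * G1 - r * H1
  U <- etah / pV; V <- U + 1 - E
  c(E * S1,
    -(S1 + E * S0) + f * gC0 * G1 * V,
    S0 - f * gC0 * (G0 * V + G1 * U),
    f * gC0 * G0 * U)
}

.polyval <- function(cf, x) {
  y <- 0
  for (c1 in cf) y <- y * x + c1
  y
}

#' Spacer-bearing fraction from the steady-state cubic
#'
#' Solves the cubic in \eqn{\nu} (fraction of bacteria with a spacer)
#' obtained by eliminating the other totals from the steady-state
#' conditions at effective immunity \code{eEff}. The physical root is real,
#' in [0, 1], and compatible with phage persistence
#' (\eqn{B p_V (1 - e_\mathrm{eff}\nu) > 1}); clearing denominators
#' introduces a spurious root at \eqn{\nu = 1/e_\mathrm{eff}} which this
#' rule excludes. If several physical roots remain, the one continuous with
#' the \eqn{\eta \to 0} limit is returned and multiplicity is flagged.
#'
#' @inheritParams odeRHS
#' @param eEff effective immunity (the theory layer passes \eqn{e/m}).
#' @return list with \code{nu}, \code{regime} tag and \code{multiple}
#'   flag.
#' @export
nuStarCubic <- function(params, eEff) {
  stopifnot(eEff >= 0, eEff <= 1)
  cf <- .nuCubicCoeffs(params, eEff)
  roots <- .physRoots(cf, params, eEff)
  if (!length(roots)) {
    ## no spacer-bearing steady state with surviving phage
    return(list(nu = NA_real_, regime = "no-physical-root",
                multiple = FALSE))
  }
  multiple <- length(roots) > 1
  nu <- roots[1]
  if (multiple) {
    ## continuity with the eta -> 0 limit: follow the branch from small eta
    ref <- .physRoots(.nuCubicCoeffs(params, eEff, eta = 1e-12),
                      params, eEff)
    if (length(ref)) nu <- roots[which.min(abs(roots - ref[1]))]
  }
  ## Newton polishing on the cubic
  dcf <- cf[-length(cf)] * (length(cf) - 1):1
  for (i in 1:3) {
    d <- .polyval(dcf, nu)
    if (abs(d) > 0) nu <- nu - .polyval(cf, nu) / d
  }
  nu <- min(max(nu, 0), 1)
  list(nu = nu, regime = "full-cubic-root", multiple = multiple)
}

.physRoots <- function(cf, params, eEff) {
  keep <- abs(cf) > max(abs(cf)) * 1e-13
  first <- which(keep)[1]
  cf <- cf[first:length(cf)]
  if (length(cf) < 2) return(numeric(0))
  z <- polyroot(rev(cf))
  re <- Re(z)[abs(Im(z)) < 1e-7 * (1 + abs(Re(z)))]
  re <- re[re > -1e-9 & re < 1 + 1e-9]
  re <- pmin(pmax(re, 0), 1)
  ## phage persistence: x* > 0 requires B pV (1 - E nu) > 1
  re <- re[params@B * params@pV * (1 - eEff * re) > 1]
  sort(unique(round(re, 12)))
}

#' Closed-form approximations for the spacer-bearing fraction
#'
#' Dominant-balance approximations obtained by dropping coefficients of the
#' steady-state cubic \eqn{a\nu^3 + b\nu^2 + c\nu + d = 0}: \code{dropA}
#' solves the quadratic without the cubic term (valid at high \eqn{\eta},
#' moderate immunity), \code{dropD} drops the constant term (high
#' effective immunity), and \code{dropCubicQuadratic} is \eqn{-d/c}
#' (low \eqn{\eta} and low immunity). \code{lowImmunity} is the
#' low-average-immunity form
#' \eqn{\nu \approx 1/(1 + r/(\hat\eta\alpha\tilde n_V) -
#' e_\mathrm{eff}(p_V/\hat\eta - ABp_V/((A-1)(Bp_V-1))))} whose
#' \eqn{e_\mathrm{eff} \to 0} limit is \code{nuTilde}
#' \eqn{= 1/(1 + r/(\hat\eta \alpha \tilde n_V))}. \code{largeE} is the
#' exact \eqn{\eta \to 0} root of the cubic at the given \code{eEff}
#' (the quadratic factor left after \eqn{\nu = 0} splits off).
#'
#' The \code{lowImmunity} form diverges at the critical effective immunity
#' where its denominator vanishes (see \code{\link{criticalEffectiveE}});
#' near that point \code{divergent} is flagged.
#'
#' @inheritParams nuStarCubic
#' @return list of approximations plus \code{recommended}, the
#'   dominant-balance choice for the (\eqn{\eta}, \code{eEff}) band, and a
#'   \code{divergent} flag.
#' @export
nuApproximations <- function(params, eEff) {
  cf <- .nuCubicCoeffs(params, eEff)
  a <- cf[1]; b <- cf[2]; cc <- cf[3]; d <- cf[4]
  quadRoot <- function(A2, A1, A0) {
    disc <- A1^2 - 4 * A2 * A0
    if (is.na(disc) || disc < 0 || A2 == 0) return(NA_real_)
    r <- c((-A1 + sqrt(disc)) / (2 * A2), (-A1 - sqrt(disc)) / (2 * A2))
    r <- r[r >= 0 & r <= 1]
    if (length(r)) r[1] else NA_real_
  }
  dropA <- quadRoot(b, cc, d)
  dropD <- quadRoot(a, b, cc)
  dropCQ <- -d / cc

  th <- phageThreshold(params)
  A <- th[["A"]]
  etah <- params@eta * (1 - params@pV)
  nVt <- if (A > 1) noCrisprSteadyState(params)[["nVTilde"]] else NA_real_
  r <- lossRate(params); al <- adsorptionRate(params); pV <- params@pV
  B <- params@B
  nuTilde <- 1 / (1 + r / (etah * al * nVt))
  denom <- 1 + r / (etah * al * nVt) -
    eEff * (pV / etah - A * B * pV / ((A - 1) * (B * pV - 1)))
  lowImmunity <- 1 / denom
  divergent <- is.finite(denom) && abs(denom) < 0.05

  ## eta -> 0 quadratic factor; the w = 0 root at nu = 1/e_eff is spurious
  cf0 <- .nuCubicCoeffs(params, eEff, eta = 0)
  disc0 <- cf0[2]^2 - 4 * cf0[1] * cf0[3]
  largeE <- if (is.na(disc0) || disc0 < 0 || cf0[1] == 0) NA_real_ else {
    rts <- (-cf0[2] + c(1, -1) * sqrt(disc0)) / (2 * cf0[1])
    rts <- rts[rts >= 0 & rts <= 1 &
                 params@B * params@pV * (1 - eEff * rts) > 1]
    if (length(rts)) rts[1] else NA_real_
  }

  eta <- params@eta
  recommended <-
    if (eEff <= 0.01) dropCQ
    else if (eEff <= 0.05) { if (eta >= 1e-2) dropA else dropCQ }
    else if (eEff <= 0.1) { if (eta > 1e-5) dropA else dropCQ }
    else if (eEff <= 0.5) { if (eta <= 1e-4) dropD else NA_real_ }
    else { if (eta <= 1e-5) dropD else NA_real_ }
  list(dropA = dropA, dropD = dropD, dropCubicQuadratic = dropCQ,
       nuTilde = nuTilde, lowImmunity = lowImmunity, largeE = largeE,
       recommended = recommended, divergent = divergent)
}

#' Critical effective immunity
#'
#' The value of effective immunity \eqn{e/m} at which the denominator of
#' the low-immunity approximation for \eqn{\nu} vanishes; substituting it
#' into the mean-field equations and letting \eqn{\eta \to 0} recovers the
#' no-CRISPR totals. Returns the full expression, its two-term series in
#' \eqn{\hat\eta}, and the acquisition probability at which the third term
#' of the low-immunity denominator changes sign
#' (\eqn{\hat\eta A B = (A-1)(B p_V - 1)}).
#'
#' @param params a \linkS4class{SimParams}.
#' @return list with \code{emStarFull}, \code{emStarSeries},
#'   \code{etaSignThreshold} and \code{seriesValid} (FALSE when
#'   \eqn{\hat\eta A B \ge (A-1)(Bp_V-1)} flips the denominator sign).
#' @export
criticalEffectiveE <- function(params) {
  th <- phageThreshold(params)
  A <- th[["A"]]
  if (A <= 1) stop("phage-extinct regime (A <= 1)")
  B <- params@B; pV <- params@pV
  etah <- params@eta * (1 - pV)
  nVt <- noCrisprSteadyState(params)[["nVTilde"]]
  al <- adsorptionRate(params); r <- lossRate(params)
  lhs <- (A - 1) * (B * pV - 1)
  full <- lhs * (al * etah * nVt + r) / (al * nVt * pV * (lhs - A * B * etah))
  series <- r / (al * nVt * pV) + etah / pV
  etaSign <- lhs / ((1 - pV) * A * B)
  list(emStarFull = full, emStarSeries = series,
       etaSignThreshold = etaSign, seriesValid = etah * A * B < lhs)
}

#' Deterministic steady state at a given effective immunity
#'
#' Composes the \eqn{\nu} cubic with the closed forms for the rescaled
#' totals \eqn{x^* = n_B/C_0}, \eqn{y^* = n_V/C_0} and the nutrient level,
#' and verifies the result against \code{\link{odeRHS}}. In the
#' phage-extinct regime the bacteria-only fixed point
#' (\eqn{x^* = 1-f, y^* = 0, \nu = 0}) is returned and flagged.
#'
#' @inheritParams nuStarCubic
#' @return a \linkS4class{SteadyState}.
#' @examples
#' steadyState(simParams(), eEff = 0)    # no-CRISPR totals
#' @export
steadyState <- function(params, eEff) {
  stopifnot(eEff >= 0, eEff <= 1)
  gC0 <- params@gC0; f <- params@f; alC0 <- params@alphaC0
  pV <- params@pV; B <- params@B
  A <- phageThreshold(params)[["A"]]
  sol <- if (A > 1) nuStarCubic(params, eEff) else
    list(nu = NA_real_, regime = "no-physical-root", multiple = FALSE)
  if (is.na(sol$nu)) {
    out <- new("SteadyState", xStar = 1 - f, yStar = 0, nuStar = 0,
               cStar = f, eEff = eEff, regime = "phage-extinct",
               phageExtinct = TRUE, residual = 0)
    return(out)
  }
  nu <- sol$nu
  w <- 1 - eEff * nu
  xStar <- f * gC0 / (alC0 * (B * pV * w - 1))
  cStar <- f / (f + xStar)
  yStar <- gC0 * (cStar - f) / (alC0 * pV * w)
  totals <- c(nBs = nu * xStar, nV = yStar, nB0 = (1 - nu) * xStar,
              C = cStar) * params@C0
  rhs <- odeRHS(totals, params, eEff)
  residual <- max(abs(rhs) / (gC0 * pmax(totals, 1)))
  regime <- sol$regime
  if (sol$multiple) regime <- paste0(regime, "+multiple")
  new("SteadyState", xStar = xStar, yStar = yStar, nuStar = nu,
      cStar = cStar, eEff = eEff, regime = regime, phageExtinct = FALSE,
      residual = residual)
}

setMethod("show", "SteadyState", function(object) {
  cat(sprintf(
    "SteadyState (e_eff=%.4g, %s): x*=%.4g y*=%.4g nu*=%.4g C*/C0=%.4g (residual %.1e)\n",
    object@eEff, object@regime, object@xStar, object@yStar, object@nuStar,
    object@cStar, object@residual))
})
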