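## Closed-form and sampling toy models linking CRISPR array length,
## protospacer repertoire structure, and average immunity.

#' Average immunity as a function of CRISPR array length
#'
#' If a single spacer gives baseline immunity \eqn{a_1}, each additional
#' spacer reduces the remaining susceptibility by the same factor
#' \eqn{C = 1 - a_1}, giving \eqn{a_n = 1 - (1-a_1)^n}: immunity gains
#' diminish as arrays grow (an array twice as long is less than twice as
#' immune).
#'
#' @param a1 baseline single-spacer immunity in [0, 1].
#' @param n array length (non-negative integer, vectorized).
#' @return immunity \eqn{a_n}.
#' @examples
#' arrayImmunity(0.5, 2)  # 0.75
#' @export
arrayImmunity <- function(a1, n) {
  stopifnot(a1 >= 0, a1 <= 1, all(n >= 0), all(n == round(n)))
  1 - (1 - a1)^n
}

#' Expected initial average immunity of a strain mixture
#'
#' Equal proportions of \code{m} CRISPR strains face one escape phage that
#' infects exactly one of them (spacer effectiveness 1). Without a surface
#' mutant the average immunity is \eqn{(m-1)/m}; adding one
#' always-resistant surface-mutant strain in equal proportion gives
#' \eqn{m/(m+1)}.
#'
#' @param m number of CRISPR strains (>= 1).
#' @param includeSurface include the surface-mutant strain.
#' @return expected average immunity.
#' @examples
#' strainMixtureImmunity(3)                        # 2/3
#' strainMixtureImmunity(3, includeSurface = TRUE) # 3/4
#' @export
strainMixtureImmunity <- function(m, includeSurface = FALSE) {
  stopifnot(m >= 1)
  if (includeSurface) m / (m + 1) else (m - 1) / m
}

## sample spacer tokens from the pool under the abundance law
.sampleTokens <- function(poolTypes, n, law, meanRank) {
  k <- length(poolTypes)
  w <- switch(law,
    uniform = rep(1, k),
    exponential = {
      p <- 1 / meanRank                 # geometric weights over ranks
      (1 - p)^(seq_len(k) - 1)
    })
  sample(poolTypes, n, replace = TRUE, prob = w)
}

## partition n tokens into arrays under the length law
.arrayLengths <- function(nTokens, meanLen, law, sdGauss = 2) {
  lens <- integer(0)
  used <- 0L
  while (used < nTokens) {
    l <- switch(law,
      constant = meanLen,
      gaussian = max(1L, round(stats::rnorm(1, meanLen, sdGauss))),
      exponential = max(1L, round(stats::rexp(1, 1 / meanLen))))
    l <- min(l, nTokens - used)
    lens <- c(lens, l)
    used <- used + l
  }
  lens
}

#' Sample average immunity versus diversity for structured repertoires
#'
#' Builds synthetic phage protospacer arrays and bacterial spacer arrays
#' from a pool of unique sequences and scores the organism-level
#' set-overlap average immunity (any shared element makes the bacterium
#' immune; effectiveness 1). Three protospacer-origin scenarios:
#' \code{"random"} draws each phage's protospacers independently
#' (evolutionarily diverse population); \code{"sweeps"} mimics successive
#' selective sweeps (phage k carries novel protospacers in its first
#' positions); \code{"last"} varies only the final protospacer on a
#' shared backbone (clonal population under rapid escape mutation, where
#' multi-spacer bacteria can always target the conserved positions).
#'
#' @param poolSize number of unique protospacer sequences available.
#' @param nPhages number of phages.
#' @param protospacersPerPhage protospacers per phage (x).
#' @param spacersPerBacterium mean spacers per bacterium (n).
#' @param lengthLaw array-length law: \code{"constant"},
#'   \code{"gaussian"} (sd 2) or \code{"exponential"}.
#' @param abundanceLaw spacer sampling weights over ranked pool types:
#'   \code{"uniform"} or \code{"exponential"} (geometric with mean rank
#'   \code{abundanceMean}).
#' @param assignment protospacer origin scenario (above).
#' @param nSpacers total spacer tokens sampled into arrays.
#' @param abundanceMean mean rank of the geometric abundance law.
#' @param replicates independent array-assortment repetitions.
#' @param seed optional seed.
#' @return list with \code{meanImmunity}, \code{sdImmunity},
#'   \code{immunity} (per replicate), and \code{diversity} (unique types
#'   in use).
#' @export
assortAndScore <- function(poolSize, nPhages = 100L,
                           protospacersPerPhage = 1L,
                           spacersPerBacterium = 1L,
                           lengthLaw = c("constant", "gaussian",
                                         "exponential"),
                           abundanceLaw = c("exponential", "uniform"),
                           assignment = c("random", "sweeps", "last"),
                           nSpacers = 1000L, abundanceMean = 6,
                           replicates = 20L, seed = NULL) {
  lengthLaw <- match.arg(lengthLaw)
  abundanceLaw <- match.arg(abundanceLaw)
  assignment <- match.arg(assignment)
  x <- protospacersPerPhage
  stopifnot(x >= 1, spacersPerBacterium >= 1, poolSize >= x)
  if (!is.null(seed)) set.seed(seed)
  pool <- seq_len(poolSize)

  phageArrays <- switch(assignment,
    random = lapply(seq_len(nPhages), function(i) sample(pool, x)),
    sweeps = {
      extra <- setdiff(pool, seq_len(x))
      lapply(seq_len(nPhages), function(k) {
        arr <- seq_len(x)
        nSwap <- min(k - 1L, x)
        if (nSwap > 0 && length(extra)) {
          idx <- ((k - 2L) * nSwap + seq_len(nSwap) - 1L) %%
            length(extra) + 1L
          arr[seq_len(nSwap)] <- extra[idx]
        }
        arr
      })
    },
    last = {
      extra <- setdiff(pool, seq_len(x))
      lapply(seq_len(nPhages), function(k) {
        arr <- seq_len(x)
        if (length(extra))
          arr[x] <- extra[(k - 1L) %% length(extra) + 1L]
        arr
      })
    })
  pMat <- matrix(FALSE, nPhages, poolSize)
  for (i in seq_len(nPhages)) pMat[i, phageArrays[[i]]] <- TRUE

  imm <- numeric(replicates)
  for (rep in seq_len(replicates)) {
    tokens <- .sampleTokens(pool, nSpacers, abundanceLaw, abundanceMean)
    lens <- .arrayLengths(nSpacers, spacersPerBacterium, lengthLaw)
    idx <- rep(seq_along(lens), lens)
    bMat <- matrix(FALSE, length(lens), poolSize)
    bMat[cbind(idx, tokens)] <- TRUE
    overlap <- (bMat %*% t(pMat)) > 0
    imm[rep] <- mean(overlap)
  }
  list(meanImmunity = mean(imm),
       sdImmunity = if (replicates > 1) stats::sd(imm) else NA_real_,
       immunity = imm,
       diversity = length(unique(unlist(phageArrays))))
}
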