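## Binary protospacer/spacer sequence space.
##
## A type is a bit pattern of length L <= 30 stored in a single R integer;
## bit k (0-based, lowest first) is position k of the sequence. Serialized
## form is a left-to-right 0/1 string, character k+1 = bit k.

.POPCOUNT16 <- local({
  tab <- integer(65536L)
  for (b in 0:15) {
    idx <- which(bitwAnd(0:65535, bitwShiftL(1L, b)) != 0L)
    tab[idx] <- tab[idx] + 1L
  }
  tab
})

.popcount <- function(x) {
  .POPCOUNT16[bitwAnd(x, 65535L) + 1L] +
    .POPCOUNT16[bitwShiftR(x, 16L) + 1L]
}

#' Hamming (L1) distance between binary sequences
#'
#' The mutational distance between two types: the number of positions at
#' which their bits differ. Vectorized with recycling.
#'
#' @param s1,s2 integer-coded sequences (see \code{\link{stringToSeq}}).
#' @return non-negative integer distance(s) in \code{[0, L]}.
#' @examples
#' hammingDistance(stringToSeq("01"), stringToSeq("11"))  # 1
#' @export
hammingDistance <- function(s1, s2) {
  s1 <- as.integer(s1); s2 <- as.integer(s2)
  if (anyNA(s1) || anyNA(s2)) stop("sequences must not contain NA")
  .popcount(bitwXor(s1, s2))
}

#' Serialize an integer-coded sequence to a 0/1 string
#'
#' @param s integer-coded sequence(s).
#' @param L sequence length in bits.
#' @return character vector of fixed-width 0/1 strings; character k is bit
#'   k-1 (lowest bit first).
#' @export
seqToString <- function(s, L = 30L) {
  s <- as.integer(s)
  vapply(s, function(x)
    paste(bitwAnd(bitwShiftR(x, 0:(L - 1L)), 1L), collapse = ""),
    character(1))
}

#' Parse a 0/1 string into an integer-coded sequence
#'
#' @param str character vector of 0/1 strings (all the same length, at most
#'   30 bits).
#' @return integer vector of sequence codes.
#' @export
stringToSeq <- function(str) {
  L <- unique(nchar(str))
  if (length(L) != 1L) stop("all strings must have equal length")
  if (L > 30L) stop("at most 30 bits are supported")
  vapply(str, function(x) {
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    if (!all(ch %in% c("0", "1"))) stop("not a 0/1 string: ", x)
    sum(bitwShiftL(as.integer(ch), 0:(L - 1L)))
  }, integer(1), USE.NAMES = FALSE)
}

## Draw a flip mask for one offspring with k >= 1 flipped bits.
.flipMasks <- function(nFlips, L) {
  vapply(nFlips, function(k) {
    pos <- sample.int(L, k) - 1L
    sum(bitwShiftL(1L, pos))
  }, integer(1))
}

## Truncated-at-zero binomial: number of flips per mutated offspring.
.rFlipCount <- function(n, L, mu) {
  if (n == 0L) return(integer(0))
  if (mu >= 1) return(rep(L, n))
  k <- 1:L
  p <- stats::dbinom(k, L, mu)
  sample(k, n, replace = TRUE, prob = p)
}

#' Draw the offspring of one phage burst with mutation
#'
#' Each of the \code{B * L} bits of the burst flips independently with
#' probability \code{mu}, so an individual offspring carries one or more
#' mutations with probability \eqn{1-(1-\mu)^L}. Offspring that differ from
#' the parent are new mutant types (which may, rarely, coincide with an
#' existing type).
#'
#' @param parent integer-coded parent protospacer.
#' @param B burst size (number of offspring).
#' @param mu per-base per-replication mutation probability.
#' @param L protospacer length.
#' @return integer vector of \code{B} offspring sequence codes.
#' @export
drawBurstOffspring <- function(parent, B, mu, L = 30L) {
  if (mu < 0 || mu > 1) stop("mu must lie in [0, 1]")
  if (B < 1) stop("B must be >= 1")
  parent <- as.integer(parent)
  off <- rep.int(parent, B)
  if (mu == 0) return(off)
  nMut <- stats::rbinom(1L, B, 1 - (1 - mu)^L)
  if (nMut > 0L) {
    which <- sample.int(B, nMut)
    masks <- .flipMasks(.rFlipCount(nMut, L, mu), L)
    off[which] <- bitwXor(off[which], masks)
  }
  off
}

## Bulk form used by the engines: for nOffspring total phage offspring of
## one parent type, return the integer codes of the mutated ones only
## (the remainder are parental copies).
.drawMutants <- function(parent, nOffspring, mu, L) {
  if (mu == 0 || nOffspring == 0) return(integer(0))
  nMut <- stats::rbinom(1L, nOffspring, 1 - (1 - mu)^L)
  if (nMut == 0L) return(integer(0))
  masks <- .flipMasks(.rFlipCount(nMut, L, mu), L)
  bitwXor(as.integer(parent), masks)
}

#' Infection success probability of a phage against one bacterium
#'
#' The pairwise kernel \eqn{p_V(i, j)}. A naive bacterium (no spacer) is
#' killed with probability \code{pV}. For a spacer at mutational distance
#' \eqn{d} from the protospacer: all-or-nothing immunity gives
#' \eqn{p_V(1-e)} iff \eqn{d = 0}; exponential cross-reactivity gives
#' \eqn{p_V(1 - e\,e^{-d/\theta})}; step cross-reactivity gives
#' \eqn{p_V(1-e)} iff \eqn{d \le \theta}. \code{theta = 0} with mode
#' \code{"exponential"} is defined as the all-or-nothing kernel.
#'
#' @param spacer integer-coded spacer, or \code{NA} for a naive bacterium.
#' @param protospacer integer-coded protospacer.
#' @param pV naive infection success probability.
#' @param e spacer effectiveness.
#' @param xr a \linkS4class{CrossReactivity} kernel.
#' @return probability in \code{[pV(1-e), pV]}; vectorized with recycling.
#' @examples
#' infectionSuccess(NA, 0L, pV = 0.02, e = 0.95)            # 0.02
#' infectionSuccess(5L, 5L, pV = 0.02, e = 0.95)            # 0.001
#' @export
infectionSuccess <- function(spacer, protospacer, pV, e,
                             xr = crossReactivity("none")) {
  n <- max(length(spacer), length(protospacer))
  spacer <- rep_len(spacer, n); protospacer <- rep_len(protospacer, n)
  out <- rep_len(pV, n)
  has <- !is.na(spacer)
  if (!any(has)) return(out)
  d <- hammingDistance(spacer[has], protospacer[has])
  out[has] <- infectionSuccessD(d, pV, e, xr)
  out
}

#' Infection success as a function of mutational distance
#'
#' Distance-based form of \code{\link{infectionSuccess}} for bacteria that
#' carry a spacer.
#'
#' @param d non-negative mutational distance(s).
#' @inheritParams infectionSuccess
#' @return probability vector, same length as \code{d}.
#' @export
infectionSuccessD <- function(d, pV, e, xr = crossReactivity("none")) {
  stopifnot(pV >= 0, pV <= 1, e >= 0, e <= 1, all(d >= 0))
  mode <- xr@mode; theta <- xr@theta
  if (theta == 0) mode <- "none"
  switch(mode,
    none = pV * (1 - e * (d == 0)),
    exponential = pV * (1 - e * exp(-d / theta)),
    step = pV * (1 - e * (d <= theta)))
}
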