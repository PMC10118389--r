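## IO for configurations, the synthetic fixture generator, and helpers
## behind the command-line wrapper (inst/cli/crispr-coevo.R).

#' Generate a synthetic paired abundance fixture
#'
#' Emulates the statistical shape of experiment-derived clone-count
#' tables without any sequencing input: clone sizes are drawn from an
#' exponential law (rounded up to at least 1), a chosen fraction of
#' bacterial types is matched by a phage type with the same label, and at
#' each step every type (matched pairs jointly) is replaced by a fresh
#' label with the turnover probability. Sizes are redrawn independently
#' at every time point; type identity carries the temporal signal.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param seed integer seed.
#' @return list with \code{bacteria} and \code{phage}
#'   \linkS4class{AbundanceSeries}.
#' @export
generateFixture <- function(spec = new("FixtureSpec"), seed = 1L) {
  validObject(spec)
  set.seed(seed)
  nT <- spec@nTimes
  times <- seq(0, by = spec@dt, length.out = nT)
  nBt <- spec@nBacteriaTypes; nVt <- spec@nPhageTypes
  nShared <- round(spec@overlap * nBt)
  if (nShared > nVt) stop("overlap asks for more shared types than phage types")
  counter <- 0L
  fresh <- function(n) {
    ids <- sprintf("t%06d", counter + seq_len(n))
    counter <<- counter + n
    ids
  }
  shared <- fresh(nShared)
  bOnly <- fresh(nBt - nShared)
  vOnly <- fresh(nVt - nShared)
  bTypes <- matrix("", nBt, nT); vTypes <- matrix("", nVt, nT)
  bTypes[, 1] <- c(shared, bOnly)
  vTypes[, 1] <- c(shared, vOnly)
  for (k in 2:nT) {
    bTypes[, k] <- bTypes[, k - 1]; vTypes[, k] <- vTypes[, k - 1]
    ## matched pairs turn over jointly so the overlap fraction is stable
    pairFlip <- stats::runif(nShared) < spec@turnover
    if (any(pairFlip)) {
      nf <- fresh(sum(pairFlip))
      bTypes[seq_len(nShared)[pairFlip], k] <- nf
      vTypes[seq_len(nShared)[pairFlip], k] <- nf
    }
    soloB <- which(stats::runif(nBt - nShared) < spec@turnover)
    if (length(soloB)) bTypes[nShared + soloB, k] <- fresh(length(soloB))
    soloV <- which(stats::runif(nVt - nShared) < spec@turnover)
    if (length(soloV)) vTypes[nShared + soloV, k] <- fresh(length(soloV))
  }
  build <- function(typeMat, nTypes, pop) {
    allTypes <- sort(unique(as.vector(typeMat)))
    cnt <- matrix(0, length(allTypes), nT)
    for (k in seq_len(nT)) {
      sizes <- pmax(1, round(stats::rexp(nTypes, 1 / spec@meanCloneSize)))
      cnt[match(typeMat[, k], allTypes), k] <- sizes
    }
    abundanceSeries(times, allTypes, cnt, pop, spec@units)
  }
  list(bacteria = build(bTypes, nBt, "bacteria"),
       phage = build(vTypes, nVt, "phage"))
}

.CONFIG_KEYS <- c("C0", "gC0", "f", "alphaC0", "B", "pV", "e", "R", "eta",
                  "mu", "L", "xr.mode", "xr.theta",
                  "tEndGen", "seed", "snapshots", "nV0", "mInit")

#' Write a run configuration
#'
#' Flat \code{key = value} file naming every parameter field exactly as in
#' \linkS4class{SimParams}, plus optional run keys (\code{tEndGen},
#' \code{seed}, \code{snapshots}, \code{nV0}, \code{mInit}).
#'
#' @param params a \linkS4class{SimParams}.
#' @param path output file.
#' @param extra named list of run keys.
#' @return invisibly, the path.
#' @export
writeRunConfig <- function(params, path, extra = list()) {
  kv <- c(C0 = params@C0, gC0 = params@gC0, f = params@f,
          alphaC0 = params@alphaC0, B = params@B, pV = params@pV,
          e = params@e, R = params@R, eta = params@eta, mu = params@mu,
          L = params@L)
  lines <- c(sprintf("%s = %.17g", names(kv), kv),
             sprintf("xr.mode = %s", params@xr@mode),
             sprintf("xr.theta = %g", params@xr@theta))
  for (n in names(extra)) {
    if (!n %in% .CONFIG_KEYS) stop("unknown config key: ", n)
    lines <- c(lines, sprintf("%s = %g", n, extra[[n]]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#'
#' Unknown keys are errors (guards against silent typos in parameter
#' sweeps).
#'
#' @param path a file written by \code{\link{writeRunConfig}} (or by
#'   hand in the same format).
#' @return list with \code{params} (a \linkS4class{SimParams}) and
#'   \code{extra} (run keys).
#' @export
readRunConfig <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1])
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  unknown <- setdiff(keys, .CONFIG_KEYS)
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  if (anyDuplicated(keys)) stop("duplicate config key")
  get <- function(k, default) if (k %in% keys)
    as.numeric(vals[keys == k]) else default
  xr <- crossReactivity(
    if ("xr.mode" %in% keys) vals[keys == "xr.mode"] else "none",
    get("xr.theta", 0))
  params <- simParams(C0 = get("C0", 1e4), gC0 = get("gC0", 2.4e-2),
                      f = get("f", 0.3), alphaC0 = get("alphaC0", 2e-2),
                      B = get("B", 170), pV = get("pV", 0.02),
                      e = get("e", 0.95), R = get("R", 0.04),
                      eta = get("eta", 1e-3), mu = get("mu", 1e-5),
                      L = get("L", 30), xr = xr)
  extra <- list()
  for (k in c("tEndGen", "seed", "snapshots", "nV0", "mInit"))
    if (k %in% keys) extra[[k]] <- as.numeric(vals[keys == k])
  list(params = params, extra = extra)
}

#' Write the totals table of a run as TSV
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeTotalsTSV <- function(result, path) {
  utils::write.table(result@totals, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the clone log of a run as TSV
#'
#' @param clones data.frame from \code{\link{recordClones}}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeCloneLogTSV <- function(clones, path) {
  utils::write.table(clones, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
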