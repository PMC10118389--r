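#' Construct an abundance series
#'
#' @param times time points (strictly increasing after ordering).
#' @param types clone identifiers, one per row of \code{counts}.
#' @param counts numeric matrix, types by times.
#' @param population \code{"bacteria"} or \code{"phage"}.
#' @param units time units.
#' @return an \linkS4class{AbundanceSeries}.
#' @export
abundanceSeries <- function(times, types, counts,
                            population = c("bacteria", "phage"),
                            units = c("minutes", "generations", "days")) {
  population <- match.arg(population)
  units <- match.arg(units)
  counts <- as.matrix(counts)
  o <- order(times)
  new("AbundanceSeries", times = as.numeric(times)[o],
      types = as.character(types), counts = counts[, o, drop = FALSE],
      population = population, units = units)
}

#' @describeIn abundanceSeries time points of a series.
#' @param x an \linkS4class{AbundanceSeries}.
#' @export
seriesTimes <- function(x) x@times

#' @describeIn abundanceSeries type identifiers of a series.
#' @export
seriesTypes <- function(x) x@types

#' @describeIn abundanceSeries counts matrix (types by times).
#' @export
seriesCounts <- function(x) {
  m <- x@counts
  dimnames(m) <- list(x@types, x@times)
  m
}

setMethod("show", "AbundanceSeries", function(object) {
  cat(sprintf(
    "AbundanceSeries (%s): %d types x %d times [%g..%g %s]\n",
    object@population, length(object@types), length(object@times),
    min(object@times), max(object@times), object@units))
})

#' Interpolate a series onto a regular grid
#'
#' Linear interpolation of counts onto a grid at the minimum sampling
#' interval (or a supplied interval), the convention used before averaging
#' time-shifted statistics. Interpolants are convex combinations, so no
#' negative counts can arise; presence after interpolation means
#' count > 0.
#'
#' @param x an \linkS4class{AbundanceSeries}.
#' @param interval grid spacing; default the minimum sampling interval.
#' @return an \linkS4class{AbundanceSeries} on the regular grid.
#' @export
interpolateSeries <- function(x, interval = NULL) {
  if (length(x@times) < 2) return(x)
  if (is.null(interval)) interval <- min(diff(x@times))
  grid <- seq(x@times[1], x@times[length(x@times)], by = interval)
  cnt <- t(apply(x@counts, 1, function(row)
    stats::approx(x@times, row, xout = grid)$y))
  if (length(grid) == 1L) cnt <- matrix(cnt, ncol = 1)
  abundanceSeries(grid, x@types, cnt, x@population, x@units)
}

#' Trim head and tail time points
#'
#' @param x an \linkS4class{AbundanceSeries}.
#' @param head,tail number of points to drop from each end.
#' @return the trimmed series.
#' @export
trimSeries <- function(x, head = 0L, tail = 0L) {
  n <- length(x@times)
  keep <- seq_len(n)
  if (head > 0) keep <- keep[-seq_len(head)]
  if (tail > 0) keep <- keep[seq_len(length(keep) - tail)]
  if (!length(keep)) stop("trimming removed all time points")
  abundanceSeries(x@times[keep], x@types,
                  x@counts[, keep, drop = FALSE], x@population, x@units)
}

#' Extract paired abundance series from a simulation
#'
#' Builds bacteria and phage series from the recorded snapshots (the
#' steady-state window by default), with types serialized as 0/1 strings.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param units report times in \code{"generations"} or \code{"minutes"}.
#' @return list with elements \code{bacteria} and \code{phage}.
#' @export
asAbundanceSeries <- function(result,
                              units = c("generations", "minutes")) {
  units <- match.arg(units)
  snaps <- result@snapshots
  if (!length(snaps)) stop("result has no snapshots")
  times <- vapply(snaps, function(s) s@time, numeric(1))
  if (units == "generations") times <- times * result@params@gC0
  L <- result@params@L
  build <- function(getSeq, getCnt, pop) {
    allSeq <- sort(unique(unlist(lapply(snaps, getSeq))))
    cnt <- matrix(0, length(allSeq), length(snaps))
    for (k in seq_along(snaps)) {
      i <- match(getSeq(snaps[[k]]), allSeq)
      cnt[i, k] <- getCnt(snaps[[k]])
    }
    types <- if (length(allSeq)) seqToString(allSeq, L) else character(0)
    abundanceSeries(times, types, cnt, pop, units)
  }
  list(bacteria = build(function(s) s@bacteriaSeq,
                        function(s) s@bacteriaCount, "bacteria"),
       phage = build(function(s) s@phageSeq,
                     function(s) s@phageCount, "phage"))
}

#' Write an abundance series as TSV
#'
#' Long format with header \code{time  population  type  count}, UTF-8,
#' tab-delimited. Zero counts are omitted.
#'
#' @param x an \linkS4class{AbundanceSeries}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeAbundanceSeries <- function(x, path) {
  rows <- which(x@counts != 0, arr.ind = TRUE)
  df <- data.frame(time = x@times[rows[, 2]],
                   population = x@population,
                   type = x@types[rows[, 1]],
                   count = x@counts[rows])
  df <- df[order(df$time, df$type), ]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# units=%s", x@units), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an abundance series from TSV
#'
#' Expects the format written by \code{\link{writeAbundanceSeries}};
#' validates the header, rejects duplicate (time, type) cells and negative
#' counts, and reports the offending line on malformed rows.
#'
#' @param path input file.
#' @return an \linkS4class{AbundanceSeries}.
#' @export
readAbundanceSeries <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  units <- "minutes"
  offset <- 1L                      # header line
  if (length(lines) && grepl("^# units=", lines[1])) {
    units <- sub("^# units=", "", lines[1])
    lines <- lines[-1]
    offset <- 2L
  }
  if (!length(lines) || !identical(strsplit(lines[1], "\t")[[1]],
                                   c("time", "population", "type", "count")))
    stop("missing or malformed header: expected 'time\tpopulation\ttype\tcount'")
  if (length(lines) < 2) stop("no data rows")
  body <- strsplit(lines[-1], "\t", fixed = TRUE)
  nf <- lengths(body)
  if (any(nf != 4L))
    stop("malformed row at line ", which(nf != 4L)[1] + offset)
  df <- data.frame(time = suppressWarnings(
                     as.numeric(vapply(body, `[`, "", 1L))),
                   population = vapply(body, `[`, "", 2L),
                   type = vapply(body, `[`, "", 3L),
                   count = suppressWarnings(
                     as.numeric(vapply(body, `[`, "", 4L))))
  if (anyNA(df$time) || anyNA(df$count)) {
    bad <- which(is.na(df$time) | is.na(df$count))[1]
    stop("non-numeric time or count at line ", bad + offset)
  }
  pop <- unique(df$population)
  if (length(pop) != 1L)
    stop("one file must contain a single population")
  if (anyDuplicated(df[, c("time", "type")]))
    stop("duplicate (time, type) cell")
  times <- sort(unique(df$time))
  types <- sort(unique(df$type))
  cnt <- matrix(0, length(types), length(times))
  cnt[cbind(match(df$type, types), match(df$time, times))] <- df$count
  abundanceSeries(times, types, cnt, pop, units)
}

## counts of one time point as a named vector (types with count > 0)
.sliceCounts <- function(x, k) {
  v <- x@counts[, k]
  names(v) <- x@types
  v[v > 0]
}
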