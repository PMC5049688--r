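#' Interval sets: ancestral material on a genome
#'
#' An `interval_set` is a sorted list of disjoint, non-adjacent half-open
#' intervals `[start, end)` in 0-based genome coordinates. It is the data
#' structure used throughout to represent the ancestral material of a
#' lineage, conversion-tract footprints and resolved regions. Construction
#' canonicalizes: intervals are sorted and overlapping or abutting intervals
#' are merged, so the representation of a set of sites is unique. On a
#' circular genome a tract wrapping the origin is stored as two intervals
#' (`[s, G)` and `[0, e)`); no operation ever sees a wrapped raw pair.
#'
#' @param starts,ends Integer vectors of equal length (interval bounds),
#'   or `starts` may be a two-column matrix.
#' @return An object of class `interval_set`: an integer matrix with
#'   columns `start` and `end`.
#' @examples
#' interval_set(c(0, 3), c(3, 6))   # merges to [0, 6)
#' @export
interval_set <- function(starts = integer(), ends = integer()) {
  if (is.matrix(starts)) {
    ends <- starts[, 2L]
    starts <- starts[, 1L]
  }
  starts <- as.integer(starts); ends <- as.integer(ends)
  if (length(starts) != length(ends)) stop("starts/ends length mismatch")
  if (any(ends <= starts)) stop("intervals must satisfy start < end")
  if (length(starts) > 1L) {
    o <- order(starts)
    starts <- starts[o]; ends <- ends[o]
    # merge overlapping or abutting
    ks <- integer(0); ke <- integer(0)
    cs <- starts[1L]; ce <- ends[1L]
    for (i in seq_along(starts)[-1L]) {
      if (starts[i] <= ce) ce <- max(ce, ends[i])
      else { ks <- c(ks, cs); ke <- c(ke, ce); cs <- starts[i]; ce <- ends[i] }
    }
    starts <- c(ks, cs); ends <- c(ke, ce)
  }
  new_interval_set(cbind(starts, ends))
}

new_interval_set <- function(m) {
  m <- matrix(as.integer(m), ncol = 2L,
              dimnames = list(NULL, c("start", "end")))
  class(m) <- c("interval_set", class(m))
  m
}

#' @export
print.interval_set <- function(x, ...) {
  if (nrow(x) == 0L) cat("interval_set: {} (empty)\n")
  else cat("interval_set:",
           paste(sprintf("[%d,%d)", x[, 1L], x[, 2L]), collapse = " "),
           sprintf(" (%d sites)\n", total_sites(x)))
  invisible(x)
}

empty_set <- function() new_interval_set(matrix(integer(), ncol = 2L))

#' Total number of sites in an interval set
#' @param x An [interval_set].
#' @return Integer, the sum of interval lengths.
#' @export
total_sites <- function(x) {
  if (nrow(x) == 0L) return(0L)
  sum(x[, 2L] - x[, 1L])
}

#' Set algebra on interval sets
#'
#' Exact set semantics on sites; results are in canonical form. Both
#' operands must live on the same genome map (coordinates are not checked
#' against a map here; the caller guarantees it).
#'
#' @param a,b [interval_set] objects.
#' @return An [interval_set].
#' @name set_ops
NULL

#' @rdname set_ops
#' @export
iset_union <- function(a, b) {
  m <- rbind(unclass(a), unclass(b))
  if (nrow(m) == 0L) return(empty_set())
  interval_set(m)
}

#' @rdname set_ops
#' @export
iset_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty_set())
  ks <- integer(0); ke <- integer(0)
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a[i, 1L], b[j, 1L])
    e <- min(a[i, 2L], b[j, 2L])
    if (s < e) { ks <- c(ks, s); ke <- c(ke, e) }
    if (a[i, 2L] < b[j, 2L]) i <- i + 1L else j <- j + 1L
  }
  new_interval_set(cbind(ks, ke))
}

#' @rdname set_ops
#' @export
iset_diff <- function(a, b) {
  if (nrow(a) == 0L) return(empty_set())
  if (nrow(b) == 0L) return(a)
  ks <- integer(0); ke <- integer(0)
  j <- 1L
  for (i in seq_len(nrow(a))) {
    s <- a[i, 1L]; e <- a[i, 2L]
    while (j <= nrow(b) && b[j, 2L] <= s) j <- j + 1L
    jj <- j
    while (jj <= nrow(b) && b[jj, 1L] < e) {
      if (b[jj, 1L] > s) { ks <- c(ks, s); ke <- c(ke, b[jj, 1L]) }
      s <- max(s, b[jj, 2L])
      jj <- jj + 1L
    }
    if (s < e) { ks <- c(ks, s); ke <- c(ke, e) }
  }
  new_interval_set(cbind(ks, ke))
}

iset_equal <- function(a, b) {
  nrow(a) == nrow(b) && all(unclass(a) == unclass(b))
}

#' Sites of an interval set as an integer vector
#' @param x An [interval_set].
#' @return Integer vector of member sites (0-based). Intended for small
#'   sets (oracles, tests).
#' @export
iset_sites <- function(x) {
  if (nrow(x) == 0L) return(integer())
  unlist(lapply(seq_len(nrow(x)), function(i) seq.int(x[i, 1L], x[i, 2L] - 1L)))
}

#' Build an interval set from member sites
#' @param sites Integer vector of 0-based sites.
#' @return The canonical [interval_set] containing exactly those sites.
#' @export
iset_from_sites <- function(sites) {
  sites <- sort(unique(as.integer(sites)))
  if (length(sites) == 0L) return(empty_set())
  brk <- c(0L, which(diff(sites) > 1L), length(sites))
  starts <- sites[brk[-length(brk)] + 1L]
  ends <- sites[brk[-1L]] + 1L
  new_interval_set(cbind(starts, ends))
}

#' Genomic footprint of a conversion tract
#'
#' Returns the set of sites covered by a conversion tract beginning at
#' `start` with the given length. On a circular genome the tract wraps
#' around the origin (a length `>= G` covers the full genome); on a linear
#' genome it is truncated at the end of the genome.
#'
#' @param start 0-based start site, in `[0, G)`.
#' @param length Tract length in sites, `>= 1`.
#' @param genome A [genome_map].
#' @return An [interval_set] in canonical form.
#' @examples
#' g <- genome_map(10)
#' wrap_interval(8, 4, g)   # {[8,10), [0,2)}
#' @export
wrap_interval <- function(start, length, genome) {
  G <- genome$total_length
  start <- as.integer(start)
  if (is.na(start) || start < 0L || start >= G)
    stop("tract start outside [0, G)")
  if (length < 1) stop("tract length must be >= 1")
  if (!is_circular(genome))
    return(new_interval_set(cbind(start, min(start + length, G))))
  if (length >= G) return(new_interval_set(cbind(0L, G)))
  e <- (start + as.integer(length)) %% G
  if (e > start) new_interval_set(cbind(start, e))
  else if (e == 0L) new_interval_set(cbind(start, G))
  else new_interval_set(cbind(c(0L, start), c(e, G)))
}
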