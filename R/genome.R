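#' Define a genome map
#'
#' A genome map is the coordinate system every other object lives on: a
#' total length `G` in sites, a topology (circular, as for most bacterial
#' chromosomes, or linear), and a fragment layout. A fragment layout
#' describes a partially assembled ("fragmented") genome as an ordered list
#' of fragment lengths, each followed by a gap of unsequenced sites. Gap
#' sites are first-class coordinates -- conversion tracts may start in or
#' span them, preserving long-range correlation along the replicon -- but
#' they carry no sequence output and are excluded from ancestral-material
#' bookkeeping.
#'
#' Coordinates are 0-based and intervals half-open `[start, end)`.
#'
#' @param length Total genome length in sites (used for a whole,
#'   unfragmented genome; equivalent to one fragment with no gap).
#' @param fragments Either a two-column matrix / data.frame with columns
#'   `length` and `gap` (gap follows the fragment), or a character string
#'   `"len:gap,len:gap,..."` as accepted on the command line. The gap after
#'   the last fragment closes the circle and must be 0 on a linear genome.
#' @param circular Logical; circular (default) or linear topology.
#'
#' @return An object of class `genome_map` with elements `total_length`,
#'   `topology`, `fragments` (data.frame with `length`, `gap`) and `spans`
#'   (an [interval_set] of the sequence-bearing sites).
#' @examples
#' genome_map(1e4)                         # whole circular genome
#' genome_map(fragments = "500:20,300:0", circular = FALSE)
#' @export
genome_map <- function(length = NULL, fragments = NULL, circular = TRUE) {
  if (is.null(fragments)) {
    if (is.null(length)) stop("supply `length` or `fragments`")
    fragments <- data.frame(length = as.integer(length), gap = 0L)
  } else if (is.character(fragments)) {
    fragments <- parse_fragment_spec(fragments)
  } else {
    fragments <- as.data.frame(fragments)
    names(fragments) <- c("length", "gap")
  }
  fragments$length <- as.integer(fragments$length)
  fragments$gap <- as.integer(fragments$gap)
  if (any(fragments$length < 1L)) stop("fragment lengths must be >= 1")
  if (any(fragments$gap < 0L)) stop("fragment gaps must be >= 0")
  if (!circular && fragments$gap[nrow(fragments)] != 0L)
    stop("the gap after the last fragment must be 0 on a linear genome")
  G <- sum(fragments$length) + sum(fragments$gap)
  starts <- cumsum(c(0L, head(fragments$length + fragments$gap, -1L)))
  spans <- new_interval_set(cbind(starts, starts + fragments$length))
  structure(
    list(total_length = as.integer(G),
         topology = if (circular) "circular" else "linear",
         fragments = fragments,
         spans = spans),
    class = "genome_map")
}

parse_fragment_spec <- function(spec) {
  parts <- strsplit(strsplit(spec, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
  bad <- vapply(parts, length, 0L) != 2L
  if (length(parts) == 0L || any(bad))
    stop("fragment spec must be \"len:gap,len:gap,...\"")
  data.frame(length = as.integer(vapply(parts, `[`, "", 1L)),
             gap = as.integer(vapply(parts, `[`, "", 2L)))
}

#' @export
print.genome_map <- function(x, ...) {
  nf <- nrow(x$fragments)
  cat(sprintf("Genome map: %d sites, %s, %d fragment%s (%d sequence-bearing sites)\n",
              x$total_length, x$topology, nf, if (nf == 1L) "" else "s",
              total_sites(x$spans)))
  invisible(x)
}

is_circular <- function(genome) genome$topology == "circular"

#' Number of sequence-bearing sites of a genome map
#' @param genome A [genome_map].
#' @return Integer count of sites that appear in sequence output.
#' @export
sequence_length <- function(genome) total_sites(genome$spans)
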