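BASES <- c("A", "C", "G", "T")

# internal coding: 0..3 <-> A,C,G,T
seq_to_int <- function(x) {
  i <- match(x, BASES) - 1L
  if (anyNA(i)) stop("sequence contains characters outside {A,C,G,T}")
  i
}
int_to_seq <- function(i) BASES[i + 1L]

#' Draw a root sequence
#'
#' The sequence assigned at the root of every local genealogy: i.i.d.
#' uniform over A, C, G, T at each sequence-bearing site, the stationary
#' distribution of the Jukes-Cantor model.
#'
#' @param genome A [genome_map].
#' @return Character vector of length [sequence_length()] (gap sites carry
#'   no sequence and are absent).
#' @export
draw_root_sequence <- function(genome) {
  int_to_seq(sample.int(4L, sequence_length(genome), replace = TRUE) - 1L)
}

#' Evolve a sequence along a branch under Jukes-Cantor
#'
#' Each site receives a Poisson(`theta/2 * branch_length`) number of
#' substitutions; each substitution replaces the base by one of the other
#' three uniformly. Two sequences whose paths to a common ancestor total
#' branch length `t` therefore differ at a fraction
#' `3/4 (1 - exp(-(4/3)(theta/2) t))` of sites in expectation.
#'
#' @param seq Character vector over A,C,G,T.
#' @param branch_length Branch length in coalescent units, `>= 0`.
#' @param theta Scaled mutation rate (rate `theta/2` per site per unit).
#' @return The evolved sequence (character vector, same length).
#' @export
evolve_edge <- function(seq, branch_length, theta) {
  if (branch_length < 0) stop("branch_length must be >= 0")
  v <- seq_to_int(seq)
  L <- length(v)
  rate <- theta / 2 * branch_length
  if (rate > 0 && L > 0) {
    nm <- rpois(1L, rate * L)
    if (nm > 0) {
      pos <- sample.int(L, nm, replace = TRUE)
      shift <- sample.int(3L, nm, replace = TRUE)
      for (i in seq_len(nm))      # sequential so repeat hits compose
        v[pos[i]] <- (v[pos[i]] + shift[i]) %% 4L
    }
  }
  int_to_seq(v)
}

#' Inject external divergence into a root-homologous tract
#'
#' Builds the donor sequence of a between-species import: each
#' sequence-bearing site of the tract is, with probability `d`, replaced
#' by one of the other three bases uniformly, otherwise copied from the
#' root sequence. `d` is the per-site probability of differing from the
#' root homolog (drawn Uniform(D1, D2) at event time and stored on the
#' event record).
#'
#' @param root_seq Character vector: the root sequence over the genome's
#'   sequence-bearing sites (as from [draw_root_sequence()]).
#' @param tract An [interval_set] in genome coordinates; gap portions are
#'   ignored.
#' @param d Divergence in `[0, 0.75]`.
#' @param genome A [genome_map].
#' @return Character vector over the tract's sequence-bearing sites, with
#'   attribute `sites` giving their 0-based genome coordinates.
#' @export
apply_external_import <- function(root_seq, tract, d, genome) {
  if (d < 0 || d > 0.75) stop("divergence d must lie in [0, 0.75]")
  keep <- iset_intersect(tract, genome$spans)
  sites <- iset_sites(keep)
  cols <- match(sites, iset_sites(genome$spans))
  v <- seq_to_int(root_seq[cols])
  hit <- runif(length(v)) < d
  if (any(hit)) {
    v[hit] <- (v[hit] + sample.int(3L, sum(hit), replace = TRUE)) %% 4L
  }
  out <- int_to_seq(v)
  attr(out, "sites") <- sites
  out
}

#' Simulate a sequence alignment down an ARG
#'
#' Assigns the root sequence at every region's local most recent common
#' ancestor, then propagates tip-ward: content evolves under Jukes-Cantor
#' along every edge, is spliced from the donor- and recipient-side parents
#' at recombination splits, and is set to the diverged root homolog at
#' external-import nodes. Gap sites produce no columns; columns map 1:1,
#' in order, to the sequence-bearing genome coordinates.
#'
#' All local MRCAs receive the same single root sequence. Under
#' Jukes-Cantor stationarity this is marginally exact for every segment;
#' only the (unobservable at stationarity) correlation between the root
#' states of different segments is not modelled.
#'
#' @param arg A [simulate_arg()] result.
#' @param root_seq Optional root sequence (character vector of length
#'   [sequence_length()]); drawn with [draw_root_sequence()] if missing.
#' @return Character matrix (class `bacsim_alignment`) with `n` rows named
#'   `sample_1 ... sample_n`.
#' @export
simulate_alignment <- function(arg, root_seq = NULL) {
  stopifnot(inherits(arg, "bacsim_arg"))
  g <- arg$params$genome
  if (is.null(root_seq)) root_seq <- draw_root_sequence(g)
  if (length(root_seq) != sequence_length(g))
    stop("root_seq length does not match the genome's sequence-bearing sites")
  # scatter onto full genome coordinates (gap entries unused)
  full <- integer(g$total_length)
  full[iset_sites(g$spans) + 1L] <- seq_to_int(root_seq)
  nd <- arg$nodes
  m <- cpp_simulate_alignment(
    match(nd$kind, c("leaf", "coalescence", "recomb_split", "external_import")) - 1L,
    nd$time,
    ifelse(is.na(nd$child1), -1L, nd$child1 - 1L),
    ifelse(is.na(nd$child2), -1L, nd$child2 - 1L),
    ifelse(is.na(nd$parent_cont), -1L, nd$parent_cont - 1L),
    ifelse(is.na(nd$parent_don), -1L, nd$parent_don - 1L),
    nd$div,
    arg$arena[, 1L], arg$arena[, 2L],
    arg$snap_off, arg$snap_n, arg$aux_off, arg$aux_n,
    arg$res$node - 1L, arg$res$off, arg$res$n,
    unclass(g$spans), arg$params$n, full, arg$params$theta)
  out <- matrix(BASES[m + 1L], nrow = nrow(m))
  rownames(out) <- paste0("sample_", seq_len(nrow(out)))
  class(out) <- c("bacsim_alignment", class(out))
  attr(out, "genome") <- g
  out
}

#' @export
print.bacsim_alignment <- function(x, ...) {
  cat(sprintf("bacsim alignment: %d sequences x %d sites\n",
              nrow(x), ncol(x)))
  k <- min(60L, ncol(x))
  for (i in seq_len(min(nrow(x), 10L)))
    cat(sprintf("  %-10s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(k)], collapse = ""),
                if (ncol(x) > k) "..." else ""))
  if (nrow(x) > 10L) cat("  ...\n")
  invisible(x)
}
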