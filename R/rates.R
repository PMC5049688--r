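#' Effective recombination rates of a lineage
#'
#' The efficiency of the simulator rests on sampling only *effective*
#' recombination events. A within-species event with start `s` and
#' geometric tract length `l` is effective iff the tract footprint
#' bipartitions the lineage's ancestral material into two non-empty parts
#' (tract side and complement); a between-species event is effective iff
#' the tract touches ancestral material at all (its donor lives outside
#' the graph, so no bipartition is required). For each start site the
#' effective tract lengths form a contiguous range, so the per-start
#' probability is a difference of two geometric tails `q^k` with
#' `q = 1 - 1/delta`, and start sites group into a handful of categories
#' (material interior, interval starts, gap runs) whose weights have
#' closed forms. These functions return
#' `rho/2 * sum_s P(effective | start = s)`, the lineage's total event
#' rate per coalescent time unit -- exactly equal to the brute-force
#' enumeration over all `(s, l)` pairs.
#'
#' Tract starts may fall in fragment gaps or outside material: only the
#' induced bipartition matters, so tracts starting in gaps that reach
#' material still count.
#'
#' @param material An [interval_set]: the lineage's ancestral material
#'   (non-empty; sites are in `[0, G)`).
#' @param genome A [genome_map].
#' @param delta Mean tract length in sites (geometric distribution).
#' @param rho Scaled per-site initiation rate (`R` for within-species,
#'   `R_e` for between-species).
#' @return Rate per coalescent time unit (numeric scalar).
#' @seealso [sample_within_event()], [sample_external_event()]
#' @examples
#' g <- genome_map(10, circular = FALSE)
#' effective_within_rate(interval_set(0, 10), g, delta = 2, rho = 1)
#' @export
effective_within_rate <- function(material, genome, delta, rho = 1) {
  if (total_sites(material) == 0L)
    stop("empty ancestral material: prune the lineage before rating it")
  0.5 * rho * cpp_within_weight(unclass(material), genome$total_length,
                                is_circular(genome), delta)
}

#' @rdname effective_within_rate
#' @export
effective_external_rate <- function(material, genome, delta, rho = 1) {
  if (total_sites(material) == 0L)
    stop("empty ancestral material: prune the lineage before rating it")
  0.5 * rho * cpp_external_weight(unclass(material), genome$total_length,
                                  is_circular(genome), delta)
}

#' Sample one effective recombination event
#'
#' Draws `(s, l)` from the joint law proportional to
#' `P(l) * [event effective]`, i.e. the tract-length distribution
#' conditioned on effectiveness -- the same decomposition that underlies
#' [effective_within_rate()], so sampling and rate agree by construction.
#' The within-species version guarantees that both the tract's intersection
#' with the material and its complement in the material are non-empty; the
#' external version guarantees that the tract touches material.
#'
#' @inheritParams effective_within_rate
#' @return A list with `s` (start site), `len` (raw tract length before
#'   any linear truncation) and `tract` (the footprint [interval_set]).
#' @export
sample_within_event <- function(material, genome, delta) {
  if (effective_within_rate(material, genome, delta) <= 0)
    stop("no effective within-species event exists for this material")
  res <- cpp_sample_within(unclass(material), genome$total_length,
                           is_circular(genome), delta)
  res$tract <- new_interval_set(res$tract)
  res
}

#' @rdname sample_within_event
#' @export
sample_external_event <- function(material, genome, delta) {
  if (total_sites(material) == 0L)
    stop("empty ancestral material")
  res <- cpp_sample_external(unclass(material), genome$total_length,
                             is_circular(genome), delta)
  res$tract <- new_interval_set(res$tract)
  res
}
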