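#' Simulate whole bacterial genomes with homologous recombination
#'
#' One-call interface: builds the parameter set, simulates the ancestral
#' recombination graph and the Jukes-Cantor alignment, and returns them
#' with the clonal frame and event list. Within-species recombination
#' imports tracts from donor lineages inside the coalescing population
#' (splitting the graph); between-species recombination injects diverged
#' sequence derived from the root homolog, which both elevates
#' substitution density on the recipient branch and creates homoplasy.
#'
#' @inheritParams sim_params
#' @param genome A [genome_map], or an integer genome length (circular).
#' @param alignment Simulate sequences (set `FALSE` for ARG-only runs).
#' @param max_events Event cap passed to [simulate_arg()].
#' @return An object of class `bacsim_sim`: list with `params`, `arg`,
#'   `alignment` (or `NULL`), `clonal` (the clonal frame `phylo`) and
#'   `events` (data.frame).
#' @examples
#' sim <- simulate_genomes(n = 5, genome = 2000, theta = 0.01,
#'                         rho_int = 0.01, delta_int = 100, seed = 1)
#' sim
#' @export
simulate_genomes <- function(n, genome, theta = 0, rho_int = 0,
                             delta_int = 500, rho_ext = 0, delta_ext = 500,
                             div_min = 0, div_max = 0, seed = NULL,
                             alignment = TRUE, max_events = 5e6) {
  params <- sim_params(n = n, genome = genome, theta = theta,
                       rho_int = rho_int, delta_int = delta_int,
                       rho_ext = rho_ext, delta_ext = delta_ext,
                       div_min = div_min, div_max = div_max, seed = seed)
  arg <- simulate_arg(params, max_events = max_events)
  aln <- if (alignment) simulate_alignment(arg) else NULL
  structure(list(params = params, arg = arg, alignment = aln,
                 clonal = clonal_frame(arg), events = events_table(arg)),
            class = "bacsim_sim")
}

#' @export
print.bacsim_sim <- function(x, ...) {
  print(x$arg)
  if (!is.null(x$alignment))
    cat(sprintf("  alignment: %d x %d sites, %d segregating\n",
                nrow(x$alignment), ncol(x$alignment),
                sum(apply(x$alignment, 2L,
                          function(cc) length(unique(cc)) > 1L))))
  invisible(x)
}

#' @export
summary.bacsim_sim <- function(object, ...) summary(object$arg, ...)

#' Plot the clonal frame of a simulation
#'
#' @param x A `bacsim_sim`.
#' @param ... Passed to `ape::plot.phylo`.
#' @export
plot.bacsim_sim <- function(x, ...) {
  ape::plot.phylo(x$clonal, ...)
  invisible(x)
}
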