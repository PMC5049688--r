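#' Simulate an ancestral recombination graph
#'
#' Runs the coalescent with gene conversion backward in time. With `k`
#' active lineages, coalescence occurs at rate `k(k-1)/2`; within-species
#' recombination at the sum over lineages of the closed-form *effective*
#' rate (only events that bipartition a lineage's ancestral material into
#' two non-empty parts are ever generated); between-species imports at the
#' sum of effective external rates (the tract must touch ancestral
#' material). A within-species event splits the recipient lineage into a
#' continuing recipient (keeps the tract's complement, inherits the
#' clonal-frame flag) and a donor (carries the tract, never clonal). An
#' external import terminates the tract's ancestry outside the population:
#' the tract is removed from backward-time material and a divergence
#' `d ~ Uniform(div_min, div_max)` is recorded for sequence simulation.
#'
#' Once a genomic region is carried by a single lineage its local most
#' recent common ancestor is recorded and the region is dropped from
#' material tracking, so events hitting fully coalesced regions (which
#' would shift all samples identically and are unobservable) are never
#' sampled. Clonal-frame lineages persist even with empty material, so the
#' complete clonal genealogy is always recovered.
#'
#' @param params A [sim_params] object.
#' @param max_events Guard against runaway parameter sets: the simulation
#'   stops with an error after this many events.
#'
#' @return An object of class `bacsim_arg`: the node table (`$nodes`),
#'   recombination event list (`$events`, see [events_table()]), clonal
#'   frame (`$clonal`, an `ape` \code{phylo} with `$tmrca`), resolution
#'   records, and the parameters. Use [clonal_frame()], [local_tree()],
#'   [simulate_alignment()], and the writers to consume it.
#' @examples
#' p <- sim_params(n = 5, genome = genome_map(2000), theta = 0.01,
#'                 rho_int = 0.01, delta_int = 100, seed = 1)
#' arg <- simulate_arg(p)
#' arg
#' @export
simulate_arg <- function(params, max_events = 5e6) {
  stopifnot(inherits(params, "bacsim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g <- params$genome
  raw <- cpp_simulate_arg(params$n, g$total_length, is_circular(g),
                          unclass(g$spans), params$rho_int, params$delta_int,
                          params$rho_ext, params$delta_ext,
                          params$div_min, params$div_max, max_events)
  nodes <- data.frame(
    id = seq_along(raw$kind),
    kind = c("leaf", "coalescence", "recomb_split", "external_import")[raw$kind + 1L],
    time = raw$time,
    child1 = raw$child1 + 1L, child2 = raw$child2 + 1L,
    parent_cont = raw$p_cont + 1L, parent_don = raw$p_don + 1L,
    div = raw$div)
  nodes$child1[nodes$child1 == 0L] <- NA_integer_
  nodes$child2[nodes$child2 == 0L] <- NA_integer_
  nodes$parent_cont[nodes$parent_cont == 0L] <- NA_integer_
  nodes$parent_don[nodes$parent_don == 0L] <- NA_integer_

  clonal <- clonal_phylo(params$n, raw$cm_time, raw$cm_a, raw$cm_b)

  structure(
    list(nodes = nodes,
         arena = cbind(start = raw$arena_start, end = raw$arena_end),
         snap_off = raw$snap_off, snap_n = raw$snap_n,
         aux_off = raw$aux_off, aux_n = raw$aux_n,
         res = data.frame(node = raw$res_node + 1L,
                          off = raw$res_off, n = raw$res_n),
         ev = list(kind = raw$ev_kind, time = raw$ev_time,
                   lineage = raw$ev_lin, off = raw$ev_off, n = raw$ev_n,
                   div = raw$ev_div),
         edges = data.frame(parent = raw$edge_parent + 1L,
                            child = raw$edge_child + 1L,
                            slot = raw$edge_slot,
                            clonal = raw$edge_clonal),
         clonal = clonal,
         tmrca = raw$tmrca,
         n_within = raw$n_within, n_external = raw$n_external,
         params = params),
    class = "bacsim_arg")
}

# fetch an interval set from the arena by (0-based) offset and count
arg_iset <- function(arg, off, n) {
  if (n == 0L) return(empty_set())
  new_interval_set(arg$arena[seq.int(off + 1L, off + n), , drop = FALSE])
}

#' Ancestral material snapshot of an ARG node
#' @param arg A [simulate_arg()] result.
#' @param id Node id (row of `arg$nodes`).
#' @param which `"snapshot"` (material of the child lineage at node
#'   creation), or `"aux"` (donor material of a split node / import tract
#'   of an external-import node).
#' @return An [interval_set].
#' @export
node_material <- function(arg, id, which = c("snapshot", "aux")) {
  which <- match.arg(which)
  if (which == "snapshot") arg_iset(arg, arg$snap_off[id], arg$snap_n[id])
  else arg_iset(arg, arg$aux_off[id], arg$aux_n[id])
}

node_resolved <- function(arg, id) {
  rows <- which(arg$res$node == id)
  if (length(rows) == 0L) return(empty_set())
  do.call(iset_union, c(list(empty_set()),
    lapply(rows, function(r) arg_iset(arg, arg$res$off[r], arg$res$n[r]))))
}

#' Recombination event list of an ARG
#'
#' @param arg A [simulate_arg()] result.
#' @return A data.frame with one row per recombination event, in
#'   chronological order: `kind` (`"within"`/`"external"`), `time`
#'   (coalescent units), `recipient_id` (lineage identifier), `tract_start`
#'   and `tract_end` (semicolon-joined for multi-interval wrapped tracts),
#'   and `divergence` (`NA` for within-species events). The tract of each
#'   event is its raw genomic footprint; `event_tract()` returns it as an
#'   [interval_set].
#' @export
events_table <- function(arg) {
  ev <- arg$ev
  k <- length(ev$kind)
  ts <- character(k); te <- character(k)
  for (i in seq_len(k)) {
    tr <- arg_iset(arg, ev$off[i], ev$n[i])
    ts[i] <- paste(tr[, 1L], collapse = ";")
    te[i] <- paste(tr[, 2L], collapse = ";")
  }
  data.frame(kind = c("within", "external")[ev$kind + 1L],
             time = ev$time, recipient_id = ev$lineage,
             tract_start = ts, tract_end = te, divergence = ev$div)
}

#' @rdname events_table
#' @param i Event index (chronological).
#' @export
event_tract <- function(arg, i) arg_iset(arg, arg$ev$off[i], arg$ev$n[i])

# build an ape phylo from the clonal merge records: tips are labels
# 1..n (0-based from C++), merge r creates label n+r at time cm_time[r]
clonal_phylo <- function(n, cm_time, cm_a, cm_b) {
  stopifnot(length(cm_time) == n - 1L)
  nm <- n - 1L
  # phylo ids: tips 1..n; merge r (time order) -> 2n - r, so root is n+1
  lab2id <- function(lab) ifelse(lab < n, lab + 1L, 2L * n - (lab - n + 1L))
  height <- numeric(2L * n - 1L)
  edge <- matrix(0L, 2L * nm, 2L)
  elen <- numeric(2L * nm)
  for (r in seq_len(nm)) {
    pid <- 2L * n - r
    height[pid] <- cm_time[r]
    for (s in 1:2) {
      cl <- if (s == 1L) cm_a[r] else cm_b[r]
      cid <- lab2id(cl)
      edge[2L * (r - 1L) + s, ] <- c(pid, cid)
      elen[2L * (r - 1L) + s] <- cm_time[r] - height[cid]
    }
  }
  tr <- structure(
    list(edge = edge, edge.length = elen,
         tip.label = paste0("sample_", seq_len(n)), Nnode = nm),
    class = "phylo", order = "pruningwise")
  attr(tr, "node_heights") <- height
  tr
}

#' Clonal frame of an ARG
#'
#' The clonal frame is the genealogy obtained by following, through every
#' recombination split, the recipient (vertically inheriting) branch: the
#' "species tree" of the sample. Recombination never removes clonal
#' lineages, so the clonal frame is distributed exactly as an n-sample
#' coalescent tree whatever the recombination rates.
#'
#' @param arg A [simulate_arg()] result.
#' @return An `ape` \code{phylo}, ultrametric in coalescent units, with a
#'   `node_heights` attribute.
#' @export
clonal_frame <- function(arg) arg$clonal

#' @export
print.bacsim_arg <- function(x, ...) {
  cat(sprintf(
    "bacsim ARG: n = %d, G = %d (%s)\n", x$params$n,
    x$params$genome$total_length, x$params$genome$topology))
  cat(sprintf("  %d nodes; %d within-species events, %d external imports\n",
              nrow(x$nodes), x$n_within, x$n_external))
  cat(sprintf("  clonal TMRCA: %.4f coalescent units\n", x$tmrca))
  invisible(x)
}

#' @export
summary.bacsim_arg <- function(object, ...) {
  ev <- events_table(object)
  structure(list(
    n = object$params$n,
    G = object$params$genome$total_length,
    n_within = object$n_within,
    n_external = object$n_external,
    tmrca = object$tmrca,
    mean_within_time = if (any(ev$kind == "within"))
      mean(ev$time[ev$kind == "within"]) else NA_real_,
    divergence_range = if (any(ev$kind == "external"))
      range(ev$divergence[ev$kind == "external"]) else c(NA_real_, NA_real_)),
    class = "summary.bacsim_arg")
}

#' @export
print.summary.bacsim_arg <- function(x, ...) {
  cat(sprintf("ARG summary: n = %d, G = %d\n", x$n, x$G))
  cat(sprintf("  within-species events: %d (mean time %.3f)\n",
              x$n_within, x$mean_within_time))
  cat(sprintf("  external imports: %d (divergence range %.3f-%.3f)\n",
              x$n_external, x$divergence_range[1], x$divergence_range[2]))
  cat(sprintf("  clonal TMRCA: %.4f\n", x$tmrca))
  invisible(x)
}
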