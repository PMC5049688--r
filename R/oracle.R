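#' Brute-force enumeration of effective recombination rates
#'
#' Independent reference implementations of the closed-form rates, by
#' direct enumeration of every start site and tract length with explicit
#' interval arithmetic. On a circular genome lengths `>= G` cover the
#' whole genome and are never effective (within) or always effective iff
#' material exists (external), so enumeration to `G` is exact; on a
#' linear genome the tract is constant for `l >= G - s` and the geometric
#' tail is summed analytically. Intended for validation on small genomes.
#'
#' @inheritParams effective_within_rate
#' @return Rate per coalescent time unit.
#' @export
enum_within_rate <- function(material, genome, delta, rho = 1) {
  rho / 2 * sum(enum_within_joint(material, genome, delta)$prob)
}

#' @rdname enum_within_rate
#' @export
enum_external_rate <- function(material, genome, delta, rho = 1) {
  G <- genome$total_length
  circ <- is_circular(genome)
  tot <- 0
  for (s in 0:(G - 1)) {
    Lmax <- if (circ) G else G - s
    for (l in seq_len(Lmax)) {
      p <- if (l < Lmax) dgeom(l - 1, 1 / delta)
           else (1 - 1 / delta)^(Lmax - 1)             # tail lump
      tr <- wrap_interval(s, l, genome)
      if (total_sites(iset_intersect(material, tr)) > 0) tot <- tot + p
    }
  }
  rho / 2 * tot
}

#' @rdname enum_within_rate
#' @return For `enum_within_joint`: a data.frame of all `(s, l)` pairs
#'   with non-zero effective probability; on linear genomes the row with
#'   `l == G - s` aggregates the whole geometric tail (every longer tract
#'   has the same truncated footprint).
#' @export
enum_within_joint <- function(material, genome, delta) {
  G <- genome$total_length
  circ <- is_circular(genome)
  out_s <- integer(); out_l <- integer(); out_p <- numeric()
  for (s in 0:(G - 1)) {
    Lmax <- if (circ) G - 1 else G - s
    for (l in seq_len(Lmax)) {
      p <- if (circ || l < Lmax) dgeom(l - 1, 1 / delta)
           else (1 - 1 / delta)^(Lmax - 1)
      tr <- wrap_interval(s, l, genome)
      don <- iset_intersect(material, tr)
      if (total_sites(don) > 0 &&
          total_sites(iset_diff(material, don)) > 0) {
        out_s <- c(out_s, s); out_l <- c(out_l, l); out_p <- c(out_p, p)
      }
    }
  }
  data.frame(s = out_s, l = out_l, prob = out_p)
}

#' Closed-form coalescent expectations
#'
#' Standard n-sample coalescent theory used as an oracle: the expected
#' time to the most recent common ancestor is `2(1 - 1/n)` and the
#' expected total branch length `2 * sum(1/(1:(n-1)))`, both in coalescent
#' units of N_e generations.
#'
#' @param n Sample size, `>= 2`.
#' @return List with `tmrca` and `total_length`.
#' @export
coalescent_expectations <- function(n) {
  stopifnot(n >= 2)
  list(tmrca = 2 * (1 - 1 / n),
       total_length = 2 * sum(1 / seq_len(n - 1)))
}

#' Rejection-sampling reference simulator
#'
#' The discarded-baseline algorithm reimplemented as a distributional
#' oracle for [simulate_arg()]: candidate within-species events are drawn
#' at the unconditioned rate `(R/2) G` per material-bearing lineage with
#' `(s, l)` from the raw product law, and candidates that do not
#' effectively alter ancestral material are discarded without touching
#' lineage state (external candidates likewise at `(R_e/2) G`, rejected
#' when the tract misses material). Event application, material pruning at
#' local MRCAs and clonal-frame tracking follow exactly the same rules as
#' the analytical simulator, but the code is fully independent pure R with
#' a per-site (not interval-based) coalescence counter. Only summaries
#' needed for distribution comparison are returned; intended for small
#' genomes (`G <= ~1000`) and modest rates.
#'
#' @param params A [sim_params] object (its `seed` is honoured).
#' @param max_events Candidate-event cap.
#' @return List with `n_within` / `n_external` (effective counts),
#'   `n_within_raw` / `n_external_raw` (candidate counts including
#'   rejections), `tmrca` (clonal frame), `lineage_time` (total time
#'   carried by material-bearing lineages, the exposure behind the raw
#'   rates), `events` (data.frame like [events_table()]) and
#'   `acceptance` (effective / raw candidate fraction).
#' @export
rejection_simulate_arg <- function(params, max_events = 1e6) {
  stopifnot(inherits(params, "bacsim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  g <- params$genome
  G <- g$total_length
  n <- params$n
  span_sites <- iset_sites(g$spans)
  cnt <- integer(G)
  cnt[span_sites + 1L] <- n

  lin <- lapply(seq_len(n), function(i)
    list(mat = g$spans, clonal = TRUE, id = i - 1L))
  next_id <- n
  t <- 0
  nw <- 0L; ne <- 0L; nwr <- 0L; ner <- 0L
  lineage_time <- 0
  n_clonal <- n
  ev <- list()
  cm_t <- numeric(0)

  repeat {
    k <- length(lin)
    live <- vapply(lin, function(l) total_sites(l$mat) > 0L, TRUE)
    if (sum(cnt) == 0L && k == 1L) break
    raw_w <- params$rho_int / 2 * G * sum(live)
    raw_e <- params$rho_ext / 2 * G * sum(live)
    coal <- k * (k - 1) / 2
    tot <- coal + raw_w + raw_e
    dt <- rexp(1, tot)
    t <- t + dt
    lineage_time <- lineage_time + dt * sum(live)
    if (nw + ne + nwr + ner > max_events) stop("candidate-event cap exceeded")
    u <- runif(1, 0, tot)
    if (u < coal) {
      ij <- sample.int(k, 2L)
      a <- lin[[ij[1L]]]; b <- lin[[ij[2L]]]
      uni <- iset_union(a$mat, b$mat)
      inter <- iset_intersect(a$mat, b$mat)
      if (a$clonal && b$clonal) cm_t <- c(cm_t, t)
      merged <- list(mat = uni, clonal = a$clonal || b$clonal, id = next_id)
      next_id <- next_id + 1L
      lin <- c(lin[-ij], list(merged))
      if (total_sites(inter) > 0L) {
        idx <- iset_sites(inter) + 1L
        cnt[idx] <- cnt[idx] - 1L
        lin <- prune_single_carriers(lin, cnt)
        cnt[cnt == 1L] <- 0L
      }
    } else if (u < coal + raw_w) {
      cand <- which(live)
      li <- cand[sample.int(length(cand), 1L)]
      s <- sample.int(G, 1L) - 1L
      l <- rgeom_mean(params$delta_int)
      tr <- wrap_interval(s, l, g)
      don <- iset_intersect(lin[[li]]$mat, tr)
      rec <- iset_diff(lin[[li]]$mat, don)
      if (total_sites(don) == 0L || total_sites(rec) == 0L) {
        nwr <- nwr + 1L                         # rejected candidate
      } else {
        nw <- nw + 1L; nwr <- nwr + 1L
        ev[[length(ev) + 1L]] <- list(kind = "within", time = t,
                                      recipient_id = lin[[li]]$id,
                                      tract = tr, divergence = NA_real_)
        donor <- list(mat = don, clonal = FALSE, id = next_id)
        next_id <- next_id + 1L
        lin[[li]]$mat <- rec
        lin <- c(lin, list(donor))
      }
    } else {
      cand <- which(live)
      li <- cand[sample.int(length(cand), 1L)]
      s <- sample.int(G, 1L) - 1L
      l <- rgeom_mean(params$delta_ext)
      tr <- wrap_interval(s, l, g)
      imp <- iset_intersect(lin[[li]]$mat, tr)
      if (total_sites(imp) == 0L) {
        ner <- ner + 1L
      } else {
        ne <- ne + 1L; ner <- ner + 1L
        d <- runif(1, params$div_min, params$div_max)
        ev[[length(ev) + 1L]] <- list(kind = "external", time = t,
                                      recipient_id = lin[[li]]$id,
                                      tract = tr, divergence = d)
        rem <- iset_diff(lin[[li]]$mat, imp)
        if (total_sites(rem) == 0L && !lin[[li]]$clonal) {
          lin <- lin[-li]
        } else {
          lin[[li]]$mat <- rem
        }
        idx <- iset_sites(imp) + 1L
        cnt[idx] <- cnt[idx] - 1L
        lin <- prune_single_carriers(lin, cnt)
        cnt[cnt == 1L] <- 0L
      }
    }
  }
  events <- if (length(ev) == 0L)
    data.frame(kind = character(), time = numeric(),
               recipient_id = integer(), tract_start = character(),
               tract_end = character(), divergence = numeric())
  else do.call(rbind, lapply(ev, function(e)
    data.frame(kind = e$kind, time = e$time, recipient_id = e$recipient_id,
               tract_start = paste(e$tract[, 1L], collapse = ";"),
               tract_end = paste(e$tract[, 2L], collapse = ";"),
               divergence = e$divergence)))
  list(n_within = nw, n_external = ne,
       n_within_raw = nwr, n_external_raw = ner,
       tmrca = if (length(cm_t)) max(cm_t) else NA_real_,
       lineage_time = lineage_time,
       events = events,
       acceptance = if (nwr + ner > 0) (nw + ne) / (nwr + ner) else NA_real_)
}

# geometric tract length with mean delta (support l >= 1)
rgeom_mean <- function(delta) 1L + stats::rgeom(1L, 1 / delta)

# drop fully coalesced sites (count == 1) from their single carrier;
# non-clonal lineages left empty disappear
prune_single_carriers <- function(lin, cnt) {
  single <- iset_from_sites(which(cnt == 1L) - 1L)
  if (total_sites(single) == 0L) return(lin)
  keep <- logical(length(lin))
  for (i in seq_along(lin)) {
    lin[[i]]$mat <- iset_diff(lin[[i]]$mat, single)
    keep[i] <- lin[[i]]$clonal || total_sites(lin[[i]]$mat) > 0L
  }
  lin[keep]
}

#' Jukes-Cantor distance
#'
#' The inverse of the forward mismatch formula of [evolve_edge()]:
#' `d_hat = -(3/4) log(1 - (4/3) p_hat)` substitutions per site from a
#' mismatch proportion `p_hat`.
#'
#' @param p Proportion of differing sites (`p < 0.75`).
#' @return Estimated substitutions per site.
#' @export
jc_distance <- function(p) {
  if (any(p >= 0.75)) stop("mismatch proportion at or beyond JC saturation")
  -3 / 4 * log(1 - 4 / 3 * p)
}

#' Robinson-Foulds branch accuracy
#'
#' The proportion of the true tree's internal branches (non-trivial
#' bipartitions of the leaf set) whose bipartition is present in the
#' inferred tree. Trees are treated as unrooted; an unresolved inferred
#' tree can only lower the score.
#'
#' @param true_tree,inferred_tree `phylo` objects on the same leaf set.
#' @return Proportion in `[0, 1]` (`NaN` when the true tree has no
#'   internal branch, i.e. fewer than 4 leaves).
#' @export
branch_accuracy <- function(true_tree, inferred_tree) {
  if (!setequal(true_tree$tip.label, inferred_tree$tip.label))
    stop("trees have different leaf sets")
  ts <- tree_bipartitions(true_tree)
  is_ <- tree_bipartitions(inferred_tree)
  if (length(ts) == 0L) return(NaN)
  mean(ts %in% is_)
}

# non-trivial bipartitions of an unrooted tree, as canonical keys:
# the side not containing the first tip label (alphabetical), sorted
tree_bipartitions <- function(tree, return_sides = FALSE) {
  tree <- ape::unroot(tree)
  labs <- sort(tree$tip.label)
  ntip <- length(labs)
  tipno <- match(tree$tip.label, labs)
  nn <- max(tree$edge)
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tipno[i]
  # accumulate tip sets in reverse edge order (ape trees are child-sorted
  # after reorder)
  tree <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  keys <- character(0); sides <- list()
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2L]
    if (ch <= ntip) next                       # trivial split
    side <- sort(below[[ch]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (1L %in% side) side <- setdiff(seq_len(ntip), side)
    keys <- c(keys, paste(side, collapse = ","))
    sides <- c(sides, list(side))
  }
  if (return_sides) list(keys = keys, sides = sides, labs = labs) else keys
}
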