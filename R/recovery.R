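#' Infer a tree from an alignment
#'
#' Distance methods (NJ, UPGMA) compute pairwise Jukes-Cantor distances
#' (`ape::dist.dna`, the inverse of the simulator's forward model) and
#' build the tree internally. Maximum likelihood is an adapter boundary:
#' it shells out to FastTree when available on the PATH and is otherwise
#' unavailable (callers downgrade with a warning).
#'
#' @param aln A [simulate_alignment()] matrix (or any character matrix of
#'   A/C/G/T with row names).
#' @param method `"nj"`, `"upgma"` or `"ml"`.
#' @return A `phylo`.
#' @export
infer_tree <- function(aln, method = c("nj", "upgma", "ml")) {
  method <- match.arg(method)
  if (method == "ml") {
    ft <- Sys.which("fasttree")
    if (!nzchar(ft)) ft <- Sys.which("FastTree")
    if (!nzchar(ft)) stop("no maximum-likelihood adapter available ",
                          "(FastTree not found on PATH)")
    fa <- tempfile(fileext = ".fasta"); on.exit(unlink(fa), add = TRUE)
    writeLines(paste0(">", rownames(aln), "\n",
                      apply(aln, 1L, paste, collapse = "")), fa)
    out <- suppressWarnings(
      system2(ft, c("-nt", "-quiet", "-nosupport", shQuote(fa)),
              stdout = TRUE, stderr = FALSE))
    return(ape::read.tree(text = paste(out, collapse = "")))
  }
  m <- tolower(aln)
  attributes(m) <- list(dim = dim(aln), dimnames = dimnames(aln))
  d <- ape::dist.dna(ape::as.DNAbin(m), model = "JC69")
  if (any(!is.finite(d)))
    stop("JC distance undefined (saturated pair); cannot build tree")
  if (method == "nj") ape::nj(d)
  else ape::as.phylo(hclust(as.dist(d), method = "average"))
}

has_ml_adapter <- function() {
  nzchar(Sys.which("fasttree")) || nzchar(Sys.which("FastTree"))
}

#' Branch age classes of an ultrametric tree
#'
#' Classifies each internal branch of the clonal frame by the distance
#' between its mid-point and the root: old branches lie within 1.32 N_e
#' generations of the root, middle-aged between 1.32 and 2.09, young
#' beyond 2.09.
#'
#' @param tree Ultrametric `phylo` (a [clonal_frame()]).
#' @param thresholds Numeric length-2: the old/middle and middle/young
#'   boundaries, in N_e generations from the root.
#' @return Data.frame with one row per non-trivial bipartition: `key`
#'   (canonical split), `mid_depth` (root-to-mid-point distance) and
#'   `age` (`"old"`, `"middle"`, `"young"`).
#' @export
branch_age_classes <- function(tree, thresholds = c(1.32, 2.09)) {
  stopifnot(length(thresholds) == 2L, diff(thresholds) > 0)
  ntip <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)      # distance from root
  labs <- sort(tree$tip.label)
  tipno <- match(tree$tip.label, labs)
  tr <- ape::reorder.phylo(tree, "postorder")
  nn <- max(tr$edge)
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- tipno[i]
  for (e in seq_len(nrow(tr$edge)))
    below[[tr$edge[e, 1L]]] <- c(below[[tr$edge[e, 1L]]],
                                 below[[tr$edge[e, 2L]]])
  out <- list()
  for (e in seq_len(nrow(tr$edge))) {
    ch <- tr$edge[e, 2L]
    if (ch <= ntip) next
    side <- sort(below[[ch]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (1L %in% side) side <- setdiff(seq_len(ntip), side)
    mid <- (depth[tr$edge[e, 1L]] + depth[ch]) / 2
    out[[length(out) + 1L]] <- data.frame(
      key = paste(side, collapse = ","), mid_depth = mid)
  }
  if (length(out) == 0L)
    return(data.frame(key = character(), mid_depth = numeric(),
                      age = character()))
  df <- do.call(rbind, out)
  df <- df[!duplicated(df$key), , drop = FALSE]   # the two root edges share
  rownames(df) <- NULL                            # one unrooted bipartition
  df$age <- cut(df$mid_depth, c(-Inf, thresholds, Inf),
                labels = c("old", "middle", "young"))
  df$age <- as.character(df$age)
  df
}

#' Clonal-frame recovery experiment
#'
#' Measures how recombination degrades phylogenetic reconstruction of the
#' clonal frame: for each recombination rate on the grid and each
#' replicate, simulate an alignment, infer a tree with each method, and
#' score the proportion of the true clonal frame's internal branches
#' recovered ([branch_accuracy()]), overall and stratified by branch age
#' ([branch_age_classes()]). Replicate `j` uses seed `seed + j` for every
#' rate, so the comparison across rates is paired over seeds.
#'
#' @param r_grid Within-species recombination rates to scan.
#' @param n_reps Replicates per rate.
#' @param n Sample size.
#' @param genome_length Genome length in sites (circular genome).
#' @param theta Scaled mutation rate.
#' @param delta Mean tract length.
#' @param methods Subset of `c("nj", "upgma", "ml")`; `"ml"` downgrades
#'   with a warning if no adapter is available.
#' @param thresholds Branch-age thresholds, see [branch_age_classes()].
#' @param seed Base seed.
#' @return List with `summary` (data.frame: `R`, `method`, `age_class`,
#'   `mean_accuracy`, `sd`, `n_reps`) and `replicates` (per-replicate
#'   accuracies for paired tests).
#' @export
run_recovery_experiment <- function(r_grid = c(0, 0.1), n_reps = 10,
                                    n = 15, genome_length = 5e4,
                                    theta = 0.01, delta = 500,
                                    methods = c("nj", "upgma"),
                                    thresholds = c(1.32, 2.09),
                                    seed = 1) {
  methods <- match.arg(methods, c("nj", "upgma", "ml"), several.ok = TRUE)
  if ("ml" %in% methods && !has_ml_adapter()) {
    warning("no ML adapter (FastTree) found; downgrading to distance methods")
    methods <- setdiff(methods, "ml")
  }
  g <- genome_map(genome_length)
  rows <- list()
  for (R in r_grid) {
    for (j in seq_len(n_reps)) {
      p <- sim_params(n = n, genome = g, theta = theta, rho_int = R,
                      delta_int = delta, seed = seed + j)
      arg <- simulate_arg(p)
      aln <- simulate_alignment(arg)
      truth <- clonal_frame(arg)
      ages <- branch_age_classes(truth, thresholds)
      for (m in methods) {
        inf <- tryCatch(infer_tree(aln, m), error = function(e) NULL)
        if (is.null(inf)) next
        found <- tree_bipartitions(inf)
        hit <- ages$key %in% found
        rows[[length(rows) + 1L]] <- data.frame(
          R = R, rep = j, method = m,
          age_class = c("overall", "old", "middle", "young"),
          accuracy = c(mean(hit),
                       vapply(c("old", "middle", "young"), function(a) {
                         idx <- ages$age == a
                         if (any(idx)) mean(hit[idx]) else NA_real_
                       }, 0)))
      }
    }
  }
  reps <- do.call(rbind, rows)
  agg <- stats::aggregate(accuracy ~ R + method + age_class, data = reps,
                          FUN = function(x) c(mean = mean(x, na.rm = TRUE),
                                              sd = sd(x, na.rm = TRUE),
                                              n = sum(!is.na(x))))
  summary <- data.frame(R = agg$R, method = agg$method,
                        age_class = agg$age_class,
                        mean_accuracy = agg$accuracy[, "mean"],
                        sd = agg$accuracy[, "sd"],
                        n_reps = agg$accuracy[, "n"])
  list(summary = summary, replicates = reps)
}
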