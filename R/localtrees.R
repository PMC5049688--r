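#' Local (marginal) genealogy of one genomic site
#'
#' Follows, from every sample, the ARG path carrying the site: at each
#' recombination split the parent whose material contains the site, up to
#' the site's local most recent common ancestor or to an external-import
#' terminator. Clades whose ancestry is resolved by an import do not reach
#' the coalescent root of the local tree -- they are attached to it as
#' *import edges* annotated with the event's divergence `d`, which is how
#' between-species recombination generates homoplasy.
#'
#' @param arg A [simulate_arg()] result.
#' @param site 0-based genome coordinate; must be sequence-bearing
#'   (gap coordinates are an error).
#' @return An object of class `local_tree`: a list with `root` (recursive
#'   node structure with `height` in coalescent units, `tips`, `children`;
#'   `NULL` when every sample's ancestry at this site is import-terminated),
#'   `imports` (list of `clade`/`d`/`time`), `site` and `n`.
#' @seealso [breakpoints()], [local_trees()], [tmrca()],
#'   [local_tree_newick()]
#' @export
local_tree <- function(arg, site) {
  g <- arg$params$genome
  site <- as.integer(site)
  if (site < 0L || site >= g$total_length)
    stop("site outside [0, G)")
  if (!site_in(g$spans, site))
    stop(sprintf("site %d is a gap coordinate and bears no sequence", site))
  nd <- arg$nodes
  res_by_node <- split(seq_len(nrow(arg$res)), arg$res$node)

  in_aux <- function(v) {
    n_ <- arg$aux_n[v]
    n_ > 0L && site_in(arg_iset(arg, arg$aux_off[v], n_), site)
  }
  in_res <- function(v) {
    rows <- res_by_node[[as.character(v)]]
    if (is.null(rows)) return(FALSE)
    for (r in rows)
      if (site_in(arg_iset(arg, arg$res$off[r], arg$res$n[r]), site)) return(TRUE)
    FALSE
  }

  n <- arg$params$n
  wnode <- seq_len(n)                  # leaves are nodes 1..n
  wsub <- lapply(seq_len(n), function(i)
    list(height = 0, tips = i, children = NULL))
  # a walker standing on the site's recorded MRCA cannot advance further,
  # but stays available for merging (its clade-mates may still be en route
  # when the record was laid down by an import elsewhere)
  rooted <- vapply(wnode, in_res, TRUE)
  imports <- list()

  while (length(wnode) > 1L) {
    cand <- which(!rooted)
    if (length(cand) == 0L)
      stop("internal error: several rooted walkers for one site")
    w <- cand[which.min(nd$time[wnode[cand]])]
    v <- wnode[w]
    P <- if (nd$kind[v] == "recomb_split" && in_aux(v)) nd$parent_don[v]
         else nd$parent_cont[v]
    if (is.na(P))
      stop("internal error: site path ends without resolution or import")
    if (nd$kind[P] == "external_import" && in_aux(P)) {
      imports[[length(imports) + 1L]] <-
        list(clade = wsub[[w]], d = nd$div[P], time = nd$time[P])
      wnode <- wnode[-w]; wsub <- wsub[-w]; rooted <- rooted[-w]
      next
    }
    other <- which(wnode == P)
    if (length(other) == 1L) {        # coalescence in the local tree
      a <- wsub[[other]]; b <- wsub[[w]]
      wsub[[other]] <- list(height = nd$time[P],
                            tips = sort(c(a$tips, b$tips)),
                            children = list(a, b))
      rooted[other] <- rooted[other] || in_res(P)
      wnode <- wnode[-w]; wsub <- wsub[-w]; rooted <- rooted[-w]
    } else {
      wnode[w] <- P
      rooted[w] <- in_res(P)
    }
  }
  root <- if (length(wnode) == 1L) wsub[[1L]] else NULL
  structure(list(root = root, imports = imports, site = site, n = n),
            class = "local_tree")
}

site_in <- function(iset, x) {
  nrow(iset) > 0L && any(iset[, 1L] <= x & x < iset[, 2L])
}

#' Time to the most recent common ancestor
#'
#' Root height in coalescent units of N_e generations. For `local_tree`
#' objects this is the coalescent root of the non-imported samples (an
#' import-only degenerate tree has no coalescent root and is an error);
#' for `phylo` trees it is the maximum root-to-tip path length.
#'
#' @param tree A `local_tree` or an (ultrametric) `phylo`.
#' @return Numeric scalar, coalescent units.
#' @export
tmrca <- function(tree) UseMethod("tmrca")

#' @export
tmrca.local_tree <- function(tree) {
  if (is.null(tree$root))
    stop("local tree has no coalescent root (all ancestry import-terminated)")
  tree$root$height
}

#' @export
tmrca.phylo <- function(tree) {
  max(ape::node.depth.edgelength(tree))
}

#' @export
print.local_tree <- function(x, ...) {
  cat(sprintf("local tree at site %d: %d samples, %d import clade(s)\n",
              x$site, x$n, length(x$imports)))
  if (!is.null(x$root))
    cat(sprintf("  coalescent root at %.4f over tips {%s}\n",
                x$root$height, paste(x$root$tips, collapse = ",")))
  for (im in x$imports)
    cat(sprintf("  import clade {%s}: d = %.4f at time %.4f\n",
                paste(im$clade$tips, collapse = ","), im$d, im$time))
  invisible(x)
}

# canonical string for tree-equality comparison: children ordered by
# smallest tip; heights printed in full double precision
canon_sub <- function(s) {
  if (is.null(s$children)) return(sprintf("t%d", s$tips[1L]))
  kids <- vapply(s$children, canon_sub, "")
  o <- order(vapply(s$children, function(k) min(k$tips), 0L))
  sprintf("(%s):%.17g", paste(kids[o], collapse = ","), s$height)
}

canon_local_tree <- function(tr) {
  ims <- ""
  if (length(tr$imports) > 0L) {
    key <- vapply(tr$imports, function(im)
      sprintf("{%s}d=%.17g@%.17g", canon_sub(im$clade), im$d, im$time), "")
    ims <- paste(sort(key), collapse = "|")
  }
  paste0(if (is.null(tr$root)) "-" else canon_sub(tr$root), "#", ims)
}

#' Genome segmentation by shared genealogy
#'
#' The minimal ordered set of boundaries such that the local tree
#' (topology, node times and import annotations) is constant within every
#' segment. Boundaries are a subset of the recombination-tract endpoints
#' recorded in the event list (plus the genome ends).
#'
#' @param arg A [simulate_arg()] result.
#' @return Integer vector of boundaries, starting with 0 and ending with
#'   the genome length; segment `i` is `[b[i], b[i+1])`.
#' @export
breakpoints <- function(arg) {
  seg <- local_trees(arg)
  c(seg$segments$start, arg$params$genome$total_length)
}

#' @rdname breakpoints
#' @return For `local_trees`: a list with `segments` (data.frame of
#'   `start`, `end`) and `trees` (one `local_tree` per segment, computed at
#'   the segment's first sequence-bearing site; `NULL` for segments wholly
#'   inside fragment gaps, which can only arise from tracts confined to a
#'   gap).
#' @export
local_trees <- function(arg) {
  g <- arg$params$genome
  G <- g$total_length
  ev <- arg$ev
  cand <- c(0L, G)
  for (i in seq_along(ev$kind)) {
    tr <- arg_iset(arg, ev$off[i], ev$n[i])
    cand <- c(cand, tr[, 1L], tr[, 2L])
  }
  cand <- sort(unique(pmin(pmax(cand, 0L), G)))
  starts <- cand[-length(cand)]
  ends <- cand[-1L]

  rep_site <- function(s, e) {
    # first sequence-bearing site in [s, e)
    for (r in seq_len(nrow(g$spans))) {
      lo <- max(s, g$spans[r, 1L]); hi <- min(e, g$spans[r, 2L])
      if (lo < hi) return(lo)
    }
    NA_integer_
  }

  segs <- list(); trees <- list(); keys <- character()
  cur_start <- starts[1L]; cur_tree <- NULL; cur_key <- NA_character_
  flush <- function(end_) {
    segs[[length(segs) + 1L]] <<- c(cur_start, end_)
    trees[[length(trees) + 1L]] <<- cur_tree
  }
  for (i in seq_along(starts)) {
    rs <- rep_site(starts[i], ends[i])
    if (is.na(rs)) next                       # gap-only piece: merge through
    tr <- local_tree(arg, rs)
    key <- canon_local_tree(tr)
    if (is.null(cur_tree)) {
      cur_tree <- tr; cur_key <- key
    } else if (!identical(key, cur_key)) {
      flush(starts[i])
      cur_start <- starts[i]; cur_tree <- tr; cur_key <- key
    }
  }
  flush(G)
  segm <- do.call(rbind, segs)
  list(segments = data.frame(start = segm[, 1L], end = segm[, 2L]),
       trees = trees)
}

#' Newick export of a local tree
#'
#' Coalescent nodes use branch lengths in coalescent units (or expected
#' substitutions per site when `units = "subs"`: lengths multiplied by
#' `theta/2`). Import clades are grafted onto the root with a branch of
#' length `2 d / theta` coalescent units -- the length whose expected
#' substitution load at rate `theta/2` equals the import's divergence `d`
#' (so `d` itself under `units = "subs"`) -- and the edge carries a
#' `[&import d=...]` comment so consumers can distinguish it. Sequence
#' simulation never uses the converted length; it uses `d` directly.
#'
#' @param tree A [local_tree()] result.
#' @param theta Scaled mutation rate used for the import-edge length
#'   conversion (and the `"subs"` rescaling).
#' @param units `"coalescent"` (default) or `"subs"`.
#' @return A single Newick string (semicolon-terminated).
#' @export
local_tree_newick <- function(tree, theta, units = c("coalescent", "subs")) {
  units <- match.arg(units)
  scale <- if (units == "subs") theta / 2 else 1
  sub_nwk <- function(s, parent_height) {
    bl <- (parent_height - s$height) * scale
    if (is.null(s$children))
      return(sprintf("sample_%d:%.10g", s$tips[1L], bl))
    kids <- vapply(s$children, sub_nwk, "", parent_height = s$height)
    sprintf("(%s):%.10g", paste(kids, collapse = ","), bl)
  }
  root_h <- if (is.null(tree$root)) 0 else tree$root$height
  parts <- character()
  if (!is.null(tree$root)) {
    if (is.null(tree$root$children)) {
      parts <- sprintf("sample_%d:0", tree$root$tips[1L])
    } else {
      kids <- vapply(tree$root$children, sub_nwk, "",
                     parent_height = root_h)
      parts <- paste(kids, collapse = ",")
    }
  }
  for (im in tree$imports) {
    ilen <- if (theta > 0) (2 * im$d / theta) * scale else im$d * scale
    body <- if (is.null(im$clade$children))
      sprintf("sample_%d", im$clade$tips[1L])
    else {
      kids <- vapply(im$clade$children, sub_nwk, "",
                     parent_height = im$clade$height)
      sprintf("(%s)", paste(kids, collapse = ","))
    }
    parts <- c(parts, sprintf("%s:%.10g[&import d=%.6g]", body, ilen, im$d))
  }
  sprintf("(%s);", paste(parts, collapse = ","))
}
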