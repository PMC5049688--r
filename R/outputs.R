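#' Output writers
#'
#' All writers start the file with a comment header recording the full
#' parameter set and seed (`;` for FASTA, `[...]` for Newick, `#` for
#' TSV, `//` for DOT), so that any output can be regenerated from its own
#' header. Leaf labels `sample_1 ... sample_n` agree across all formats.
#' All files are UTF-8 with LF line endings.
#'
#' @param arg A [simulate_arg()] result.
#' @param path Output file path.
#' @name writers
NULL

#' @rdname writers
#' @param aln A [simulate_alignment()] matrix.
#' @export
write_alignment_fasta <- function(aln, path, arg = NULL) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (!is.null(arg))
    writeLines(paste(";", param_header(arg$params)), con, sep = "\n")
  writeLines(paste0(">", rownames(aln), "\n",
                    apply(aln, 1L, paste, collapse = "")), con, sep = "\n")
  invisible(path)
}

#' @rdname writers
#' @param units Branch-length units: coalescent units of N_e generations
#'   (default) or expected substitutions per site (`"subs"`, lengths
#'   multiplied by `theta/2`).
#' @export
write_clonal_newick <- function(arg, path,
                                units = c("coalescent", "subs")) {
  units <- match.arg(units)
  tr <- clonal_frame(arg)
  if (units == "subs") tr$edge.length <- tr$edge.length * arg$params$theta / 2
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("[%s units=%s]", param_header(arg$params), units),
               ape::write.tree(tr)), con, sep = "\n")
  invisible(path)
}

#' @rdname writers
#' @export
write_local_trees_newick <- function(arg, path,
                                     units = c("coalescent", "subs")) {
  units <- match.arg(units)
  lt <- local_trees(arg)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("[%s units=%s]", param_header(arg$params), units),
             con, sep = "\n")
  for (i in seq_len(nrow(lt$segments))) {
    if (is.null(lt$trees[[i]])) next
    writeLines(c(sprintf("[segment %d %d)", lt$segments$start[i],
                         lt$segments$end[i]),
                 local_tree_newick(lt$trees[[i]], arg$params$theta, units)),
               con, sep = "\n")
  }
  invisible(path)
}

#' @rdname writers
#' @export
write_events_tsv <- function(arg, path) {
  ev <- events_table(arg)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste("#", param_header(arg$params)), con, sep = "\n")
  writeLines(paste(c("kind", "time", "recipient_id", "tract_start",
                     "tract_end", "divergence"), collapse = "\t"),
             con, sep = "\n")
  if (nrow(ev) > 0L) {
    lines <- sprintf("%s\t%.10g\t%d\t%s\t%s\t%s", ev$kind, ev$time,
                     ev$recipient_id, ev$tract_start, ev$tract_end,
                     ifelse(is.na(ev$divergence), "",
                            sprintf("%.6g", ev$divergence)))
    writeLines(lines, con, sep = "\n")
  }
  invisible(path)
}

#' Render the ARG as a Graphviz DOT graph
#'
#' Two renderings of the graph, time flowing bottom-to-top. Mode
#' `"lineage"`: edges on the clonal frame are black, non-clonal lineage
#' edges grey, and external-import nodes (and their incident edge) red.
#' Mode `"material"`: each node is labelled with a glyph string over a
#' fixed partition of the genome into segments -- `#` where the segment is
#' in the node's ancestral material, `.` where absent, `r` where it is
#' being imported from an external species at that node.
#'
#' @param arg A [simulate_arg()] result.
#' @param path Output path.
#' @param mode `"lineage"` or `"material"`.
#' @param n_glyphs Number of genome segments in material mode.
#' @return The path, invisibly.
#' @export
write_arg_dot <- function(arg, path, mode = c("lineage", "material"),
                          n_glyphs = 40) {
  mode <- match.arg(mode)
  nd <- arg$nodes
  G <- arg$params$genome$total_length
  lines <- c(sprintf("// %s", param_header(arg$params)),
             "digraph arg {", "  rankdir=BT;")
  if (mode == "lineage") {
    lines <- c(lines, "  node [shape=point, width=0.08];")
    for (v in seq_len(nrow(nd))) {
      col <- if (nd$kind[v] == "external_import") "red" else "black"
      lines <- c(lines, sprintf("  n%d [color=\"%s\"];", v, col))
    }
  } else {
    lines <- c(lines, "  node [shape=box, fontname=\"monospace\", fontsize=8];")
    bnd <- unique(round(seq(0, G, length.out = n_glyphs + 1L)))
    for (v in seq_len(nrow(nd))) {
      mat <- node_material(arg, v, "snapshot")
      imp <- if (nd$kind[v] == "external_import")
        node_material(arg, v, "aux") else empty_set()
      gl <- vapply(seq_len(length(bnd) - 1L), function(b) {
        seg <- interval_set(bnd[b], bnd[b + 1L])
        if (total_sites(iset_intersect(imp, seg)) > 0L) "r"
        else if (total_sites(iset_intersect(mat, seg)) > 0L) "#"
        else "."
      }, "")
      lines <- c(lines, sprintf("  n%d [label=\"%s\"];", v,
                                paste(gl, collapse = "")))
    }
  }
  ed <- arg$edges
  for (e in seq_len(nrow(ed))) {
    col <- if (nd$kind[ed$parent[e]] == "external_import") "red"
           else if (ed$clonal[e]) "black" else "grey"
    lines <- c(lines, sprintf("  n%d -> n%d [color=\"%s\"];",
                              ed$child[e], ed$parent[e], col))
  }
  lines <- c(lines, "}")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
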