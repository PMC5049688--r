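# shared helpers for the test suite; fixtures are built in code

count_segregating <- function(aln) {
  ref <- matrix(aln[1L, ], nrow(aln), ncol(aln), byrow = TRUE)
  sum(colSums(aln != ref) > 0L)
}

random_interval_set <- function(G) {
  k <- sample(1:(G - 1), 1L)
  iset_from_sites(sample(0:(G - 1), k))
}

# depths of every tip below a local_tree subtree (root-relative)
subtree_tip_depths <- function(s, acc = 0) {
  if (is.null(s$children)) return(acc)
  unlist(lapply(s$children, function(ch)
    subtree_tip_depths(ch, acc + (s$height - ch$height))))
}

# chi-square goodness of fit with small-cell pooling
gof_pvalue <- function(obs, expected) {
  stopifnot(length(obs) == length(expected))
  big <- expected >= 5
  o <- c(obs[big], sum(obs[!big]))
  e <- c(expected[big], sum(expected[!big]))
  keep <- e > 0
  stat <- sum((o[keep] - e[keep])^2 / e[keep])
  stats::pchisq(stat, df = sum(keep) - 1L, lower.tail = FALSE)
}

# empirical joint (s, l) check of the within-event sampler against the
# enumerated law; linear genomes lump the geometric tail at l = G - s
within_sampler_pvalue <- function(material, genome, delta, ndraw) {
  joint <- enum_within_joint(material, genome, delta)
  G <- genome$total_length
  linear <- genome$topology == "linear"
  draws <- vapply(seq_len(ndraw), function(i) {
    r <- sample_within_event(material, genome, delta)
    l <- if (linear) min(r$len, G - r$s) else r$len
    c(r$s, l)
  }, numeric(2))
  dk <- paste(draws[1L, ], draws[2L, ])
  jk <- paste(joint$s, joint$l)
  if (!all(dk %in% jk)) return(0)      # draw outside enumerated support
  obs <- as.vector(table(factor(dk, levels = jk)))
  gof_pvalue(obs, joint$prob / sum(joint$prob) * ndraw)
}
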