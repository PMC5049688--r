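test_that("root sequences are uniform, deterministic and gap-free", {
  g <- genome_map(fragments = "1000:100,500:0")
  set.seed(41); s1 <- draw_root_sequence(g)
  set.seed(41); s2 <- draw_root_sequence(g)
  expect_identical(s1, s2)
  expect_length(s1, 1500L)
  set.seed(42)
  big <- draw_root_sequence(genome_map(4e5))
  fr <- table(big) / 4e5
  se <- sqrt(0.25 * 0.75 / 4e5)
  expect_true(all(abs(fr - 0.25) < 3 * se))
})

test_that("evolve_edge follows the Jukes-Cantor mismatch formula", {
  set.seed(43)
  anc <- draw_root_sequence(genome_map(1e6))
  expect_identical(evolve_edge(anc, 0, theta = 0.05), anc)
  expect_error(evolve_edge(anc, -1, 0.05), ">= 0")
  # two branches totalling t = 2 at theta = 0.05
  tip1 <- evolve_edge(anc, 1, 0.05)
  tip2 <- evolve_edge(anc, 1, 0.05)
  p <- mean(tip1 != tip2)
  pexp <- 3 / 4 * (1 - exp(-(4 / 3) * (0.05 / 2) * 2))
  se <- sqrt(pexp * (1 - pexp) / 1e6)
  expect_lt(abs(p - pexp), 3 * se)
  # inverse consistency of the distance formula
  expect_lt(abs(jc_distance(p) - 0.05 / 2 * 2), 4e-3)
})

test_that("pairwise diversity for two samples equals theta", {
  p <- sim_params(n = 2, genome = genome_map(2e4), theta = 0.01)
  set.seed(44)
  pd <- replicate(600, {
    aln <- simulate_alignment(simulate_arg(p))
    mean(aln[1L, ] != aln[2L, ])
  })
  se <- stats::sd(pd) / sqrt(length(pd))
  expect_lt(abs(mean(pd) - 0.01), 3 * se)
})

test_that("external imports copy the root homolog at divergence d", {
  g <- genome_map(1e5, circular = FALSE)
  set.seed(45)
  rs <- draw_root_sequence(g)
  same <- apply_external_import(rs, interval_set(0, 1e5), 0, g)
  expect_identical(as.character(same), rs)
  div <- apply_external_import(rs, interval_set(0, 1e5), 0.3, g)
  se <- sqrt(0.3 * 0.7 / 1e5)
  expect_lt(abs(mean(div != rs) - 0.3), 3 * se)
  expect_error(apply_external_import(rs, interval_set(0, 10), 0.8, g), "0.75")
  # gap portions of a tract are ignored
  gf <- genome_map(fragments = "50:10,50:0")
  set.seed(46)
  rsf <- draw_root_sequence(gf)
  x <- apply_external_import(rsf, interval_set(40, 70), 0, gf)
  expect_identical(attr(x, "sites"), c(40:49, 60:69))
})

test_that("a degenerate divergence window fixes every event's divergence", {
  p <- sim_params(n = 4, genome = genome_map(500), rho_ext = 0.01,
                  delta_ext = 50, div_min = 0.21, div_max = 0.21, seed = 47)
  arg <- simulate_arg(p)
  ev <- events_table(arg)
  expect_gt(nrow(ev), 0L)
  expect_true(all(ev$divergence == 0.21))
})

test_that("with no mutation and no imports all rows equal the root sequence", {
  p <- sim_params(n = 6, genome = genome_map(fragments = "300:40,200:0"),
                  theta = 0, rho_int = 0.05, delta_int = 30, seed = 48)
  arg <- simulate_arg(p)
  set.seed(49)
  rs <- draw_root_sequence(p$genome)
  aln <- simulate_alignment(arg, rs)
  expect_equal(ncol(aln), 500L)   # columns = sum of fragment lengths
  expect_identical(rownames(aln), paste0("sample_", 1:6))
  for (i in 1:6) expect_identical(unname(aln[i, ]), rs)
})

test_that("an import marks exactly its tract on exactly its clade, making homoplasy", {
  # theta = 0 and a single external event: the only source of change
  found <- FALSE
  for (seed in 1:60) {
    p <- sim_params(n = 5, genome = genome_map(2000), theta = 0,
                    rho_ext = 0.0008, delta_ext = 300,
                    div_min = 0.4, div_max = 0.4, seed = seed)
    arg <- simulate_arg(p)
    if (arg$n_external != 1L) next
    found <- TRUE
    set.seed(1000 + seed)
    rs <- draw_root_sequence(p$genome)
    aln <- simulate_alignment(arg, rs)
    imp_node <- which(arg$nodes$kind == "external_import")
    tract <- node_material(arg, imp_node, "aux")
    site <- iset_sites(tract)[1L]
    clade <- local_tree(arg, site)$imports[[1L]]$clade$tips
    # every difference from the root lies inside the tract
    diff_from_root <- which(colSums(aln != matrix(rs, nrow(aln), ncol(aln),
                                                  byrow = TRUE)) > 0L)
    expect_true(all(diff_from_root %in% (iset_sites(tract) + 1L)))
    # and only clade members carry it
    for (cc in diff_from_root) {
      rows <- which(aln[, cc] != rs[cc])
      expect_true(all(rows %in% clade))
    }
    # the divergence is visible at rate ~ d inside the tract
    frac <- mean(aln[clade[1L], iset_sites(tract) + 1L] !=
                   rs[iset_sites(tract) + 1L])
    se <- sqrt(0.4 * 0.6 / total_sites(tract))
    expect_lt(abs(frac - 0.4), 4 * se)
    break
  }
  expect_true(found)
})

test_that("alignments stay at Jukes-Cantor stationarity under all processes", {
  p <- sim_params(n = 8, genome = genome_map(2e4), theta = 0.02,
                  rho_int = 0.02, delta_int = 200, rho_ext = 0.002,
                  delta_ext = 200, div_min = 0.1, div_max = 0.3, seed = 50)
  aln <- simulate_alignment(simulate_arg(p))
  fr <- table(factor(aln, levels = c("A", "C", "G", "T"))) / length(aln)
  # rows are correlated through shared ancestry; allow a generous band
  expect_true(all(abs(fr - 0.25) < 0.03))
})

test_that("Watterson's expectation governs segregating sites", {
  p <- sim_params(n = 10, genome = genome_map(2e4, circular = FALSE),
                  theta = 0.01)
  set.seed(51)
  S <- replicate(200, count_segregating(simulate_alignment(simulate_arg(p))))
  expS <- 0.01 * 2e4 * sum(1 / (1:9))
  se <- stats::sd(S) / sqrt(length(S))
  expect_lt(abs(mean(S) - expS), 3 * se)
})
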