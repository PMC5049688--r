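test_that("without recombination every site shares the clonal genealogy", {
  p <- sim_params(n = 6, genome = genome_map(100), seed = 31)
  arg <- simulate_arg(p)
  expect_identical(breakpoints(arg), c(0L, 100L))
  lt <- local_tree(arg, 50)
  expect_equal(tmrca(lt), arg$tmrca, tolerance = 1e-12)
  ph <- ape::read.tree(text = local_tree_newick(lt, theta = 0.01))
  expect_equal(branch_accuracy(clonal_frame(arg), ph), 1)
})

test_that("gap coordinates bear no local tree", {
  p <- sim_params(n = 3, genome = genome_map(fragments = "40:10,40:0"),
                  seed = 32)
  arg <- simulate_arg(p)
  expect_error(local_tree(arg, 45), "gap")
  expect_s3_class(local_tree(arg, 39), "local_tree")
})

test_that("local trees are ultrametric over their coalescent part", {
  p <- sim_params(n = 6, genome = genome_map(200), theta = 0,
                  rho_int = 0.08, delta_int = 20, seed = 33)
  arg <- simulate_arg(p)
  for (s in c(0L, 50L, 100L, 150L, 199L)) {
    lt <- local_tree(arg, s)
    d <- subtree_tip_depths(lt$root)
    expect_equal(length(d) + sum(vapply(lt$imports, function(im)
      length(im$clade$tips), 0L)), 6L)
    if (length(d) > 1L)
      expect_lt(max(abs(d - tmrca(lt))), 1e-9)
  }
})

test_that("the genome segmentation matches per-site genealogy classes exactly", {
  p <- sim_params(n = 4, genome = genome_map(60), theta = 0,
                  rho_int = 0.1, delta_int = 8, rho_ext = 0.05,
                  delta_ext = 5, div_min = 0.1, div_max = 0.2, seed = 15)
  arg <- simulate_arg(p)
  lt <- local_trees(arg)
  keys <- vapply(0:59, function(s)
    bacsim:::canon_local_tree(local_tree(arg, s)), "")
  seg_of_site <- findInterval(0:59, lt$segments$start)
  for (i in seq_len(nrow(lt$segments)))
    expect_length(unique(keys[seg_of_site == i]), 1L)
  for (i in seq_len(nrow(lt$segments) - 1L))
    expect_false(keys[which(seg_of_site == i)[1L]] ==
                   keys[which(seg_of_site == i + 1L)[1L]])
  # boundaries are a subset of recorded tract endpoints
  ev <- events_table(arg)
  ends <- unique(c(0L, 60L,
                   as.integer(unlist(strsplit(ev$tract_start, ";"))),
                   as.integer(unlist(strsplit(ev$tract_end, ";")))))
  expect_true(all(breakpoints(arg) %in% ends))
})

test_that("site TMRCA for two samples averages one coalescent unit", {
  p <- sim_params(n = 2, genome = genome_map(50), rho_int = 0.02,
                  delta_int = 10)
  set.seed(34)
  tm <- replicate(1500, tmrca(local_tree(simulate_arg(p), 25L)))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 1), 3 * se)
})

test_that("import clades carry their divergence and are tagged in Newick", {
  p <- sim_params(n = 4, genome = genome_map(300), theta = 0.01,
                  rho_ext = 0.01, delta_ext = 100, div_min = 0.15,
                  div_max = 0.15, seed = 35)
  arg <- simulate_arg(p)
  expect_gt(arg$n_external, 0L)
  ev <- events_table(arg)
  tract1 <- event_tract(arg, 1L)
  site <- iset_sites(tract1)[1L]
  lt <- local_tree(arg, site)
  expect_gt(length(lt$imports), 0L)
  for (im in lt$imports) expect_equal(im$d, 0.15)
  nwk <- local_tree_newick(lt, theta = 0.01)
  expect_match(nwk, "&import d=0.15", fixed = TRUE)
  # the grafted branch length is 2 d / theta in coalescent units
  expect_match(nwk, ":30\\[")
  # and d itself in substitutions-per-site units
  expect_match(local_tree_newick(lt, theta = 0.01, units = "subs"),
               ":0.15[", fixed = TRUE)
})

test_that("pairwise TMRCA correlation decays with genomic distance", {
  p <- sim_params(n = 2, genome = genome_map(400, circular = FALSE),
                  rho_int = 0.02, delta_int = 40)
  set.seed(36)
  tm <- t(replicate(1200, {
    arg <- simulate_arg(p)
    c(tmrca(local_tree(arg, 0L)), tmrca(local_tree(arg, 20L)),
      tmrca(local_tree(arg, 399L)))
  }))
  near <- stats::cor(tm[, 1L], tm[, 2L])
  far <- stats::cor(tm[, 1L], tm[, 3L])
  expect_gt(near, far)
})

test_that("circular genomes see symmetric TMRCA correlation", {
  G <- 240
  p <- sim_params(n = 2, genome = genome_map(G), rho_int = 0.03,
                  delta_int = 30)
  set.seed(37)
  tm <- t(replicate(1200, {
    arg <- simulate_arg(p)
    c(tmrca(local_tree(arg, 0L)), tmrca(local_tree(arg, 60L)),
      tmrca(local_tree(arg, G - 60L)))
  }))
  cfwd <- stats::cor(tm[, 1L], tm[, 2L])
  cbwd <- stats::cor(tm[, 1L], tm[, 3L])
  expect_lt(abs(cfwd - cbwd), 0.12)
  expect_gt(cfwd, 0)
  expect_gt(cbwd, 0)
})
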