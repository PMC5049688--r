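test_that("without recombination the ARG is the plain coalescent tree", {
  p <- sim_params(n = 7, genome = genome_map(500), seed = 1)
  arg <- simulate_arg(p)
  expect_equal(nrow(arg$nodes), 2L * 7L - 1L)
  expect_equal(arg$n_within, 0L)
  expect_equal(arg$n_external, 0L)
  expect_equal(nrow(events_table(arg)), 0L)
  tr <- clonal_frame(arg)
  expect_equal(ape::Ntip(tr), 7L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  expect_equal(tmrca(tr), arg$tmrca, tolerance = 1e-12)
})

test_that("a fixed seed reproduces the run byte for byte", {
  p <- sim_params(n = 5, genome = genome_map(2000), theta = 0.01,
                  rho_int = 0.02, delta_int = 100, rho_ext = 0.005,
                  delta_ext = 50, div_min = 0.1, div_max = 0.3, seed = 99)
  a1 <- simulate_arg(p); aln1 <- simulate_alignment(a1)
  a2 <- simulate_arg(p); aln2 <- simulate_alignment(a2)
  expect_identical(events_table(a1), events_table(a2))
  expect_identical(a1$nodes, a2$nodes)
  expect_identical(unclass(aln1), unclass(aln2))
})

test_that("every recombination split partitions material into two non-empty parts", {
  p <- sim_params(n = 6, genome = genome_map(fragments = "800:50,400:0"),
                  rho_int = 0.03, delta_int = 80, rho_ext = 0.004,
                  delta_ext = 60, div_min = 0.05, div_max = 0.2, seed = 5)
  arg <- simulate_arg(p)
  expect_gt(arg$n_within, 0L)
  nd <- arg$nodes
  for (v in which(nd$kind == "recomb_split")) {
    snap <- node_material(arg, v, "snapshot")
    don <- node_material(arg, v, "aux")
    expect_gt(total_sites(don), 0L)
    expect_gt(total_sites(iset_diff(snap, don)), 0L)
    expect_equal(total_sites(iset_intersect(don, snap)), total_sites(don))
  }
  for (v in which(nd$kind == "external_import")) {
    imp <- node_material(arg, v, "aux")
    expect_gt(total_sites(imp), 0L)
    expect_true(nd$div[v] >= 0.05 && nd$div[v] <= 0.2)
  }
  # ancestral material never contains fragment-gap sites
  gapset <- iset_diff(interval_set(0, p$genome$total_length), p$genome$spans)
  for (v in seq_len(nrow(nd)))
    expect_equal(total_sites(iset_intersect(node_material(arg, v), gapset)), 0L)
})

test_that("times increase strictly root-ward along every edge", {
  p <- sim_params(n = 5, genome = genome_map(1500), rho_int = 0.05,
                  delta_int = 100, seed = 8)
  arg <- simulate_arg(p)
  ed <- arg$edges
  expect_true(all(arg$nodes$time[ed$parent] > arg$nodes$time[ed$child]))
  # leaves number n at time 0 with full (sequence-bearing) material
  leaves <- which(arg$nodes$kind == "leaf")
  expect_length(leaves, 5L)
  expect_true(all(arg$nodes$time[leaves] == 0))
  for (v in leaves)
    expect_equal(unclass(node_material(arg, v)), unclass(p$genome$spans))
})

test_that("clonal TMRCA keeps the n-sample coalescent law at high recombination", {
  # recombination splits never remove the clonal lineage, so the clonal
  # genealogy matches the recombination-free coalescent in distribution
  g <- genome_map(2000)
  set.seed(20)
  t0 <- replicate(800, simulate_arg(sim_params(n = 6, genome = g))$tmrca)
  tR <- replicate(800, simulate_arg(
    sim_params(n = 6, genome = g, rho_int = 0.05, delta_int = 200))$tmrca)
  expect_gt(stats::ks.test(t0, tR)$p.value, 0.001)
})

test_that("mean clonal TMRCA matches the closed form 2(1 - 1/n)", {
  g <- genome_map(300)
  set.seed(21)
  tm <- replicate(1200, simulate_arg(
    sim_params(n = 4, genome = g, rho_int = 0.05, delta_int = 20))$tmrca)
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - coalescent_expectations(4)$tmrca), 3 * se)
})

test_that("the first-event race follows the effective external rate", {
  # n = 2, full circular material: external events compete with coalescence
  # at constant rates 2 (R_e/2) G versus 1 until the first event fires
  G <- 1000; Re <- 0.004
  g <- genome_map(G)
  p <- sim_params(n = 2, genome = g, rho_ext = Re, delta_ext = 20,
                  div_min = 0.1, div_max = 0.1)
  set.seed(22)
  ext_first <- replicate(2000, simulate_arg(p)$n_external > 0L)
  pr <- (Re * G) / (Re * G + 1)
  bt <- stats::binom.test(sum(ext_first), 2000, p = pr)
  expect_gt(bt$p.value, 0.001)
})

test_that("raw initiation counts pin the R/2 rate convention", {
  # measured in the rejection oracle: candidates arise at (R/2) G per
  # material-bearing lineage, so total candidates / ((R/2) G exposure) = 1
  p <- sim_params(n = 2, genome = genome_map(150, circular = FALSE),
                  rho_int = 0.04, delta_int = 10)
  set.seed(23)
  raw <- 0; expo <- 0
  for (i in 1:300) {
    r <- rejection_simulate_arg(p)
    raw <- raw + r$n_within_raw
    expo <- expo + r$lineage_time
  }
  ratio <- raw / (p$rho_int / 2 * 150 * expo)
  expect_lt(abs(ratio - 1), 0.05)
})

test_that("the event cap aborts runaway parameter sets informatively", {
  p <- sim_params(n = 10, genome = genome_map(5000), rho_int = 0.1,
                  delta_int = 500, seed = 3)
  expect_error(simulate_arg(p, max_events = 20), "event cap")
})
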