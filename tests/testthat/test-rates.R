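# The closed-form effective rates and the analytical event sampler are the
# heart of the simulator; both are held to the brute-force enumeration.

test_that("a single ancestral site admits no effective within-species event", {
  for (circ in c(TRUE, FALSE)) {
    g <- genome_map(10, circular = circ)
    expect_equal(effective_within_rate(interval_set(3, 4), g, delta = 2), 0)
    expect_equal(effective_within_rate(interval_set(3, 4), g, delta = 50), 0)
  }
  expect_error(effective_within_rate(interval_set(), genome_map(10), 2),
               "empty")
})

test_that("closed-form within rate equals brute-force enumeration exactly", {
  # whole linear genome (tail summed analytically past the truncation point)
  g10l <- genome_map(10, circular = FALSE)
  m <- interval_set(0, 10)
  expect_equal(effective_within_rate(m, g10l, 2, rho = 1),
               enum_within_rate(m, g10l, 2, rho = 1), tolerance = 1e-12)
  # two isolated sites on a circle: per-start bounds from the gap structure
  g10c <- genome_map(10)
  m2 <- interval_set(c(0, 5), c(1, 6))
  expect_equal(effective_within_rate(m2, g10c, 3),
               enum_within_rate(m2, g10c, 3), tolerance = 1e-12)
  set.seed(11)
  for (i in 1:15) {
    G <- sample(6:18, 1L)
    g <- genome_map(G, circular = runif(1) < 0.5)
    m <- random_interval_set(G)
    d <- runif(1, 1, 6)
    expect_equal(effective_within_rate(m, g, d), enum_within_rate(m, g, d),
                 tolerance = 1e-12)
  }
})

test_that("closed-form external rate equals enumeration; full genome gives R_e G / 2", {
  g <- genome_map(10)
  expect_equal(effective_external_rate(interval_set(0, 10), g, 2, rho = 0.3),
               0.3 * 10 / 2)
  gl <- genome_map(10, circular = FALSE)
  m <- interval_set(0, 1)
  expect_equal(effective_external_rate(m, gl, 2), enum_external_rate(m, gl, 2),
               tolerance = 1e-12)
  set.seed(12)
  for (i in 1:15) {
    G <- sample(6:18, 1L)
    g <- genome_map(G, circular = runif(1) < 0.5)
    m <- random_interval_set(G)
    d <- runif(1, 1, 6)
    expect_equal(effective_external_rate(m, g, d), enum_external_rate(m, g, d),
                 tolerance = 1e-12)
  }
})

test_that("sampled within-events always bipartition the material", {
  set.seed(13)
  for (i in 1:80) {
    G <- sample(8:30, 1L)
    g <- genome_map(G, circular = runif(1) < 0.5)
    m <- random_interval_set(G)
    if (effective_within_rate(m, g, 3) == 0) next
    r <- sample_within_event(m, g, 3)
    don <- iset_intersect(m, r$tract)
    expect_gt(total_sites(don), 0L)
    expect_gt(total_sites(iset_diff(m, don)), 0L)
  }
  expect_error(sample_within_event(interval_set(3, 4), genome_map(10), 2),
               "no effective")
})

test_that("two isolated sites are always separated by the sampled tract", {
  m <- interval_set(c(0, 5), c(1, 6))
  g <- genome_map(10, circular = FALSE)
  set.seed(14)
  for (i in 1:500) {
    tr <- sample_within_event(m, g, 2)$tract
    expect_true(xor(bacsim:::site_in(tr, 0L), bacsim:::site_in(tr, 5L)))
  }
})

test_that("within-event (s, l) law matches the enumerated distribution", {
  cases <- list(
    list(m = interval_set(0, 10), g = genome_map(10, circular = FALSE), d = 2),
    list(m = interval_set(c(0, 5), c(1, 6)), g = genome_map(10), d = 3),
    list(m = interval_set(c(2, 7, 10), c(5, 9, 11)), g = genome_map(14), d = 2.5))
  set.seed(15)
  for (cs in cases)
    expect_gt(within_sampler_pvalue(cs$m, cs$g, cs$d, ndraw = 5e4), 0.001)
})

test_that("start sites are uniform on a fully ancestral circle", {
  g <- genome_map(20)
  m <- interval_set(0, 20)
  set.seed(16)
  s <- vapply(1:3e4, function(i) sample_within_event(m, g, 3)$s, 0)
  p <- gof_pvalue(as.vector(table(factor(s, levels = 0:19))), rep(3e4 / 20, 20))
  expect_gt(p, 0.001)
})

test_that("huge delta on a linear genome degenerates to crossover-like splits", {
  g <- genome_map(50, circular = FALSE)
  m <- interval_set(0, 50)
  set.seed(17)
  for (i in 1:200) {
    r <- sample_within_event(m, g, 1e9)
    expect_equal(unclass(r$tract), unclass(interval_set(r$s, 50)))
  }
})

test_that("external tracts always touch material; lengths are geometric on a full circle", {
  set.seed(18)
  for (i in 1:60) {
    G <- sample(8:30, 1L)
    g <- genome_map(G, circular = runif(1) < 0.5)
    m <- random_interval_set(G)
    r <- sample_external_event(m, g, 3)
    expect_gt(total_sites(iset_intersect(m, r$tract)), 0L)
  }
  g <- genome_map(30)
  m <- interval_set(0, 30)
  ls <- vapply(1:3e4, function(i) sample_external_event(m, g, 4)$len, 0)
  pr <- dgeom(0:28, 1 / 4)
  pr <- c(pr, 1 - sum(pr))
  p <- gof_pvalue(as.vector(table(factor(pmin(ls, 30), levels = 1:30))),
                  pr * 3e4)
  expect_gt(p, 0.001)
})
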