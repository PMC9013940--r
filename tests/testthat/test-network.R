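# Gendered small-world generator: lattice construction, gender layouts,
# rewiring invariants, structural metrics, calibration.

test_that("ring lattice has the prescribed edges and degrees", {
  g <- build_ring_lattice(234, 4)
  expect_equal(igraph::ecount(g), 468)
  expect_true(all(igraph::degree(g) == 4))
  expect_true(igraph::is_simple(g))
  # k = n - 1 gives the complete graph
  g5 <- build_ring_lattice(5, 4)
  expect_equal(igraph::ecount(g5), 10)
  expect_true(all(igraph::degree(g5) == 4))
  # k = 2 is the n-cycle
  g6 <- build_ring_lattice(6, 2)
  expect_equal(igraph::ecount(g6), 6)
  expect_true(all(igraph::degree(g6) == 2))
  expect_error(build_ring_lattice(10, 3), "even")
  expect_error(build_ring_lattice(4, 4), "< n")
})

test_that("lattice clustering matches the closed form 3(k-2)/(4(k-1))", {
  for (k in c(4, 6, 8, 12)) {
    g <- assign_genders(build_ring_lattice(40, k), 20, "blocks")
    expect_equal(compute_metrics(g)$clustering_coefficient,
                 3 * (k - 2) / (4 * (k - 1)), tolerance = 1e-12)
  }
})

test_that("gender layouts place the requested number of females", {
  g <- build_ring_lattice(234, 4)
  gb <- assign_genders(g, 113, "blocks")
  expect_equal(sum(igraph::V(gb)$gender == "F"), 113)
  # blocks on a k=4 ring: 3 boundary-crossing links at each of the 2 cuts
  mets <- compute_metrics(gb)
  expect_equal(mets$link_proportions[["mf"]], 6 / 468, tolerance = 1e-12)
  # no females: no female-female or mixed links
  g0 <- assign_genders(g, 0, "random", seed = 1)
  p0 <- compute_metrics(g0)$link_proportions
  expect_equal(p0[["ff"]], 0)
  expect_equal(p0[["mf"]], 0)
  expect_equal(p0[["mm"]], 1)
  # random layout deterministic under a seed
  r1 <- assign_genders(g, 113, "random", seed = 9)
  r2 <- assign_genders(g, 113, "random", seed = 9)
  expect_identical(igraph::V(r1)$gender, igraph::V(r2)$gender)
  # interleaved alternates
  gi <- assign_genders(build_ring_lattice(10, 2), 5, "interleaved")
  expect_identical(igraph::V(gi)$gender, rep(c("F", "M"), 5))
})

test_that("rewiring preserves edge count and simplicity, p=0 is a no-op", {
  g <- assign_genders(build_ring_lattice(60, 6), 30, "blocks")
  expect_identical(igraph::as_edgelist(gendered_rewire(g, 0, 0.5, seed = 1)),
                   igraph::as_edgelist(g))
  for (s in 1:15) {
    p <- runif(1); q <- runif(1)
    rw <- gendered_rewire(g, p, q, seed = s)
    expect_equal(igraph::ecount(rw), 180)
    expect_equal(igraph::vcount(rw), 60)
    expect_true(igraph::is_simple(rw))
    expect_identical(igraph::V(rw)$gender, igraph::V(g)$gender)
  }
})

test_that("homophilous rewiring lowers the cross-gender link share", {
  base <- assign_genders(build_ring_lattice(120, 6), 58, "blocks")
  mf <- function(q, s) compute_metrics(
    gendered_rewire(base, 0.5, q, seed = s))$link_proportions[["mf"]]
  m0 <- mean(vapply(1:60, function(s) mf(0, s), numeric(1)))
  m1 <- mean(vapply(1:60, function(s) mf(1, s), numeric(1)))
  expect_lt(m1, m0)
})

test_that("clustering decays with rewiring probability", {
  base <- assign_genders(build_ring_lattice(120, 6), 60, "blocks")
  cc_at <- function(p) mean(vapply(1:40, function(s)
    compute_metrics(gendered_rewire(base, p, 0, seed = 100 + s))$clustering_coefficient,
    numeric(1)))
  ccs <- vapply(c(0, 0.05, 0.2, 1), cc_at, numeric(1))
  expect_equal(ccs[1], 0.6, tolerance = 1e-12)  # 3(k-2)/(4(k-1)) at k=6
  expect_true(all(diff(ccs) < 0))
})

test_that("metrics agree with brute-force oracles", {
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  m <- compute_metrics(k4)
  expect_equal(m$clustering_coefficient, 1)
  expect_equal(m$average_path_length, 1)
  # 3-node path: APL (1+1+2)/3
  path3 <- graph_from_adj(rbind(c(0, 1, 0), c(1, 0, 1), c(0, 1, 0)))
  expect_equal(compute_metrics(path3)$average_path_length, 4 / 3)
  # ring lattice APL against Floyd-Warshall
  ring <- assign_genders(build_ring_lattice(24, 4), 12, "blocks")
  expect_equal(compute_metrics(ring)$average_path_length,
               oracle_apl(adj_from_igraph(ring)), tolerance = 1e-12)
  expect_equal(compute_metrics(ring)$clustering_coefficient,
               oracle_local_cc(adj_from_igraph(ring)), tolerance = 1e-12)
  set.seed(8)
  for (i in 1:5) {
    A <- random_connected_graph(8, 0.35)
    g <- graph_from_adj(A, sample(c("F", "M"), 8, replace = TRUE))
    mm <- compute_metrics(g)
    expect_equal(mm$average_path_length, oracle_apl(A), tolerance = 1e-12)
    expect_equal(mm$clustering_coefficient, oracle_local_cc(A), tolerance = 1e-12)
    expect_equal(sum(mm$link_proportions), 1, tolerance = 1e-9)
  }
  # disconnected graphs: APL on the largest component, flagged
  two <- graph_from_adj(rbind(c(0, 1, 0, 0, 0), c(1, 0, 1, 0, 0),
                              c(0, 1, 0, 0, 0), c(0, 0, 0, 0, 1),
                              c(0, 0, 0, 1, 0)))
  md <- compute_metrics(two)
  expect_true(md$disconnected)
  expect_equal(md$average_path_length, 4 / 3)
})

test_that("generate_network composes deterministically under a seed", {
  spec <- network_spec(n = 234, n_female = 113, ring_degree = 6,
                       rewire_prob = 0.1, gender_layout = "blocks", seed = 5)
  n1 <- generate_network(spec)
  n2 <- generate_network(spec)
  expect_identical(igraph::as_edgelist(n1), igraph::as_edgelist(n2))
  expect_equal(igraph::vcount(n1), 234)
  expect_equal(igraph::ecount(n1), 234 * 6 / 2)
  expect_equal(sum(igraph::V(n1)$gender == "F"), 113)
  spec2 <- spec; spec2$seed <- 6
  expect_false(identical(igraph::as_edgelist(n1),
                         igraph::as_edgelist(generate_network(spec2))))
})

test_that("network files round-trip through GraphML and edge lists", {
  net <- generate_network(network_spec(n = 40, n_female = 19, ring_degree = 4,
                                       rewire_prob = 0.2, seed = 3))
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  back <- read_network_graphml(gml)
  expect_equal(igraph::vcount(back), 40)
  expect_identical(igraph::V(back)$gender, igraph::V(net)$gender)
  expect_identical(igraph::as_edgelist(back, names = FALSE),
                   igraph::as_edgelist(net, names = FALSE))
  elp <- tempfile(fileext = ".tsv")
  write_network_edgelist(net, elp)
  back2 <- read_network_edgelist(elp)
  expect_identical(igraph::V(back2)$gender, igraph::V(net)$gender)
  expect_equal(igraph::ecount(back2), igraph::ecount(net))
  unlink(c(gml, elp, paste0(elp, ".nodes")))
})

test_that("spec YAML/JSON round-trips", {
  spec <- network_spec(n = 100, n_female = 48, ring_degree = 6,
                       rewire_prob = 0.07, homophily_prob = 0.3,
                       gender_layout = "random", seed = 2)
  for (ext in c(".yaml", ".json")) {
    path <- tempfile(fileext = ext)
    write_network_spec(spec, path)
    expect_equal(read_network_spec(path), spec)
    unlink(path)
  }
})

test_that("calibration recovers a spec whose own metrics are the target", {
  # self-recovery: targets measured from one candidate's average metrics
  spec0 <- network_spec(n = 80, n_female = 40, ring_degree = 6,
                        rewire_prob = 0.05, gender_layout = "blocks")
  mets <- vapply(1:20, function(s) {
    sp <- spec0; sp$seed <- s
    m <- compute_metrics(generate_network(sp))
    c(m$clustering_coefficient, m$average_path_length, m$link_proportions)
  }, numeric(5))
  mu <- rowMeans(mets)
  targets <- metric_targets(mu[1], mu[2],
                            c(mm = mu[3], ff = mu[4], mf = mu[5]) / sum(mu[3:5]))
  cal <- calibrate_spec(targets, k_values = c(4, 6, 8),
                        p_values = c(0.01, 0.05, 0.2), q_values = 0,
                        layouts = "blocks", n = 80, n_female = 40,
                        n_reps = 20, seed = 99)
  expect_equal(cal$spec$ring_degree, 6)
  expect_equal(cal$spec$rewire_prob, 0.05)
  expect_lt(cal$loss, 0.15)
  expect_error(calibrate_spec(targets, k_values = numeric(0)), "empty")
})
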