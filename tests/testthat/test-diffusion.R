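# Contagion engine: deterministic limits, Markov-chain micro-oracles,
# stopping rules and run summaries.

test_that("zero spread never influences anyone beyond the seeds", {
  net <- path_net(6)
  traj <- run_diffusion(net, 1, uniform_params(0, max_ticks = 20), seed = 1)
  expect_true(all(traj$n_influenced == 1))
  expect_equal(attr(traj, "stop_reason"), "equilibrium")
})

test_that("deterministic wavefront advances one node per tick", {
  net <- path_net(5)
  traj <- run_diffusion(net, 1, uniform_params(1), seed = 1)
  expect_equal(traj$n_influenced, 1:5)
  expect_equal(max(traj$tick), 4)
  expect_equal(attr(traj, "stop_reason"), "absorbed")
  s <- summarize_run(traj)
  expect_equal(s$speed, 100 * (1 - 0.2) / 4)
})

test_that("total resistance strips all non-seeds after each tick", {
  net <- path_net(4)
  p <- uniform_params(1, r_male = 1, r_female = 1,
                      reversion_mode = "per_tick", max_ticks = 10)
  traj <- run_diffusion(net, 2, p, seed = 3)
  # influenced set returns to seeds whenever reversion fires
  expect_equal(traj$n_influenced[1], 1)
  final <- attr(traj, "final_state")
  # non-seed agents flip on then off; the seed persists throughout
  expect_true(final[2])
})

test_that("runs are reproducible under a seed and absorbing without resistance", {
  net <- generate_network(network_spec(n = 60, n_female = 30, ring_degree = 4,
                                       rewire_prob = 0.1, seed = 2))
  p <- uniform_params(0.4)
  t1 <- run_diffusion(net, 1:9, p, seed = 7)
  t2 <- run_diffusion(net, 1:9, p, seed = 7)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  # influence never recedes with zero resistance
  expect_true(all(diff(t1$n_influenced) >= 0))
  expect_equal(t1$n_influenced[nrow(t1)], 60)
  expect_equal(attr(t1, "stop_reason"), "absorbed")
})

test_that("single-step infection probability compounds as 1-(1-s)^j", {
  # B disjoint stars whose j leaves are all seeded: after one tick each
  # center is an independent Bernoulli(1 - (1-s)^j) draw
  s <- 0.2
  B <- 4000
  for (j in 1:3) {
    nv <- B * (j + 1)
    centers <- seq(1, nv, by = j + 1)
    el <- cbind(rep(centers, each = j),
                rep(centers, each = j) + sequence(rep(j, B)))
    net <- igraph::graph_from_edgelist(el, directed = FALSE)
    igraph::V(net)$gender <- "M"
    seeds <- setdiff(seq_len(nv), centers)
    p <- uniform_params(s, max_ticks = 1, equilibrium_window = 1,
                        equilibrium_tol = 0)
    hits <- numeric(0)
    for (rep in 1:5) {
      traj <- run_diffusion(net, seeds, p, seed = 100 * j + rep)
      hits <- c(hits, attr(traj, "final_state")[centers])
    }
    p_hat <- mean(hits)
    p_true <- 1 - (1 - s)^j
    expect_lt(abs(p_hat - p_true), 3.5 * sqrt(p_true * (1 - p_true) / length(hits)))
  }
})

test_that("state distribution matches exact Markov-chain enumeration", {
  # 3-node path, seed in the middle, per-tick reversion with resistance
  genders <- c("F", "M", "M")
  net <- path_net(3, genders)
  A <- adj_from_igraph(net)
  params <- diffusion_params(spread_chance = c(mm = 0.3, ff = 0.25, mf = 0.15),
                             resistance_chance = c(male = 0.1, female = 0.2),
                             reversion_mode = "per_tick", max_ticks = 3,
                             equilibrium_window = 1, equilibrium_tol = 0)
  spread <- matrix(0, 3, 3)
  spread[1, 2] <- spread[2, 1] <- 0.15   # F-M link
  spread[2, 3] <- spread[3, 2] <- 0.30   # M-M link
  resist <- c(0.2, 0.1, 0.1)
  exact <- markov_distribution_after(A, seeds = 2, spread, resist, t = 3)

  nrep <- 20000
  counts <- numeric(8)
  for (r in seq_len(nrep)) {
    traj <- run_diffusion(net, 2, params, seed = r)
    idx <- state_index(attr(traj, "final_state"))
    counts[idx] <- counts[idx] + 1
  }
  emp <- counts / nrep
  for (st in 1:8) {
    tol <- 4 * sqrt(max(exact[st] * (1 - exact[st]), 1e-6) / nrep)
    expect_lt(abs(emp[st] - exact[st]), tol + 1e-12)
  }
})

test_that("mean absorption time matches the exact chain expectation", {
  net <- path_net(3)
  A <- adj_from_igraph(net)
  spread <- A * 0.5
  expected <- markov_expected_absorption(A, seeds = 2, spread)
  expect_equal(expected, 8 / 3, tolerance = 1e-6)   # max of two geometrics
  nrep <- 10000
  p_abs <- uniform_params(0.5, max_ticks = 200, equilibrium_window = 1,
                          equilibrium_tol = 0)
  ticks <- vapply(seq_len(nrep), function(r) {
    max(run_diffusion(net, 2, p_abs, seed = 5000 + r)$tick)
  }, numeric(1))
  expect_lt(abs(mean(ticks) - expected), 4 * sd(ticks) / sqrt(nrep))
})

test_that("raising a spread chance does not slow expected progress", {
  net <- generate_network(network_spec(n = 60, n_female = 30, ring_degree = 4,
                                       rewire_prob = 0.1, seed = 9))
  prog <- function(s_mm) {
    p <- diffusion_params(spread_chance = c(mm = s_mm, ff = 0.2, mf = 0.1),
                          resistance_chance = c(male = 0, female = 0),
                          max_ticks = 5, equilibrium_window = 1,
                          equilibrium_tol = 0)
    mean(vapply(1:150, function(r) {
      traj <- run_diffusion(net, 1:9, p, seed = 300 + r)
      traj$n_influenced[nrow(traj)]
    }, numeric(1)))
  }
  expect_gt(prog(0.45), prog(0.1))
})

test_that("per-gender speeds recombine to the population speed", {
  net <- generate_network(network_spec(n = 80, n_female = 37, ring_degree = 6,
                                       rewire_prob = 0.1, seed = 12))
  p <- diffusion_params(reversion_mode = "on_influence")
  for (s in 1:5) {
    traj <- run_diffusion(net, select_random_seeds(net, 0.15, seed = s), p,
                          seed = 40 + s)
    su <- summarize_run(traj)
    expect_equal((37 / 80) * su$speed_female + (43 / 80) * su$speed_male,
                 su$speed, tolerance = 1e-10)
  }
})

test_that("success modes summarise the final fraction as specified", {
  net <- path_net(5)
  traj <- run_diffusion(net, 1, uniform_params(1), seed = 1)
  expect_equal(summarize_run(traj, "final_fraction")$success, 100)
  expect_equal(summarize_run(traj, "replicate_threshold", 0.99)$success, 100)
  still <- run_diffusion(net, 1, uniform_params(0, max_ticks = 15), seed = 1)
  expect_equal(summarize_run(still, "replicate_threshold", 0.5)$success, 0)
  expect_equal(summarize_run(still, "final_fraction")$success, 20)
})

test_that("an empty seed set warns and stays uninfluenced", {
  net <- path_net(4)
  expect_warning(traj <- run_diffusion(net, integer(0), uniform_params(0.5)),
                 "empty seed")
  expect_true(all(traj$n_influenced == 0))
})

test_that("trajectory CSV carries the stop reason on the last row", {
  net <- path_net(5)
  traj <- run_diffusion(net, 1, uniform_params(1), seed = 1)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(traj, path)
  df <- read.csv(path)
  expect_equal(df$stop_reason[nrow(df)], "absorbed")
  expect_equal(df$n_influenced, 1:5)
  unlink(path)
})
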