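test_that("initial-selection strategies follow their definitions", {
  ## path graph A - B - C with unit weights
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 1; W[2, 3] <- W[3, 2] <- 1
  g <- zip_graph(W, c("A", "B", "C"), "adjacency")
  expect_identical(select_initial(g, 2, "scattered", start = "A"), c(1L, 3L))

  ## star with centre S carrying the heaviest edges: closer picks the
  ## heaviest neighbour of S first
  Ws <- matrix(0, 4, 4)
  Ws[1, 2] <- Ws[2, 1] <- 0.9
  Ws[1, 3] <- Ws[3, 1] <- 0.4
  Ws[1, 4] <- Ws[4, 1] <- 0.7
  gs <- zip_graph(Ws, c("S", "B", "C", "D"), "aggregated_contact")
  expect_identical(select_initial(gs, 2, "closer", start = "S"), c(1L, 2L))
  expect_identical(select_initial(gs, 3, "closer", start = "S"),
                   c(1L, 2L, 4L))

  ## selecting all nodes returns V for every strategy
  for (st in c("random", "scattered", "closer"))
    expect_identical(select_initial(gs, 4, st, seed = 1), 1:4)
  expect_error(select_initial(gs, 5, "random"), "cannot select")

  ## seeded determinism of the random strategy
  expect_identical(select_initial(gs, 2, "random", seed = 7),
                   select_initial(gs, 2, "random", seed = 7))
})

test_that("scattered selection maximizes min weighted distance (brute force)", {
  g <- normalize_weights(rand_graph(8, density = 0.6, seed = 60))
  sel <- select_initial(g, 2, "scattered", start = 3)
  ## brute force: best partner for node 3 by shortest-path distance
  ig <- igraph::graph_from_adjacency_matrix(
    ifelse(g$W > 0, 1 / g$W, 0), mode = "undirected", weighted = TRUE)
  D <- igraph::distances(ig)
  best <- which.max(D[, 3])
  expect_identical(sort(c(3L, as.integer(best))), sel)
})

test_that("candidate scoring is the norm against the label vector", {
  expect_equal(al_distance(0.5, c(0, 1)), sqrt(0.5))
  expect_equal(al_distance(0.4, c(0.4, 0.4, 0.4)), 0)
  d1 <- al_distance(0.5, c(0, 1)); d2 <- al_distance(2.0, c(0, 1))
  expect_equal(d2, sqrt(4 + 1))
  expect_gt(d2, d1)  # the outlying prediction wins the argmax
})

test_that("the selection loop grows the labeled set deterministically", {
  sim <- simulate_study(sim_config(N = 15, TS = 6, seed = 61,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  ctl <- vaxstl_control(hidden = 8, t_hidden = 4, epochs = 30,
                        dropout = 0.2, eps = 0.05)

  r0 <- active_learn(panel, sim$graph, initial_size = 5, budget = 0,
                     control = ctl, seed = 61)
  expect_identical(r0$K, r0$initial_K)

  r2 <- active_learn(panel, sim$graph, initial_size = 5, budget = 2,
                     control = ctl, seed = 61)
  expect_length(r2$K, 7)
  expect_identical(nrow(r2$trace), 2L)
  expect_true(all(r2$initial_K %in% r2$K))
  expect_false(anyDuplicated(r2$K) > 0)
  expect_true(all(is.finite(r2$trace$score)))

  ## deterministic given the seed
  r2b <- active_learn(panel, sim$graph, initial_size = 5, budget = 2,
                      control = ctl, seed = 61)
  expect_identical(r2$K, r2b$K)
  expect_equal(r2$trace, r2b$trace)

  ## exhausting the node set selects everything regardless of scores
  rall <- active_learn(panel, sim$graph, initial_size = 13, budget = 2,
                       control = ctl, seed = 61)
  expect_identical(rall$K, 1:15)
  expect_error(active_learn(panel, sim$graph, initial_size = 13,
                            budget = 5, control = ctl, seed = 61),
               "exceeds")
})

test_that("a node whose labels sit far from the training labels is queried first", {
  ## planted outlier: one ZIP with extreme hesitancy and distinctive
  ## features; every other ZIP is homogeneous
  N <- 8; TS <- 5
  nc <- array(0.2, c(N, 2, TS))
  nc[8, 1, ] <- 0.95
  h <- matrix(0.1, N, TS)
  h[8, ] <- 0.6
  pan <- node_panel(sprintf("Z%02d", 1:N), sprintf("Q%d", 1:TS), nc, h,
                    matrix(100L, N, TS), c("a", "b"), normalized = TRUE)
  W <- matrix(1, N, N); diag(W) <- 0
  g <- zip_graph(W, pan$zips, "adjacency", normalized = TRUE)
  ctl <- vaxstl_control(hidden = 8, t_hidden = 4, epochs = 300,
                        dropout = 0, lr = 5e-3, eps = 0.05)
  res <- active_learn(pan, g, initial_size = 4, budget = 1,
                      initial_K = 1:4, control = ctl, seed = 3)
  expect_identical(res$trace$node[1], 8L)
})

test_that("al_score refuses candidates that are already labeled", {
  sim <- simulate_study(sim_config(N = 12, TS = 5, seed = 62,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  split <- train_split(panel, K = 1:6)
  fit <- vaxstl(panel, sim$graph, split,
                vaxstl_control(hidden = 4, t_hidden = 4, epochs = 10,
                               eps = 0.05), seed = 1)
  expect_error(al_score(fit, 3), "already")
  expect_true(is.finite(al_score(fit, 9)))
})
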