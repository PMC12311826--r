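test_that("a zero learning rate leaves both modules untouched", {
  sim <- simulate_study(sim_config(N = 12, TS = 5, seed = 70,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  split <- train_split(panel, 0.7, seed = 70)
  ctl0 <- vaxstl_control(hidden = 6, t_hidden = 4, epochs = 1, lr = 0,
                         lambda = 0, dropout = 0, eps = 0.05)
  ctl5 <- ctl0; ctl5$epochs <- 5
  f1 <- vaxstl(panel, sim$graph, split, ctl0, seed = 1)
  f5 <- vaxstl(panel, sim$graph, split, ctl5, seed = 1)
  expect_identical(coef(f1)$spatial, coef(f5)$spatial)
  expect_identical(coef(f1)$temporal, coef(f5)$temporal)
})

test_that("training is bitwise reproducible under a fixed seed", {
  sim <- simulate_study(sim_config(N = 12, TS = 5, seed = 71,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  split <- train_split(panel, 0.7, seed = 71)
  ctl <- vaxstl_control(hidden = 6, t_hidden = 4, epochs = 25,
                        dropout = 0.5, eps = 0.05)
  f1 <- vaxstl(panel, sim$graph, split, ctl, seed = 9)
  f2 <- vaxstl(panel, sim$graph, split, ctl, seed = 9)
  expect_identical(f1$trace, f2$trace)
  expect_identical(coef(f1), coef(f2))
  f3 <- vaxstl(panel, sim$graph, split, ctl, seed = 10)
  expect_false(identical(f1$trace, f3$trace))
})

test_that("the two losses touch disjoint parameter sets", {
  ## loss1 and its gradient are functions of the spatial parameters only:
  ## perturbing the temporal module cannot change them, and the spatial
  ## gradient names cover exactly the spatial parameters
  g <- normalize_weights(rand_graph(6, seed = 72))
  X <- matrix(rnorm(18), 6, 3)
  y <- runif(6, 0.1, 0.4)
  ms <- vaxscape:::with_seed(1, vaxscape:::ms_init(3, 4, 2))
  fw <- vaxscape:::ms_forward(ms, X, g$W)
  l <- vaxscape:::loss1(y, fw$yhat, 0.01, ms)
  gr <- vaxscape:::ms_backward(ms, fw$cache, l$dy)
  expect_identical(names(gr), names(ms))

  mt <- vaxscape:::with_seed(2, vaxscape:::mt_init(4, "lstm"))
  fw2 <- vaxscape:::mt_forward(mt, matrix(fw$yhat, 6, 1))
  gr2 <- vaxscape:::mt_backward(mt, fw2$cache, matrix(1, 6, 1))
  expect_identical(names(gr2), names(mt))
  expect_length(intersect(names(gr), names(gr2)),
                length(intersect(names(ms), names(mt))))

  ## and the Adam step on one module is a pure function of that module
  st <- vaxscape:::adam_init(ms)
  up <- vaxscape:::adam_step(ms, gr, st, 1e-3)
  expect_identical(names(up$par), names(ms))
})

test_that("cold-start predictions never read evaluation nodes' hesitancy", {
  sim <- simulate_study(sim_config(N = 15, TS = 6, seed = 73,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  split <- train_split(panel, 0.6, seed = 73)
  ctl <- vaxstl_control(hidden = 6, t_hidden = 4, epochs = 40,
                        dropout = 0.2, eps = 0.05)
  fit <- vaxstl(panel, sim$graph, split, ctl, seed = 4)
  p1 <- predict(fit)

  scrambled <- panel
  scrambled$h[split$eval, ] <- 0.99
  p2 <- predict(fit, panel = scrambled)
  expect_identical(p1, p2)
})

test_that("a linear hesitancy surface is recovered on a noiseless panel", {
  sim <- simulate_study(sim_config(N = 20, TS = 7, seed = 74,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  beta <- vaxscape:::default_beta() / 30
  hlin <- sapply(seq_along(panel$quarters),
                 function(t) as.vector(panel$nc[, , t] %*% beta))
  hlin <- 0.15 + hlin - min(hlin)
  pan <- node_panel(panel$zips, panel$quarters, panel$nc, pmin(hlin, 1),
                    panel$p, panel$feature_names, normalized = TRUE)
  split <- train_split(pan, 0.7, seed = 74)
  ctl <- vaxstl_control(hidden = 16, t_hidden = 8, epochs = 700,
                        dropout = 0, lambda = 0, lr = 2e-3)
  fit <- vaxstl(pan, sim$graph, split, ctl, seed = 0)
  Y <- vaxscape:::spatial_series(fit, pan, sim$graph)
  K <- split$K
  train_mape <- mape(as.vector(pan$h[K, 1:fit$T_train]), as.vector(Y[K, ]))
  expect_lt(train_mape, 0.1)
})

test_that("run_experiment produces a complete, reproducible report", {
  cfg <- list(seed = 5,
              sim = list(N = 18, TS = 6,
                         pop_lognormal = c(log(2000), 0.6)),
              split = list(train_frac = 0.7),
              control = list(hidden = 8, t_hidden = 4, epochs = 50,
                             dropout = 0.2, eps = 0.05))
  t0 <- Sys.time()
  rep1 <- run_experiment(cfg)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_named(rep1$metrics, c("mape", "mse", "rmse", "mae", "r2"))
  expect_true(all(vapply(rep1$metrics, is.finite, logical(1))))
  expect_identical(rep1$seed, 5)
  expect_match(rep1$config_hash, "^[0-9a-f]{32}$")

  rep2 <- run_experiment(cfg)
  expect_identical(rep1$metrics, rep2$metrics)
  expect_identical(rep1$predictions, rep2$predictions)

  ## written report round trip
  d <- withr::local_tempdir()
  cfg$out <- d
  run_experiment(cfg)
  disk <- jsonlite::read_json(file.path(d, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(disk$metrics$r2, rep1$metrics$r2, tolerance = 1e-12)
  expect_true(file.exists(file.path(d, "predictions.csv")))

  ## missing data paths error informatively
  expect_error(run_experiment(list(seed = 1,
                                   data = list(panel_dir = "nope_dir",
                                               graph_file = "nope.csv"))),
               "missing input")
})

test_that("multi-step forecasts run closed loop and respect the horizon cap", {
  sim <- simulate_study(sim_config(N = 15, TS = 8, seed = 75,
                                   pop_lognormal = c(log(2000), 0.6)))
  panel <- normalize_features(sim$panel)
  split <- train_split(panel, 0.7, seed = 75)
  ctl <- vaxstl_control(hidden = 6, t_hidden = 4, epochs = 30,
                        dropout = 0.2, horizon = 4, eps = 0.05)
  fit <- vaxstl(panel, sim$graph, split, ctl, seed = 2)
  pr <- predict(fit)
  expect_identical(dim(pr), c(length(split$eval), 4L))
  expect_identical(fit$T_train, 4L)  # TS - horizon
  expect_error(predict(fit, horizon = 5), "exceeds")

  ## horizon-1 predictions coincide with the first rollout column
  pr1 <- predict(fit, horizon = 1)
  expect_equal(pr[, 1], pr1[, 1])
})
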