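test_that("LSTM cell matches hand-coded gate equations", {
  H <- 3
  par <- vaxscape:::with_seed(1, vaxscape:::mt_init(H, "lstm"))
  x <- c(0.3, -0.5)
  fw <- vaxscape:::mt_forward(par, matrix(x, 2, 1))
  sig <- function(z) 1 / (1 + exp(-z))
  for (n in 1:2) {
    z <- x[n] * par$Wx + par$b  # h0 = 0
    i <- sig(z[1:H]); f <- sig(z[(H + 1):(2 * H)])
    g <- tanh(z[(2 * H + 1):(3 * H)]); o <- sig(z[(3 * H + 1):(4 * H)])
    cc <- i * g
    hh <- o * tanh(cc)
    want <- sum(hh * par$Wy) + par$by
    expect_lt(abs(fw$out[n, 1] - want), 1e-10)
  }
})

test_that("GRU cell matches hand-coded gate equations", {
  H <- 2
  par <- vaxscape:::with_seed(2, vaxscape:::mt_init(H, "gru"))
  x <- 0.7
  fw <- vaxscape:::mt_forward(par, matrix(x, 1, 1))
  sig <- function(z) 1 / (1 + exp(-z))
  zrz <- x * par$Wx + par$b
  r <- sig(zrz[1:H]); z <- sig(zrz[(H + 1):(2 * H)])
  n <- tanh(x * par$Wxn + r * 0 + par$bn)
  hh <- (1 - z) * n
  expect_lt(abs(fw$out[1, 1] - (sum(hh * par$Wy) + par$by)), 1e-10)
})

test_that("zero-weight recurrences output the head bias everywhere", {
  for (type in c("lstm", "gru")) {
    par <- vaxscape:::with_seed(3, vaxscape:::mt_init(4, type))
    zero <- lapply(par, function(x) x * 0)
    attributes(zero) <- attributes(par)
    zero$by <- 0.21
    fw <- vaxscape:::mt_forward(zero, matrix(rnorm(12), 3, 4))
    expect_equal(unname(fw$out), matrix(0.21, 3, 4))
    ## horizon-4 closed loop from a zero model: four copies of the bias
    pr <- vaxscape:::mt_forecast(zero, matrix(rnorm(8), 2, 4), horizon = 4)
    expect_equal(unname(pr), matrix(0.21, 2, 4))
  }
})

test_that("temporal loss aligns outputs one step ahead and matches an oracle", {
  par <- vaxscape:::with_seed(4, vaxscape:::mt_init(3, "lstm"))
  targets <- matrix(runif(12, 0.1, 0.5), 3, 4)
  mask <- matrix(TRUE, 3, 4)

  ## perfect predictions: zero loss
  fake_out <- cbind(targets[, 2:4], 0)
  l <- vaxscape:::loss2(fake_out, targets, mask, 0, par)
  expect_equal(l$value, 0)

  ## single aligned pair: |0.4 - 0.3| / 0.4 = 0.25
  tg <- matrix(c(0.9, 0.4), 1, 2)
  ou <- matrix(c(0.3, 99), 1, 2)  # only o(1) vs h(2) is in scope
  expect_equal(vaxscape:::loss2(ou, tg, matrix(TRUE, 1, 2), 0, par)$value,
               0.25)

  ## random batch vs flattened-vector oracle
  set.seed(9)
  out <- matrix(runif(12, 0.1, 0.6), 3, 4)
  msk <- matrix(runif(12) > 0.2, 3, 4)
  l2 <- vaxscape:::loss2(out, targets, msk, 0.05, par)
  o <- out[, 1:3][msk[, 2:4]]
  y <- targets[, 2:4][msk[, 2:4]]
  hand <- mean(abs(y - o) / pmax(abs(y), 1e-3)) +
    0.05 * vaxscape:::l2_term(par)
  expect_equal(l2$value, hand, tolerance = 1e-12)
})

test_that("temporal backprop matches finite differences", {
  par <- vaxscape:::with_seed(5, vaxscape:::mt_init(3, "lstm"))
  X <- matrix(rnorm(8, 0.2, 0.1), 2, 4)
  tg <- matrix(runif(8, 0.1, 0.5), 2, 4)
  msk <- matrix(TRUE, 2, 4)
  lossfun <- function(p) {
    fw <- vaxscape:::mt_forward(p, X)
    vaxscape:::loss2(fw$out, tg, msk, 0.01, p)$value
  }
  fw <- vaxscape:::mt_forward(par, X)
  l <- vaxscape:::loss2(fw$out, tg, msk, 0.01, par)
  gr <- vaxscape:::add_l2_grad(
    vaxscape:::mt_backward(par, fw$cache, l$dOut), par, 0.01)
  eps <- 1e-6
  for (nm in c("Wx", "Wh", "b", "Wy")) {
    for (k in c(1, length(par[[nm]]))) {
      pp <- par; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- par; pm[[nm]][k] <- pm[[nm]][k] - eps
      fd <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_lt(abs(fd - gr[[nm]][k]) / max(abs(fd), 1e-4), 1e-3)
    }
  }
})

test_that("forecasts are per-node independent and extend the sequence", {
  par <- vaxscape:::with_seed(6, vaxscape:::mt_init(4, "lstm"))
  X <- matrix(rnorm(20, 0.2, 0.05), 4, 5)
  fw <- vaxscape:::mt_forward(par, X)
  pr <- vaxscape:::mt_forecast(par, X, horizon = 1)
  expect_equal(pr[, 1], fw$out[, 5])  # horizon 1 = last output column

  ## editing other nodes' series leaves a node's forecast unchanged
  X2 <- X; X2[2:4, ] <- rnorm(15)
  pr2 <- vaxscape:::mt_forecast(par, X2, horizon = 3)
  pr1 <- vaxscape:::mt_forecast(par, X, horizon = 3)
  expect_equal(pr1[1, ], pr2[1, ])

  expect_error(vaxscape:::mt_forecast(par, X, horizon = 0), "horizon")
})

test_that("a trained sequence model reproduces a constant series", {
  ## constant input/target series: the model should learn to emit c
  cval <- 0.25
  N <- 8; TT <- 6
  pan <- node_panel(sprintf("Z%03d", 1:N), paste0("2019Q", rep(1:4, 2))[1:TT],
                    array(runif(N * 2 * TT), c(N, 2, TT)),
                    matrix(cval, N, TT), matrix(100L, N, TT), c("a", "b"),
                    normalized = TRUE)
  g <- normalize_weights(rand_graph(N, seed = 7))
  ctl <- vaxstl_control(spatial = "none", t_hidden = 8, epochs = 400,
                        dropout = 0, lr = 5e-3, lambda = 0, eps = 0.05)
  fit <- vaxstl(pan, g, train_split(pan, K = 1:6), ctl, seed = 1)
  pr <- predict(fit, nodes = 7:8)
  expect_lt(max(abs(pr - cval)), 0.05)
})

test_that("temporal training error decreases on a noiseless AR(1) panel", {
  N <- 10; TT <- 8
  vaxscape:::with_seed(11, {
    h <- matrix(0, N, TT)
    h[, 1] <- runif(N, 0.2, 0.4)
    for (t in 2:TT) h[, t] <- 0.05 + 0.85 * h[, t - 1]
  })
  pan <- node_panel(sprintf("Z%03d", 1:N), sprintf("Q%d", 1:TT),
                    array(runif(N * 2 * TT), c(N, 2, TT)), h,
                    matrix(100L, N, TT), c("a", "b"), normalized = TRUE)
  g <- normalize_weights(rand_graph(N, seed = 12))
  ctl <- vaxstl_control(spatial = "none", t_hidden = 8, epochs = 50,
                        dropout = 0, lr = 5e-3, lambda = 0, eps = 0.05)
  fit <- vaxstl(pan, g, train_split(pan, K = 1:8), ctl, seed = 2)
  tr <- fit$trace$loss2
  expect_lt(tr[50], tr[1])
  expect_lt(min(tr[41:50]), min(tr[1:10]))
})
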