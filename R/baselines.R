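#' Linear regression with neighbour information (LRN)
#'
#' Ordinary least squares from each node's features at the last training
#' quarter, augmented with one spatial feature — the weighted sum of
#' *labeled* neighbours' hesitancy, `sum_{j in N(i) & K} h_j(T) * a(i, j)`
#' — to the hesitancy at the target quarter. Fit on the labeled nodes,
#' applied to the evaluation nodes; nodes with no labeled neighbours get a
#' neighbour feature of 0. A singular design falls back to a small ridge
#' penalty with a warning.
#'
#' @param panel a normalized [node_panel()].
#' @param graph a weight-normalized [zip_graph()].
#' @param split a [train_split()].
#' @param target_step target quarter index; default `T + 1` with
#'   `T = target_step - 1 = TS - 1`.
#' @return List with `pred` (named vector over evaluation nodes),
#'   `coefficients`, and `T_train`.
#' @export
lrn_forecast <- function(panel, graph, split,
                         target_step = length(panel$quarters)) {
  Tt <- target_step - 1L
  assert_that(Tt >= 1, "target_step must exceed 1")
  K <- split$K; ev <- split$eval
  hT <- numeric(length(panel$zips))
  hT[K] <- panel$h[K, Tt]
  Wk <- graph$W[, K, drop = FALSE]
  neigh <- as.vector(Wk %*% panel$h[K, Tt])
  Xfull <- cbind(1, feature_matrix(panel, Tt), neigh)
  ok <- K[panel$mask[K, target_step]]
  Xk <- Xfull[ok, , drop = FALSE]
  yk <- panel$h[ok, target_step]
  fit <- stats::lm.fit(Xk, yk)
  beta <- fit$coefficients
  if (anyNA(beta)) {
    warning("singular LRN design; falling back to ridge (1e-6)")
    XtX <- crossprod(Xk) + diag(1e-6, ncol(Xk))
    beta <- solve(XtX, crossprod(Xk, yk))[, 1]
  }
  pred <- as.vector(Xfull[ev, , drop = FALSE] %*% beta)
  names(pred) <- panel$zips[ev]
  list(pred = pred, coefficients = beta, T_train = Tt)
}

## feedforward net on flattened per-node feature history
mlp_fit_predict <- function(panel, graph, split, ctl) {
  Tt <- ctl$T_train %||% (length(panel$quarters) - ctl$horizon)
  target <- Tt + ctl$horizon
  d <- dim(panel$nc)
  Xflat <- matrix(panel$nc[, , seq_len(Tt)], d[1], d[2] * Tt)
  K <- split$K
  ok <- K[panel$mask[K, target]]
  y <- panel$h[ok, target]
  hdim <- ctl$hidden
  par <- list(W1 = glorot(ncol(Xflat), hdim), b1 = rep(0, hdim),
              W2 = glorot(hdim, hdim), b2 = rep(0, hdim),
              W3 = glorot(hdim, 1), b3 = 0)
  st <- adam_init(par)
  fwd <- function(par, X, training = FALSE) {
    Z1 <- X %*% par$W1 + matrix(par$b1, nrow(X), hdim, byrow = TRUE)
    H1 <- relu(Z1)
    M1 <- if (training && ctl$dropout > 0) drop_mask(H1, ctl$dropout) else NULL
    if (!is.null(M1)) H1 <- H1 * M1
    Z2 <- H1 %*% par$W2 + matrix(par$b2, nrow(X), hdim, byrow = TRUE)
    H2 <- relu(Z2)
    M2 <- if (training && ctl$dropout > 0) drop_mask(H2, ctl$dropout) else NULL
    if (!is.null(M2)) H2 <- H2 * M2
    y <- as.vector(H2 %*% par$W3) + par$b3
    list(y = y, Z1 = Z1, H1 = H1, M1 = M1, Z2 = Z2, H2 = H2, X = X)
  }
  for (e in seq_len(ctl$epochs)) {
    fw <- fwd(par, Xflat[ok, , drop = FALSE], training = TRUE)
    dy <- mape_grad(y, fw$y, ctl$eps)
    dH2 <- outer(dy, as.vector(par$W3))
    if (!is.null(fw$M2)) dH2 <- dH2 * fw$M2
    dZ2 <- dH2 * (fw$Z2 > 0)
    dH1 <- dZ2 %*% t(par$W2)
    if (!is.null(fw$M1)) dH1 <- dH1 * fw$M1
    dZ1 <- dH1 * (fw$Z1 > 0)
    g <- list(W1 = t(fw$X) %*% dZ1, b1 = colSums(dZ1),
              W2 = t(fw$H1) %*% dZ2, b2 = colSums(dZ2),
              W3 = t(fw$H2) %*% dy, b3 = sum(dy))
    g <- add_l2_grad(g, par, ctl$lambda)
    up <- adam_step(par, g, st, ctl$lr)
    par <- up$par; st <- up$state
  }
  pred <- fwd(par, Xflat[split$eval, , drop = FALSE])$y
  names(pred) <- panel$zips[split$eval]
  pred
}

#' Fit a comparison model and forecast the target quarter
#'
#' Runs one of the comparison or ablation models under the same split and
#' panel as the main learner and returns its evaluation-set forecast:
#' \describe{
#'   \item{`lrn`}{linear regression with a labeled-neighbour feature
#'     (see [lrn_forecast()]).}
#'   \item{`mlp`}{feedforward net on each node's flattened feature
#'     history (no graph, no recurrence).}
#'   \item{`gnn_gru`}{the full model with the LSTM swapped for a GRU.}
#'   \item{`gcn_lstm`}{the full model with message passing swapped for
#'     symmetric-normalized-adjacency convolution with self-loops.}
#'   \item{`gnn_only`}{spatial module alone; the forecast reuses the last
#'     training quarter's features (persistence of features).}
#'   \item{`lstm_only`}{sequence model trained directly on labeled nodes'
#'     observed hesitancy series and applied to the evaluation nodes'
#'     *observed* series — note this reads evaluation nodes' histories,
#'     a different information regime from the cold-start models; reports
#'     should flag it.}
#' }
#'
#' @param name model name (see above).
#' @param panel,graph,split,control,seed as in [vaxstl()].
#' @return Named numeric vector of forecasts over `split$eval` at
#'   `T + horizon`.
#' @export
baseline_forecast <- function(name = c("lrn", "mlp", "gnn_gru", "gcn_lstm",
                                       "gnn_only", "lstm_only"),
                              panel, graph, split,
                              control = vaxstl_control(), seed = 1) {
  name <- match.arg(name)
  ctl <- control
  if (name == "lrn") {
    Tt <- ctl$T_train %||% (length(panel$quarters) - ctl$horizon)
    return(lrn_forecast(panel, graph, split,
                        target_step = Tt + ctl$horizon)$pred)
  }
  if (name == "mlp") return(with_seed(seed, mlp_fit_predict(panel, graph,
                                                            split, ctl)))
  ctl$spatial <- switch(name, gcn_lstm = "gcn", lstm_only = "none",
                        ctl$spatial)
  ctl$temporal <- switch(name, gnn_gru = "gru", gnn_only = "none",
                         ctl$temporal)
  fit <- vaxstl(panel, graph, split, ctl, seed = seed)
  predict(fit)[, ctl$horizon]
}
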