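#' Training controls for the spatio-temporal learner
#'
#' Collects the hyperparameters of the two-module model. Defaults mirror
#' the configuration used for full claims-scale panels (2 GraphConv layers
#' of 256 hidden units, an LSTM of 32 units, 50% dropout, Adam with
#' learning rate 5e-4, L2 weight 5e-4, 15000 epochs); desk-scale analyses
#' and the package's own tests pass much smaller `hidden` / `epochs`.
#'
#' @param n_layers number of message-passing layers in the spatial module.
#' @param hidden hidden width of the spatial module.
#' @param t_hidden hidden width of the temporal module.
#' @param dropout dropout rate in `[0, 1)` applied between spatial layers
#'   and on the recurrent output, active only in training mode.
#' @param lr Adam learning rate (both optimizers).
#' @param lambda L2 regularization weight on all weight matrices, added to
#'   each module's loss.
#' @param epochs number of training steps; one step is a pass over all
#'   training quarters (one Adam update of the spatial module per quarter)
#'   plus one update of the temporal module.
#' @param eps denominator floor used inside the MAPE losses.
#' @param spatial spatial module type: `"graphconv"` (order-1
#'   Weisfeiler-Leman message passing), `"gcn"` (symmetric-normalized
#'   adjacency with self-loops), or `"none"` (sequence-only ablation).
#' @param temporal temporal module type: `"lstm"`, `"gru"`, or `"none"`
#'   (spatial-only ablation).
#' @param loss2_alignment `"shift"` trains the sequence model one step
#'   ahead (output at t is compared with the target at t + 1), making the
#'   final output a genuine forecast; `"reconstruction"` compares output
#'   at t with the target at t.
#' @param lr_decay multiplicative step decay of the learning rate: the
#'   rate is multiplied by `lr_decay` at 60% and again at 85% of the
#'   epoch budget (1 = constant rate). Stabilises the final iterate on
#'   small panels.
#' @param ms_update `"per_quarter"` makes one Adam update of the spatial
#'   module per training quarter inside each epoch (the literal
#'   alternating schedule); `"batch"` accumulates the gradient over all
#'   quarters and makes a single update per epoch (smoother on small
#'   panels).
#' @param horizon forecast horizon the model is trained to serve (1 =
#'   next quarter). Multi-step forecasts run closed-loop.
#' @param T_train last training quarter index; defaults to
#'   `TS - horizon` so the panel's final quarter(s) are held out as the
#'   forecast target.
#' @param include_lagged_h append each node's lagged hesitancy h(t-1) to
#'   its features (labeled-node experiments only: this breaks the
#'   cold-start contract for unlabeled nodes).
#' @return A list of class `vaxstl_control`.
#' @export
vaxstl_control <- function(n_layers = 2, hidden = 256, t_hidden = 32,
                           dropout = 0.5, lr = 5e-4, lambda = 5e-4,
                           epochs = 15000, eps = 1e-3,
                           spatial = c("graphconv", "gcn", "none"),
                           temporal = c("lstm", "gru", "none"),
                           loss2_alignment = c("shift", "reconstruction"),
                           lr_decay = 1,
                           ms_update = c("per_quarter", "batch"),
                           horizon = 1, T_train = NULL,
                           include_lagged_h = FALSE) {
  assert_that(n_layers >= 1, "n_layers must be >= 1")
  assert_that(hidden >= 1 && t_hidden >= 1, "hidden sizes must be >= 1")
  assert_that(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  assert_that(lr >= 0, "lr must be nonnegative")
  assert_that(epochs >= 1, "epochs must be >= 1")
  assert_that(horizon >= 1, "horizon must be >= 1")
  structure(list(n_layers = n_layers, hidden = hidden, t_hidden = t_hidden,
                 dropout = dropout, lr = lr, lambda = lambda,
                 epochs = epochs, eps = eps,
                 spatial = match.arg(spatial),
                 temporal = match.arg(temporal),
                 loss2_alignment = match.arg(loss2_alignment),
                 lr_decay = lr_decay,
                 ms_update = match.arg(ms_update),
                 horizon = horizon, T_train = T_train,
                 include_lagged_h = isTRUE(include_lagged_h)),
            class = "vaxstl_control")
}

#' Split panel nodes into labeled and evaluation sets
#'
#' @param panel a [node_panel()] (or an integer N).
#' @param train_frac fraction of nodes labeled for training.
#' @param seed RNG seed for the uniform draw.
#' @param K explicit labeled set (ZIP names or indices); overrides
#'   `train_frac`.
#' @return A list of class `train_split` with integer index vectors `K`
#'   (labeled) and `eval` (the remaining nodes).
#' @export
train_split <- function(panel, train_frac = 0.7, seed = 1, K = NULL) {
  N <- if (inherits(panel, "node_panel")) length(panel$zips) else panel
  if (is.null(K)) {
    K <- with_seed(seed, sort(sample.int(N, max(1L, round(train_frac * N)))))
  } else if (is.character(K)) {
    K <- match(K, panel$zips)
    assert_that(!anyNA(K), "unknown ZIP in split")
    K <- sort(K)
  } else K <- sort(as.integer(K))
  assert_that(length(K) >= 1 && max(K) <= N, "invalid labeled set")
  structure(list(K = K, eval = setdiff(seq_len(N), K)),
            class = "train_split")
}

## feature matrix for quarter t, optionally with lagged hesitancy
feature_matrix <- function(panel, t, include_lagged_h = FALSE) {
  Xt <- panel$nc[, , t, drop = TRUE]
  if (is.null(dim(Xt))) Xt <- matrix(Xt, ncol = length(panel$feature_names))
  if (include_lagged_h) {
    lag <- if (t > 1) panel$h[, t - 1] else rep(0, nrow(Xt))
    Xt <- cbind(Xt, lag)
  }
  Xt
}

## Alternate training of the spatial module (per-quarter Adam updates
## against loss1) and the temporal module (one Adam update per epoch
## against loss2 on the spatial outputs, treated as constant inputs).
fit_engine <- function(panel, graph, split, ctl) {
  N <- length(panel$zips); TS <- length(panel$quarters)
  Tt <- as.integer(ctl$T_train %||% (TS - ctl$horizon))
  assert_that(Tt >= 2 && Tt < TS + 1, "need at least 2 training quarters")
  K <- split$K
  assert_that(length(K) >= 1, "empty labeled set")
  A <- if (ctl$spatial == "gcn") gcn_propagation(graph$W) else graph$W
  d_in <- length(panel$feature_names) + ctl$include_lagged_h
  ms <- NULL; mt <- NULL; st1 <- NULL; st2 <- NULL
  if (ctl$spatial != "none")
    ms <- ms_init(d_in, ctl$hidden, ctl$n_layers,
                  type = if (ctl$spatial == "gcn") "gcn" else "graphconv")
  if (ctl$temporal != "none") mt <- mt_init(ctl$t_hidden, ctl$temporal)
  if (!is.null(ms)) st1 <- adam_init(ms)
  if (!is.null(mt)) st2 <- adam_init(mt)
  hK <- panel$h[K, seq_len(Tt), drop = FALSE]
  mK <- panel$mask[K, seq_len(Tt), drop = FALSE]
  trace <- matrix(NA_real_, ctl$epochs, 2,
                  dimnames = list(NULL, c("loss1", "loss2")))
  for (e in seq_len(ctl$epochs)) {
    lr_e <- ctl$lr * ctl$lr_decay^((e > 0.6 * ctl$epochs) +
                                     (e > 0.85 * ctl$epochs))
    Y <- matrix(0, N, Tt)
    l1s <- rep(NA_real_, Tt)
    if (!is.null(ms)) {
      acc <- NULL
      for (t in seq_len(Tt)) {
        Xt <- feature_matrix(panel, t, ctl$include_lagged_h)
        fw <- ms_forward(ms, Xt, A, training = TRUE, dropout = ctl$dropout)
        sel <- K[panel$mask[K, t]]
        if (length(sel)) {
          l <- loss1(panel$h[sel, t], fw$yhat[sel], ctl$lambda, ms, ctl$eps)
          l1s[t] <- l$value
          dy <- numeric(N); dy[sel] <- l$dy
          g <- ms_backward(ms, fw$cache, dy)
          if (ctl$ms_update == "per_quarter") {
            g <- add_l2_grad(g, ms, ctl$lambda)
            up <- adam_step(ms, g, st1, lr_e)
            ms <- up$par; st1 <- up$state
          } else {
            acc <- if (is.null(acc)) g
            else Map(function(a, b) a + b, acc, g)
          }
        }
        ## the series handed to the temporal module is the deterministic
        ## (evaluation-mode) spatial output, matching what forecasting
        ## uses; it is a constant input to Mt's optimizer
        Y[, t] <- if (ctl$dropout > 0)
          ms_forward(ms, Xt, A, training = FALSE)$yhat else fw$yhat
      }
      if (ctl$ms_update == "batch" && !is.null(acc)) {
        nt <- sum(!is.na(l1s))
        acc <- lapply(acc, function(x) x / nt)
        acc <- add_l2_grad(acc, ms, ctl$lambda)
        up <- adam_step(ms, acc, st1, lr_e)
        ms <- up$par; st1 <- up$state
        ## Y was computed with pre-update weights; acceptable one-step lag
      }
    } else {
      Y <- panel$h[, seq_len(Tt), drop = FALSE]
    }
    l2v <- NA_real_
    if (!is.null(mt)) {
      fw2 <- mt_forward(mt, Y[K, , drop = FALSE], training = TRUE,
                        dropout = ctl$dropout)
      l2 <- loss2(fw2$out, hK, mK, ctl$lambda, mt, ctl$eps,
                  ctl$loss2_alignment)
      l2v <- l2$value
      g2 <- add_l2_grad(mt_backward(mt, fw2$cache, l2$dOut), mt, ctl$lambda)
      up <- adam_step(mt, g2, st2, lr_e)
      mt <- up$par; st2 <- up$state
    }
    trace[e, ] <- c(mean(l1s, na.rm = TRUE), l2v)
    bad <- trace[e, ][!is.na(trace[e, ])]
    if (length(bad) && !all(is.finite(bad)))
      stopf("non-finite loss at epoch %d (loss1=%.4g, loss2=%.4g): %s",
            e, trace[e, 1], trace[e, 2],
            "try a smaller learning rate or lambda")
  }
  list(ms = ms, mt = mt, A = A, T_train = Tt, trace = as.data.frame(trace))
}

#' Fit the spatio-temporal vaccine-hesitancy learner
#'
#' Trains the two-module model on a quarterly ZIP panel and a ZIP graph:
#' a spatial module (stacked order-1 Weisfeiler-Leman message-passing
#' layers with a linear head) regresses hesitancy on each quarter's
#' demographic features over the graph, and a temporal module (LSTM)
#' consumes the spatial module's per-quarter predictions as a scalar
#' series and forecasts the next quarter's hesitancy. The two modules are
#' optimized *separately*, each with its own Adam optimizer and its own
#' MAPE + L2 loss; the series fed to the temporal module is treated as a
#' constant input (no gradient flows back into the spatial module).
#' Only labeled nodes (`split$K`) contribute to either loss; message
#' passing always runs over the full graph so unlabeled nodes' features
#' inform their neighbours.
#'
#' @param panel a normalized [node_panel()].
#' @param graph a weight-normalized [zip_graph()] over the same ZIPs.
#' @param split a [train_split()].
#' @param control a [vaxstl_control()].
#' @param seed integer seed controlling parameter initialization and
#'   dropout; a fixed seed reproduces the loss trace bitwise.
#' @return An object of class `vaxstl` with components `ms`, `mt`
#'   (parameter lists), `trace` (per-epoch losses), and the inputs needed
#'   by [predict.vaxstl()].
#' @seealso [predict.vaxstl()], [baseline_forecast()], [active_learn()]
#' @examples
#' sim <- simulate_study(sim_config(N = 25, TS = 6, seed = 7))
#' panel <- normalize_features(sim$panel)
#' split <- train_split(panel, 0.7, seed = 7)
#' fit <- vaxstl(panel, sim$graph, split,
#'               vaxstl_control(hidden = 8, t_hidden = 4, epochs = 30),
#'               seed = 7)
#' predict(fit)[1:3, ]
#' @export
vaxstl <- function(panel, graph, split, control = vaxstl_control(),
                   seed = 1) {
  assert_that(inherits(panel, "node_panel"), "panel must be a node_panel")
  assert_that(inherits(graph, "zip_graph"), "graph must be a zip_graph")
  assert_that(identical(panel$zips, graph$zips),
              "panel and graph must share the same ZIP ordering")
  if (!panel$normalized)
    warning("panel features are not normalized; see normalize_features()")
  if (!graph$normalized && control$spatial == "graphconv")
    warning("graph weights are not normalized; see normalize_weights()")
  eng <- with_seed(seed, fit_engine(panel, graph, split, control))
  structure(list(ms = eng$ms, mt = eng$mt, trace = eng$trace,
                 T_train = eng$T_train, control = control, split = split,
                 panel = panel, graph = graph, seed = seed,
                 call = match.call()),
            class = "vaxstl")
}

## spatial-module series for all nodes, evaluation mode
spatial_series <- function(object, panel, graph) {
  ctl <- object$control
  Tt <- object$T_train
  N <- length(panel$zips)
  if (is.null(object$ms)) return(panel$h[, seq_len(Tt), drop = FALSE])
  A <- if (ctl$spatial == "gcn") gcn_propagation(graph$W) else graph$W
  Y <- matrix(0, N, Tt)
  for (t in seq_len(Tt))
    Y[, t] <- ms_forward(object$ms,
                         feature_matrix(panel, t, ctl$include_lagged_h),
                         A, training = FALSE)$yhat
  Y
}

#' Forecast hesitancy for a set of nodes
#'
#' Cold-start prediction: runs the spatial module over quarters 1..T with
#' full-graph message passing (all nodes' *features* participate; no
#' node's hesitancy label is read), then rolls the temporal module over
#' each requested node's predicted series. The output at the last input
#' step is the forecast for T + 1; longer horizons feed each prediction
#' back as the next input (closed loop). Deterministic: dropout is off.
#'
#' @param object a fitted [vaxstl()] model.
#' @param panel,graph data to predict on; default to the training inputs.
#' @param nodes integer indices or ZIP names; defaults to the evaluation
#'   set of the training split.
#' @param horizon number of quarters ahead; must not exceed the horizon
#'   the model was configured for.
#' @param ... unused.
#' @return Numeric matrix `[length(nodes), horizon]` with ZIP rownames.
#' @export
predict.vaxstl <- function(object, panel = object$panel,
                           graph = object$graph, nodes = NULL,
                           horizon = NULL, ...) {
  ctl <- object$control
  horizon <- horizon %||% ctl$horizon
  if (horizon > ctl$horizon)
    stopf("horizon %d exceeds the configured horizon %d", horizon,
          ctl$horizon)
  nodes <- nodes %||% object$split$eval
  if (is.character(nodes)) {
    nodes <- match(nodes, panel$zips)
    assert_that(!anyNA(nodes), "unknown ZIP in nodes")
  }
  Y <- spatial_series(object, panel, graph)
  if (!is.null(object$mt)) {
    preds <- mt_forecast(object$mt, Y[nodes, , drop = FALSE], horizon)
  } else {
    ## spatial-only ablation: forecast from the last observed features
    ## (persistence-of-features assumption for every horizon step)
    preds <- matrix(Y[nodes, object$T_train], length(nodes), horizon)
  }
  rownames(preds) <- panel$zips[nodes]
  colnames(preds) <- paste0("T+", seq_len(horizon))
  preds
}

#' @export
print.vaxstl <- function(x, ...) {
  ctl <- x$control
  cat(sprintf("Spatio-temporal hesitancy learner (%s + %s)\n",
              ctl$spatial, ctl$temporal))
  cat(sprintf("  %d ZIPs, trained on quarters 1..%d, %d labeled nodes\n",
              length(x$panel$zips), x$T_train, length(x$split$K)))
  le <- x$trace[nrow(x$trace), ]
  cat(sprintf("  final losses after %d epochs: loss1 = %.4f, loss2 = %s\n",
              nrow(x$trace), le$loss1,
              if (is.na(le$loss2)) "-" else sprintf("%.4f", le$loss2)))
  invisible(x)
}

#' @export
summary.vaxstl <- function(object, ...) {
  target <- object$T_train + object$control$horizon
  out <- list(model = object, target_step = target, metrics = NULL)
  if (target <= length(object$panel$quarters)) {
    ev <- object$split$eval
    ok <- ev[object$panel$mask[ev, target]]
    pred <- predict(object)[match(ok, object$split$eval),
                            object$control$horizon]
    out$metrics <- regression_metrics(object$panel$h[ok, target], pred,
                                      eps = object$control$eps)
  }
  class(out) <- "summary.vaxstl"
  out
}

#' @export
print.summary.vaxstl <- function(x, ...) {
  print(x$model)
  if (!is.null(x$metrics)) {
    cat(sprintf("Evaluation-set forecast at quarter %d (%s):\n",
                x$target_step,
                x$model$panel$quarters[x$target_step]))
    print(x$metrics)
  }
  invisible(x)
}

#' @export
coef.vaxstl <- function(object, ...) {
  list(spatial = object$ms, temporal = object$mt)
}

#' @export
residuals.vaxstl <- function(object, ...) {
  target <- object$T_train + object$control$horizon
  assert_that(target <= length(object$panel$quarters),
              "target quarter lies beyond the panel")
  ev <- object$split$eval
  pred <- predict(object)[, object$control$horizon]
  r <- object$panel$h[ev, target] - pred
  r[!object$panel$mask[ev, target]] <- NA
  r
}

#' @export
plot.vaxstl <- function(x, which = 1, ...) {
  if (1 %in% which) {
    tr <- x$trace
    graphics::matplot(seq_len(nrow(tr)), tr, type = "l", lty = 1,
                      col = c("steelblue", "firebrick"),
                      xlab = "epoch", ylab = "loss", ...)
    graphics::legend("topright", c("loss1 (spatial)", "loss2 (temporal)"),
                     lty = 1, col = c("steelblue", "firebrick"), bty = "n")
  }
  if (2 %in% which) {
    target <- x$T_train + x$control$horizon
    if (target <= length(x$panel$quarters)) {
      ev <- x$split$eval
      pred <- predict(x)[, x$control$horizon]
      obs <- x$panel$h[ev, target]
      graphics::plot(obs, pred, xlab = "observed hesitancy",
                     ylab = "forecast", ...)
      graphics::abline(0, 1, lty = 2)
    }
  }
  invisible(x)
}
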