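#' Order-1 Weisfeiler-Leman message-passing layer (GraphConv)
#'
#' Computes, for every node i,
#' `out_i = W_self x_i + W_neigh * sum_j W[i, j] x_j + bias`:
#' a learned combination of the node's own features and the weighted sum of
#' its neighbours' features. This is the k = 1 member of the k-GNN family;
#' a node with no neighbours depends only on its own features, and no
#' activation is applied (the caller inserts nonlinearities between stacked
#' layers).
#'
#' @param X numeric `[N, d_in]` node-feature matrix.
#' @param graph a [zip_graph()] (normally weight-normalized).
#' @param w_self numeric `[d_in, d_out]` self-weight matrix.
#' @param w_neigh numeric `[d_in, d_out]` neighbour-weight matrix.
#' @param bias numeric vector of length `d_out`.
#' @return Numeric `[N, d_out]` matrix.
#' @export
graph_conv <- function(X, graph, w_self, w_neigh, bias) {
  assert_that(nrow(X) == length(graph$zips), "X rows must match graph nodes")
  assert_that(ncol(X) == nrow(w_self) && ncol(X) == nrow(w_neigh),
              "weight shapes inconsistent with X")
  assert_that(ncol(w_self) == ncol(w_neigh) && ncol(w_self) == length(bias),
              "output shapes inconsistent")
  X %*% w_self + (graph$W %*% X) %*% w_neigh +
    matrix(bias, nrow(X), length(bias), byrow = TRUE)
}

## symmetric-normalized adjacency with self-loops (GCN propagation matrix)
gcn_propagation <- function(W) {
  A <- W
  diag(A) <- diag(A) + 1
  d <- rowSums(A)
  Dm <- 1 / sqrt(d)
  A * outer(Dm, Dm)
}

## ---- spatial module Ms -----------------------------------------------

## params: l{k}.Ws, l{k}.Wn, l{k}.b per layer (GraphConv) or l{k}.W, l{k}.b
## (GCN); head Whead (hidden x 1), bhead (scalar)
ms_init <- function(d_in, hidden, n_layers, type = c("graphconv", "gcn")) {
  type <- match.arg(type)
  par <- list()
  din <- d_in
  for (l in seq_len(n_layers)) {
    if (type == "graphconv") {
      par[[sprintf("Ws%d", l)]] <- glorot(din, hidden)
      par[[sprintf("Wn%d", l)]] <- glorot(din, hidden)
    } else {
      par[[sprintf("Wg%d", l)]] <- glorot(din, hidden)
    }
    par[[sprintf("b%d", l)]] <- rep(0, hidden)
    din <- hidden
  }
  par$Whead <- glorot(din, 1)
  par$bhead <- 0
  attr(par, "n_layers") <- n_layers
  attr(par, "type") <- type
  par
}

## forward pass; A is the (normalized) weight matrix, or the GCN
## propagation matrix for type "gcn". Activation (relu) and dropout are
## applied between conv layers only; the head is linear.
ms_forward <- function(par, X, A, training = FALSE, dropout = 0) {
  L <- attr(par, "n_layers")
  type <- attr(par, "type")
  H <- X
  cache <- list(H = vector("list", L + 1L), Z = vector("list", L),
                M = vector("list", L))
  cache$H[[1]] <- H
  for (l in seq_len(L)) {
    if (type == "graphconv") {
      Z <- H %*% par[[sprintf("Ws%d", l)]] +
        (A %*% H) %*% par[[sprintf("Wn%d", l)]]
    } else {
      Z <- (A %*% H) %*% par[[sprintf("Wg%d", l)]]
    }
    Z <- Z + matrix(par[[sprintf("b%d", l)]], nrow(Z), ncol(Z), byrow = TRUE)
    cache$Z[[l]] <- Z
    if (l < L) {
      Hl <- relu(Z)
      if (training && dropout > 0) {
        m <- drop_mask(Hl, dropout)
        cache$M[[l]] <- m
        Hl <- Hl * m
      }
      H <- Hl
    } else H <- Z
    cache$H[[l + 1L]] <- H
  }
  yhat <- as.vector(H %*% par$Whead) + par$bhead
  cache$A <- A
  list(yhat = yhat, cache = cache)
}

## backward pass: dy is dLoss/dyhat (length N); returns gradient list
ms_backward <- function(par, cache, dy) {
  L <- attr(par, "n_layers")
  type <- attr(par, "type")
  A <- cache$A
  grad <- lapply(par, function(x) x * 0)
  Hlast <- cache$H[[L + 1L]]
  grad$Whead <- t(Hlast) %*% dy
  grad$bhead <- sum(dy)
  dH <- outer(dy, as.vector(par$Whead))
  for (l in rev(seq_len(L))) {
    dZ <- dH
    if (l < L) {
      dZ <- dZ * (cache$Z[[l]] > 0)
      if (!is.null(cache$M[[l]])) dZ <- dZ * cache$M[[l]]
    }
    Hin <- cache$H[[l]]
    if (type == "graphconv") {
      grad[[sprintf("Ws%d", l)]] <- t(Hin) %*% dZ
      grad[[sprintf("Wn%d", l)]] <- t(A %*% Hin) %*% dZ
      grad[[sprintf("b%d", l)]] <- colSums(dZ)
      if (l > 1L)
        dH <- dZ %*% t(par[[sprintf("Ws%d", l)]]) +
          A %*% (dZ %*% t(par[[sprintf("Wn%d", l)]]))
    } else {
      AH <- A %*% Hin
      grad[[sprintf("Wg%d", l)]] <- t(AH) %*% dZ
      grad[[sprintf("b%d", l)]] <- colSums(dZ)
      if (l > 1L) dH <- A %*% (dZ %*% t(par[[sprintf("Wg%d", l)]]))
    }
  }
  grad
}

## loss1 = MAPE over labeled nodes + lambda * Lr; returns value and dyhat
loss1 <- function(y_true, y_pred, lambda, par, eps = 1e-3) {
  assert_that(length(y_true) > 0, "empty labeled set in loss1")
  list(value = mape(y_true, y_pred, eps) + lambda * l2_term(par),
       dy = mape_grad(y_true, y_pred, eps))
}
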