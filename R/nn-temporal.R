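## ---- temporal module Mt: LSTM / GRU over per-node scalar series -------
##
## Inputs are [N, T] matrices of per-node scalar series (the spatial
## module's predictions, or observed hesitancy for the sequence-only
## ablation). The recurrence is vectorized over nodes; each node's series
## is processed independently. The linear head maps the hidden state at
## input step t to an output o(t); under the one-step-ahead alignment,
## o(t) is the forecast of the target at t + 1.

## LSTM params: Wx (1 x 4H as vector 4H), Wh (H x 4H), b (4H, forget bias
## 1), head Wy (H), by. Gate order: input, forget, cell, output.
mt_init <- function(hidden, type = c("lstm", "gru")) {
  type <- match.arg(type)
  H <- hidden
  par <- if (type == "lstm") {
    b <- rep(0, 4 * H); b[(H + 1):(2 * H)] <- 1
    list(Wx = as.vector(glorot(1, 4 * H)), Wh = glorot(H, 4 * H), b = b,
         Wy = as.vector(glorot(H, 1)), by = 0)
  } else {
    list(Wx = as.vector(glorot(1, 2 * H)), Wh = glorot(H, 2 * H),
         b = rep(0, 2 * H),
         Wxn = as.vector(glorot(1, H)), Whn = glorot(H, H), bn = rep(0, H),
         Wy = as.vector(glorot(H, 1)), by = 0)
  }
  attr(par, "hidden") <- H
  attr(par, "type") <- type
  par
}

mt_forward <- function(par, Xseq, training = FALSE, dropout = 0) {
  H <- attr(par, "hidden")
  type <- attr(par, "type")
  N <- nrow(Xseq); TT <- ncol(Xseq)
  assert_that(TT >= 1, "temporal module needs at least one input step")
  hs <- matrix(0, N, H); cs <- matrix(0, N, H)
  out <- matrix(0, N, TT)
  cache <- list(type = type, steps = vector("list", TT), X = Xseq)
  for (t in seq_len(TT)) {
    x <- Xseq[, t]
    if (type == "lstm") {
      Z <- outer(x, par$Wx) + hs %*% par$Wh +
        matrix(par$b, N, 4 * H, byrow = TRUE)
      i <- sigm(Z[, 1:H, drop = FALSE])
      f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigm(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      cs_new <- f * cs + i * g
      tc <- tanh(cs_new)
      hs_new <- o * tc
      st <- list(i = i, f = f, g = g, o = o, c_prev = cs, tc = tc,
                 h_prev = hs, x = x)
    } else {
      Zrz <- outer(x, par$Wx) + hs %*% par$Wh +
        matrix(par$b, N, 2 * H, byrow = TRUE)
      r <- sigm(Zrz[, 1:H, drop = FALSE])
      z <- sigm(Zrz[, (H + 1):(2 * H), drop = FALSE])
      hn_lin <- hs %*% par$Whn
      n <- tanh(outer(x, par$Wxn) + r * hn_lin +
                  matrix(par$bn, N, H, byrow = TRUE))
      hs_new <- (1 - z) * n + z * hs
      cs_new <- cs
      st <- list(r = r, z = z, n = n, hn_lin = hn_lin, h_prev = hs, x = x)
    }
    hd <- hs_new
    if (training && dropout > 0) {
      m <- drop_mask(hd, dropout)
      st$m <- m
      hd <- hd * m
    }
    out[, t] <- as.vector(hd %*% par$Wy) + par$by
    st$hd <- hd
    cache$steps[[t]] <- st
    hs <- hs_new; cs <- cs_new
  }
  list(out = out, cache = cache, h_last = hs, c_last = cs)
}

mt_backward <- function(par, cache, dOut) {
  H <- attr(par, "hidden")
  type <- cache$type
  N <- nrow(dOut); TT <- ncol(dOut)
  grad <- lapply(par, function(x) x * 0)
  dh_next <- matrix(0, N, H)
  dc_next <- matrix(0, N, H)
  for (t in rev(seq_len(TT))) {
    st <- cache$steps[[t]]
    dout <- dOut[, t]
    grad$Wy <- grad$Wy + as.vector(t(st$hd) %*% dout)
    grad$by <- grad$by + sum(dout)
    dhd <- outer(dout, par$Wy)
    if (!is.null(st$m)) dhd <- dhd * st$m
    dh <- dhd + dh_next
    if (type == "lstm") {
      do_ <- dh * st$tc
      dc <- dh * st$o * (1 - st$tc^2) + dc_next
      di <- dc * st$g
      df <- dc * st$c_prev
      dg <- dc * st$i
      dZ <- cbind(di * st$i * (1 - st$i),
                  df * st$f * (1 - st$f),
                  dg * (1 - st$g^2),
                  do_ * st$o * (1 - st$o))
      grad$Wx <- grad$Wx + as.vector(st$x %*% dZ)
      grad$Wh <- grad$Wh + t(st$h_prev) %*% dZ
      grad$b <- grad$b + colSums(dZ)
      dh_next <- dZ %*% t(par$Wh)
      dc_next <- dc * st$f
    } else {
      dn <- dh * (1 - st$z)
      dz <- dh * (st$h_prev - st$n)
      dpre_n <- dn * (1 - st$n^2)
      dr <- dpre_n * st$hn_lin
      grad$Wxn <- grad$Wxn + as.vector(st$x %*% dpre_n)
      grad$Whn <- grad$Whn + t(st$h_prev) %*% (dpre_n * st$r)
      grad$bn <- grad$bn + colSums(dpre_n)
      dZrz <- cbind(dr * st$r * (1 - st$r), dz * st$z * (1 - st$z))
      grad$Wx <- grad$Wx + as.vector(st$x %*% dZrz)
      grad$Wh <- grad$Wh + t(st$h_prev) %*% dZrz
      grad$b <- grad$b + colSums(dZrz)
      dh_next <- dZrz %*% t(par$Wh) + (dpre_n * st$r) %*% t(par$Whn) +
        dh * st$z
    }
  }
  grad
}

## loss2: MAPE over one-step-ahead aligned, unmasked pairs + lambda * Lr.
## outputs o(t) are compared with targets h(t+1) for t = 1..T-1 under the
## "shift" alignment, or with h(t) under the literal "reconstruction"
## reading. Returns value and dOut matrix.
loss2 <- function(outputs, targets, mask, lambda, par, eps = 1e-3,
                  alignment = c("shift", "reconstruction")) {
  alignment <- match.arg(alignment)
  TT <- ncol(outputs)
  if (alignment == "shift") {
    assert_that(TT >= 2, "shift alignment needs TS >= 2")
    o <- outputs[, seq_len(TT - 1L), drop = FALSE]
    y <- targets[, 2:TT, drop = FALSE]
    m <- mask[, 2:TT, drop = FALSE]
    off <- 0L
  } else {
    o <- outputs; y <- targets; m <- mask; off <- 0L
  }
  sel <- which(m)
  assert_that(length(sel) > 0, "no unmasked pairs for loss2")
  val <- mape(y[sel], o[sel], eps) + lambda * l2_term(par)
  dO <- matrix(0, nrow(outputs), ncol(outputs))
  dsub <- matrix(0, nrow(o), ncol(o))
  dsub[sel] <- mape_grad(y[sel], o[sel], eps)
  if (alignment == "shift") dO[, seq_len(TT - 1L)] <- dsub else dO <- dsub
  list(value = val, dOut = dO)
}

## closed-loop forecast: run over the observed series, then feed each
## prediction back as the next input for horizon - 1 extra steps.
mt_forecast <- function(par, Xseq, horizon = 1) {
  assert_that(horizon >= 1, "horizon must be >= 1")
  fw <- mt_forward(par, Xseq, training = FALSE)
  N <- nrow(Xseq)
  preds <- matrix(0, N, horizon)
  preds[, 1] <- fw$out[, ncol(Xseq)]
  if (horizon > 1) {
    hs <- fw$h_last; cs <- fw$c_last
    x <- preds[, 1]
    for (k in 2:horizon) {
      step <- mt_step_state(par, x, hs, cs)
      preds[, k] <- step$out
      hs <- step$h; cs <- step$c
      x <- step$out
    }
  }
  preds
}

## single recurrence step from an explicit state (used by the rollout)
mt_step_state <- function(par, x, hs, cs) {
  H <- attr(par, "hidden")
  type <- attr(par, "type")
  N <- length(x)
  if (type == "lstm") {
    Z <- outer(x, par$Wx) + hs %*% par$Wh +
      matrix(par$b, N, 4 * H, byrow = TRUE)
    i <- sigm(Z[, 1:H, drop = FALSE])
    f <- sigm(Z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigm(Z[, (3 * H + 1):(4 * H), drop = FALSE])
    cs <- f * cs + i * g
    hs <- o * tanh(cs)
  } else {
    Zrz <- outer(x, par$Wx) + hs %*% par$Wh +
      matrix(par$b, N, 2 * H, byrow = TRUE)
    r <- sigm(Zrz[, 1:H, drop = FALSE])
    z <- sigm(Zrz[, (H + 1):(2 * H), drop = FALSE])
    n <- tanh(outer(x, par$Wxn) + r * (hs %*% par$Whn) +
                matrix(par$bn, N, H, byrow = TRUE))
    hs <- (1 - z) * n + z * hs
  }
  list(out = as.vector(hs %*% par$Wy) + par$by, h = hs, c = cs)
}
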