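## Minimal neural-network primitives: parameter lists are flat named lists
## of numeric arrays; names starting with "W" are weight matrices (subject
## to L2 regularization), others are biases.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

relu <- function(x) pmax(x, 0)

sigm <- function(x) 1 / (1 + exp(-x))

## inverted-dropout mask with the same shape as x
drop_mask <- function(x, rate) {
  if (rate <= 0) return(array(1, dim(x) %||% length(x)))
  m <- array(stats::rbinom(length(x), 1, 1 - rate) / (1 - rate),
             dim(x) %||% length(x))
  m
}

## sum of squared entries of all weight matrices (L2 term Lr)
l2_term <- function(par) {
  s <- 0
  for (nm in names(par)) if (startsWith(nm, "W")) s <- s + sum(par[[nm]]^2)
  s
}

## add d(lambda * Lr)/dW = 2 lambda W to gradients
add_l2_grad <- function(grad, par, lambda) {
  if (lambda == 0) return(grad)
  for (nm in names(par)) if (startsWith(nm, "W"))
    grad[[nm]] <- grad[[nm]] + 2 * lambda * par[[nm]]
  grad
}

adam_init <- function(par) {
  zero <- lapply(par, function(x) x * 0)
  list(m = zero, v = zero, t = 0L)
}

adam_step <- function(par, grad, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(par)) {
    g <- grad[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    par[[nm]] <- par[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(par = par, state = state)
}

#' Mean absolute percentage error
#'
#' `mean(|y - yhat| / max(|y|, eps))`: the training loss of both model
#' modules and the headline evaluation metric. Targets of exactly zero (no
#' refusals in a quarter) would make the ratio undefined, so the
#' denominator is floored at `eps`.
#'
#' @param y numeric vector of observed values.
#' @param yhat numeric vector of predictions.
#' @param eps floor applied to `|y|` in the denominator (default `1e-3`).
#' @return The MAPE as a plain fraction (0.25 means 25%).
#' @export
mape <- function(y, yhat, eps = 1e-3) {
  assert_that(length(y) == length(yhat), "length mismatch in mape")
  assert_that(length(y) > 0, "mape of empty vectors")
  mean(abs(y - yhat) / pmax(abs(y), eps))
}

## gradient of mape w.r.t. yhat
mape_grad <- function(y, yhat, eps = 1e-3) {
  sign(yhat - y) / (pmax(abs(y), eps) * length(y))
}
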