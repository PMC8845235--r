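# Compact feed-forward actor/critic networks with analytic backprop.
#
# Both networks consume the flattened W-day state window (daily features +
# rhythm one-hot + padding-mask channel, replicated-first-day padded, plus
# statics) and, optionally, a trainable diagnosis-embedding branch: each
# padded diagnosis index sequence is mapped through an embedding matrix and
# mean-pooled into a fixed-size vector that is concatenated to the window.
# Index 0 is padding (excluded from the mean); the last embedding row is the
# reserved unknown-code index. Gradients are exact and are verified against
# finite differences in the test suite.

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

new_net <- function(kind = c("actor", "critic", "dual"), d_state, K,
                    hidden = 64L, embed_rows = 0L, embed_dim = 8L) {
  kind <- match.arg(kind)
  use_diag <- embed_rows > 0L
  de <- if (use_diag) embed_dim else 0L
  params <- list()
  if (use_diag) params$E <- matrix(stats::rnorm(embed_rows * embed_dim, 0, 0.1),
                                   embed_rows, embed_dim)
  if (kind == "dual") {
    hx <- hidden
    hd <- max(4L, hidden %/% 4L)
    params$W1 <- glorot(d_state, hx)
    params$b1 <- numeric(hx)
    params$W1d <- glorot(de, hd)
    params$b1d <- numeric(hd)
    params$W2 <- glorot(hx + hd, K)
    params$b2 <- numeric(K)
  } else {
    d_in <- d_state + de + if (kind == "critic") K else 0L
    d_out <- if (kind == "critic") 1L else K
    params$W1 <- glorot(d_in, hidden)
    params$b1 <- numeric(hidden)
    params$W2 <- glorot(hidden, d_out)
    params$b2 <- numeric(d_out)
  }
  list(kind = kind, d_state = d_state, K = K, hidden = hidden,
       use_diag = use_diag, embed_dim = de, params = params)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# mean-pooled embedding of padded index sequences (0 = padding)
emb_mean <- function(E, Didx) {
  n <- nrow(Didx)
  de <- ncol(E)
  acc <- matrix(0, n, de)
  counts <- rowSums(Didx > 0L)
  for (p in seq_len(ncol(Didx))) {
    v <- which(Didx[, p] > 0L)
    if (length(v)) acc[v, ] <- acc[v, ] + E[Didx[v, p], , drop = FALSE]
  }
  list(vec = acc / pmax(counts, 1), counts = counts)
}

emb_backward <- function(E, Didx, dvec_grad, counts) {
  dE <- matrix(0, nrow(E), ncol(E))
  scaled <- dvec_grad / pmax(counts, 1)
  for (p in seq_len(ncol(Didx))) {
    v <- which(Didx[, p] > 0L)
    if (!length(v)) next
    agg <- rowsum(scaled[v, , drop = FALSE], group = Didx[v, p])
    rows <- as.integer(rownames(agg))
    dE[rows, ] <- dE[rows, ] + agg
  }
  dE
}

net_forward <- function(net, S, Didx = NULL, A = NULL) {
  p <- net$params
  emb <- NULL
  dvec <- NULL
  if (net$use_diag) {
    emb <- emb_mean(p$E, Didx)
    dvec <- emb$vec
  }
  if (net$kind == "dual") {
    Z1 <- sweep(S %*% p$W1, 2, p$b1, `+`)
    H1 <- tanh(Z1)
    Z1d <- sweep(dvec %*% p$W1d, 2, p$b1d, `+`)
    H1d <- tanh(Z1d)
    H <- cbind(H1, H1d)
    Z2 <- sweep(H %*% p$W2, 2, p$b2, `+`)
    out <- sigmoid(Z2)
    return(list(out = out,
                cache = list(S = S, Didx = Didx, emb = emb, H1 = H1,
                             H1d = H1d, H = H, out = out)))
  }
  X <- S
  if (net$use_diag) X <- cbind(X, dvec)
  if (net$kind == "critic") X <- cbind(X, A)
  Z1 <- sweep(X %*% p$W1, 2, p$b1, `+`)
  H1 <- tanh(Z1)
  Z2 <- sweep(H1 %*% p$W2, 2, p$b2, `+`)
  out <- if (net$kind == "critic") Z2 else sigmoid(Z2)
  list(out = out, cache = list(X = X, Didx = Didx, emb = emb, H1 = H1,
                               out = out))
}

# dZ2 = dLoss / d(output preactivation); returns gradients named like params
net_backward <- function(net, cache, dZ2) {
  p <- net$params
  g <- list()
  if (net$kind == "dual") {
    g$W2 <- t(cache$H) %*% dZ2
    g$b2 <- colSums(dZ2)
    dH <- dZ2 %*% t(p$W2)
    hx <- ncol(cache$H1)
    dZ1 <- dH[, seq_len(hx), drop = FALSE] * (1 - cache$H1^2)
    dZ1d <- dH[, -seq_len(hx), drop = FALSE] * (1 - cache$H1d^2)
    g$W1 <- t(cache$S) %*% dZ1
    g$b1 <- colSums(dZ1)
    g$W1d <- t(cache$emb$vec) %*% dZ1d
    g$b1d <- colSums(dZ1d)
    ddvec <- dZ1d %*% t(p$W1d)
    g$E <- emb_backward(p$E, cache$Didx, ddvec, cache$emb$counts)
    return(g)
  }
  g$W2 <- t(cache$H1) %*% dZ2
  g$b2 <- colSums(dZ2)
  dZ1 <- (dZ2 %*% t(p$W2)) * (1 - cache$H1^2)
  g$W1 <- t(cache$X) %*% dZ1
  g$b1 <- colSums(dZ1)
  if (net$use_diag) {
    ds <- net$d_state
    ddvec <- (dZ1 %*% t(p$W1))[, ds + seq_len(net$embed_dim), drop = FALSE]
    g$E <- emb_backward(p$E, cache$Didx, ddvec, cache$emb$counts)
  }
  g
}

# gradient of the critic output w.r.t. its action inputs (for the actor's
# deterministic policy gradient); dq is dLoss/d(critic output), N x 1
critic_action_grad <- function(critic, cache, dq) {
  p <- critic$params
  dZ1 <- (dq %*% t(p$W2)) * (1 - cache$H1^2)
  dX <- dZ1 %*% t(p$W1)
  a_cols <- ncol(cache$X) - critic$K + seq_len(critic$K)
  dX[, a_cols, drop = FALSE]
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Soft target-network update
#'
#' Moves every target parameter a fraction `tau` of the way to its live
#' counterpart: `theta' <- tau * theta + (1 - tau) * theta'`. `tau = 1`
#' copies the live network; `tau = 0` freezes the target.
#'
#' @param live,target named lists of numeric parameter arrays with matching
#'   names and shapes (e.g. the `$params` element of an actor or critic).
#' @param tau soft-update weight in `(0, 1]` (0 allowed for a frozen target).
#' @return the updated target parameter list.
#' @export
soft_update <- function(live, target, tau) {
  stopifnot(tau >= 0, tau <= 1, identical(names(live), names(target)))
  for (nm in names(live)) {
    target[[nm]] <- tau * live[[nm]] + (1 - tau) * target[[nm]]
  }
  target
}
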