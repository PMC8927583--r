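# Minimal neural-network engine: dense / batch-norm / dropout feed-forward
# stacks and stacked (bi)directional LSTM sequence classifiers, trained with
# Adam on binary cross-entropy. Written directly in R matrix algebra --
# model sizes here are tiny (9-128 inputs, tens of hidden units), so BLAS
# matmuls dominate and no compiled framework is needed. Analytic gradients
# are verified against finite differences in the test suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Binary cross-entropy loss
#'
#' `-(1/N) * sum(L_i log(y_i) + (1 - L_i) log(1 - y_i))` over N windows,
#' with predicted probabilities clipped to `(eps, 1 - eps)` so perfectly
#' confident predictions stay finite. At `y = 0.5` everywhere the loss is
#' `log(2)` regardless of the labels.
#'
#' @param labels 0/1 vector.
#' @param probabilities Predicted probabilities of the positive (high-load)
#'   class, same length.
#' @param eps Clipping constant.
#' @return Mean loss (scalar).
#' @export
bce_loss <- function(labels, probabilities, eps = 1e-7) {
  if (length(labels) != length(probabilities)) {
    abort("`labels` and `probabilities` must have the same length.")
  }
  if (!all(labels %in% c(0, 1))) abort("`labels` must be 0 or 1.")
  p <- pmin(pmax(probabilities, eps), 1 - eps)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

# ---- parameter containers ---------------------------------------------------

# He-scaled dense initialisation
init_dense <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out),
       b = rep(0, n_out))
}

n_params <- function(params) sum(vapply(params, length, integer(1)))

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  for (k in names(params)) {
    g <- grads[[k]]
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * g
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * g^2
    params[[k]] <- params[[k]] -
      lr * (state$m[[k]] / corr1) / (sqrt(state$v[[k]] / corr2) + eps)
  }
  list(params = params, state = state)
}

# inverted dropout mask (training only)
dropout_mask <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  array(stats::rbinom(prod(dims), 1, 1 - rate) / (1 - rate), dims)
}

# ---- feed-forward network ---------------------------------------------------

# params layout: W1,b1,gamma1,beta1, ..., W_out,b_out
# architecture per hidden layer: dense -> batchnorm -> ReLU -> dropout
init_feedforward <- function(input_dim, widths) {
  params <- list()
  d <- input_dim
  for (l in seq_along(widths)) {
    dn <- init_dense(d, widths[l])
    params[[paste0("W", l)]] <- dn$W
    params[[paste0("b", l)]] <- dn$b
    params[[paste0("gamma", l)]] <- rep(1, widths[l])
    params[[paste0("beta", l)]] <- rep(0, widths[l])
    d <- widths[l]
  }
  out <- init_dense(d, 1)
  params$W_out <- out$W
  params$b_out <- out$b
  params
}

init_bn_stats <- function(widths) {
  list(mean = lapply(widths, function(w) rep(0, w)),
       var = lapply(widths, function(w) rep(1, w)))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

ff_forward <- function(params, X, widths, dropout = 0, training = FALSE,
                       bn_stats = NULL) {
  B <- nrow(X)
  caches <- vector("list", length(widths))
  a <- X
  for (l in seq_along(widths)) {
    z <- a %*% params[[paste0("W", l)]] +
      rep(params[[paste0("b", l)]], each = B)
    if (training) {
      mu <- colMeans(z)
      v <- colMeans(z^2) - mu^2
      if (!is.null(bn_stats)) {
        bn_stats$mean[[l]] <- (1 - BN_MOMENTUM) * bn_stats$mean[[l]] + BN_MOMENTUM * mu
        bn_stats$var[[l]] <- (1 - BN_MOMENTUM) * bn_stats$var[[l]] + BN_MOMENTUM * v
      }
    } else {
      mu <- bn_stats$mean[[l]]
      v <- bn_stats$var[[l]]
    }
    zc <- z - rep(mu, each = B)
    inv_sd <- 1 / sqrt(v + BN_EPS)
    zhat <- zc * rep(inv_sd, each = B)
    bn <- zhat * rep(params[[paste0("gamma", l)]], each = B) +
      rep(params[[paste0("beta", l)]], each = B)
    h <- pmax(bn, 0)
    mask <- if (training) dropout_mask(dim(h), dropout) else NULL
    a_out <- if (is.null(mask)) h else h * mask
    caches[[l]] <- list(a_in = a, zhat = zhat, inv_sd = inv_sd, bn = bn,
                        mask = mask)
    a <- a_out
  }
  logit <- drop(a %*% params$W_out) + params$b_out
  list(prob = sigmoid(logit), a_last = a, caches = caches, bn_stats = bn_stats)
}

ff_backward <- function(params, fwd, y, widths) {
  B <- length(y)
  grads <- list()
  dlogit <- (fwd$prob - y) / B                    # BCE + sigmoid
  grads$W_out <- crossprod(fwd$a_last, dlogit)
  grads$b_out <- sum(dlogit)
  da <- outer(dlogit, drop(params$W_out))
  for (l in rev(seq_along(widths))) {
    cache <- fwd$caches[[l]]
    if (!is.null(cache$mask)) da <- da * cache$mask
    dbn <- da * (cache$bn > 0)                    # ReLU
    gamma <- params[[paste0("gamma", l)]]
    grads[[paste0("gamma", l)]] <- colSums(dbn * cache$zhat)
    grads[[paste0("beta", l)]] <- colSums(dbn)
    dzhat <- dbn * rep(gamma, each = B)
    # batch-norm backward through batch statistics
    m1 <- colMeans(dzhat)
    m2 <- colMeans(dzhat * cache$zhat)
    dz <- (dzhat - rep(m1, each = B) - cache$zhat * rep(m2, each = B)) *
      rep(cache$inv_sd, each = B)
    grads[[paste0("W", l)]] <- crossprod(cache$a_in, dz)
    grads[[paste0("b", l)]] <- colSums(dz)
    da <- dz %*% t(params[[paste0("W", l)]])
  }
  grads
}

# ---- LSTM -------------------------------------------------------------------

# Gate order in the 4h-wide weight blocks: input, forget, cell, output.
init_lstm_layer <- function(input_dim, hidden) {
  W <- matrix(rnorm(input_dim * 4 * hidden, 0, sqrt(1 / input_dim)),
              input_dim, 4 * hidden)
  U <- matrix(rnorm(hidden * 4 * hidden, 0, sqrt(1 / hidden)),
              hidden, 4 * hidden)
  b <- rep(0, 4 * hidden)
  b[(hidden + 1):(2 * hidden)] <- 1    # forget-gate bias init
  list(W = W, U = U, b = b)
}

# X: (B, d, L) array. Returns output sequence H (B, h, L) in input time
# order plus the final hidden state of the processing direction.
lstm_forward <- function(W, U, b, X, reverse = FALSE) {
  B <- dim(X)[1]
  L <- dim(X)[3]
  h <- ncol(U)
  hdim <- h / 4
  steps <- if (reverse) L:1 else 1:L
  H <- array(0, c(B, hdim, L))
  hprev <- matrix(0, B, hdim)
  cprev <- matrix(0, B, hdim)
  caches <- vector("list", L)
  ii <- 1:hdim
  ff <- hdim + ii
  gg <- 2 * hdim + ii
  oo <- 3 * hdim + ii
  for (t in steps) {
    A <- X[, , t, drop = FALSE]
    dim(A) <- c(B, dim(X)[2])
    Agate <- A %*% W + hprev %*% U + rep(b, each = B)
    i_g <- sigmoid(Agate[, ii, drop = FALSE])
    f_g <- sigmoid(Agate[, ff, drop = FALSE])
    g_g <- tanh(Agate[, gg, drop = FALSE])
    o_g <- sigmoid(Agate[, oo, drop = FALSE])
    c_t <- f_g * cprev + i_g * g_g
    tc <- tanh(c_t)
    h_t <- o_g * tc
    caches[[t]] <- list(x = A, hprev = hprev, cprev = cprev, i = i_g,
                        f = f_g, g = g_g, o = o_g, tc = tc)
    H[, , t] <- h_t
    hprev <- h_t
    cprev <- c_t
  }
  list(H = H, h_last = hprev, caches = caches, reverse = reverse)
}

# dH: (B, hdim, L) upstream sequence gradients (zero where unused);
# dh_last: gradient on the final state. Returns dX and parameter grads.
lstm_backward <- function(W, U, b, fwd, dH, dh_last = NULL) {
  caches <- fwd$caches
  L <- length(caches)
  B <- nrow(caches[[1]]$x)
  d <- ncol(caches[[1]]$x)
  hdim <- dim(dH)[2]
  steps <- if (fwd$reverse) L:1 else 1:L
  dW <- W * 0
  dU <- U * 0
  db <- b * 0
  dX <- array(0, c(B, d, L))
  dh_next <- if (is.null(dh_last)) matrix(0, B, hdim) else dh_last
  dc_next <- matrix(0, B, hdim)
  for (t in rev(steps)) {
    cache <- caches[[t]]
    dh <- dh_next + matrix(dH[, , t], B, hdim)
    do <- dh * cache$tc
    dc <- dh * cache$o * (1 - cache$tc^2) + dc_next
    di <- dc * cache$g
    dg <- dc * cache$i
    df <- dc * cache$cprev
    dc_next <- dc * cache$f
    dA <- cbind(di * cache$i * (1 - cache$i),
                df * cache$f * (1 - cache$f),
                dg * (1 - cache$g^2),
                do * cache$o * (1 - cache$o))
    dW <- dW + crossprod(cache$x, dA)
    dU <- dU + crossprod(cache$hprev, dA)
    db <- db + colSums(dA)
    dX[, , t] <- dA %*% t(W)
    dh_next <- dA %*% t(U)
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

# ---- recurrent classifier ---------------------------------------------------

# Architecture: per-timestep dimensionality-reducing dense map, then
# `n_layers` stacked LSTM layers (bidirectional when configured), dropout on
# the sequences between layers and on the final state, then a sigmoid head
# reading the final hidden state(s) of the last layer.
init_recurrent <- function(input_dim, reduce_units, hidden_units, n_layers,
                           bidirectional) {
  params <- list()
  red <- init_dense(input_dim, reduce_units)
  params$W_red <- red$W
  params$b_red <- red$b
  d <- reduce_units
  dirs <- if (bidirectional) c("f", "b") else "f"
  for (l in seq_len(n_layers)) {
    for (dr in dirs) {
      lay <- init_lstm_layer(d, hidden_units)
      params[[paste0("W", l, dr)]] <- lay$W
      params[[paste0("U", l, dr)]] <- lay$U
      params[[paste0("b", l, dr)]] <- lay$b
    }
    d <- hidden_units * length(dirs)
  }
  out <- init_dense(d, 1)
  params$W_out <- out$W
  params$b_out <- out$b
  params
}

rnn_forward <- function(params, X, cfg, training = FALSE) {
  B <- dim(X)[1]
  L <- dim(X)[3]
  dirs <- if (cfg$bidirectional) c("f", "b") else "f"
  # per-timestep affine reduction
  Xm <- matrix(aperm(X, c(1, 3, 2)), B * L, dim(X)[2])
  Zm <- Xm %*% params$W_red + rep(params$b_red, each = B * L)
  Z <- aperm(array(Zm, c(B, L, cfg$reduce_units)), c(1, 3, 2))
  layers <- vector("list", cfg$lstm_layers)
  inp <- Z
  masks <- vector("list", cfg$lstm_layers)
  for (l in seq_len(cfg$lstm_layers)) {
    outs <- lapply(dirs, function(dr) {
      lstm_forward(params[[paste0("W", l, dr)]], params[[paste0("U", l, dr)]],
                   params[[paste0("b", l, dr)]], inp, reverse = dr == "b")
    })
    H <- if (length(outs) == 2) {
      array(c(outs[[1]]$H, outs[[2]]$H),
            c(B, 2 * cfg$hidden_units, L))   # filled blockwise below
    } else {
      outs[[1]]$H
    }
    if (length(outs) == 2) {
      H[, seq_len(cfg$hidden_units), ] <- outs[[1]]$H
      H[, cfg$hidden_units + seq_len(cfg$hidden_units), ] <- outs[[2]]$H
    }
    mask <- if (training && l < cfg$lstm_layers) {
      dropout_mask(dim(H), cfg$dropout)
    } else {
      NULL
    }
    layers[[l]] <- outs
    masks[l] <- list(mask)
    inp <- if (is.null(mask)) H else H * mask
  }
  h_last <- do.call(cbind, lapply(layers[[cfg$lstm_layers]],
                                  function(o) o$h_last))
  head_mask <- if (training) dropout_mask(dim(h_last), cfg$dropout) else NULL
  h_drop <- if (is.null(head_mask)) h_last else h_last * head_mask
  logit <- drop(h_drop %*% params$W_out) + params$b_out
  list(prob = sigmoid(logit), layers = layers, masks = masks,
       head_mask = head_mask, h_drop = h_drop, Xm = Xm, B = B, L = L)
}

rnn_backward <- function(params, fwd, y, cfg) {
  B <- fwd$B
  L <- fwd$L
  h <- cfg$hidden_units
  dirs <- if (cfg$bidirectional) c("f", "b") else "f"
  grads <- list()
  dlogit <- (fwd$prob - y) / B
  grads$W_out <- crossprod(fwd$h_drop, dlogit)
  grads$b_out <- sum(dlogit)
  dh_drop <- outer(dlogit, drop(params$W_out))
  if (!is.null(fwd$head_mask)) dh_drop <- dh_drop * fwd$head_mask
  dh_last <- dh_drop
  dH_up <- array(0, c(B, h * length(dirs), L))
  for (l in rev(seq_len(cfg$lstm_layers))) {
    if (!is.null(fwd$masks[[l]])) dH_up <- dH_up * fwd$masks[[l]]
    dX_sum <- NULL
    for (di in seq_along(dirs)) {
      dr <- dirs[di]
      cols <- (di - 1) * h + seq_len(h)
      dH_dir <- dH_up[, cols, , drop = FALSE]
      dim(dH_dir) <- c(B, h, L)
      dhl <- if (l == cfg$lstm_layers && !is.null(dh_last)) {
        dh_last[, cols, drop = FALSE]
      } else {
        NULL
      }
      bk <- lstm_backward(params[[paste0("W", l, dr)]],
                          params[[paste0("U", l, dr)]],
                          params[[paste0("b", l, dr)]],
                          fwd$layers[[l]][[di]], dH_dir, dhl)
      grads[[paste0("W", l, dr)]] <- bk$dW
      grads[[paste0("U", l, dr)]] <- bk$dU
      grads[[paste0("b", l, dr)]] <- bk$db
      dX_sum <- if (is.null(dX_sum)) bk$dX else dX_sum + bk$dX
    }
    dH_up <- dX_sum
  }
  # back through the per-timestep reduction
  dZm <- matrix(aperm(dH_up, c(1, 3, 2)), B * L, cfg$reduce_units)
  grads$W_red <- crossprod(fwd$Xm, dZm)
  grads$b_red <- colSums(dZm)
  grads
}

# stack a list of (d x L) matrices into a (B, d, L) array
stack_windows <- function(feature_list) {
  d <- nrow(feature_list[[1]])
  L <- ncol(feature_list[[1]])
  aperm(array(unlist(feature_list), c(d, L, length(feature_list))),
        c(3, 1, 2))
}
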