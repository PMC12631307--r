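# Masked-loss multitask feed-forward regressor.
#
# Architecture: features -> two ReLU hidden layers -> linear heads, one per
# endpoint. The output layer is decomposed into a shared weight vector plus
# L2-penalized task-specific deltas: tasks with abundant data shape the
# shared component, and a task with little or no data falls back on it.
# This is what gives the model its cross-learning and zero-shot behaviour
# on correlated endpoints. Targets are standardized per task over observed
# training cells and de-standardized at prediction. The loss is mean squared
# error over observed cells only (see masked_loss()).

#' Configuration for the multitask regressor
#'
#' @param hidden sizes of the two hidden layers.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param patience early-stopping patience (epochs without validation
#'   improvement before stopping; best weights are restored).
#' @param val_frac fraction of training compounds held out for early
#'   stopping.
#' @param l2_shared weight decay on shared weights.
#' @param l2_task weight decay on task-specific output deltas; larger values
#'   tie the endpoint heads more strongly together.
#' @return A list of class `mtl_config`.
#' @export
mtl_config <- function(hidden = c(64, 32), epochs = 200, batch_size = 256,
                       lr = 0.01, patience = 20, val_frac = 0.1,
                       l2_shared = 1e-4, l2_task = 0.05) {
  structure(list(hidden = hidden, epochs = epochs, batch_size = batch_size,
                 lr = lr, patience = patience, val_frac = val_frac,
                 l2_shared = l2_shared, l2_task = l2_task),
            class = "mtl_config")
}

#' Mean squared error over observed cells only
#'
#' The training loss of the multitask regressor: squared errors are averaged
#' over cells where the observation mask is `TRUE`; predictions at
#' unobserved cells do not enter the loss at all.
#'
#' @param pred,target numeric matrices (rows = compounds, columns = tasks).
#' @param mask logical or 0/1 matrix of the same shape.
#' @return Scalar loss; 0 with a warning when the mask is empty.
#' @export
masked_loss <- function(pred, target, mask) {
  stopifnot(all(dim(pred) == dim(target)), all(dim(pred) == dim(mask)))
  m <- (mask > 0) * 1
  s <- sum(m)
  if (s == 0) {
    warning("masked_loss: empty mask; loss defined as 0")
    return(0)
  }
  sum(m * (pred - target)^2, na.rm = TRUE) / s
}

relu <- function(x) (x > 0) * x

nn_init <- function(d_in, hidden, n_tasks) {
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)), nr, nc)
  list(W1 = he(d_in, hidden[1]), b1 = rep(0, hidden[1]),
       W2 = he(hidden[1], hidden[2]), b2 = rep(0, hidden[2]),
       wc = stats::rnorm(hidden[2], 0, sqrt(1 / hidden[2])), bc = 0,
       V = matrix(0, hidden[2], n_tasks), bt = rep(0, n_tasks))
}

nn_forward <- function(par, X) {
  Z1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  A1 <- relu(Z1)
  Z2 <- sweep(A1 %*% par$W2, 2, par$b2, "+")
  A2 <- relu(Z2)
  W3 <- par$V + par$wc
  P <- sweep(A2 %*% W3, 2, par$bt + par$bc, "+")
  list(P = P, A1 = A1, A2 = A2, Z1 = Z1, Z2 = Z2)
}

nn_grads <- function(par, X, Y, M, cfg) {
  fw <- nn_forward(par, X)
  s <- max(1, sum(M))
  dP <- 2 * M * (fw$P - Y) / s
  W3 <- par$V + par$wc
  dW3 <- crossprod(fw$A2, dP)
  db3 <- colSums(dP)
  dA2 <- dP %*% t(W3)
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$A1, dZ2) + 2 * cfg$l2_shared * par$W2
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(par$W2)
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(X, dZ1) + 2 * cfg$l2_shared * par$W1
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
       wc = rowSums(dW3) + 2 * cfg$l2_shared * par$wc,
       bc = sum(db3),
       V = dW3 + 2 * cfg$l2_task * par$V,
       bt = db3 + 2 * cfg$l2_task * par$bt)
}

adam_state <- function(par) {
  list(m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0), t = 0)
}

adam_step <- function(par, grads, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  for (nm in names(par)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

# core trainer on numeric matrices; y standardized per task beforehand
nn_train <- function(X, Y, M, cfg, seed) {
  with_seed(seed, {
    n <- nrow(X)
    par <- nn_init(ncol(X), cfg$hidden, ncol(Y))
    st <- adam_state(par)
    n_val <- max(1, floor(cfg$val_frac * n))
    val_idx <- sample(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (sum(M[val_idx, , drop = FALSE]) == 0 || length(tr_idx) < 2) {
      val_idx <- integer(0)
      tr_idx <- seq_len(n)
    }
    Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
    Mtr <- M[tr_idx, , drop = FALSE]
    best <- list(loss = Inf, par = par, epoch = 0)
    stale <- 0
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(nrow(Xtr))
      starts <- seq(1, nrow(Xtr), by = cfg$batch_size)
      for (s0 in starts) {
        idx <- ord[s0:min(s0 + cfg$batch_size - 1, nrow(Xtr))]
        if (sum(Mtr[idx, , drop = FALSE]) == 0) next
        g <- nn_grads(par, Xtr[idx, , drop = FALSE], Ytr[idx, , drop = FALSE],
                      Mtr[idx, , drop = FALSE], cfg)
        upd <- adam_step(par, g, st, cfg$lr)
        par <- upd$par; st <- upd$st
      }
      if (length(val_idx)) {
        pv <- nn_forward(par, X[val_idx, , drop = FALSE])$P
        vl <- masked_loss(pv, Y[val_idx, , drop = FALSE], M[val_idx, , drop = FALSE])
        if (vl < best$loss - 1e-6) {
          best <- list(loss = vl, par = par, epoch = epoch)
          stale <- 0
        } else {
          stale <- stale + 1
          if (stale >= cfg$patience) break
        }
      } else {
        best <- list(loss = NA_real_, par = par, epoch = epoch)
      }
    }
    best
  })
}
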