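# Minimal dual-branch 1D convolutional network (internal engine).
#
# Architecture: each input (normalized intensity trace; autocorrelation)
# feeds its own conv1d -> ReLU -> max-pool branch; the flattened branch
# outputs are concatenated into one fully connected ReLU layer and a
# softmax output, trained end-to-end with cross-entropy, elastic-net
# weight regularization and Adam. Implemented directly on BLAS-backed
# matrix ops; model sizes here are tiny (inputs of ~64 points), so no
# external deep-learning framework is needed.

relu <- function(x) (x + abs(x)) / 2

im2col <- function(X, k) {
  # X: N x T -> (N*out_len) x k, row index (pos-1)*N + n
  T <- ncol(X); out_len <- T - k + 1L
  Xc <- matrix(0, nrow(X) * out_len, k)
  for (j in seq_len(k)) Xc[, j] <- as.vector(X[, j:(j + out_len - 1L)])
  Xc
}

nn_dims <- function(spec, T_i, T_g, n_classes) {
  br <- spec$branches
  k <- spec$kernel_size
  dims <- list()
  feat <- 0L
  if (br %in% c("both", "intensity")) {
    dims$out_i <- T_i - k + 1L
    dims$pool_i <- dims$out_i %/% spec$pool_size
    feat <- feat + dims$pool_i * spec$n_kernels
  }
  if (br %in% c("both", "frequency")) {
    dims$out_g <- T_g - k + 1L
    dims$pool_g <- dims$out_g %/% spec$pool_size
    feat <- feat + dims$pool_g * spec$n_kernels
  }
  dims$feat <- feat
  dims$n_classes <- n_classes
  dims
}

nn_init <- function(spec, T_i, T_g, n_classes, seed) {
  if (spec$branches %in% c("both", "intensity") && T_i < spec$kernel_size)
    stopf("trace length %d shorter than kernel size %d", T_i,
          spec$kernel_size)
  if (spec$branches %in% c("both", "frequency") && T_g < spec$kernel_size)
    stopf("autocorrelation length %d shorter than kernel size %d", T_g,
          spec$kernel_size)
  d <- nn_dims(spec, T_i, T_g, n_classes)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  with_seed(seed, {
    p <- list()
    if (spec$branches %in% c("both", "intensity")) {
      p$ci_W <- he(spec$kernel_size, spec$n_kernels)
      p$ci_b <- rep(0, spec$n_kernels)
    }
    if (spec$branches %in% c("both", "frequency")) {
      p$cg_W <- he(spec$kernel_size, spec$n_kernels)
      p$cg_b <- rep(0, spec$n_kernels)
    }
    p$d1_W <- he(d$feat, spec$dense_units)
    p$d1_b <- rep(0, spec$dense_units)
    p$d2_W <- he(spec$dense_units, n_classes)
    p$d2_b <- rep(0, n_classes)
    list(params = p, dims = d)
  })
}

branch_forward <- function(X, W, b, spec) {
  N <- nrow(X)
  k <- spec$kernel_size
  out_len <- ncol(X) - k + 1L
  Xc <- im2col(X, k)
  Z <- Xc %*% W
  Z <- sweep(Z, 2, b, `+`)
  A <- relu(Z)
  A3 <- array(A, c(N, out_len, spec$n_kernels))
  pool_len <- out_len %/% spec$pool_size
  oi <- seq(1L, spec$pool_size * pool_len, by = spec$pool_size)
  ei <- oi + 1L
  O <- A3[, oi, , drop = FALSE]
  E <- A3[, ei, , drop = FALSE]
  P <- pmax(O, E)
  list(Xc = Xc, Z = Z, A3 = A3, mask = O >= E, oi = oi, ei = ei,
       out_len = out_len, pool_len = pool_len,
       flat = matrix(P, N, pool_len * spec$n_kernels))
}

branch_backward <- function(fwd, dflat, W, spec, N) {
  dP <- array(dflat, c(N, fwd$pool_len, spec$n_kernels))
  dA3 <- array(0, dim(fwd$A3))
  dA3[, fwd$oi, ] <- dP * fwd$mask
  dA3[, fwd$ei, ] <- dP * !fwd$mask
  dA <- matrix(dA3, N * fwd$out_len, spec$n_kernels)
  dZ <- dA * (fwd$Z > 0)
  list(dW = crossprod(fwd$Xc, dZ), db = colSums(dZ),
       # input gradient unused (inputs are data), omitted
       NULL)
}

nn_forward <- function(p, spec, Xi, Xg, dims) {
  N <- if (!is.null(Xi)) nrow(Xi) else nrow(Xg)
  flats <- list(); fw <- list()
  if (spec$branches %in% c("both", "intensity")) {
    fw$i <- branch_forward(Xi, p$ci_W, p$ci_b, spec)
    flats <- c(flats, list(fw$i$flat))
  }
  if (spec$branches %in% c("both", "frequency")) {
    fw$g <- branch_forward(Xg, p$cg_W, p$cg_b, spec)
    flats <- c(flats, list(fw$g$flat))
  }
  H0 <- do.call(cbind, flats)
  H1 <- relu(sweep(H0 %*% p$d1_W, 2, p$d1_b, `+`))
  logits <- sweep(H1 %*% p$d2_W, 2, p$d2_b, `+`)
  m <- apply(logits, 1, max)
  ex <- exp(logits - m)
  probs <- ex / rowSums(ex)
  list(fw = fw, H0 = H0, H1 = H1, probs = probs, N = N)
}

nn_loss_grad <- function(p, spec, Xi, Xg, y, n_classes, dims) {
  f <- nn_forward(p, spec, Xi, Xg, dims)
  N <- f$N
  Y <- matrix(0, N, n_classes)
  Y[cbind(seq_len(N), y)] <- 1
  eps <- 1e-12
  loss <- -mean(log(f$probs[cbind(seq_len(N), y)] + eps))
  dlogits <- (f$probs - Y) / N
  g <- list()
  g$d2_W <- crossprod(f$H1, dlogits)
  g$d2_b <- colSums(dlogits)
  dH1 <- tcrossprod(dlogits, p$d2_W) * (f$H1 > 0)
  g$d1_W <- crossprod(f$H0, dH1)
  g$d1_b <- colSums(dH1)
  dH0 <- tcrossprod(dH1, p$d1_W)
  ofs <- 0L
  if (spec$branches %in% c("both", "intensity")) {
    w <- ncol(f$fw$i$flat)
    bb <- branch_backward(f$fw$i, dH0[, ofs + seq_len(w), drop = FALSE],
                          p$ci_W, spec, N)
    g$ci_W <- bb$dW; g$ci_b <- bb$db
    ofs <- ofs + w
  }
  if (spec$branches %in% c("both", "frequency")) {
    w <- ncol(f$fw$g$flat)
    bb <- branch_backward(f$fw$g, dH0[, ofs + seq_len(w), drop = FALSE],
                          p$cg_W, spec, N)
    g$cg_W <- bb$dW; g$cg_b <- bb$db
  }
  # elastic-net penalty on weight matrices (not biases)
  for (nm in names(p)) {
    if (grepl("_W$", nm)) {
      loss <- loss + spec$l1 * sum(abs(p[[nm]])) + spec$l2 * sum(p[[nm]]^2)
      g[[nm]] <- g[[nm]] + spec$l1 * sign(p[[nm]]) + 2 * spec$l2 * p[[nm]]
    }
  }
  list(loss = loss, grads = g)
}

nn_train <- function(Xi, Xg, y, spec, n_classes, seed, epochs = NULL) {
  epochs <- epochs %||% spec$epochs
  T_i <- if (!is.null(Xi)) ncol(Xi) else 1L
  T_g <- if (!is.null(Xg)) ncol(Xg) else 1L
  init <- nn_init(spec, T_i, T_g, n_classes, seed)
  p <- init$params
  m <- lapply(p, function(x) x * 0)
  v <- lapply(p, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  N <- length(y)
  history <- numeric(epochs)
  with_seed(child_seed(seed, 777L), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      losses <- c()
      for (start in seq(1L, N, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1L, N)]
        lg <- nn_loss_grad(p, spec,
                           if (!is.null(Xi)) Xi[idx, , drop = FALSE],
                           if (!is.null(Xg)) Xg[idx, , drop = FALSE],
                           y[idx], n_classes, init$dims)
        step <- step + 1L
        for (nm in names(p)) {
          gmat <- lg$grads[[nm]]
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * gmat
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * gmat^2
          mhat <- m[[nm]] / (1 - b1^step)
          vhat <- v[[nm]] / (1 - b2^step)
          p[[nm]] <- p[[nm]] - spec$lr * mhat / (sqrt(vhat) + eps)
        }
        losses <- c(losses, lg$loss)
      }
      history[ep] <- mean(losses)
    }
  })
  list(params = p, dims = init$dims, history = history)
}

nn_predict_probs <- function(model, spec, Xi, Xg) {
  nn_forward(model$params, spec, Xi, Xg, model$dims)$probs
}
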