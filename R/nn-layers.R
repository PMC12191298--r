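# Minimal CNN layer framework in base R.
#
# Tensors are plain arrays, channel-first with the batch last:
#   1D feature maps: (channels, length, batch)
#   2D feature maps: (channels, height, width, batch)
#   feature vectors: (features, batch) matrices
# Convolutions are im2col gathers driving BLAS matrix products. Every layer
# is an environment with $fwd(x, train) and $bwd(dout) closures; trainable
# layers carry $params/$grads lists updated by the SGD stepper. Backward
# passes are verified against finite differences in the test suite.

.nn_env <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  class(self) <- "nn_layer"
  self
}

.zero_like <- function(p) if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else p * 0

# He-normal initialization for ReLU networks.
.he_init <- function(n_out, fan_in) {
  matrix(stats::rnorm(n_out * fan_in, sd = sqrt(2 / fan_in)), n_out, fan_in)
}

## ---- 1D convolution ------------------------------------------------------

nn_conv1d <- function(c_in, c_out, k, stride = 1, pad = (k - 1) %/% 2,
                      bias = TRUE) {
  self <- .nn_env("conv1d")
  self$c_in <- c_in; self$c_out <- c_out; self$k <- k
  self$stride <- stride; self$pad <- pad; self$bias <- bias
  self$params <- list(W = .he_init(c_out, c_in * k))
  if (bias) self$params$b <- numeric(c_out)
  self$grads <- lapply(self$params, .zero_like)

  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    if (C != c_in) stop("conv1d: expected ", c_in, " input channels, got ", C)
    Lp <- L + 2 * self$pad
    xp <- array(0, c(C, Lp, B))
    xp[, self$pad + seq_len(L), ] <- x
    Lout <- (Lp - k) %/% stride + 1
    starts <- stride * (seq_len(Lout) - 1)
    cols <- matrix(0, C * k, Lout * B)
    for (j in seq_len(k)) {
      sl <- xp[, j + starts, , drop = FALSE]
      cols[(j - 1) * C + seq_len(C), ] <- matrix(sl, C, Lout * B)
    }
    outm <- self$params$W %*% cols
    if (bias) outm <- outm + self$params$b
    self$cache <- list(cols = cols, Lp = Lp, L = L, Lout = Lout, B = B, starts = starts)
    array(outm, c(c_out, Lout, B))
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    dm <- matrix(dout, c_out, cc$Lout * cc$B)
    self$grads$W <- dm %*% t(cc$cols)
    if (bias) self$grads$b <- rowSums(dm)
    dcols <- crossprod(self$params$W, dm)
    dxp <- array(0, c(c_in, cc$Lp, cc$B))
    for (j in seq_len(k)) {
      idx <- j + cc$starts
      dxp[, idx, ] <- dxp[, idx, , drop = FALSE] +
        array(dcols[(j - 1) * c_in + seq_len(c_in), , drop = FALSE], c(c_in, cc$Lout, cc$B))
    }
    dxp[, self$pad + seq_len(cc$L), , drop = FALSE]
  }
  self
}

## ---- 2D convolution ------------------------------------------------------

nn_conv2d <- function(c_in, c_out, k, stride = 1, pad = (k - 1) %/% 2,
                      bias = TRUE) {
  self <- .nn_env("conv2d")
  self$c_in <- c_in; self$c_out <- c_out; self$k <- k
  self$stride <- stride; self$pad <- pad; self$bias <- bias
  self$params <- list(W = .he_init(c_out, c_in * k * k))
  if (bias) self$params$b <- numeric(c_out)
  self$grads <- lapply(self$params, .zero_like)

  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    if (C != c_in) stop("conv2d: expected ", c_in, " input channels, got ", C)
    Hp <- H + 2 * self$pad; Wp <- W + 2 * self$pad
    xp <- array(0, c(C, Hp, Wp, B))
    xp[, self$pad + seq_len(H), self$pad + seq_len(W), ] <- x
    Hout <- (Hp - k) %/% stride + 1; Wout <- (Wp - k) %/% stride + 1
    hs <- stride * (seq_len(Hout) - 1); ws <- stride * (seq_len(Wout) - 1)
    cols <- matrix(0, C * k * k, Hout * Wout * B)
    r <- 0
    for (v in seq_len(k)) for (u in seq_len(k)) {
      sl <- xp[, u + hs, v + ws, , drop = FALSE]
      cols[r + seq_len(C), ] <- matrix(sl, C, Hout * Wout * B)
      r <- r + C
    }
    outm <- self$params$W %*% cols
    if (bias) outm <- outm + self$params$b
    self$cache <- list(cols = cols, H = H, W = W, Hp = Hp, Wp = Wp,
                       Hout = Hout, Wout = Wout, B = B, hs = hs, ws = ws)
    array(outm, c(c_out, Hout, Wout, B))
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    dm <- matrix(dout, c_out, cc$Hout * cc$Wout * cc$B)
    self$grads$W <- dm %*% t(cc$cols)
    if (bias) self$grads$b <- rowSums(dm)
    dcols <- crossprod(self$params$W, dm)
    dxp <- array(0, c(c_in, cc$Hp, cc$Wp, cc$B))
    r <- 0
    for (v in seq_len(k)) for (u in seq_len(k)) {
      dxp[, u + cc$hs, v + cc$ws, ] <- dxp[, u + cc$hs, v + cc$ws, , drop = FALSE] +
        array(dcols[r + seq_len(c_in), , drop = FALSE], c(c_in, cc$Hout, cc$Wout, cc$B))
      r <- r + c_in
    }
    dxp[, self$pad + seq_len(cc$H), self$pad + seq_len(cc$W), , drop = FALSE]
  }
  self
}

## ---- batch normalization (per channel, any spatial rank) -----------------

nn_batchnorm <- function(c_ch, eps = 1e-5, momentum = 0.1) {
  self <- .nn_env("batchnorm")
  self$params <- list(gamma = rep(1, c_ch), beta = rep(0, c_ch))
  self$grads <- lapply(self$params, .zero_like)
  self$run_mean <- rep(0, c_ch); self$run_var <- rep(1, c_ch)

  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; N <- prod(d[-1])
    xm <- matrix(x, C, N)
    if (train || isTRUE(self$calibrating)) {
      mu <- rowMeans(xm)
      xc <- xm - mu
      v <- rowMeans(xc^2)
      if (isTRUE(self$calibrating)) {
        # exact-statistics pass: accumulate for the law-of-total-variance
        # estimate run_var = E[within-batch var] + Var[batch means]
        self$cal_n <- self$cal_n + 1
        self$cal_mu <- self$cal_mu + mu
        self$cal_mu2 <- self$cal_mu2 + mu^2
        self$cal_var <- self$cal_var + v * N / max(N - 1, 1)
      } else {
        self$run_mean <- (1 - momentum) * self$run_mean + momentum * mu
        self$run_var <- (1 - momentum) * self$run_var + momentum * v * N / max(N - 1, 1)
      }
    } else {
      mu <- self$run_mean; v <- self$run_var
      xc <- xm - mu
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- xc * istd
    self$cache <- list(xhat = xhat, istd = istd, dims = d, train = train)
    array(self$params$gamma * xhat + self$params$beta, d)
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    C <- cc$dims[1]; N <- prod(cc$dims[-1])
    dm <- matrix(dout, C, N)
    self$grads$gamma <- rowSums(dm * cc$xhat)
    self$grads$beta <- rowSums(dm)
    if (cc$train) {
      dx <- (self$params$gamma * cc$istd) *
        (dm - rowMeans(dm) - cc$xhat * rowMeans(dm * cc$xhat))
    } else {
      dx <- (self$params$gamma * cc$istd) * dm
    }
    array(dx, cc$dims)
  }
  self
}

## ---- activations, pooling, dropout ---------------------------------------

nn_relu <- function() {
  self <- .nn_env("relu")
  self$fwd <- function(x, train = FALSE) {
    self$mask <- x > 0
    x * self$mask
  }
  self$bwd <- function(dout) dout * self$mask
  self
}

nn_maxpool1d <- function(k = 3, stride = 2, pad = 1) {
  self <- .nn_env("maxpool1d")
  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; L <- d[2]; B <- d[3]
    Lp <- L + 2 * pad
    xp <- array(-Inf, c(C, Lp, B))
    xp[, pad + seq_len(L), ] <- x
    Lout <- (Lp - k) %/% stride + 1
    starts <- stride * (seq_len(Lout) - 1)
    best <- xp[, 1 + starts, , drop = FALSE]
    arg <- array(1L, dim(best))
    for (j in 2:k) {
      cand <- xp[, j + starts, , drop = FALSE]
      sel <- cand > best
      best[sel] <- cand[sel]; arg[sel] <- j
    }
    self$cache <- list(arg = arg, L = L, Lp = Lp, B = B, C = C, starts = starts)
    best
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    dxp <- array(0, c(cc$C, cc$Lp, cc$B))
    for (j in seq_len(k)) {
      idx <- j + cc$starts
      dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + dout * (cc$arg == j)
    }
    dxp[, pad + seq_len(cc$L), , drop = FALSE]
  }
  self
}

nn_maxpool2d <- function(k = 3, stride = 2, pad = 1) {
  self <- .nn_env("maxpool2d")
  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; H <- d[2]; W <- d[3]; B <- d[4]
    Hp <- H + 2 * pad; Wp <- W + 2 * pad
    xp <- array(-Inf, c(C, Hp, Wp, B))
    xp[, pad + seq_len(H), pad + seq_len(W), ] <- x
    Hout <- (Hp - k) %/% stride + 1; Wout <- (Wp - k) %/% stride + 1
    hs <- stride * (seq_len(Hout) - 1); ws <- stride * (seq_len(Wout) - 1)
    best <- NULL; arg <- NULL
    jj <- 0
    for (v in seq_len(k)) for (u in seq_len(k)) {
      jj <- jj + 1
      cand <- xp[, u + hs, v + ws, , drop = FALSE]
      if (is.null(best)) {
        best <- cand; arg <- array(1L, dim(cand))
      } else {
        sel <- cand > best
        best[sel] <- cand[sel]; arg[sel] <- jj
      }
    }
    self$cache <- list(arg = arg, H = H, W = W, Hp = Hp, Wp = Wp,
                       B = B, C = C, hs = hs, ws = ws)
    best
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    dxp <- array(0, c(cc$C, cc$Hp, cc$Wp, cc$B))
    jj <- 0
    for (v in seq_len(k)) for (u in seq_len(k)) {
      jj <- jj + 1
      dxp[, u + cc$hs, v + cc$ws, ] <- dxp[, u + cc$hs, v + cc$ws, , drop = FALSE] +
        dout * (cc$arg == jj)
    }
    dxp[, pad + seq_len(cc$H), pad + seq_len(cc$W), , drop = FALSE]
  }
  self
}

# Global average pooling over all spatial dims -> (C, B) matrix.
nn_gap <- function() {
  self <- .nn_env("gap")
  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; B <- d[length(d)]; L <- prod(d[-c(1, length(d))])
    xm <- array(x, c(C, L, B))
    self$cache <- list(dims = d, L = L, B = B, C = C)
    out <- matrix(0, C, B)
    for (b in seq_len(B)) out[, b] <- .rowMeans(matrix(xm[, , b], C, L), C, L)
    out
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    dx <- dout[, rep(seq_len(cc$B), each = cc$L), drop = FALSE] / cc$L
    array(dx, cc$dims)
  }
  self
}

nn_dropout <- function(rate = 0.2) {
  self <- .nn_env("dropout")
  self$rate <- rate
  self$fwd <- function(x, train = FALSE) {
    if (!train || rate <= 0) { self$mask <- NULL; return(x) }
    self$mask <- (array(stats::runif(length(x)), dim(x)) >= rate) / (1 - rate)
    x * self$mask
  }
  self$bwd <- function(dout) if (is.null(self$mask)) dout else dout * self$mask
  self
}

nn_dense <- function(d_in, d_out) {
  self <- .nn_env("dense")
  self$params <- list(W = .he_init(d_out, d_in), b = numeric(d_out))
  self$grads <- lapply(self$params, .zero_like)
  self$fwd <- function(x, train = FALSE) {
    self$cache <- x
    self$params$W %*% x + self$params$b
  }
  self$bwd <- function(dout) {
    self$grads$W <- dout %*% t(self$cache)
    self$grads$b <- rowSums(dout)
    crossprod(self$params$W, dout)
  }
  self
}

## ---- squeeze-and-excitation (channel attention) --------------------------

# Squeeze: global average pool per channel; excitation: two-layer perceptron
# with the given reduction producing sigmoid weights in (0, 1) that rescale
# the channels.
nn_se <- function(c_ch, reduction = 4) {
  self <- .nn_env("se")
  hid <- max(1L, c_ch %/% reduction)
  self$params <- list(W1 = .he_init(hid, c_ch), b1 = numeric(hid),
                      W2 = .he_init(c_ch, hid), b2 = numeric(c_ch))
  self$grads <- lapply(self$params, .zero_like)

  self$fwd <- function(x, train = FALSE) {
    d <- dim(x); C <- d[1]; B <- d[length(d)]; L <- prod(d[-c(1, length(d))])
    xm <- array(x, c(C, L, B))
    z <- matrix(0, C, B)
    for (b in seq_len(B)) z[, b] <- .rowMeans(matrix(xm[, , b], C, L), C, L)
    pre1 <- self$params$W1 %*% z + self$params$b1
    h <- pmax(pre1, 0)
    s <- 1 / (1 + exp(-(self$params$W2 %*% h + self$params$b2)))
    sbig <- array(s[, rep(seq_len(B), each = L), drop = FALSE], d)
    self$cache <- list(x = x, z = z, pre1 = pre1, h = h, s = s, sbig = sbig,
                       dims = d, L = L, B = B, C = C)
    x * sbig
  }
  self$bwd <- function(dout) {
    cc <- self$cache
    ds <- matrix(0, cc$C, cc$B)
    prod_m <- array(dout * cc$x, c(cc$C, cc$L, cc$B))
    for (b in seq_len(cc$B)) ds[, b] <- .rowSums(matrix(prod_m[, , b], cc$C, cc$L), cc$C, cc$L)
    dpre2 <- ds * cc$s * (1 - cc$s)
    self$grads$W2 <- dpre2 %*% t(cc$h)
    self$grads$b2 <- rowSums(dpre2)
    dh <- crossprod(self$params$W2, dpre2) * (cc$pre1 > 0)
    self$grads$W1 <- dh %*% t(cc$z)
    self$grads$b1 <- rowSums(dh)
    dz <- crossprod(self$params$W1, dh)
    dzbig <- array(dz[, rep(seq_len(cc$B), each = cc$L), drop = FALSE] / cc$L,
                   cc$dims)
    dout * cc$sbig + dzbig
  }
  # inspection hook: the last excitation weights, strictly in (0, 1)
  self$last_weights <- function() self$cache$s
  self
}

## ---- composition helpers -------------------------------------------------

nn_seq <- function(...) {
  self <- .nn_env("seq")
  self$children <- list(...)
  self$fwd <- function(x, train = FALSE) {
    for (ch in self$children) x <- ch$fwd(x, train)
    x
  }
  self$bwd <- function(dout) {
    for (ch in rev(self$children)) dout <- ch$bwd(dout)
    dout
  }
  self
}

# Depth-first collection of trainable layer environments.
nn_collect <- function(layer) {
  out <- list()
  if (!is.null(layer$params)) out <- list(layer)
  for (ch in layer$children %||% list())
    out <- c(out, nn_collect(ch))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Recompute every batch-norm layer's inference statistics exactly from the
# given batches of inputs (weights frozen, dropout off). Running averages
# updated with momentum lag behind the final weights when an epoch holds only
# a handful of batches; this pass replaces them with aggregate statistics
# under the trained weights.
nn_bn_recalibrate <- function(net, batches) {
  bns <- Filter(function(ly) identical(ly$type, "batchnorm"), net$param_layers)
  if (length(bns) == 0 || length(batches) == 0) return(invisible(NULL))
  for (bn in bns) {
    bn$calibrating <- TRUE
    bn$cal_n <- 0
    bn$cal_mu <- bn$cal_mu2 <- bn$cal_var <- bn$run_mean * 0
  }
  for (inputs in batches) net$forward(inputs, train = FALSE)
  for (bn in bns) {
    n <- bn$cal_n
    mu <- bn$cal_mu / n
    bn$run_mean <- mu
    bn$run_var <- bn$cal_var / n + pmax(bn$cal_mu2 / n - mu^2, 0)
    bn$calibrating <- FALSE
  }
  invisible(NULL)
}

# One SGD-with-momentum update over every parameter of a model.
nn_sgd_step <- function(layers, lr, momentum = 0.9) {
  for (ly in layers) {
    if (is.null(ly$vel)) ly$vel <- lapply(ly$params, .zero_like)
    for (nm in names(ly$params)) {
      ly$vel[[nm]] <- momentum * ly$vel[[nm]] - lr * ly$grads[[nm]]
      ly$params[[nm]] <- ly$params[[nm]] + ly$vel[[nm]]
    }
  }
  invisible(NULL)
}

nn_n_params <- function(layers) {
  sum(vapply(layers, function(ly) sum(vapply(ly$params, length, 0L)), 0))
}

# Softmax cross-entropy: returns loss, probabilities and dlogits.
nn_softmax_xent <- function(logits, y) {
  B <- ncol(logits)
  mx <- apply(logits, 2, max)
  ex <- exp(sweep(logits, 2, mx))
  p <- sweep(ex, 2, colSums(ex), "/")
  picked <- p[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dl <- p
  dl[cbind(y, seq_len(B))] <- dl[cbind(y, seq_len(B))] - 1
  list(loss = loss, probs = p, dlogits = dl / B)
}
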