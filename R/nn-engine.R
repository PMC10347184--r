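# Minimal reverse-mode neural-network engine for 1-D signals.
#
# Batches travel through layers as a "tensor": a plain (L*n) x C matrix M
# with row index (i-1)*L + t (time fastest within each sample) plus the
# time length L and batch size n. Convolutions are im2col + BLAS matrix
# products; every layer is an environment carrying its parameters,
# gradients, Adam state and fwd/bwd closures, so weight sharing between two
# models is plain reference sharing of layer environments.

nn_tensor <- function(x, L, n) list(x = x, L = L, n = n)

# [n x C x L] array of segments -> engine tensor.
segments_to_tensor <- function(seg) {
  d <- dim(seg)
  m <- aperm(seg, c(3, 1, 2))          # L x n x C
  dim(m) <- c(d[3] * d[1], d[2])
  nn_tensor(m, d[3], d[1])
}

new_layer <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$params <- list()
  self$grads <- list()
  self$opt <- list()
  self$children <- list()
  self
}

# ---- convolution -----------------------------------------------------------

nn_conv1d <- function(in_ch, out_ch, k, stride = 1L, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  self <- new_layer(sprintf("conv1d %d->%d k=%d s=%d %s", in_ch, out_ch, k, stride, pad))
  self$params <- list(
    W = matrix(rnorm(k * in_ch * out_ch, sd = sqrt(2 / (k * in_ch))),
               k * in_ch, out_ch),
    b = numeric(out_ch))
  pl <- if (pad == "same") (k - 1L) %/% 2L else 0L
  pr <- if (pad == "same") k - 1L - pl else 0L
  im2col <- function(xp, Lp, n, Lout) {
    cpp_im2col(xp, n, Lp, k, stride, Lout)
  }
  self$fwd <- function(t, train = FALSE) {
    L <- t$L; n <- t$n
    if (pl + pr > 0L) {
      Lp <- L + pl + pr
      xp <- matrix(0, Lp * n, in_ch)
      rows <- rep((0:(n - 1)) * Lp, each = L) + rep(seq_len(L) + pl, times = n)
      xp[rows, ] <- t$x
    } else {
      Lp <- L; xp <- t$x
    }
    Lout <- (Lp - k) %/% stride + 1L
    if (Lout < 1L) rlang::abort(sprintf("%s: input length %d too short", self$type, L))
    Xc <- im2col(xp, Lp, n, Lout)
    out <- Xc %*% self$params$W
    out <- out + rep(self$params$b, each = nrow(out))
    if (train) self$cache <- list(Xc = Xc, Lp = Lp, L = L, n = n, Lout = Lout)
    nn_tensor(out, Lout, n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dout <- dt$x
    self$grads$W <- crossprod(cc$Xc, dout)
    self$grads$b <- colSums(dout)
    # Input gradient block-by-block over kernel offsets: avoids forming the
    # full (Lout*n) x (k*C) gradient patch matrix.
    dxp <- matrix(0, cc$Lp * cc$n, in_ch)
    for (j in seq_len(k)) {
      cs <- ((j - 1L) * in_ch + 1L):(j * in_ch)
      dXj <- tcrossprod(dout, self$params$W[cs, , drop = FALSE])
      dxp <- cpp_col2im_offset(dxp, dXj, cc$n, cc$Lp, j, stride, cc$Lout)
    }
    if (pl + pr > 0L) {
      rows <- rep((0:(cc$n - 1)) * cc$Lp, each = cc$L) +
        rep(seq_len(cc$L) + pl, times = cc$n)
      dx <- dxp[rows, , drop = FALSE]
    } else {
      dx <- dxp
    }
    nn_tensor(dx, cc$L, cc$n)
  }
  self
}

# ---- batch normalization ---------------------------------------------------

nn_bn1d <- function(ch, momentum = 0.9, eps = 1e-5) {
  self <- new_layer(sprintf("batchnorm %d", ch))
  self$params <- list(gamma = rep(1, ch), beta = numeric(ch))
  self$run_mean <- numeric(ch)
  self$run_var <- rep(1, ch)
  self$fwd <- function(t, train = FALSE) {
    x <- t$x; m <- nrow(x)
    if (train) {
      mu <- colMeans(x)
      xc <- x - rep(mu, each = m)
      v <- colMeans(xc * xc)
      self$run_mean <- momentum * self$run_mean + (1 - momentum) * mu
      self$run_var <- momentum * self$run_var + (1 - momentum) * v
      istd <- 1 / sqrt(v + eps)
      xhat <- xc * rep(istd, each = m)
      self$cache <- list(xhat = xhat, istd = istd, m = m)
      out <- xhat * rep(self$params$gamma, each = m) + rep(self$params$beta, each = m)
    } else {
      istd <- 1 / sqrt(self$run_var + eps)
      out <- (x - rep(self$run_mean, each = m)) * rep(istd * self$params$gamma, each = m) +
        rep(self$params$beta, each = m)
    }
    nn_tensor(out, t$L, t$n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dout <- dt$x; m <- cc$m
    self$grads$gamma <- colSums(dout * cc$xhat)
    self$grads$beta <- colSums(dout)
    dxhat <- dout * rep(self$params$gamma, each = m)
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cc$xhat)
    dx <- (dxhat - rep(s1 / m, each = m) - cc$xhat * rep(s2 / m, each = m)) *
      rep(cc$istd, each = m)
    nn_tensor(dx, dt$L, dt$n)
  }
  self
}

# ---- activations / pooling -------------------------------------------------

nn_relu <- function() {
  self <- new_layer("relu")
  self$fwd <- function(t, train = FALSE) {
    out <- t$x
    mask <- out > 0
    out[!mask] <- 0
    if (train) self$cache <- mask
    nn_tensor(out, t$L, t$n)
  }
  self$bwd <- function(dt) {
    mask <- self$cache; self$cache <- NULL
    dx <- dt$x
    dx[!mask] <- 0
    nn_tensor(dx, dt$L, dt$n)
  }
  self
}

nn_maxpool1d <- function(pool, stride = pool) {
  self <- new_layer(sprintf("maxpool %d/%d", pool, stride))
  self$fwd <- function(t, train = FALSE) {
    L <- t$L; n <- t$n
    Lout <- (L - pool) %/% stride + 1L
    if (Lout < 1L) rlang::abort(sprintf("%s: input length %d too short", self$type, L))
    idx0 <- rep((0:(n - 1)) * L, each = Lout) +
      rep(seq.int(0L, by = stride, length.out = Lout), times = n)
    cur <- t$x[idx0 + 1L, , drop = FALSE]
    arg <- matrix(1L, nrow(cur), ncol(cur))
    if (pool > 1L) {
      for (j in 2:pool) {
        cand <- t$x[idx0 + j, , drop = FALSE]
        upd <- cand > cur
        if (any(upd)) {
          arg[upd] <- j
          cur[upd] <- cand[upd]
        }
      }
    }
    if (train) self$cache <- list(arg = arg, idx0 = idx0, L = L, n = n, C = ncol(cur))
    nn_tensor(cur, Lout, n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dx <- matrix(0, cc$L * cc$n, cc$C)
    for (j in seq_len(pool)) {
      sel <- cc$arg == j
      if (!any(sel)) next
      contrib <- dt$x
      contrib[!sel] <- 0
      dx[cc$idx0 + j, ] <- dx[cc$idx0 + j, , drop = FALSE] + contrib
    }
    nn_tensor(dx, cc$L, cc$n)
  }
  self
}

nn_global_avgpool <- function() {
  self <- new_layer("globalavgpool")
  self$fwd <- function(t, train = FALSE) {
    grp <- rep(seq_len(t$n), each = t$L)
    out <- rowsum(t$x, grp, reorder = FALSE) / t$L
    if (train) self$cache <- list(L = t$L, n = t$n)
    nn_tensor(out, 1L, t$n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dx <- dt$x[rep(seq_len(cc$n), each = cc$L), , drop = FALSE] / cc$L
    nn_tensor(dx, cc$L, cc$n)
  }
  self
}

nn_global_maxpool <- function() {
  self <- new_layer("globalmaxpool")
  self$fwd <- function(t, train = FALSE) {
    L <- t$L; n <- t$n; C <- ncol(t$x)
    xm <- t$x
    dim(xm) <- c(L, n * C)                 # columns = (sample, channel), sample fastest
    arg <- max.col(t(xm), ties.method = "first")
    mx <- xm[(seq_len(n * C) - 1L) * L + arg]
    out <- matrix(mx, n, C)
    if (train) self$cache <- list(arg = arg, L = L, n = n, C = C)
    nn_tensor(out, 1L, n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dx <- matrix(0, cc$L * cc$n, cc$C)
    ic <- seq_len(cc$n * cc$C) - 1L
    i <- ic %% cc$n            # sample index - 1
    ch <- ic %/% cc$n          # channel index - 1
    lin <- ch * (cc$L * cc$n) + i * cc$L + cc$arg
    dx[lin] <- as.vector(dt$x)
    nn_tensor(dx, cc$L, cc$n)
  }
  self
}

nn_dense <- function(in_dim, out_dim) {
  self <- new_layer(sprintf("dense %d->%d", in_dim, out_dim))
  self$params <- list(
    W = matrix(rnorm(in_dim * out_dim, sd = sqrt(2 / in_dim)), in_dim, out_dim),
    b = numeric(out_dim))
  self$fwd <- function(t, train = FALSE) {
    out <- t$x %*% self$params$W
    out <- out + rep(self$params$b, each = nrow(out))
    if (train) self$cache <- t$x
    nn_tensor(out, 1L, t$n)
  }
  self$bwd <- function(dt) {
    x <- self$cache; self$cache <- NULL
    self$grads$W <- crossprod(x, dt$x)
    self$grads$b <- colSums(dt$x)
    nn_tensor(tcrossprod(dt$x, self$params$W), 1L, dt$n)
  }
  self
}

nn_take_last <- function() {
  self <- new_layer("take_last")
  self$fwd <- function(t, train = FALSE) {
    rows <- seq_len(t$n) * t$L
    if (train) self$cache <- list(L = t$L, n = t$n, C = ncol(t$x))
    nn_tensor(t$x[rows, , drop = FALSE], 1L, t$n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    dx <- matrix(0, cc$L * cc$n, cc$C)
    dx[seq_len(cc$n) * cc$L, ] <- dt$x
    nn_tensor(dx, cc$L, cc$n)
  }
  self
}

# ---- LSTM ------------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

nn_lstm <- function(in_dim, H) {
  self <- new_layer(sprintf("lstm %d->%d", in_dim, H))
  sc <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1            # forget-gate bias
  self$params <- list(
    Wx = matrix(runif(in_dim * 4 * H, -sc, sc), in_dim, 4 * H),
    Wh = matrix(runif(H * 4 * H, -sc, sc), H, 4 * H),
    b = b)
  gi <- 1:H; gf <- (H + 1):(2 * H); gg <- (2 * H + 1):(3 * H); go <- (3 * H + 1):(4 * H)
  self$fwd <- function(t, train = FALSE) {
    L <- t$L; n <- t$n
    h <- matrix(0, n, H); cst <- matrix(0, n, H)
    out <- matrix(0, L * n, H)
    caches <- if (train) vector("list", L)
    for (tt in seq_len(L)) {
      rows <- tt + L * (0:(n - 1))
      xt <- t$x[rows, , drop = FALSE]
      g <- xt %*% self$params$Wx + h %*% self$params$Wh +
        rep(self$params$b, each = n)
      i <- sigmoid(g[, gi, drop = FALSE])
      f <- sigmoid(g[, gf, drop = FALSE])
      gg_ <- tanh(g[, gg, drop = FALSE])
      o <- sigmoid(g[, go, drop = FALSE])
      c_prev <- cst
      cst <- f * c_prev + i * gg_
      tc <- tanh(cst)
      h_prev <- h
      h <- o * tc
      out[rows, ] <- h
      if (train) {
        caches[[tt]] <- list(xt = xt, i = i, f = f, g = gg_, o = o,
                             c_prev = c_prev, tc = tc, h_prev = h_prev)
      }
    }
    if (train) self$cache <- list(caches = caches, L = L, n = n)
    nn_tensor(out, L, n)
  }
  self$bwd <- function(dt) {
    cc <- self$cache; self$cache <- NULL
    L <- cc$L; n <- cc$n
    dWx <- 0 * self$params$Wx; dWh <- 0 * self$params$Wh; db <- 0 * self$params$b
    dx <- matrix(0, L * n, in_dim)
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    for (tt in rev(seq_len(L))) {
      s <- cc$caches[[tt]]
      rows <- tt + L * (0:(n - 1))
      dh <- dt$x[rows, , drop = FALSE] + dh_next
      do_ <- dh * s$tc
      dtc <- dh * s$o * (1 - s$tc^2) + dc_next
      di <- dtc * s$g
      df <- dtc * s$c_prev
      dg <- dtc * s$i
      dc_next <- dtc * s$f
      G <- cbind(di * s$i * (1 - s$i),
                 df * s$f * (1 - s$f),
                 dg * (1 - s$g^2),
                 do_ * s$o * (1 - s$o))
      dWx <- dWx + crossprod(s$xt, G)
      dWh <- dWh + crossprod(s$h_prev, G)
      db <- db + colSums(G)
      dx[rows, ] <- tcrossprod(G, self$params$Wx)
      dh_next <- tcrossprod(G, self$params$Wh)
    }
    self$grads$Wx <- dWx; self$grads$Wh <- dWh; self$grads$b <- db
    nn_tensor(dx, L, n)
  }
  self
}

# ---- composite blocks ------------------------------------------------------

# Residual block: conv-relu-conv with identity skip, then relu.
nn_residual <- function(ch, k = 3L) {
  self <- new_layer(sprintf("residual %d k=%d", ch, k))
  conv1 <- nn_conv1d(ch, ch, k, pad = "same")
  relu1 <- nn_relu()
  conv2 <- nn_conv1d(ch, ch, k, pad = "same")
  relu2 <- nn_relu()
  self$children <- list(conv1, relu1, conv2, relu2)
  self$fwd <- function(t, train = FALSE) {
    h <- conv2$fwd(relu1$fwd(conv1$fwd(t, train), train), train)
    relu2$fwd(nn_tensor(h$x + t$x, t$L, t$n), train)
  }
  self$bwd <- function(dt) {
    d <- relu2$bwd(dt)
    d1 <- conv1$bwd(relu1$bwd(conv2$bwd(d)))
    nn_tensor(d1$x + d$x, d$L, d$n)
  }
  self
}

# Multi-kernel block: parallel same-length convolutions with kernel sizes
# `ks`, outputs combined by elementwise addition (not concatenation), then
# batch norm, relu and stride-2 temporal downsampling.
nn_multikernel <- function(ch, ks = c(1L, 3L, 5L, 7L)) {
  self <- new_layer(sprintf("multikernel %d {%s}", ch, paste(ks, collapse = ",")))
  convs <- lapply(ks, function(k) nn_conv1d(ch, ch, k, pad = "same"))
  bn <- nn_bn1d(ch)
  act <- nn_relu()
  pool <- nn_maxpool1d(2L, 2L)
  self$children <- c(convs, list(bn, act, pool))
  self$fwd <- function(t, train = FALSE) {
    outs <- lapply(convs, function(cv) cv$fwd(t, train))
    s <- outs[[1]]$x
    for (j in 2:length(outs)) s <- s + outs[[j]]$x
    pool$fwd(act$fwd(bn$fwd(nn_tensor(s, outs[[1]]$L, t$n), train), train), train)
  }
  self$bwd <- function(dt) {
    d <- bn$bwd(act$bwd(pool$bwd(dt)))
    acc <- NULL
    Lin <- NULL
    for (cv in convs) {
      di <- cv$bwd(d)
      Lin <- di$L
      acc <- if (is.null(acc)) di$x else acc + di$x
    }
    nn_tensor(acc, Lin, d$n)
  }
  self
}

# ---- graph helpers ---------------------------------------------------------

flatten_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (length(ly$children) > 0) {
      out <- c(out, flatten_layers(ly$children))
    } else {
      out <- c(out, list(ly))
    }
  }
  out
}

net_forward <- function(layers, t, train = FALSE) {
  for (ly in layers) t <- ly$fwd(t, train)
  t
}

net_backward <- function(layers, dt) {
  for (ly in rev(layers)) dt <- ly$bwd(dt)
  dt
}

net_n_params <- function(layers) {
  sum(vapply(flatten_layers(layers),
             function(ly) sum(vapply(ly$params, length, 0L)), 0))
}

# Softmax cross-entropy: returns loss and gradient wrt logits.
softmax_ce <- function(logits, y) {
  n <- nrow(logits)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  list(loss = loss, dlogits = dp / n, prob = p)
}

adam_step <- function(layers, lr, step, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (ly in flatten_layers(layers)) {
    if (length(ly$params) == 0) next
    for (nm in names(ly$params)) {
      g <- ly$grads[[nm]]
      if (is.null(g)) next
      st <- ly$opt[[nm]]
      if (is.null(st)) st <- list(m = 0 * g, v = 0 * g)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g * g
      mhat <- st$m / (1 - beta1^step)
      vhat <- st$v / (1 - beta2^step)
      ly$params[[nm]] <- ly$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      ly$opt[[nm]] <- st
    }
  }
}

# Drop cached activations (after a training run) and optimizer state.
net_clear_state <- function(layers) {
  for (ly in flatten_layers(layers)) {
    ly$cache <- NULL
  }
  invisible(NULL)
}
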