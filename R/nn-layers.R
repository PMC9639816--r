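# A small CPU neural-network engine.
#
# No deep-learning framework is available in this environment, so the network
# is built directly on BLAS matrix products.  Batch tensors are R arrays laid
# out N x T x E x C (sample, time, electrode, feature channel); because R is
# column-major with N fastest and C slowest, setting `dim(x) <- c(N*T*E, C)`
# views a tensor as an (N*T*E) x C matrix with rows ordered sample-fastest,
# which every layer below exploits.  All kernels in this architecture are
# narrow (8x1, 1x8, 2x1, 1x2, 1x1), so convolution gathers the few kernel
# taps into one im2col matrix and runs a single GEMM; the tap matrix is
# cached for the backward pass.
#
# Each layer is an environment with fields `param_names` (character),
# parameters and their gradients, plus closures `fwd(x, training)` and
# `bwd(dy)`.  `bwd` must be called exactly once after a training-mode `fwd`;
# it consumes the cached activations.  Composite layers expose their
# parameter-bearing children through `param_layers`.

.sigmoid <- function(x) 1 / (1 + exp(-x))

# left-biased size-preserving padding: for an even kernel the extra pad
# sample goes before the data
.pad_before <- function(k) as.integer(ceiling((k - 1) / 2))

#' @noRd
conv2d_new <- function(kt, ke, cin, cout, name = "conv") {
  self <- new.env(parent = emptyenv())
  self$kind <- "conv2d"; self$name <- name
  self$kt <- kt; self$ke <- ke; self$cin <- cin; self$cout <- cout
  sd <- sqrt(2 / (kt * ke * cin + kt * ke * cout))       # Glorot
  self$W <- array(stats::rnorm(kt * ke * cin * cout, 0, sd),
                  c(kt, ke, cin, cout))
  self$b <- numeric(cout)
  self$param_names <- c("W", "b")
  self$grads <- list()
  self$param_layers <- list(self)

  # weight tensor viewed as a (kt*ke*cin) x cout matrix whose row blocks
  # match the column blocks of the im2col matrix (tap-major, channel-minor)
  wmat <- function() {
    W <- aperm(self$W, c(3L, 1L, 2L, 4L))   # cin, kt, ke, cout
    dim(W) <- c(cin * kt * ke, cout)
    W
  }

  # For electrode-axis kernels (kt == 1) the electrode and channel axes are
  # adjacent in the N x T x E x C layout, so the convolution is one GEMM of
  # the (N*T) x (E*cin) input view against a structured (E*cin) x (E*cout)
  # weight matrix; (row, col) index pairs of each kernel tap are precomputed
  # per input width E.
  self$eidx <- list()
  econv_index <- function(E) {
    key <- as.character(E)
    if (!is.null(self$eidx[[key]])) return(self$eidx[[key]])
    be <- .pad_before(ke)
    rows <- integer(0); cols <- integer(0); taps <- integer(0)
    for (je in seq_len(ke)) for (ci in seq_len(cin)) for (co in seq_len(cout)) {
      e_out <- seq_len(E)
      e_in <- e_out + je - 1L - be
      ok <- e_in >= 1L & e_in <= E
      rows <- c(rows, e_in[ok] + E * (ci - 1L))
      cols <- c(cols, e_out[ok] + E * (co - 1L))
      taps <- c(taps, rep.int(je + ke * ((ci - 1L) + cin * (co - 1L)),
                              sum(ok)))
    }
    out <- list(at = cbind(rows, cols), tap = taps)
    self$eidx[[key]] <- out
    out
  }
  econv_wbig <- function(E, idx) {
    Wb <- matrix(0, E * cin, E * cout)
    wv <- self$W                    # dim (1, ke, cin, cout): tap index je + ke*((ci-1)+cin*(co-1))
    Wb[idx$at] <- wv[idx$tap]
    Wb
  }

  self$fwd <- function(x, training = FALSE) {
    d <- dim(x); N <- d[1L]; Tn <- d[2L]; E <- d[3L]
    R <- N * Tn * E
    if (kt == 1L && ke > 1L) {                 # fused electrode-axis GEMM
      idx <- econv_index(E)
      dim(x) <- c(N * Tn, E * cin)
      Y <- x %*% econv_wbig(E, idx)
      if (any(self$b != 0))
        Y <- Y + rep(self$b, each = R)         # col-major: e fast, co slow
      if (training) { self$Xc <- x; self$dims <- d }
      dim(Y) <- c(N, Tn, E, cout)
      return(Y)
    }
    if (kt == 1L && ke == 1L) {
      Xc <- x; dim(Xc) <- c(R, cin)
    } else {
      bt <- .pad_before(kt); be <- .pad_before(ke)
      xp <- array(0, c(N, Tn + kt - 1L, E + ke - 1L, cin))
      xp[, bt + seq_len(Tn), be + seq_len(E), ] <- x
      Xc <- matrix(0, R, kt * ke * cin)
      j <- 0L
      for (je in seq_len(ke)) for (jt in seq_len(kt)) {
        xs <- xp[, jt:(jt + Tn - 1L), je:(je + E - 1L), , drop = FALSE]
        dim(xs) <- c(R, cin)
        Xc[, j + seq_len(cin)] <- xs
        j <- j + cin
      }
    }
    Y <- Xc %*% wmat()
    if (any(self$b != 0)) Y <- Y + rep(self$b, each = R)
    if (training) { self$Xc <- Xc; self$dims <- d }
    dim(Y) <- c(N, Tn, E, cout)
    Y
  }

  self$bwd <- function(dy) {
    d <- self$dims; N <- d[1L]; Tn <- d[2L]; E <- d[3L]
    R <- N * Tn * E
    if (kt == 1L && ke > 1L) {
      idx <- econv_index(E)
      dim(dy) <- c(N * Tn, E * cout)
      gWbig <- crossprod(self$Xc, dy)
      gw <- numeric(kt * ke * cin * cout)
      agg <- rowsum(gWbig[idx$at], idx$tap)
      gw[as.integer(rownames(agg))] <- agg
      dim(gw) <- c(kt, ke, cin, cout)
      db <- colSums(dy)
      dim(db) <- c(E, cout)                   # bias is per output channel
      self$grads <- list(W = gw, b = colSums(db))
      dXm <- tcrossprod(dy, econv_wbig(E, idx))
      self$Xc <- NULL
      dim(dXm) <- c(N, Tn, E, cin)
      return(dXm)
    }
    dim(dy) <- c(R, cout)
    gWm <- crossprod(self$Xc, dy)                     # (cin*kt*ke) x cout
    dim(gWm) <- c(cin, kt, ke, cout)
    dXc <- tcrossprod(dy, wmat())                     # R x (cin*kt*ke)
    self$grads <- list(W = aperm(gWm, c(2L, 3L, 1L, 4L)), b = colSums(dy))
    self$Xc <- NULL
    if (kt == 1L && ke == 1L) {
      dim(dXc) <- c(N, Tn, E, cin)
      return(dXc)
    }
    bt <- .pad_before(kt); be <- .pad_before(ke)
    dXp <- array(0, c(N, Tn + kt - 1L, E + ke - 1L, cin))
    j <- 0L
    for (je in seq_len(ke)) for (jt in seq_len(kt)) {
      ts <- jt:(jt + Tn - 1L); es <- je:(je + E - 1L)
      dxs <- dXc[, j + seq_len(cin), drop = FALSE]
      dim(dxs) <- c(N, Tn, E, cin)
      dXp[, ts, es, ] <- dXp[, ts, es, , drop = FALSE] + dxs
      j <- j + cin
    }
    dXp[, bt + seq_len(Tn), be + seq_len(E), , drop = FALSE]
  }
  self
}

#' @noRd
relu_new <- function(name = "relu") {
  self <- new.env(parent = emptyenv())
  self$kind <- "relu"; self$name <- name
  self$param_names <- character(0); self$param_layers <- list()
  self$fwd <- function(x, training = FALSE) {
    mask <- x > 0
    if (training) self$mask <- mask
    x * mask
  }
  self$bwd <- function(dy) {
    dx <- dy * self$mask
    self$mask <- NULL
    dx
  }
  self
}

# Batch normalisation over the feature-channel axis: statistics are taken
# over every sample and spatial position of each channel.  Inference mode
# uses exponentially smoothed running statistics (momentum 0.1).  Scale and
# shift are folded into one multiply-add; the backward pass recomputes the
# normalised activations from the cached input view.
#' @noRd
batchnorm_new <- function(C, name = "bn", eps = 1e-5, momentum = 0.1) {
  self <- new.env(parent = emptyenv())
  self$kind <- "batchnorm"; self$name <- name
  self$gamma <- rep(1, C); self$beta <- rep(0, C)
  self$run_mean <- rep(0, C); self$run_var <- rep(1, C)
  self$param_names <- c("gamma", "beta")
  self$grads <- list(); self$param_layers <- list(self)

  self$fwd <- function(x, training = FALSE) {
    d <- dim(x); R <- prod(d) %/% C
    xm <- x; dim(xm) <- c(R, C)
    if (training) {
      mu <- colMeans(xm)
      v <- colMeans(xm * xm) - mu * mu
      v[v < 0] <- 0
      invstd <- 1 / sqrt(v + eps)
      self$run_mean <- (1 - momentum) * self$run_mean + momentum * mu
      self$run_var <- (1 - momentum) * self$run_var + momentum * v
      self$xm <- xm; self$mu <- mu; self$invstd <- invstd; self$dims <- d
    } else {
      mu <- self$run_mean
      invstd <- 1 / sqrt(self$run_var + eps)
    }
    scale <- self$gamma * invstd
    shift <- self$beta - mu * scale
    y <- xm * rep(scale, each = R) + rep(shift, each = R)
    dim(y) <- d
    y
  }

  self$bwd <- function(dy) {
    d <- self$dims; R <- prod(d) %/% C
    dim(dy) <- c(R, C)
    xhat <- (self$xm - rep(self$mu, each = R)) * rep(self$invstd, each = R)
    dgamma <- colSums(dy * xhat)
    dbeta <- colSums(dy)
    # dx = invstd/R * (R*dxhat - sum(dxhat) - xhat*sum(dxhat*xhat)),
    # with dxhat = dy * gamma
    dx <- rep(self$gamma * self$invstd, each = R) *
      (dy - rep(dbeta / R, each = R) - xhat * rep(dgamma / R, each = R))
    self$grads <- list(gamma = dgamma, beta = dbeta)
    self$xm <- NULL; self$mu <- NULL; self$invstd <- NULL
    dim(dx) <- d
    dx
  }
  self
}

#' @noRd
dense_new <- function(cin, cout, name = "dense") {
  self <- new.env(parent = emptyenv())
  self$kind <- "dense"; self$name <- name
  sd <- sqrt(2 / (cin + cout))
  self$W <- matrix(stats::rnorm(cin * cout, 0, sd), cin, cout)
  self$b <- numeric(cout)
  self$param_names <- c("W", "b")
  self$grads <- list(); self$param_layers <- list(self)
  self$fwd <- function(x, training = FALSE) {
    if (training) self$x <- x
    sweep(x %*% self$W, 2L, self$b, "+")
  }
  self$bwd <- function(dy) {
    self$grads <- list(W = crossprod(self$x, dy), b = colSums(dy))
    dx <- tcrossprod(dy, self$W)
    self$x <- NULL
    dx
  }
  self
}

# inverted dropout: scaling at train time, identity at inference
#' @noRd
dropout_new <- function(rate, name = "dropout") {
  self <- new.env(parent = emptyenv())
  self$kind <- "dropout"; self$name <- name; self$rate <- rate
  self$param_names <- character(0); self$param_layers <- list()
  self$fwd <- function(x, training = FALSE) {
    if (!training || rate <= 0) return(x)
    keep <- 1 - rate
    self$mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
    x * self$mask
  }
  self$bwd <- function(dy) {
    if (is.null(self$mask)) return(dy)
    dx <- dy * self$mask
    self$mask <- NULL
    dx
  }
  self
}

# global average pooling over both spatial axes: N x T x E x C -> N x C
#' @noRd
gap_new <- function(name = "gap") {
  self <- new.env(parent = emptyenv())
  self$kind <- "gap"; self$name <- name
  self$param_names <- character(0); self$param_layers <- list()
  self$fwd <- function(x, training = FALSE) {
    d <- dim(x); N <- d[1L]; TE <- d[2L] * d[3L]; C <- d[4L]
    if (training) self$dims <- d
    dim(x) <- c(N * TE, C)
    grp <- rep_len(seq_len(N), N * TE)
    y <- rowsum(x, grp) / TE
    dimnames(y) <- NULL
    y
  }
  self$bwd <- function(dy) {
    d <- self$dims; N <- d[1L]; TE <- d[2L] * d[3L]
    dx <- dy[rep_len(seq_len(N), N * TE), , drop = FALSE] / TE
    dim(dx) <- d
    dx
  }
  self
}

# softmax + categorical cross-entropy, fused for a stable gradient
#' @noRd
softmax_xent <- function(logits, y) {
  N <- nrow(logits)
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  ll <- log(p[cbind(seq_len(N), y)] + 1e-12)
  dlogits <- p
  dlogits[cbind(seq_len(N), y)] <- dlogits[cbind(seq_len(N), y)] - 1
  list(loss = -mean(ll), probs = p, dlogits = dlogits / N)
}

#' @noRd
softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

# ---- Adam -------------------------------------------------------------

#' @noRd
adam_new <- function(layers, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  self <- new.env(parent = emptyenv())
  self$layers <- layers; self$lr <- lr
  self$beta1 <- beta1; self$beta2 <- beta2; self$eps <- eps
  self$t <- 0L
  self$state <- lapply(layers, function(l)
    lapply(stats::setNames(l$param_names, l$param_names), function(nm) {
      p <- get(nm, envir = l)
      list(m = 0 * p, v = 0 * p)
    }))
  self$step <- function() {
    self$t <- self$t + 1L
    bc1 <- 1 - self$beta1^self$t
    bc2 <- 1 - self$beta2^self$t
    for (i in seq_along(self$layers)) {
      l <- self$layers[[i]]
      for (nm in l$param_names) {
        g <- l$grads[[nm]]
        st <- self$state[[i]][[nm]]
        st$m <- self$beta1 * st$m + (1 - self$beta1) * g
        st$v <- self$beta2 * st$v + (1 - self$beta2) * g * g
        self$state[[i]][[nm]] <- st
        upd <- self$lr * (st$m / bc1) / (sqrt(st$v / bc2) + self$eps)
        assign(nm, get(nm, envir = l) - upd, envir = l)
      }
    }
  }
  self
}

`%||%` <- function(a, b) if (is.null(a)) b else a
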