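# Channel and spatial attention, and the residual attention block.
#
# Channel attention (CAS): squeeze the spatial axes with global average and
# max pooling, push both descriptors through one shared bottleneck MLP
# (C -> C/r -> C, ReLU on both layers), sum, sigmoid -> a per-channel map
# Mc in (0,1) applied as F * Mc broadcast over space.
#
# Spatial attention (SAS): pool over the channel axis with mean and max,
# concatenate to an H x W x 2 descriptor, convolve with a (2,1) then a (1,2)
# single-filter kernel (morphology along time, then across adjacent
# electrodes), sigmoid -> a per-position map Ms in (0,1) applied broadcast
# over channels.
#
# The residual block applies channel attention first, then spatial attention,
# then adds the original input back:
#   G = F * Mc(F);  H = G * Ms(G);  out = F + H.
# With both maps at sigmoid(0) = 0.5 and constant F this gives 1.25 * F,
# so the branch can never die.

# row-group vector for an N x T x E x C tensor viewed as (N*T*E) x C
.grp_n <- function(N, TE) rep_len(seq_len(N), N * TE)

#' @noRd
channel_attention_new <- function(C, r, name = "cas") {
  if (C %% r != 0L)
    stopf("channel attention: C = %d is not divisible by reduction rate r = %d",
          C, r)
  Ch <- C %/% r
  self <- new.env(parent = emptyenv())
  self$kind <- "channel_attention"; self$name <- name; self$C <- C
  sd0 <- sqrt(2 / (C + Ch)); sd1 <- sqrt(2 / (Ch + C))
  self$W0 <- matrix(stats::rnorm(C * Ch, 0, sd0), C, Ch)
  self$b0 <- numeric(Ch)
  self$W1 <- matrix(stats::rnorm(Ch * C, 0, sd1), Ch, C)
  self$b1 <- numeric(C)
  self$param_names <- c("W0", "b0", "W1", "b1")
  self$grads <- list(); self$param_layers <- list(self)

  mlp <- function(x, N) {
    pre1 <- x %*% self$W0 + rep(self$b0, each = N)
    h1 <- pmax(pre1, 0)
    pre2 <- h1 %*% self$W1 + rep(self$b1, each = N)
    list(pre1 = pre1, h1 = h1, pre2 = pre2, out = pmax(pre2, 0))
  }

  self$fwd <- function(F_, training = FALSE) {
    d <- dim(F_); N <- d[1L]; TE <- d[2L] * d[3L]
    xm <- matrix(F_, ncol = C)
    avg <- rowsum(xm, .grp_n(N, TE)) / TE                  # N x C
    dimnames(avg) <- NULL
    Xm <- matrix(aperm(array(F_, c(N, TE, C)), c(1L, 3L, 2L)), nrow = N * C)
    idx <- max.col(Xm, ties.method = "first")              # spatial argmax
    mx <- matrix(Xm[cbind(seq_len(N * C), idx)], N, C)
    fa <- mlp(avg, N); fm <- mlp(mx, N)
    Mc <- .sigmoid(fa$out + fm$out)
    if (training) {
      self$cache <- list(avg = avg, mx = mx, idx = idx, fa = fa, fm = fm,
                         Mc = Mc, dims = d)
    }
    Mc
  }

  self$bwd <- function(dMc) {
    cc <- self$cache
    d <- cc$dims; N <- d[1L]; TE <- d[2L] * d[3L]
    ds <- dMc * cc$Mc * (1 - cc$Mc)
    back_branch <- function(f, x) {
      dh2 <- ds * (f$pre2 > 0)
      dW1 <- crossprod(f$h1, dh2); db1 <- colSums(dh2)
      dpre1 <- tcrossprod(dh2, self$W1) * (f$pre1 > 0)
      dW0 <- crossprod(x, dpre1); db0 <- colSums(dpre1)
      list(dx = tcrossprod(dpre1, self$W0),
           dW0 = dW0, db0 = db0, dW1 = dW1, db1 = db1)
    }
    ba <- back_branch(cc$fa, cc$avg)
    bm <- back_branch(cc$fm, cc$mx)
    self$grads <- list(W0 = ba$dW0 + bm$dW0, b0 = ba$db0 + bm$db0,
                       W1 = ba$dW1 + bm$dW1, b1 = ba$db1 + bm$db1)
    # average-pool path: spread each (n, c) gradient uniformly over space
    dFvec <- as.vector(ba$dx[.grp_n(N, TE), , drop = FALSE] / TE)
    # max-pool path: route each (n, c) gradient to its argmax position;
    # Xm row r corresponds to n = (r-1) %% N + 1, c = (r-1) %/% N + 1,
    # and position idx[r] in the (N, TE, C) layout
    r <- seq_len(N * C)
    n <- (r - 1L) %% N + 1L
    ch <- (r - 1L) %/% N
    lin <- n + N * ((cc$idx - 1L) + TE * ch)
    dFvec[lin] <- dFvec[lin] + as.vector(bm$dx)
    self$cache <- NULL
    array(dFvec, d)
  }
  self
}

#' @noRd
spatial_attention_new <- function(kernels = list(c(2L, 1L), c(1L, 2L)),
                                  name = "sas") {
  self <- new.env(parent = emptyenv())
  self$kind <- "spatial_attention"; self$name <- name
  cin <- 2L
  self$convs <- lapply(seq_along(kernels), function(i) {
    k <- kernels[[i]]
    l <- conv2d_new(k[1L], k[2L], if (i == 1L) 2L else 1L, 1L,
                    name = paste0(name, "_conv", i))
    l
  })
  self$param_names <- character(0)
  self$param_layers <- self$convs

  self$fwd <- function(G, training = FALSE) {
    d <- dim(G); C <- d[4L]
    xm <- matrix(G, ncol = C)
    avg <- rowMeans(xm)
    idx <- max.col(xm, ties.method = "first")              # channel argmax
    mx <- xm[cbind(seq_along(idx), idx)]
    P <- array(c(avg, mx), c(d[1:3], 2L))
    z <- P
    for (l in self$convs) z <- l$fwd(z, training)
    Ms <- .sigmoid(z)
    if (training) self$cache <- list(idx = idx, Ms = Ms, C = C, dims = d)
    Ms
  }

  self$bwd <- function(dMs) {
    cc <- self$cache
    dz <- dMs * cc$Ms * (1 - cc$Ms)
    for (l in rev(self$convs)) dz <- l$bwd(dz)
    n_pos <- prod(cc$dims[1:3])
    davg <- as.vector(dz[, , , 1L])
    dmx <- as.vector(dz[, , , 2L])
    dxm <- matrix(davg / cc$C, nrow = n_pos, ncol = cc$C)  # mean backward
    at <- cbind(seq_len(n_pos), cc$idx)
    dxm[at] <- dxm[at] + dmx                               # max backward
    self$cache <- NULL
    array(dxm, cc$dims)
  }
  self
}

#' @noRd
rescbam_new <- function(C, r, sas_kernels = list(c(2L, 1L), c(1L, 2L)),
                        name = "rescbam") {
  self <- new.env(parent = emptyenv())
  self$kind <- "rescbam"; self$name <- name; self$C <- C
  self$cas <- channel_attention_new(C, r, paste0(name, "_cas"))
  self$sas <- spatial_attention_new(sas_kernels, paste0(name, "_sas"))
  self$param_names <- character(0)
  self$param_layers <- c(self$cas$param_layers, self$sas$param_layers)

  self$fwd <- function(F_, training = FALSE) {
    d <- dim(F_); N <- d[1L]; TE <- d[2L] * d[3L]
    Mc <- self$cas$fwd(F_, training)
    Fm <- matrix(F_, ncol = C)
    Gm <- Fm * Mc[.grp_n(N, TE), , drop = FALSE]
    Garr <- array(Gm, d)
    Ms <- self$sas$fwd(Garr, training)
    msvec <- as.vector(Ms)
    Hm <- Gm * msvec                                       # column recycling
    out <- F_ + array(Hm, d)
    if (training) {
      self$cache <- list(Fm = Fm, Mc = Mc, Gm = Gm, msvec = msvec, dims = d)
    } else {
      self$last_maps <- list(Mc = Mc, Ms = Ms)
    }
    out
  }

  self$bwd <- function(dout) {
    cc <- self$cache
    d <- cc$dims; N <- d[1L]; TE <- d[2L] * d[3L]
    dHm <- matrix(dout, ncol = C)
    dG1 <- dHm * cc$msvec
    dMs <- array(rowSums(dHm * cc$Gm), c(d[1:3], 1L))
    dG2 <- self$sas$bwd(dMs)
    dGm <- dG1 + matrix(dG2, ncol = C)
    grp <- .grp_n(N, TE)
    dF2 <- dGm * cc$Mc[grp, , drop = FALSE]
    dMc <- rowsum(dGm * cc$Fm, grp)
    dF3 <- self$cas$bwd(dMc)
    out <- dout + array(dF2, d) + dF3
    self$cache <- NULL
    out
  }
  self
}
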