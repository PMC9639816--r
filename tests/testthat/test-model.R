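# Architecture: shapes, attention semantics, residual block, gradients.

test_that("default configuration reproduces every printed tensor shape", {
  m <- build_model(model_config(n_classes = 49L), seed = 1)
  x <- array(rnorm(400 * 12), c(1, 400, 12, 1))
  out <- forward_model(m, x, return_intermediates = TRUE)
  # stream widths (8, 2, 2)
  expect_equal(vapply(out$streams, function(s) dim(s)[3], numeric(1)),
               c(8, 2, 2))
  expect_equal(dim(out$H_early), c(1, 400, 12, 32))
  expect_equal(dim(out$H_late), c(1, 400, 12, 128))
  expect_equal(dim(out$H_final), c(1, 400, 12, 160))
  expect_equal(dim(out$H_GAP), c(1, 160))
  expect_equal(dim(out$H_out), c(1, 49))
  expect_equal(rowSums(out$H_out), 1, tolerance = 1e-6)
  # ResCBAM internals per the reference table: CAS hidden width C/r = 32
  # for the first block (C = 64), attention maps in (0, 1)
  rb <- m$streams[[1]][[4]]
  expect_equal(dim(rb$cas$W0), c(64, 32))
  maps <- rb$last_maps
  expect_equal(dim(maps$Mc), c(1, 64))
  expect_equal(dim(maps$Ms), c(1, 400, 8, 1))
  expect_true(all(maps$Mc > 0 & maps$Mc < 1))
  expect_true(all(maps$Ms > 0 & maps$Ms < 1))
})

test_that("stream splitting partitions and reconstructs the input", {
  x <- array(rnorm(2 * 50 * 12), c(2, 50, 12, 1))
  parts <- split_streams(x)
  expect_equal(vapply(parts, function(p) dim(p)[3], numeric(1)), c(8, 2, 2))
  recon <- array(0, dim(x))
  recon[, , 1:8, ] <- parts[[1]]; recon[, , 9:10, ] <- parts[[2]]
  recon[, , 11:12, ] <- parts[[3]]
  expect_identical(recon, x)
  expect_error(model_config(5, stream_slices = list(1:8, 8:10, 11:12)),
               "overlap")
  expect_error(model_config(5, stream_slices = list(1:8, 9:10)), "partition")
})

test_that("BConv order is conv -> ReLU -> BN and shapes are preserved", {
  set.seed(2)
  conv <- conv2d_new(8L, 1L, 1L, 64L)
  x <- array(rnorm(2 * 100 * 8), c(2, 100, 8, 1))
  y <- conv$fwd(x)
  expect_equal(dim(y), c(2, 100, 8, 64))
  # all-zero input -> all-zero BConv output in inference mode
  bn <- batchnorm_new(64L)
  relu <- relu_new()
  z <- bn$fwd(relu$fwd(conv$fwd(array(0, dim(x)))))
  expect_true(all(abs(z) < 1e-12))
  # train-mode BN centres each feature channel
  xt <- array(rnorm(8 * 100 * 8), c(8, 100, 8, 1))
  a <- relu$fwd(conv$fwd(xt, TRUE), TRUE)
  zb <- bn$fwd(a, TRUE)
  ch_means <- colMeans(matrix(zb, ncol = 64))
  expect_lt(max(abs(ch_means)), 0.1)
})

test_that("zero-weight attention maps equal sigmoid(0) = 0.5 exactly", {
  set.seed(3)
  cas <- zero_params(channel_attention_new(8L, 2L))
  F_ <- array(rnorm(2 * 10 * 4 * 8), c(2, 10, 4, 8))
  expect_true(all(cas$fwd(F_) == 0.5))
  sas <- zero_params(spatial_attention_new())
  expect_true(all(sas$fwd(F_) == 0.5))
  # C = 64, r = 2 -> hidden width 32; indivisible C is rejected
  expect_equal(ncol(channel_attention_new(64L, 2L)$W0), 32L)
  expect_error(channel_attention_new(7L, 2L), "divisible")
})

test_that("channel attention is invariant to spatial permutations", {
  set.seed(8)
  cas <- channel_attention_new(6L, 2L)
  F_ <- array(rnorm(3 * 5 * 4 * 6), c(3, 5, 4, 6))
  Fp <- F_[, sample(5), sample(4), , drop = FALSE]
  expect_equal(cas$fwd(F_), cas$fwd(Fp), tolerance = 1e-12)
})

test_that("spatial attention pooling collapses constant channels", {
  set.seed(4)
  sas <- spatial_attention_new()
  base <- array(rnorm(2 * 8 * 4), c(2, 8, 4, 1))
  F_ <- array(rep(base, 5), c(2, 8, 4, 5))    # constant over channels
  xm <- matrix(F_, ncol = 5)
  expect_equal(rowMeans(xm), do.call(pmax, asplit(xm, 2)),
               ignore_attr = TRUE)                          # mean == max
})

test_that("the residual block satisfies its limit cases", {
  set.seed(5)
  C <- 8L
  # attention forced to 0.5/0.5 by zero weights, constant input -> 1.25 * F
  rb <- zero_params(rescbam_new(C, 2L))
  F_ <- array(3, c(2, 10, 4, C))
  expect_equal(rb$fwd(F_), 1.25 * F_, tolerance = 1e-12)
  # attention forced to ~1 by a huge positive bias -> F + F = 2F
  rb2 <- zero_params(rescbam_new(C, 2L))
  assign("b1", rep(50, C), envir = rb2$cas)
  assign("b", 50, envir = rb2$sas$convs[[2]])
  expect_equal(rb2$fwd(F_), 2 * F_, tolerance = 1e-6)
  # shape preservation on the reference geometry
  rb3 <- rescbam_new(64L, 2L)
  x64 <- array(rnorm(400 * 8 * 64), c(1, 400, 8, 64))
  expect_equal(dim(rb3$fwd(x64)), c(1, 400, 8, 64))
})

test_that("early fusion width obeys the configuration", {
  m0 <- build_model(model_config(5, early_width = 0L), seed = 1)
  x <- array(rnorm(400 * 12), c(1, 400, 12, 1))
  out <- forward_model(m0, x, return_intermediates = TRUE)
  expect_null(out$H_early)
  expect_equal(dim(out$H_final)[4], 128)      # H_final = H_late
  # an identity-like single 1x1 filter replicates the input channel
  cv <- conv2d_new(1L, 1L, 1L, 1L)
  assign("W", array(1, c(1, 1, 1, 1)), envir = cv)
  assign("b", 0, envir = cv)
  expect_equal(cv$fwd(x)[, , , 1], x[, , , 1])
})

test_that("inference is stateless: permuting a batch permutes outputs", {
  m <- build_model(tiny_model_config(), seed = 3)
  set.seed(9)
  x <- array(rnorm(6 * 20 * 4), c(6, 20, 4, 1))
  p <- forward_model(m, x)
  perm <- c(4, 1, 6, 2, 5, 3)
  expect_equal(forward_model(m, x[perm, , , , drop = FALSE]), p[perm, ],
               tolerance = 1e-12)
  expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-6)
})

test_that("analytic gradients match finite differences everywhere", {
  set.seed(42)
  m <- build_model(tiny_model_config(), seed = 7)
  # jitter parameters so no pre-activation sits exactly on a ReLU kink
  for (l in m$param_layers)
    for (nm in l$param_names) {
      p <- get(nm, envir = l)
      assign(nm, p + rnorm(length(p), 0, 0.05), envir = l)
    }
  N <- 4L
  x <- array(rnorm(N * 10 * 4), c(N, 10, 4, 1))
  y <- sample(1:3, N, replace = TRUE)
  loss_fn <- function() {
    logits <- forward_model(m, x, training = TRUE)
    sm <- softmax_xent(logits, y)
    backward_model(m, sm$dlogits * 0)        # flush caches
    sm$loss
  }
  logits <- forward_model(m, x, training = TRUE)
  sm <- softmax_xent(logits, y)
  dx <- backward_model(m, sm$dlogits)
  saved <- lapply(m$param_layers, function(l) l$grads)
  eps <- 1e-5
  worst <- 0
  for (li in seq_along(m$param_layers)) {
    l <- m$param_layers[[li]]
    for (nm in l$param_names) {
      p <- get(nm, envir = l)
      g <- saved[[li]][[nm]]
      for (i in sample(length(p), min(4L, length(p)))) {
        p0 <- p[i]
        p[i] <- p0 + eps; assign(nm, p, envir = l); lp <- loss_fn()
        p[i] <- p0 - eps; assign(nm, p, envir = l); lm <- loss_fn()
        p[i] <- p0; assign(nm, p, envir = l)
        fd <- (lp - lm) / (2 * eps)
        worst <- max(worst, abs(fd - g[i]) / max(1e-3, abs(fd) + abs(g[i])))
      }
    }
  }
  expect_lt(worst, 1e-4)
  # input gradient too
  i <- 17L
  x0 <- x[i]
  x[i] <- x0 + eps; lp <- loss_fn()
  x[i] <- x0 - eps; lm <- loss_fn()
  x[i] <- x0
  expect_equal(dx[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
})

test_that("electrode-permutation equivariance within a stream slice", {
  # permuting electrodes inside stream 2 and permuting the early-fusion
  # input correspondingly must leave stream-1 outputs unchanged (streams are
  # independent), and a 1-wide electrode kernel makes stream 2 equivariant
  m <- build_model(tiny_model_config(), seed = 11)
  set.seed(1)
  x <- array(rnorm(2 * 20 * 4), c(2, 20, 4, 1))
  xp <- x[, , c(1, 2, 4, 3), , drop = FALSE]   # swap electrodes of stream 2
  o1 <- forward_model(m, x, return_intermediates = TRUE)
  o2 <- forward_model(m, xp, return_intermediates = TRUE)
  expect_equal(o2$streams[[1]], o1$streams[[1]], tolerance = 1e-12)
})
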