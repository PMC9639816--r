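# The multi-stream feature-fusion network.
#
# Topology: the 400 x 12 x 1 fragment is split along the electrode axis into
# three muscle-region streams (forearm ring 8, digitorum pair 2, upper-arm
# pair 2).  Each stream runs BConv1 (kernel 8x1, morphology along time) ->
# residual attention -> BConv2 (kernel 1x8 / 1x2, across electrodes) ->
# residual attention, where a BConv block is convolution -> ReLU -> batch
# normalisation (in that order).  Late fusion concatenates the stream outputs
# along the electrode axis (T x 12 x 128 by default); early fusion expands
# the raw fragment with C_early 1x1 linear convolutions (T x 12 x 32).  The
# two are concatenated channel-wise (160 channels), globally average-pooled
# to one neuron per channel, and classified by FC -> dropout -> FC-softmax.

#' Model configuration
#'
#' Defaults reproduce the reference architecture for 12-electrode, 400-sample
#' fragments: stream slices (8, 2, 2), 64 then 128 filters, reduction rate 2,
#' early width 32, late width 128 (160 fused channels).
#'
#' @param n_classes number of gesture classes.
#' @param n_channels electrode count E (default 12).
#' @param stream_slices list of 1-based electrode index ranges, one per
#'   stream; must partition `1:n_channels` without overlap.
#' @param bconv1_filters,bconv2_filters filter counts of the two BConv
#'   blocks per stream (64, 128).
#' @param bconv1_kernel kernel of BConv1, `(time, electrode)` (default
#'   `c(8, 1)`: 8 time samples of one electrode).
#' @param bconv2_kernels list of per-stream BConv2 kernels; default
#'   `(1, 8)` for the 8-electrode stream and `(1, 2)` for the 2-electrode
#'   streams (the electrode axis is only 2 wide there).
#' @param reduction_rate bottleneck reduction r of channel attention.
#' @param sas_kernels ordered spatial-attention convolution kernels.
#' @param early_width number of 1x1 early-fusion filters, `0` disables the
#'   early branch entirely (default 32).
#' @param fc_width width of the fully connected layer (default 512).
#' @param dropout_rate dropout before the output layer (default 0.5).
#' @return a `model_config` list.
#' @export
model_config <- function(n_classes, n_channels = 12L,
                         stream_slices = list(1:8, 9:10, 11:12),
                         bconv1_filters = 64L, bconv2_filters = 128L,
                         bconv1_kernel = c(8L, 1L),
                         bconv2_kernels = NULL,
                         reduction_rate = 2L,
                         sas_kernels = list(c(2L, 1L), c(1L, 2L)),
                         early_width = 32L, fc_width = 512L,
                         dropout_rate = 0.5) {
  if (!is_count(n_classes, 2L)) stopf("n_classes must be >= 2")
  slices <- lapply(stream_slices, as.integer)
  flat <- unlist(slices)
  if (any(duplicated(flat)))
    stopf("stream slices overlap: electrode(s) %s appear twice",
          paste(unique(flat[duplicated(flat)]), collapse = ", "))
  if (!setequal(flat, seq_len(n_channels)) || length(flat) != n_channels)
    stopf("stream slices must partition electrodes 1..%d", n_channels)
  if (bconv1_filters %% reduction_rate != 0L ||
      bconv2_filters %% reduction_rate != 0L)
    stopf("filter counts must be divisible by the reduction rate")
  if (is.null(bconv2_kernels))
    bconv2_kernels <- lapply(slices, function(s)
      c(1L, min(8L, length(s))))
  if (length(bconv2_kernels) != length(slices))
    stopf("need one bconv2 kernel per stream")
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels),
                 stream_slices = slices,
                 bconv1_filters = as.integer(bconv1_filters),
                 bconv2_filters = as.integer(bconv2_filters),
                 bconv1_kernel = as.integer(bconv1_kernel),
                 bconv2_kernels = lapply(bconv2_kernels, as.integer),
                 reduction_rate = as.integer(reduction_rate),
                 sas_kernels = lapply(sas_kernels, as.integer),
                 early_width = as.integer(early_width),
                 fc_width = as.integer(fc_width),
                 dropout_rate = dropout_rate),
            class = "model_config")
}

#' Reduced-width preset of the model configuration
#'
#' Same topology at desk scale (8/16 filters, early width 8, FC 64): used for
#' CPU training experiments on synthetic data.
#'
#' @inheritParams model_config
#' @param ... overrides passed on to [model_config()].
#' @export
model_config_reduced <- function(n_classes, ...) {
  model_config(n_classes, bconv1_filters = 8L, bconv2_filters = 16L,
               early_width = 8L, fc_width = 64L, ...)
}

#' Split a fragment batch into muscle-region streams
#'
#' @param x array `N x T x E x 1` (or `N x T x E`).
#' @param stream_slices electrode index ranges, as in [model_config()].
#' @return list of `N x T x |slice| x 1` tensors; concatenating them along
#'   the electrode axis reconstructs the input exactly.
#' @export
split_streams <- function(x, stream_slices = list(1:8, 9:10, 11:12)) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  E <- dim(x)[3L]
  flat <- unlist(stream_slices)
  if (any(duplicated(flat)) || any(flat < 1L) || any(flat > E))
    stopf("stream slices must be disjoint subsets of 1..%d", E)
  lapply(stream_slices, function(s) x[, , s, , drop = FALSE])
}

#' Build the network
#'
#' Instantiates all layers with Glorot-initialised weights drawn from `seed`.
#'
#' @param cfg a [model_config()].
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `semg_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    n_streams <- length(cfg$stream_slices)
    streams <- lapply(seq_len(n_streams), function(s) {
      k1 <- cfg$bconv1_kernel; k2 <- cfg$bconv2_kernels[[s]]
      list(
        conv2d_new(k1[1L], k1[2L], 1L, cfg$bconv1_filters,
                   sprintf("s%d_bconv1", s)),
        relu_new(sprintf("s%d_relu1", s)),
        batchnorm_new(cfg$bconv1_filters, sprintf("s%d_bn1", s)),
        rescbam_new(cfg$bconv1_filters, cfg$reduction_rate, cfg$sas_kernels,
                    sprintf("s%d_rescbam1", s)),
        conv2d_new(k2[1L], k2[2L], cfg$bconv1_filters, cfg$bconv2_filters,
                   sprintf("s%d_bconv2", s)),
        relu_new(sprintf("s%d_relu2", s)),
        batchnorm_new(cfg$bconv2_filters, sprintf("s%d_bn2", s)),
        rescbam_new(cfg$bconv2_filters, cfg$reduction_rate, cfg$sas_kernels,
                    sprintf("s%d_rescbam2", s))
      )
    })
    early <- if (cfg$early_width > 0L)
      conv2d_new(1L, 1L, 1L, cfg$early_width, "early_1x1") else NULL
    c_final <- cfg$early_width + cfg$bconv2_filters
    head <- list(
      gap = gap_new(),
      fc1 = dense_new(c_final, cfg$fc_width, "fc1"),
      relu = relu_new("fc_relu"),
      dropout = dropout_new(cfg$dropout_rate),
      fc2 = dense_new(cfg$fc_width, cfg$n_classes, "fc_out")
    )
    model <- list(cfg = cfg, streams = streams, early = early, head = head)
    model$param_layers <- c(
      unlist(lapply(streams, function(st)
        unlist(lapply(st, function(l) l$param_layers), recursive = FALSE)),
        recursive = FALSE),
      if (!is.null(early)) early$param_layers,
      head$fc1$param_layers, head$fc2$param_layers)
    class(model) <- "semg_model"
    model
  })
}

#' @export
print.semg_model <- function(x, ...) {
  n_par <- sum(vapply(x$param_layers, function(l)
    sum(vapply(l$param_names, function(nm) length(get(nm, envir = l)),
               numeric(1))), numeric(1)))
  cat(sprintf(
    "<semg_model> %d streams (widths %s), filters %d/%d, early %d, fc %d, %d classes; %s parameters\n",
    length(x$streams),
    paste(lengths(x$cfg$stream_slices), collapse = ","),
    x$cfg$bconv1_filters, x$cfg$bconv2_filters, x$cfg$early_width,
    x$cfg$fc_width, x$cfg$n_classes, format(n_par, big.mark = ",")))
  invisible(x)
}

#' Forward pass
#'
#' Maps a batch of fragments to class probabilities.  With
#' `return_intermediates = TRUE` also returns the named fusion tensors
#' (`streams`, `H_early`, `H_late`, `H_final`, `H_GAP`, `logits`, `H_out`)
#' for shape auditing.
#'
#' @param model a [build_model()] network.
#' @param x array `N x T x E x 1` (an `N x T x E` array or a single `T x E`
#'   matrix are promoted).
#' @param training logical; training mode enables batch statistics, dropout
#'   and activation caching for [backward_model()].
#' @param return_intermediates logical.
#' @return `N x n_classes` probability matrix (rows sum to 1), or a list of
#'   intermediates.
#' @export
forward_model <- function(model, x, training = FALSE,
                          return_intermediates = FALSE) {
  stopifnot(inherits(model, "semg_model"))
  if (is.matrix(x)) dim(x) <- c(1L, dim(x))
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  cfg <- model$cfg
  d <- dim(x)
  if (d[3L] != cfg$n_channels)
    stopf("input has %d electrodes, model expects %d", d[3L], cfg$n_channels)
  xs <- split_streams(x, cfg$stream_slices)
  outs <- vector("list", length(xs))
  for (s in seq_along(xs)) {
    z <- xs[[s]]
    for (l in model$streams[[s]]) z <- l$fwd(z, training)
    outs[[s]] <- z
  }
  # late fusion: concatenate stream outputs along the electrode axis
  H_late <- array(0, c(d[1L], d[2L], cfg$n_channels, cfg$bconv2_filters))
  for (s in seq_along(xs))
    H_late[, , cfg$stream_slices[[s]], ] <- outs[[s]]
  # early fusion: 1x1 linear expansion of the un-split fragment
  if (!is.null(model$early)) {
    H_early <- model$early$fwd(x, training)
    H_final <- array(0, c(d[1L], d[2L], cfg$n_channels,
                          cfg$early_width + cfg$bconv2_filters))
    H_final[, , , seq_len(cfg$early_width)] <- H_early
    H_final[, , , cfg$early_width + seq_len(cfg$bconv2_filters)] <- H_late
  } else {
    H_early <- NULL
    H_final <- H_late
  }
  h <- model$head
  H_GAP <- h$gap$fwd(H_final, training)
  z <- h$fc1$fwd(H_GAP, training)
  z <- h$relu$fwd(z, training)
  z <- h$dropout$fwd(z, training)
  logits <- h$fc2$fwd(z, training)
  probs <- softmax_rows(logits)
  if (return_intermediates)
    list(streams = outs, H_early = H_early, H_late = H_late,
         H_final = H_final, H_GAP = H_GAP, logits = logits, H_out = probs)
  else if (training)
    logits
  else probs
}

#' Backward pass
#'
#' Propagates the loss gradient through the network, leaving parameter
#' gradients in each layer.  Must follow a `training = TRUE` forward call.
#'
#' @param model a `semg_model`.
#' @param dlogits gradient of the loss with respect to the logits.
#' @return gradient with respect to the input batch, invisibly.
#' @export
backward_model <- function(model, dlogits) {
  cfg <- model$cfg
  h <- model$head
  dz <- h$fc2$bwd(dlogits)
  dz <- h$dropout$bwd(dz)
  dz <- h$relu$bwd(dz)
  dgap <- h$fc1$bwd(dz)
  dfinal <- h$gap$bwd(dgap)
  d <- dim(dfinal)
  if (!is.null(model$early)) {
    dearly <- dfinal[, , , seq_len(cfg$early_width), drop = FALSE]
    dlate <- dfinal[, , , cfg$early_width + seq_len(cfg$bconv2_filters),
                    drop = FALSE]
    dx <- model$early$bwd(dearly)
  } else {
    dlate <- dfinal
    dx <- array(0, c(d[1:2], cfg$n_channels, 1L))
  }
  for (s in seq_along(model$streams)) {
    dzs <- dlate[, , cfg$stream_slices[[s]], , drop = FALSE]
    for (l in rev(model$streams[[s]])) dzs <- l$bwd(dzs)
    dx[, , cfg$stream_slices[[s]], ] <-
      dx[, , cfg$stream_slices[[s]], , drop = FALSE] + dzs
  }
  invisible(dx)
}

# deep-copy all learnable state (parameters + BN running stats)
snapshot_params <- function(model) {
  snaps <- lapply(model$param_layers, function(l) {
    nms <- c(l$param_names,
             if (l$kind == "batchnorm") c("run_mean", "run_var"))
    lapply(stats::setNames(nms, nms), function(nm) get(nm, envir = l))
  })
  snaps
}

restore_params <- function(model, snaps) {
  for (i in seq_along(model$param_layers)) {
    l <- model$param_layers[[i]]
    for (nm in names(snaps[[i]])) assign(nm, snaps[[i]][[nm]], envir = l)
  }
  invisible(model)
}

#' Class-probability predictions for a fragment set
#'
#' Runs the network in inference mode, in batches to bound memory.
#'
#' @param model a `semg_model`.
#' @param x a [fragment_set()] or an `N x T x E` array.
#' @param batch_size inference batch size.
#' @return `N x n_classes` probability matrix.
#' @export
predict_probs <- function(model, x, batch_size = 256L) {
  emg <- if (inherits(x, "fragment_set")) x$emg else x
  if (length(dim(emg)) == 2L) dim(emg) <- c(1L, dim(emg))
  n <- dim(emg)[1L]
  out <- matrix(0, n, model$cfg$n_classes)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + batch_size - 1L)
    out[idx, ] <- forward_model(model, emg[idx, , , drop = FALSE])
    at <- at + batch_size
  }
  out
}
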