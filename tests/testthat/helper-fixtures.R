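# Shared fixtures: everything is generated in code at test time.

# a fast protocol: few classes/repetitions, short movements, low rate
tiny_protocol <- function(n_classes = 2L, n_repetitions = 2L, seed = 1L,
                          movement_s = 0.5, rest_s = 0.25, fs = 400) {
  protocol_config(n_classes = n_classes, n_repetitions = n_repetitions,
                  movement_s = movement_s, rest_s = rest_s, fs = fs,
                  seed = seed)
}

# a model small enough for exhaustive gradient checks (seconds, not minutes)
tiny_model_config <- function(n_classes = 3L) {
  model_config(n_classes = n_classes, n_channels = 4L,
               stream_slices = list(1:2, 3:4),
               bconv1_filters = 4L, bconv2_filters = 6L,
               bconv1_kernel = c(3L, 1L),
               bconv2_kernels = list(c(1L, 2L), c(1L, 2L)),
               early_width = 2L, fc_width = 8L, dropout_rate = 0)
}

tiny_fragment_set <- function(n = 12L, Tn = 20L, E = 4L, n_classes = 3L,
                              seed = 1L) {
  set.seed(seed)
  # repetitions in blocks so every repetition holds every class
  fragment_set(array(rnorm(n * Tn * E), c(n, Tn, E)),
               label = rep_len(seq_len(n_classes), n),
               repetition = rep(1:6, each = ceiling(n / 6))[seq_len(n)])
}

# a segment fixture with a deterministic waveform
make_segment <- function(L = 100L, E = 3L, label = 1L, repetition = 1L,
                         seed = 1L) {
  set.seed(seed)
  structure(list(data = matrix(rnorm(L * E), L, E), label = as.integer(label),
                 repetition = as.integer(repetition), subject_id = 1L,
                 source_track = "stimulus", start = 1L, warped = FALSE),
            class = "gesture_segment")
}

# zero out every parameter of a layer (and its children)
zero_params <- function(layer) {
  for (l in layer$param_layers)
    for (nm in l$param_names)
      assign(nm, 0 * get(nm, envir = l), envir = l)
  invisible(layer)
}
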