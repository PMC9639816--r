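# Synthetic NinaPro-protocol recordings.
#
# sEMG is well modelled, at the second-order-statistics level, as
# amplitude-modulated band-limited (10-500 Hz) Gaussian noise.  The generator
# reproduces the acquisition protocol of the 12-electrode NinaPro databases:
# each gesture class repeated 6 times, 5 s of movement alternating with 3 s of
# rest, 2000 Hz sampling, per-sample stimulus/repetition label tracks, and a
# "restimulus"-style posterior track whose run boundaries are jittered inward.
# Each class drives a distinct spatial activation pattern across three
# electrode regions (forearm ring, digitorum pair, upper-arm pair).

#' Protocol configuration for the synthetic recording generator
#'
#' Defaults are the NinaPro DB2/DB4 acquisition protocol values: 6 repetitions
#' per gesture, 5 s movement alternating with 3 s rest, 2000 Hz, 12
#' electrodes.  `amplitude` sets the overall physical scale (1e-4, i.e. the
#' ~100 microvolt level of raw sEMG, so that Z-score rescaling from 1e-4 to
#' order 1 is exercised downstream).
#'
#' @param n_classes number of gesture classes.
#' @param n_repetitions repetitions per class (default 6).
#' @param movement_s,rest_s movement / rest durations in seconds (5 and 3).
#' @param fs sampling rate in Hz (2000).
#' @param n_channels electrode count (12).
#' @param noise_sd baseline (rest) noise amplitude relative to `amplitude`.
#' @param region_gain named activation gains for the three electrode regions.
#' @param amplitude physical amplitude scale of the stored signal.
#' @param restim_jitter maximum inward boundary jitter of the posterior
#'   (restimulus) track, as a fraction of run length (default 0.1).
#' @param mains_hz optional mains interference frequency to inject (e.g. 50);
#'   `NULL` (default) disables the injector.
#' @param mains_amp amplitude of the injected mains tone relative to
#'   `amplitude`.
#' @param seed RNG seed; identical seed + config give a bit-identical
#'   recording.
#' @return a `protocol_config` list.
#' @export
protocol_config <- function(n_classes = 49L, n_repetitions = 6L,
                            movement_s = 5, rest_s = 3, fs = 2000,
                            n_channels = 12L, noise_sd = 0.1,
                            region_gain = c(forearm = 1, digitorum = 0.8,
                                            upperarm = 0.6),
                            amplitude = 1e-4,
                            restim_jitter = 0.1,
                            mains_hz = NULL, mains_amp = 0.5,
                            seed = 1L) {
  if (!is_count(n_classes)) stopf("n_classes must be >= 1")
  if (!is_count(n_repetitions)) stopf("n_repetitions must be >= 1")
  if (!is_count(n_channels)) stopf("n_channels must be >= 1")
  if (fs <= 0 || movement_s <= 0 || rest_s < 0) stopf("invalid durations/fs")
  if (restim_jitter < 0 || restim_jitter > 0.5) stopf("restim_jitter in [0, 0.5]")
  structure(list(n_classes = as.integer(n_classes),
                 n_repetitions = as.integer(n_repetitions),
                 movement_s = movement_s, rest_s = rest_s, fs = fs,
                 n_channels = as.integer(n_channels), noise_sd = noise_sd,
                 region_gain = region_gain, amplitude = amplitude,
                 restim_jitter = restim_jitter,
                 mains_hz = mains_hz, mains_amp = mains_amp,
                 seed = seed),
            class = "protocol_config")
}

# electrode -> region map for the 12-electrode layout: 8 forearm-ring,
# 2 digitorum, 2 upper-arm.  Other channel counts scale the same 8:2:2 split.
channel_regions <- function(n_channels) {
  if (n_channels == 12L)
    return(rep(c("forearm", "digitorum", "upperarm"), c(8L, 2L, 2L)))
  n_fore <- max(1L, round(n_channels * 8 / 12))
  n_dig <- max(0L, round(n_channels * 2 / 12))
  n_up <- n_channels - n_fore - n_dig
  if (n_up < 0L) { n_dig <- n_dig + n_up; n_up <- 0L }
  rep(c("forearm", "digitorum", "upperarm"), c(n_fore, n_dig, n_up))
}

# smooth ramp-up / plateau / ramp-down envelope (raised cosine over the first
# and last `ramp_frac` of the run)
.movement_envelope <- function(n, ramp_frac = 0.1) {
  nr <- max(1L, floor(n * ramp_frac))
  env <- rep(1, n)
  up <- 0.5 * (1 - cos(pi * seq_len(nr) / nr))
  env[seq_len(nr)] <- up
  env[n + 1L - seq_len(nr)] <- up
  env
}

#' Generate a synthetic NinaPro-protocol recording
#'
#' The stimulus track contains exactly `n_classes * n_repetitions` maximal
#' nonzero runs of `movement_s * fs` samples, separated (and preceded) by rest
#' runs of `rest_s * fs` samples; classes are performed in order, each
#' repeated consecutively, as in the NinaPro protocol.  The EMG carrier is
#' band-limited (10-500 Hz) Gaussian noise whose per-channel amplitude during
#' a movement is `region_gain[region(channel)] * w[class, channel] * envelope`,
#' with class-specific channel weights `w` drawn once from the seed; the rest
#' floor is `noise_sd`.  The restimulus track equals the stimulus track with
#' each run boundary jittered inward by an independent uniform 0 to
#' `restim_jitter` fraction of the run length, emulating posterior
#' re-labelling.
#'
#' @param cfg a [protocol_config()].
#' @param subject_id,exercise_id identifiers stored on the recording.
#' @return a [recording()].
#' @export
generate_recording <- function(cfg = protocol_config(), subject_id = 1L,
                               exercise_id = 1L) {
  stopifnot(inherits(cfg, "protocol_config"))
  with_seed(cfg$seed, {
    mov_n <- as.integer(round(cfg$movement_s * cfg$fs))
    rest_n <- as.integer(round(cfg$rest_s * cfg$fs))
    n_runs <- cfg$n_classes * cfg$n_repetitions
    total <- rest_n + n_runs * (mov_n + rest_n)
    cls_of_run <- rep(seq_len(cfg$n_classes), each = cfg$n_repetitions)
    rep_of_run <- rep(seq_len(cfg$n_repetitions), times = cfg$n_classes)
    run_start <- rest_n + (seq_len(n_runs) - 1L) * (mov_n + rest_n) + 1L

    stimulus <- integer(total)
    repetition <- integer(total)
    class_track <- integer(total)
    env_track <- numeric(total)
    env <- .movement_envelope(mov_n)
    for (r in seq_len(n_runs)) {
      idx <- run_start[r]:(run_start[r] + mov_n - 1L)
      stimulus[idx] <- cls_of_run[r]
      repetition[idx] <- rep_of_run[r]
      class_track[idx] <- cls_of_run[r]
      env_track[idx] <- env
    }

    regions <- channel_regions(cfg$n_channels)
    w <- matrix(stats::runif(cfg$n_classes * cfg$n_channels, 0.5, 1.5),
                cfg$n_classes, cfg$n_channels)

    # carrier band: 10-500 Hz at the protocol rate, capped below Nyquist
    # for scaled-down sampling rates
    hi <- min(500, 0.45 * cfg$fs)
    emg <- matrix(0, total, cfg$n_channels)
    active <- class_track > 0L
    for (ch in seq_len(cfg$n_channels)) {
      carrier <- bandpass_filter(stats::rnorm(total), cfg$fs, low = 10,
                                 high = hi)
      amp <- rep(cfg$noise_sd, total)
      amp[active] <- amp[active] +
        cfg$region_gain[[regions[ch]]] * w[class_track[active], ch] *
        env_track[active]
      x <- carrier * amp
      if (!is.null(cfg$mains_hz))
        x <- x + cfg$mains_amp *
          sin(2 * pi * cfg$mains_hz * (seq_len(total) - 1L) / cfg$fs)
      emg[, ch] <- x * cfg$amplitude
    }

    restimulus <- integer(total)
    for (r in seq_len(n_runs)) {
      j1 <- floor(stats::runif(1, 0, cfg$restim_jitter) * mov_n)
      j2 <- floor(stats::runif(1, 0, cfg$restim_jitter) * mov_n)
      a <- run_start[r] + j1
      b <- run_start[r] + mov_n - 1L - j2
      if (a <= b) restimulus[a:b] <- cls_of_run[r]
    }

    recording(emg, cfg$fs, stimulus, restimulus, repetition,
              subject_id = subject_id, exercise_id = exercise_id)
  })
}

#' Generate a labelled fragment dataset directly
#'
#' Bypasses segmentation: emits `n_classes * n_per_class` window fragments
#' whose class-conditional channel-power patterns differ by the `separation`
#' knob.  Each class k has a fixed channel-amplitude pattern
#' `1 + separation * u[k, channel]` with `u` uniform on (0, 1) drawn once from
#' the seed; `separation = 0` makes all classes exchangeable (chance-level
#' ceiling), large values make them linearly separable from channel power
#' alone.  Repetition indices 1..6 are assigned cyclically within each class
#' so repetition-wise splitting applies.
#'
#' @param n_classes number of classes (>= 2).
#' @param n_per_class fragments per class.
#' @param separation effect-size knob (default 2, a strong but noisy
#'   separation; per-fragment log-normal amplitude jitter keeps single
#'   channels non-deterministic).
#' @param window fragment length in samples (default 400).
#' @param n_channels electrodes (default 12).
#' @param fs sampling rate for the band-limited carrier (default 2000).
#' @param seed RNG seed; fixed seed gives an identical dataset.
#' @return a [fragment_set()].
#' @export
generate_fragment_dataset <- function(n_classes, n_per_class,
                                      separation = 2, window = 400L,
                                      n_channels = 12L, fs = 2000,
                                      seed = 1L) {
  if (!is_count(n_classes, 2L)) stopf("n_classes must be >= 2")
  if (!is_count(n_per_class)) stopf("n_per_class must be >= 1")
  if (separation < 0) stopf("separation must be >= 0")
  with_seed(seed, {
    n <- n_classes * n_per_class
    u <- matrix(stats::runif(n_classes * n_channels), n_classes, n_channels)
    amp <- 1 + separation * u                      # class x channel amplitude
    label <- rep(seq_len(n_classes), each = n_per_class)
    emg <- array(0, c(n, window, n_channels))
    jit <- exp(stats::rnorm(n, 0, 0.1))            # per-fragment scale jitter,
                                                   # common to all channels
    # one long band-limited stream per channel, sliced into fragments
    hi <- min(500, 0.45 * fs)
    for (ch in seq_len(n_channels)) {
      carrier <- bandpass_filter(stats::rnorm(n * window), fs, low = 10,
                                 high = hi)
      m <- matrix(carrier, nrow = window)          # window x n
      emg[, , ch] <- t(m) * (amp[label, ch] * jit)
    }
    repetition <- as.integer((seq_len(n_per_class) - 1L) %% 6L + 1L)
    fragment_set(emg, label,
                 rep(repetition, times = n_classes), subject = 1L)
  })
}
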