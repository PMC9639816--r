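# The synthetic recording and fragment generators.

test_that("the stimulus track honours the acquisition protocol exactly", {
  cfg <- tiny_protocol(n_classes = 3L, n_repetitions = 2L, seed = 3)
  rec <- generate_recording(cfg)
  runs <- rle(rec$stimulus)
  mov <- which(runs$values > 0L)
  expect_length(mov, 3L * 2L)
  # every movement run has movement_s * fs samples, rests have rest_s * fs
  expect_true(all(runs$lengths[mov] == cfg$movement_s * cfg$fs))
  expect_true(all(runs$lengths[-mov] == cfg$rest_s * cfg$fs))
  # run-length ledger: movement + rest samples account for every sample
  expect_identical(sum(runs$lengths), nrow(rec$emg))
  # repetition track numbers each class's runs 1..n_repetitions
  for (k in 1:3) {
    reps <- rec$repetition[rec$stimulus == k]
    expect_setequal(unique(reps), 1:2)
  }
})

test_that("identical config and seed give a bit-identical recording", {
  cfg <- tiny_protocol(seed = 77)
  r1 <- generate_recording(cfg)
  r2 <- generate_recording(cfg)
  expect_identical(r1$emg, r2$emg)
  expect_identical(r1$restimulus, r2$restimulus)
  # and the generator does not disturb the caller's RNG stream
  set.seed(5); before <- rnorm(3)
  set.seed(5); invisible(generate_recording(cfg)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("movement power exceeds rest power on activated channels", {
  rec <- generate_recording(tiny_protocol(n_classes = 2L, seed = 8))
  act <- rec$stimulus > 0L
  for (ch in c(1L, 9L, 11L)) {        # one channel from each region
    ratio <- mean(rec$emg[act, ch]^2) / mean(rec$emg[!act, ch]^2)
    expect_gt(ratio, 2)
  }
})

test_that("at 2000 Hz nearly all signal power lies in the 10-500 Hz band", {
  cfg <- protocol_config(n_classes = 1L, n_repetitions = 2L, movement_s = 2,
                         rest_s = 1, fs = 2000, seed = 4)
  rec <- generate_recording(cfg)
  x <- rec$emg[, 1]
  spec <- Mod(stats::fft(x))^2
  n <- length(x)
  freq <- (seq_len(n) - 1) * cfg$fs / n
  half <- freq <= cfg$fs / 2
  inband <- half & freq >= 10 & freq <= 500
  expect_gt(sum(spec[inband]) / sum(spec[half]), 0.95)
})

test_that("restimulus runs are jittered inward within the stimulus runs", {
  rec <- generate_recording(tiny_protocol(n_classes = 3L, seed = 12))
  # restimulus active samples are a subset of stimulus active samples
  expect_true(all(rec$stimulus[rec$restimulus > 0L] ==
                    rec$restimulus[rec$restimulus > 0L]))
  # same number of runs, each shorter than or equal to the original
  rs <- rle(rec$restimulus); ss <- rle(rec$stimulus)
  expect_equal(sum(rs$values > 0), sum(ss$values > 0))
  expect_true(all(rs$lengths[rs$values > 0] <= ss$lengths[ss$values > 0]))
  # jitter bounded by 10% per side
  expect_true(all(rs$lengths[rs$values > 0] >=
                    0.8 * ss$lengths[ss$values > 0] - 2))
})

test_that("optional mains injector adds a 50 Hz line", {
  cfg <- tiny_protocol(n_classes = 1L, n_repetitions = 1L, fs = 400, seed = 2)
  cfg$mains_hz <- 50
  rec <- generate_recording(cfg)
  x <- rec$emg[, 1] / cfg$amplitude
  n <- length(x)
  spec <- Mod(stats::fft(x))^2
  freq <- (seq_len(n) - 1) * cfg$fs / n
  peak <- freq[which.max(spec[freq > 0 & freq <= 200])]
  expect_equal(peak, 50, tolerance = 0.05)
})

test_that("fragment dataset separation knob controls class structure", {
  f0 <- generate_fragment_dataset(3, 4, separation = 0, window = 64L,
                                  seed = 2)
  expect_length(f0, 12L)
  expect_equal(dim(f0$emg), c(12L, 64L, 12L))
  # determinism
  f0b <- generate_fragment_dataset(3, 4, separation = 0, window = 64L,
                                   seed = 2)
  expect_identical(f0$emg, f0b$emg)
  # with separation, between-class channel-power patterns differ strongly
  fs1 <- generate_fragment_dataset(4, 40, separation = 3, window = 128L,
                                   seed = 3)
  pow <- t(apply(fs1$emg, 1, function(m) colMeans(m^2)))
  pow <- pow / rowSums(pow)            # scale-free pattern
  cent <- apply(pow, 2, function(col) tapply(col, fs1$label, mean))
  within <- mean(vapply(1:4, function(k)
    mean(rowSums(sweep(pow[fs1$label == k, ], 2, cent[k, ])^2)), numeric(1)))
  between <- mean(dist(cent)^2)
  expect_gt(between / within, 5)
})
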