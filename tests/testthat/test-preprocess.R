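# Segmentation, Z-score normalisation, fragmentation, splitting.

test_that("segmentation equals a brute-force run-length oracle", {
  # the documented example: [0,3,3,0,3,3,3] -> two class-3 segments (2, 3)
  lab <- c(0L, 3L, 3L, 0L, 3L, 3L, 3L)
  rec <- recording(matrix(seq_len(14), 7, 2), fs = 10, stimulus = lab,
                   repetition = c(0L, 1L, 1L, 0L, 2L, 2L, 2L))
  segs <- segment_actions(rec)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, function(s) nrow(s$data), integer(1)), c(2L, 3L))
  expect_equal(vapply(segs, `[[`, integer(1), "label"), c(3L, 3L))
  expect_equal(vapply(segs, `[[`, integer(1), "repetition"), c(1L, 2L))
  # segment data are the exact rows of the recording
  expect_equal(segs[[2]]$data, rec$emg[5:7, ])

  # property: for random label tracks, segments match an independent oracle
  set.seed(42)
  for (i in 1:25) {
    lab <- sample(0:3, 60, replace = TRUE)
    rep_track <- ifelse(lab > 0L, 1L, 0L)
    rec <- recording(matrix(rnorm(120), 60, 2), fs = 10, stimulus = lab,
                     repetition = rep_track)
    segs <- segment_actions(rec)
    # oracle: scan for maximal constant nonzero runs
    runs <- 0L; cur <- 0L
    for (v in c(lab, 0L)) {
      if (v != cur) { if (cur > 0L) runs <- runs + 1L; cur <- v }
    }
    expect_length(segs, runs)
    expect_equal(sum(vapply(segs, function(s) nrow(s$data), integer(1))),
                 sum(lab > 0L))
  }
})

test_that("all-rest recordings yield no segments; zero repetition warns", {
  rec <- recording(matrix(0, 10, 2), fs = 10, stimulus = rep(0L, 10),
                   repetition = rep(0L, 10))
  expect_length(segment_actions(rec), 0L)

  rec2 <- recording(matrix(rnorm(20), 10, 2), fs = 10,
                    stimulus = c(0L, 1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L),
                    repetition = rep(0L, 10))
  w <- capture_warnings(segs <- segment_actions(rec2))
  expect_length(w, 2L)                       # one per zero-repetition run
  expect_match(w, "occurrence", all = TRUE)
  expect_equal(vapply(segs, `[[`, integer(1), "repetition"), c(1L, 2L))
})

test_that("Z-score gives per-channel mean 0 and population SD 1", {
  # definition on a known column
  st <- zscore_fit(matrix(c(1, 2, 3), ncol = 1))
  expect_equal(st$mu, 2, ignore_attr = TRUE)
  expect_equal(st$sigma, sqrt(2 / 3), ignore_attr = TRUE)   # population SD

  set.seed(7)
  x <- cbind(1e-4 * rnorm(500, 2), 1e-2 * rnorm(500, -1))   # mixed scales
  st <- zscore_fit(x)
  y <- zscore_apply(x, st)
  expect_lt(max(abs(colMeans(y))), 1e-8)
  expect_lt(max(abs(sqrt(colMeans(sweep(y, 2, colMeans(y))^2)) - 1)), 1e-6)

  # identity stats give the identity map
  id <- structure(list(mu = c(0, 0), sigma = c(1, 1)), class = "norm_stats")
  expect_equal(zscore_apply(x, id), x)

  # idempotence: re-fitting on normalised data changes nothing material
  y2 <- zscore_apply(y, zscore_fit(y))
  expect_lt(max(abs(y2 - y)), 1e-12 + max(abs(y)) * 1e-12)

  # constant channel is rejected by name
  expect_error(zscore_fit(cbind(rnorm(10), rep(1, 10))), "2")
})

test_that("fragment counts follow floor((L - W)/S) + 1 and never cross segments", {
  seg <- make_segment(L = 10000L, E = 2L)
  fr <- fragment(seg, window_ms = 200, step_ms = 50, fs = 2000)
  expect_length(fr, 97L)                       # (10000 - 400)/100 + 1
  expect_true(all(vapply(fr, function(f) nrow(f$data), integer(1)) == 400L))
  # boundary cases
  expect_length(fragment(make_segment(L = 400L), fs = 2000), 1L)
  expect_length(fragment(make_segment(L = 399L), fs = 2000), 0L)

  # property: formula matches brute-force enumeration for random (L, W, S)
  set.seed(11)
  for (i in 1:1000) {
    L <- sample(1:500, 1); W <- sample(1:120, 1); S <- sample(1:60, 1)
    brute <- 0L; start <- 1L
    while (start + W - 1L <= L) { brute <- brute + 1L; start <- start + S }
    formula_n <- if (L < W) 0L else (L - W) %/% S + 1L
    expect_identical(formula_n, brute)
  }

  # windows tile the segment without crossing its boundary
  seg2 <- make_segment(L = 950L, E = 2L)
  fr2 <- fragment(seg2, window_ms = 100, step_ms = 30, fs = 1000)
  offs <- vapply(fr2, `[[`, numeric(1), "offset")
  expect_true(all(offs + 100 <= 950))
  expect_equal(fr2[[3]]$data, seg2$data[61:160, ])
})

test_that("fragment_segments reports skipped-short segments", {
  segs <- list(make_segment(L = 500L, E = 2L, label = 1L),
               make_segment(L = 50L, E = 2L, label = 2L))
  out <- fragment_segments(segs, window_ms = 100, step_ms = 50, fs = 1000)
  rep <- attr(out, "report")
  expect_equal(rep$n_skipped, 1L)
  expect_equal(rep$n_fragments, length(out))
  expect_true(all(out$label == 1L))
})

test_that("repetition split and folds respect the protocol", {
  fs0 <- tiny_fragment_set(n = 60L, n_classes = 2L)
  split <- split_by_repetition(fs0)
  expect_setequal(unique(split$train$repetition), c(1L, 3L, 4L, 6L))
  expect_setequal(unique(split$test$repetition), c(2L, 5L))
  expect_length(intersect(unique(split$train$repetition),
                          unique(split$test$repetition)), 0L)
  expect_equal(length(split$train) + length(split$test), 60L)

  split <- make_folds(split, k = 4L)
  expect_length(split$folds, 4L)
  val_reps <- vapply(split$folds, function(f)
    unique(split$train$repetition[f$val_idx]), integer(1))
  expect_setequal(val_reps, c(1L, 3L, 4L, 6L))    # all distinct, one each
  for (f in split$folds)
    expect_length(intersect(f$train_idx, f$val_idx), 0L)

  # error paths
  expect_error(split_by_repetition(fs0, train_reps = 1:4, test_reps = 4:5),
               "disjoint")
  s1 <- split_by_repetition(fs0, train_reps = 1L, test_reps = 2L)
  expect_error(make_folds(s1, k = 4L), "cannot make 4 folds")
})

test_that("warped fragments train but never validate", {
  fs0 <- tiny_fragment_set(n = 40L)
  fs0$warped[1:18] <- TRUE                 # every repetition keeps unwarped data
  split <- suppressWarnings(make_folds(split_by_repetition(fs0), k = 4L))
  for (f in split$folds)
    expect_false(any(split$train$warped[f$val_idx]))
})
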