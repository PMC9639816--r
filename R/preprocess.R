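# Preprocessing chain: rest-separated action segmentation, per-channel
# Z-score normalisation, overlapping sliding-window fragmentation, and
# repetition-based train/test/fold splitting.

#' Segment a recording into gestures, with rest as the separator
#'
#' One segment per maximal run of a constant nonzero label on the recording's
#' active label track (chosen at read/construction time).  The repetition
#' index of a segment is the majority value of the repetition track over the
#' run, which is robust to the boundary jitter of posterior (restimulus)
#' labels; if the repetition track is all-zero over a run, a warning is
#' raised and the repetition is assigned by occurrence count of that class.
#'
#' @param rec a [recording()].
#' @return list of `gesture_segment` objects (fields `data`, `label`,
#'   `repetition`, `subject_id`, `source_track`, `start`, `warped`), in
#'   temporal order.
#' @export
segment_actions <- function(rec) {
  stopifnot(inherits(rec, "semg_recording"))
  lab <- active_labels(rec)
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values > 0L)
  seen <- integer(0)                      # per-class occurrence counter
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    k <- keep[i]
    idx <- starts[k]:ends[k]
    cls <- runs$values[k]
    reps <- rec$repetition[idx]
    reps <- reps[reps > 0L]
    if (length(reps) == 0L) {
      n_prev <- sum(seen == cls)
      warnf("segment %d (class %d) has an all-zero repetition track; assigning repetition %d by occurrence count",
            i, cls, n_prev + 1L)
      rep_i <- n_prev + 1L
    } else {
      tab <- tabulate(reps)
      rep_i <- which.max(tab)
    }
    seen <- c(seen, cls)
    out[[i]] <- structure(list(
      data = rec$emg[idx, , drop = FALSE],
      label = cls, repetition = rep_i,
      subject_id = rec$subject_id, source_track = rec$label_track,
      start = starts[k], warped = FALSE
    ), class = "gesture_segment")
  }
  out
}

#' @export
print.gesture_segment <- function(x, ...) {
  cat(sprintf("<gesture_segment> class %d rep %d: %d x %d%s\n", x$label,
              x$repetition, nrow(x$data), ncol(x$data),
              if (isTRUE(x$warped)) " (time-warped)" else ""))
  invisible(x)
}

#' Fit per-channel Z-score statistics
#'
#' Computes the mean and population standard deviation of each electrode
#' channel over the supplied data (a matrix, or a list of gesture segments
#' whose rows are concatenated).  The intended fit scope is the concatenated
#' training-repetition data of one subject, so that test data never leaks
#' into the normaliser.
#'
#' @param x numeric matrix (samples x channels) or list of segments.
#' @return a `norm_stats` object with fields `mu` and `sigma`.
#' @export
zscore_fit <- function(x) {
  if (is.list(x) && !is.matrix(x))
    x <- do.call(rbind, lapply(x, function(s) s$data))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stopf("Z-score fit needs at least 2 samples per channel")
  mu <- colMeans(x)
  sigma <- sqrt(colMeans(sweep(x, 2L, mu)^2))    # population SD
  bad <- which(sigma <= 0)
  if (length(bad) > 0L)
    stopf("constant channel(s) %s: standard deviation is zero",
          paste(bad, collapse = ", "))
  structure(list(mu = mu, sigma = sigma), class = "norm_stats")
}

#' Apply Z-score normalisation
#'
#' `y = (x - mu) / sigma`, columnwise per electrode channel.
#'
#' @param x numeric matrix (samples x channels).
#' @param stats a `norm_stats` from [zscore_fit()].
#' @return normalised matrix of the same shape.
#' @export
zscore_apply <- function(x, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mu))
    stopf("data has %d channels but stats were fit on %d",
          ncol(x), length(stats$mu))
  sweep(sweep(x, 2L, stats$mu), 2L, stats$sigma, "/")
}

# apply the normaliser to every segment in a list
zscore_segments <- function(segments, stats) {
  lapply(segments, function(s) { s$data <- zscore_apply(s$data, stats); s })
}

#' Cut one gesture segment into overlapping window fragments
#'
#' Sliding windows of `window_ms` advanced by `step_ms`, fully contained in
#' the segment (no window ever crosses a segment boundary, preserving the
#' independence of gestures).  For a segment of `L` samples with window `W`
#' and step `S` samples the count is `floor((L - W) / S) + 1` when `L >= W`,
#' else zero.
#'
#' @param seg a `gesture_segment`.
#' @param window_ms window length in milliseconds (default 200, i.e. 400
#'   samples at 2000 Hz).
#' @param step_ms step length in milliseconds (default 50).
#' @param fs sampling rate in Hz.
#' @return list of `fragment_emg` objects (fields `data`, `label`,
#'   `repetition`, `subject_id`, `warped`, `segment_start`, `offset`); empty
#'   when the segment is shorter than one window.
#' @export
fragment <- function(seg, window_ms = 200, step_ms = 50, fs = 2000) {
  W <- as.integer(round(window_ms * fs / 1000))
  S <- as.integer(round(step_ms * fs / 1000))
  if (W < 1L || S < 1L) stopf("window and step must be at least one sample")
  L <- nrow(seg$data)
  if (L < W) return(list())
  n <- (L - W) %/% S + 1L
  lapply(seq_len(n) - 1L, function(i) {
    structure(list(
      data = seg$data[(i * S + 1L):(i * S + W), , drop = FALSE],
      label = seg$label, repetition = seg$repetition,
      subject_id = seg$subject_id, warped = isTRUE(seg$warped),
      segment_start = seg$start, offset = i * S
    ), class = "fragment_emg")
  })
}

#' Fragment a list of segments into a fragment set
#'
#' Applies [fragment()] to each segment and binds the windows into one
#' [fragment_set()].  Segments shorter than one window are skipped and
#' counted in the attached report.
#'
#' @inheritParams fragment
#' @param segments list of `gesture_segment` objects.
#' @return a `fragment_set` with attribute `report`: a list with
#'   `n_segments`, `n_fragments`, `n_skipped`.
#' @export
fragment_segments <- function(segments, window_ms = 200, step_ms = 50,
                              fs = 2000) {
  W <- as.integer(round(window_ms * fs / 1000))
  frs <- lapply(segments, fragment, window_ms = window_ms,
                step_ms = step_ms, fs = fs)
  n_skipped <- sum(lengths(frs) == 0L)
  flat <- unlist(frs, recursive = FALSE)
  n <- length(flat)
  if (n == 0L) {
    E <- if (length(segments) > 0L) ncol(segments[[1L]]$data) else 0L
    fs_out <- fragment_set(array(0, c(0L, W, E)), integer(0), integer(0))
  } else {
    E <- ncol(flat[[1L]]$data)
    emg <- array(0, c(n, W, E))
    for (i in seq_len(n)) emg[i, , ] <- flat[[i]]$data
    fs_out <- fragment_set(
      emg,
      vapply(flat, `[[`, integer(1), "label"),
      vapply(flat, `[[`, integer(1), "repetition"),
      vapply(flat, function(f) as.integer(f$subject_id), integer(1)),
      vapply(flat, `[[`, logical(1), "warped"))
  }
  attr(fs_out, "report") <- list(n_segments = length(segments),
                                 n_fragments = n, n_skipped = n_skipped)
  fs_out
}

#' Split fragments by repetition index
#'
#' The intrasubject protocol: repetitions 1, 3, 4 and 6 train, repetitions
#' 2 and 5 test.  Train and test always come from disjoint repetition
#' indices.
#'
#' @param fragments a [fragment_set()].
#' @param train_reps,test_reps disjoint integer repetition sets.
#' @return a `split_set` with fields `train`, `test`, `train_reps`,
#'   `test_reps` and (after [make_folds()]) `folds`.
#' @export
split_by_repetition <- function(fragments, train_reps = c(1L, 3L, 4L, 6L),
                                test_reps = c(2L, 5L)) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (length(intersect(train_reps, test_reps)) > 0L)
    stopf("train and test repetition sets must be disjoint")
  structure(list(
    train = fragments[fragments$repetition %in% train_reps],
    test = fragments[fragments$repetition %in% test_reps],
    train_reps = as.integer(train_reps), test_reps = as.integer(test_reps),
    folds = NULL
  ), class = "split_set")
}

#' Build repeated-gesture cross-validation folds
#'
#' Fold i holds out the i-th training repetition as validation and trains on
#' the remaining training repetitions; the test set stays fixed at the test
#' repetitions.  Time-warped (augmented) fragments never enter a validation
#' subset: they join the training side of every fold.
#'
#' @param split a `split_set` from [split_by_repetition()].
#' @param k number of folds; must not exceed the number of training
#'   repetitions (default 4, one per training repetition).
#' @return the `split_set` with `folds`: a list of `(train_idx, val_idx)`
#'   index pairs into `split$train`.
#' @export
make_folds <- function(split, k = 4L) {
  stopifnot(inherits(split, "split_set"))
  if (k > length(split$train_reps))
    stopf("cannot make %d folds from %d training repetitions",
          k, length(split$train_reps))
  reps <- split$train$repetition
  warped <- split$train$warped
  lab <- split$train$label
  folds <- lapply(split$train_reps[seq_len(k)], function(vr) {
    val <- which(reps == vr & !warped)
    train <- which(reps != vr)
    miss <- setdiff(unique(lab), unique(lab[val]))
    if (length(miss) > 0L)
      warnf("fold with validation repetition %d is missing class(es) %s",
            vr, paste(miss, collapse = ", "))
    list(train_idx = train, val_idx = val, val_rep = vr)
  })
  split$folds <- folds
  split
}

#' Preprocess a recording end to end
#'
#' The full chain: band-pass denoise, segment on the active label track,
#' split segments by repetition, fit the Z-score normaliser on the
#' concatenated training-repetition data, normalise all segments, optionally
#' time-warp-augment the training segments (doubling them), fragment, and
#' assemble train/test fragment sets.
#'
#' @param rec a [recording()].
#' @param window_ms,step_ms sliding-window parameters (200 / 50 ms).
#' @param train_reps,test_reps repetition split (defaults 1,3,4,6 / 2,5).
#' @param low,high,order band-pass parameters; the default band is
#'   10-500 Hz, with the upper edge capped below Nyquist for scaled-down
#'   sampling rates.
#' @param augment `NULL`, or a [warp_config()] to double the training
#'   segments with time-warped copies before fragmentation.
#' @return list with `train` and `test` [fragment_set()]s, the fitted
#'   `stats`, and a `report` of segment/fragment counts.
#' @export
preprocess_recording <- function(rec, window_ms = 200, step_ms = 50,
                                 train_reps = c(1L, 3L, 4L, 6L),
                                 test_reps = c(2L, 5L),
                                 low = 10, high = NULL, order = 4L,
                                 augment = NULL) {
  stopifnot(inherits(rec, "semg_recording"))
  if (is.null(high)) high <- min(500, 0.45 * rec$fs)
  rec$emg <- bandpass_filter(rec$emg, rec$fs, low, high, order)
  segs <- segment_actions(rec)
  is_train <- vapply(segs, function(s) s$repetition %in% train_reps, logical(1))
  is_test <- vapply(segs, function(s) s$repetition %in% test_reps, logical(1))
  stats <- zscore_fit(segs[is_train])
  segs <- zscore_segments(segs, stats)
  train_segs <- segs[is_train]
  if (!is.null(augment))
    train_segs <- augment_training_set(train_segs, augment)
  train <- fragment_segments(train_segs, window_ms, step_ms, rec$fs)
  test <- fragment_segments(segs[is_test], window_ms, step_ms, rec$fs)
  list(train = train, test = test, stats = stats,
       report = list(n_segments = length(segs),
                     n_train_segments = length(train_segs),
                     n_train_fragments = length(train),
                     n_test_fragments = length(test),
                     n_skipped = attr(train, "report")$n_skipped +
                       attr(test, "report")$n_skipped))
}
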