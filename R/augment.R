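# Time-warping augmentation.
#
# A single monotone piecewise-linear time map, with fixed endpoints, is
# applied identically to all electrode channels by linear interpolation, so
# inter-channel synchronisation and amplitude are preserved while the local
# timeline speeds up and slows down.  The warp is controlled by the number of
# speed changes and the maximum/minimum speed ratio.

#' Time-warp configuration
#'
#' @param n_speed_changes number of interior speed-change knots; the warp has
#'   `n_speed_changes + 1` constant-speed bins (default 4).
#' @param max_speed_ratio bound on (fastest bin speed)/(slowest bin speed);
#'   1 gives the identity warp (default 2).
#' @param seed RNG seed for reproducible augmentation, or `NULL`.
#' @return a `warp_config` list.
#' @export
warp_config <- function(n_speed_changes = 4L, max_speed_ratio = 2,
                        seed = NULL) {
  if (!is_count(n_speed_changes)) stopf("n_speed_changes must be >= 1")
  if (max_speed_ratio < 1) stopf("max_speed_ratio must be >= 1")
  structure(list(n_speed_changes = as.integer(n_speed_changes),
                 max_speed_ratio = max_speed_ratio, seed = seed),
            class = "warp_config")
}

# Build the warp map m over output positions 0..L-1: split the axis into
# equal bins, draw one speed per bin uniformly from [1, max_speed_ratio]
# (the fastest bin randomised by the shuffle), integrate, and renormalise to
# fixed endpoints m(0) = 0, m(L-1) = L-1.  Strictly increasing by
# construction since all speeds are positive.  Consumes RNG state.
.warp_map <- function(L, cfg) {
  n_bins <- cfg$n_speed_changes + 1L
  speeds <- sample(stats::runif(n_bins, 1, cfg$max_speed_ratio))
  bin <- pmin(n_bins, 1L + ((seq_len(L - 1L) - 1L) * n_bins) %/% (L - 1L))
  m <- c(0, cumsum(speeds[bin]))
  m <- m * (L - 1) / m[L]
  stopifnot(all(diff(m) > 0))
  m
}

#' Time-warp one gesture segment
#'
#' @param seg a `gesture_segment` (or any list with an `L x E` matrix in
#'   `$data`) with `L >= 2`.
#' @param cfg a [warp_config()].
#' @return the segment with warped `data` (same length) and `warped = TRUE`.
#' @export
time_warp <- function(seg, cfg = warp_config()) {
  stopifnot(inherits(cfg, "warp_config"))
  L <- nrow(seg$data)
  if (L < 2L) stopf("cannot time-warp a segment with fewer than 2 samples")
  with_seed(cfg$seed, {
    m <- .warp_map(L, cfg)
    t0 <- seq_len(L) - 1
    out <- seg$data
    for (j in seq_len(ncol(out)))
      out[, j] <- stats::approx(t0, seg$data[, j], xout = m)$y
    seg$data <- out
    seg$warped <- TRUE
    seg
  })
}

#' Double a training segment list with time-warped copies
#'
#' Returns the original segments followed by one warped copy of each, with
#' the copies flagged `warped = TRUE`.  Augmentation happens at segment
#' level, before fragmentation, so windows cut from a warped segment differ
#' from the originals.  A `warp_config` with `max_speed_ratio = 1` gives an
#' identity augmentation (copies equal originals to interpolation tolerance).
#'
#' @param segments non-empty list of `gesture_segment` objects.
#' @param cfg a [warp_config()]; its `seed` (if any) seeds the whole sweep,
#'   with per-segment warps drawn sequentially.
#' @return list of `2 * length(segments)` segments.
#' @export
augment_training_set <- function(segments, cfg = warp_config()) {
  if (length(segments) == 0L) stopf("no training segments to augment")
  per_seg <- cfg; per_seg$seed <- NULL     # one stream for the whole sweep
  warped <- with_seed(cfg$seed, lapply(segments, time_warp, cfg = per_seg))
  c(segments, warped)
}
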