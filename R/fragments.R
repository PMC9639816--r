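# Fragment containers: a fragment is one fixed-length analysis window
# (default 400 samples x 12 electrodes), the network's input unit.

#' Construct a fragment set
#'
#' The columnar container for window-level data: an `N x T x E` array plus
#' parallel label, repetition, subject and augmentation-flag vectors.  This is
#' the unit the training/evaluation harness consumes.
#'
#' @param emg numeric array `N x T x E` (fragments x samples x electrodes).
#' @param label integer gesture class per fragment (>= 1; rest is never a
#'   fragment).
#' @param repetition integer repetition index per fragment.
#' @param subject subject identifier per fragment (recycled if scalar).
#' @param warped logical: was the fragment cut from a time-warped
#'   (augmented) segment?  Recycled if scalar.
#' @return an object of class `fragment_set`.
#' @export
fragment_set <- function(emg, label, repetition,
                         subject = 1L, warped = FALSE) {
  if (length(dim(emg)) != 3L)
    stopf("fragment emg must be an N x T x E array")
  n <- dim(emg)[1L]
  label <- as.integer(label); repetition <- as.integer(repetition)
  subject <- rep_len(as.integer(subject), n)
  warped <- rep_len(as.logical(warped), n)
  if (length(label) != n || length(repetition) != n)
    stopf("label/repetition length must equal the number of fragments (%d)", n)
  if (n > 0L && any(label < 1L))
    stopf("fragment labels must be >= 1 (rest is never fragmented)")
  structure(list(emg = emg, label = label, repetition = repetition,
                 subject = subject, warped = warped),
            class = "fragment_set")
}

#' @export
length.fragment_set <- function(x) dim(x$emg)[1L]

#' @export
`[.fragment_set` <- function(x, i) {
  fragment_set(x$emg[i, , , drop = FALSE], x$label[i], x$repetition[i],
               x$subject[i], x$warped[i])
}

#' @export
print.fragment_set <- function(x, ...) {
  d <- dim(x$emg)
  cat(sprintf("<fragment_set> %d fragments of %d x %d, %d classes, reps {%s}%s\n",
              d[1L], d[2L], d[3L], length(unique(x$label)),
              paste(sort(unique(x$repetition)), collapse = ","),
              if (any(x$warped)) sprintf(", %d warped", sum(x$warped)) else ""))
  invisible(x)
}

#' Combine fragment sets
#' @param ... `fragment_set` objects with identical window geometry.
#' @return a single `fragment_set`.
#' @export
bind_fragment_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1L]]) && !inherits(sets[[1L]], "fragment_set"))
    sets <- sets[[1L]]
  stopifnot(all(vapply(sets, inherits, logical(1), "fragment_set")))
  dims <- unique(lapply(sets, function(s) dim(s$emg)[2:3]))
  if (length(dims) != 1L) stopf("fragment sets have mismatched window geometry")
  ns <- vapply(sets, length, integer(1))
  emg <- array(0, c(sum(ns), dims[[1L]]))
  at <- 0L
  for (s in sets) {
    if (length(s) > 0L) emg[at + seq_len(length(s)), , ] <- s$emg
    at <- at + length(s)
  }
  fragment_set(emg,
               unlist(lapply(sets, `[[`, "label")),
               unlist(lapply(sets, `[[`, "repetition")),
               unlist(lapply(sets, `[[`, "subject")),
               unlist(lapply(sets, `[[`, "warped")))
}

#' Serialize / deserialize a fragment dataset
#'
#' The container is a single RDS file holding the `N x T x E` array and the
#' label/repetition/subject/warped vectors; R serialisation round-trips
#' doubles bit-exactly.  Labels are normalised to one integer type on write.
#'
#' @param fragments a [fragment_set()]; must be non-empty.
#' @param path file path.
#' @return `path` (write) / a `fragment_set` (read).
#' @export
write_fragment_dataset <- function(fragments, path) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (length(fragments) == 0L)
    stopf("refusing to write an empty fragment set")
  saveRDS(fragments, path, version = 2)
  invisible(path)
}

#' @rdname write_fragment_dataset
#' @export
read_fragment_dataset <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  x <- readRDS(path)
  if (!inherits(x, "fragment_set"))
    stopf("%s is not a fragment dataset container", path)
  x
}
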