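# The Recording container: continuous multichannel sEMG plus the NinaPro
# label tracks (stimulus, restimulus, repetition) at a fixed sampling rate.

#' Construct an sEMG recording
#'
#' A recording holds the continuous `T x E` EMG matrix together with the three
#' per-sample NinaPro label tracks: `stimulus` (prompted gesture label,
#' 0 = rest), `restimulus` (posterior, movement-refined re-labelling, same
#' coding) and `repetition` (1..6 during a movement, 0 at rest).  Amplitudes
#' are kept in whatever unit the source stores (DB2 is microvolt-scale, DB4
#' volt-scale); Z-score normalisation later removes the scale, so no unit
#' conversion is ever applied.  Electrode i of the acquisition protocol is
#' column i of `emg` (columns 1-8 forearm ring, 9-10 flexor/extensor
#' digitorum, 11-12 biceps/triceps in the 12-electrode layout).
#'
#' @param emg numeric matrix, samples by electrodes.
#' @param fs sampling rate in Hz.
#' @param stimulus,restimulus,repetition integer label tracks, one value per
#'   sample row of `emg`.
#' @param subject_id,exercise_id identifiers carried through the pipeline.
#' @param label_track which label track downstream segmentation should use,
#'   `"stimulus"` (default) or `"restimulus"`.
#' @return an object of class `semg_recording`.
#' @export
recording <- function(emg, fs, stimulus, restimulus = stimulus,
                      repetition, subject_id = 1L, exercise_id = 1L,
                      label_track = c("stimulus", "restimulus")) {
  label_track <- match.arg(label_track)
  emg <- as.matrix(emg)
  n <- nrow(emg)
  if (ncol(emg) < 1L) stopf("recording needs at least one electrode column")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stopf("fs must be a positive sampling rate in Hz")
  for (nm in c("stimulus", "restimulus", "repetition")) {
    v <- get(nm)
    if (length(v) != n)
      stopf("label track '%s' has %d samples but emg has %d rows",
            nm, length(v), n)
    if (any(!is.finite(v)) || any(v < 0) || any(v != round(v)))
      stopf("label track '%s' must contain non-negative integers", nm)
  }
  structure(list(
    emg = emg, fs = fs,
    stimulus = as.integer(stimulus),
    restimulus = as.integer(restimulus),
    repetition = as.integer(repetition),
    subject_id = subject_id, exercise_id = exercise_id,
    label_track = label_track
  ), class = "semg_recording")
}

#' @export
print.semg_recording <- function(x, ...) {
  cat(sprintf(
    "<semg_recording> subject %s, exercise %s: %d samples x %d electrodes @ %g Hz\n",
    x$subject_id, x$exercise_id, nrow(x$emg), ncol(x$emg), x$fs))
  runs <- rle(x[[x$label_track]])
  cat(sprintf("  label track '%s': %d movement runs, %d gesture classes\n",
              x$label_track, sum(runs$values > 0L),
              length(setdiff(unique(runs$values), 0L))))
  invisible(x)
}

# the per-sample gesture label track chosen at read time
active_labels <- function(rec) rec[[rec$label_track]]

#' Read a NinaPro-layout .mat recording
#'
#' Expects the public NinaPro DB2/DB4 variable layout: `emg` (samples x
#' electrodes) plus the `stimulus`, `restimulus` and `repetition` label
#' vectors; `subject` and `exercise` scalars are picked up when present.  The
#' chosen `label_track` is stored on the returned recording so that all
#' downstream segmentation uses it.
#'
#' @param path path to the `.mat` file.
#' @param label_track `"stimulus"` (prompted labels) or `"restimulus"`
#'   (posterior movement-refined labels).
#' @param fs sampling rate to record; the NinaPro DB2/DB4 protocol value
#'   (2000 Hz) by default (the .mat files do not store it).
#' @return a [recording()] object.
#' @export
read_recording <- function(path, label_track = c("stimulus", "restimulus"),
                           fs = 2000) {
  label_track <- match.arg(label_track)
  vars <- read_mat(path)
  for (key in c("emg", "stimulus", "restimulus", "repetition"))
    if (is.null(vars[[key]]))
      stopf("MAT file %s lacks required array '%s'", path, key)
  emg <- vars$emg
  if (is.null(dim(emg))) dim(emg) <- c(length(emg), 1L)
  n <- nrow(emg)
  for (key in c("stimulus", "restimulus", "repetition"))
    if (length(vars[[key]]) != n)
      stopf("integrity error in %s: '%s' has %d samples, emg has %d rows",
            path, key, length(vars[[key]]), n)
  recording(
    emg = emg, fs = fs,
    stimulus = vars$stimulus, restimulus = vars$restimulus,
    repetition = vars$repetition,
    subject_id = if (!is.null(vars$subject)) as.integer(vars$subject[1L]) else 1L,
    exercise_id = if (!is.null(vars$exercise)) as.integer(vars$exercise[1L]) else 1L,
    label_track = label_track
  )
}

#' Write a recording in the NinaPro .mat layout
#'
#' Emits the same variable names [read_recording()] expects, so synthetic
#' recordings round-trip through the on-disk format.
#'
#' @param rec a [recording()].
#' @param path output `.mat` path.
#' @return `path`, invisibly.
#' @export
write_recording_mat <- function(rec, path) {
  stopifnot(inherits(rec, "semg_recording"))
  write_mat(list(
    emg = rec$emg,
    stimulus = as.numeric(rec$stimulus),
    restimulus = as.numeric(rec$restimulus),
    repetition = as.numeric(rec$repetition),
    subject = as.numeric(rec$subject_id),
    exercise = as.numeric(rec$exercise_id)
  ), path)
}
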