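# End-to-end demonstration on synthetic data.

#' Run the synthetic end-to-end demo
#'
#' Generates a small synthetic recording under the acquisition protocol,
#' preprocesses it (band-pass, segmentation, Z-score, time-warping
#' augmentation, fragmentation), trains a reduced-width network per
#' cross-validation fold, and reports the fold table.  Sized to complete in
#' minutes on one CPU.
#'
#' @param seed master RNG seed.
#' @param n_classes gesture classes in the synthetic protocol (default 3).
#' @param n_repetitions repetitions per class (default 6, the protocol
#'   value).
#' @param epochs training epochs per fold (default 3 for the demo).
#' @param k number of cross-validation folds (default 4).
#' @param augment logical; double the training segments by time warping.
#' @param verbose print per-epoch progress.
#' @param ... further protocol overrides passed to [protocol_config()]
#'   (e.g. `movement_s`, `rest_s`, `fs`) for scaled-down runs.
#' @return list with the preprocessing `report`, the `cv` result and its
#'   `fold_table` (fold OAs plus average).
#' @export
run_demo <- function(seed = 1L, n_classes = 3L, n_repetitions = 6L,
                     epochs = 3L, k = 4L, augment = TRUE, verbose = FALSE,
                     ...) {
  pcfg <- protocol_config(n_classes = n_classes,
                          n_repetitions = n_repetitions, seed = seed, ...)
  rec <- generate_recording(pcfg)
  prep <- preprocess_recording(
    rec, augment = if (augment) warp_config(seed = seed + 1L) else NULL)
  split <- split_by_repetition(prep$train)
  split$test <- prep$test
  split <- make_folds(split, k = k)
  mcfg <- model_config_reduced(n_classes = n_classes)
  tcfg <- train_config(epochs = epochs, batch_size = 64L, seed = seed,
                       verbose = verbose)
  cv <- cross_validate(split, mcfg, tcfg)
  oas <- vapply(cv$folds, `[[`, numeric(1), "OA")
  fold_table <- c(stats::setNames(oas, paste0("fold", seq_along(oas))),
                  average = cv$average_OA)
  list(report = prep$report, cv = cv, fold_table = fold_table)
}
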