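#' Default training-set size for an epoch length
#'
#' The conventional per-stage training sizes: 100 epochs per stage at 4 s
#' epochs (6.67 min of manual scoring per stage), 50 at 10 s (8.33 min),
#' and 40 at 30 s (20 min). Other epoch lengths have no convention and
#' require an explicit size.
#'
#' @param epoch_length Epoch length in seconds: 4, 10 or 30.
#' @return Integer size per stage.
#' @export
default_training_size <- function(epoch_length) {
  sizes <- c(`4` = 100L, `10` = 50L, `30` = 40L)
  key <- as.character(epoch_length)
  if (!key %in% names(sizes))
    stopf("no default training size for %g s epochs; pass size_per_stage",
          epoch_length)
  unname(sizes[key])
}

#' Sample a per-recording training set
#'
#' Draws `size_per_stage` epochs per vigilance stage uniformly at random
#' without replacement from the eligible (non-ARTIFACT, non-UNDETERMINED)
#' epochs of a manually scored hypnogram. When a stage has fewer eligible
#' epochs than requested, all of them are taken and a warning is issued;
#' a stage with no eligible epoch is an error.
#'
#' @param h Reference [hypnogram()].
#' @param size_per_stage Epochs per stage (>= 1); default from
#'   [default_training_size()] of the grid's epoch length.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param recording_id Identifier recorded in the training set.
#' @return Object of class `training_set`: a data.frame with columns
#'   `recording`, `epoch` (1-based index) and `stage`, plus attributes
#'   `seed` and `vocabulary`.
#' @export
sample_training_set <- function(h, size_per_stage = NULL, seed = 1L,
                                recording_id = "recording") {
  stopifnot(inherits(h, "hypnogram"))
  vocab <- hypnogram_vocab(h)
  size_per_stage <- size_per_stage %||%
    default_training_size(hypnogram_grid(h)$epoch_length)
  if (size_per_stage < 1L) stopf("'size_per_stage' must be >= 1")
  labels <- unclass(h)
  eligible <- !(labels %in% SPECIAL_LABELS)
  picks <- with_seed(seed, {
    lapply(as.character(vocab), function(st) {
      pool <- which(eligible & labels == st)
      if (length(pool) == 0L)
        stopf("stage %s has no eligible epochs to sample from", st)
      k <- min(size_per_stage, length(pool))
      if (k < size_per_stage)
        warnf("stage %s: only %d eligible epochs (requested %d); taking all",
              st, length(pool), size_per_stage)
      sort(pool[sample.int(length(pool), k)])
    })
  })
  df <- data.frame(
    recording = recording_id,
    epoch = unlist(picks),
    stage = rep(as.character(vocab), lengths(picks)),
    stringsAsFactors = FALSE)
  structure(df, seed = seed, vocabulary = vocab,
            class = c("training_set", "data.frame"))
}

#' Build paired training sets from baseline and treatment recordings
#'
#' For study designs where each subject is recorded twice, two training
#' regimes are supported: `LONGITUDINAL` splits `size_per_stage` as evenly
#' as possible across the two recordings (an odd remainder goes to the
#' baseline), and `BASELINE_ONLY` draws every training epoch from the
#' baseline recording alone. Provenance is recorded per epoch in the
#' `recording` column.
#'
#' @param baseline,treatment Reference [hypnogram()]s sharing vocabulary
#'   and epoch length.
#' @param size_per_stage Total epochs per stage across both recordings.
#' @param mode `"LONGITUDINAL"` or `"BASELINE_ONLY"`.
#' @param seed Integer seed.
#' @param ids Length-2 character vector naming the two recordings.
#' @return A `training_set` (see [sample_training_set()]).
#' @export
build_paired_training_sets <- function(baseline, treatment,
                                       size_per_stage = NULL,
                                       mode = c("LONGITUDINAL",
                                                "BASELINE_ONLY"),
                                       seed = 1L,
                                       ids = c("baseline", "treatment")) {
  mode <- match.arg(mode)
  stopifnot(inherits(baseline, "hypnogram"), inherits(treatment, "hypnogram"))
  if (!identical(as.character(hypnogram_vocab(baseline)),
                 as.character(hypnogram_vocab(treatment))))
    stopf("baseline and treatment hypnograms use different vocabularies")
  if (hypnogram_grid(baseline)$epoch_length !=
      hypnogram_grid(treatment)$epoch_length)
    stopf("baseline and treatment hypnograms use different epoch lengths")
  size_per_stage <- size_per_stage %||%
    default_training_size(hypnogram_grid(baseline)$epoch_length)

  if (mode == "BASELINE_ONLY") {
    ts <- sample_training_set(baseline, size_per_stage, seed,
                              recording_id = ids[1L])
    return(ts)
  }
  n_base <- ceiling(size_per_stage / 2)   # odd remainder to baseline
  n_treat <- size_per_stage - n_base
  a <- sample_training_set(baseline, n_base, seed, recording_id = ids[1L])
  parts <- list(a)
  if (n_treat >= 1L) {
    b <- sample_training_set(treatment, n_treat, derive_seed(seed, 2L),
                             recording_id = ids[2L])
    parts <- c(parts, list(b))
  }
  df <- do.call(rbind, lapply(parts, as.data.frame))
  df <- df[order(df$stage, df$recording, df$epoch), ]
  rownames(df) <- NULL
  structure(df, seed = seed, vocabulary = hypnogram_vocab(baseline),
            class = c("training_set", "data.frame"))
}
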