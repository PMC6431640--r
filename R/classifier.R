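#' Fit a per-recording stage classifier
#'
#' Trains a seeded random-forest ensemble (class-balanced via per-class
#' weights) on the feature rows of the training epochs. The model retains
#' the expected feature names and rejects prediction inputs whose columns
#' differ. This is a conventional ensemble-of-trees scorer chosen for its
#' robustness on small, mixed-scale training sets and for exposing
#' per-class scores; it makes no claim to reproduce any proprietary
#' classifier's internals.
#'
#' @param features A `feature_matrix` from [extract_features()].
#' @param training A `training_set`; its epochs index rows of `features`.
#' @param seed Integer seed making the fit deterministic.
#' @param ntree Number of trees.
#' @return Object of class `stage_model`.
#' @export
fit_stage_model <- function(features, training, seed = 1L, ntree = 300L) {
  stopifnot(inherits(features, "feature_matrix"),
            inherits(training, "training_set"))
  vocab <- attr(training, "vocabulary")
  if (any(training$epoch < 1L | training$epoch > nrow(features)))
    stopf("training epoch index outside the feature matrix (1..%d)",
          nrow(features))
  y <- factor(training$stage, levels = as.character(vocab))
  present <- levels(y)[tabulate(y, nbins = nlevels(y)) > 0L]
  if (length(present) < 2L)
    stopf("training set spans a single stage (%s); need >= 2",
          paste(present, collapse = ","))
  x <- features[training$epoch, , drop = FALSE]
  if (!all(is.finite(x))) stopf("non-finite training features")
  yd <- droplevels(y)
  cw <- as.numeric(length(yd) / (nlevels(yd) * table(yd)))
  fit <- with_seed(seed,
    randomForest::randomForest(
      x = as.data.frame(x), y = yd, ntree = ntree,
      classwt = cw, importance = FALSE))
  structure(
    list(forest = fit, feature_names = colnames(features),
         vocabulary = vocab, stages_fit = levels(yd), seed = seed),
    class = "stage_model")
}

#' @export
print.stage_model <- function(x, ...) {
  cat(sprintf("<stage_model> %d features, stages: %s (seed %d)\n",
              length(x$feature_names),
              paste(x$stages_fit, collapse = ", "), x$seed))
  invisible(x)
}

#' Predict a stage for every epoch
#'
#' Scores every feature row with the fitted ensemble and assigns the
#' highest-scoring stage; ties are broken toward the earlier vocabulary
#' label. Per-epoch class scores (normalized to sum to 1) are attached to
#' the result as the `"scores"` attribute for use by
#' [apply_consistency_rules()].
#'
#' @param model A `stage_model`.
#' @param features A `feature_matrix` with the same column names, in the
#'   same order, as the one the model was fitted on.
#' @param rules Optional [consistency_rules()] applied to the raw
#'   prediction before returning.
#' @return A [hypnogram()] of `nrow(features)` epochs with a `"scores"`
#'   attribute (matrix `n_epochs x n_stages`).
#' @export
predict_stages <- function(model, features, rules = NULL) {
  stopifnot(inherits(model, "stage_model"),
            inherits(features, "feature_matrix"))
  if (!identical(colnames(features), model$feature_names))
    stopf("feature names/order differ from those used at training")
  prob <- stats::predict(model$forest, newdata = as.data.frame(features),
                         type = "prob")
  vocab <- model$vocabulary
  scores <- matrix(0, nrow(prob), length(vocab),
                   dimnames = list(NULL, as.character(vocab)))
  scores[, colnames(prob)] <- prob
  rs <- rowSums(scores)
  scores <- scores / ifelse(rs > 0, rs, 1)
  pick <- max.col(scores, ties.method = "first")  # earlier label wins ties
  h <- hypnogram(as.character(vocab)[pick], vocab,
                 grid = attr(features, "grid"))
  attr(h, "scores") <- scores
  if (!is.null(rules)) h <- apply_consistency_rules(h, rules)
  h
}

#' Minimum bout-duration consistency rules
#'
#' Converts per-stage minimum bout durations in seconds to whole epochs by
#' ceiling division (e.g. an 8 s minimum at 4 s epochs is 2 epochs; a 12 s
#' minimum at 4 s epochs is 3 epochs). Stages absent from `min_bout_s`
#' get a 1-epoch minimum (no constraint).
#'
#' @param min_bout_s Named numeric vector of minimum bout durations in
#'   seconds per stage, e.g. `c(W = 4, NREM = 8, REM = 8)`.
#' @param epoch_length Epoch length in seconds.
#' @return Object of class `consistency_rules`: named integer vector of
#'   minimum bout lengths in epochs.
#' @export
consistency_rules <- function(min_bout_s, epoch_length) {
  if (length(min_bout_s) == 0L)
    return(structure(integer(), epoch_length = epoch_length,
                     class = "consistency_rules"))
  if (is.null(names(min_bout_s)) || any(!nzchar(names(min_bout_s))))
    stopf("'min_bout_s' must be a named vector (stage = seconds)")
  ep <- pmax(1L, as.integer(ceiling(min_bout_s / epoch_length - 1e-9)))
  structure(stats::setNames(ep, names(min_bout_s)),
            epoch_length = epoch_length, class = "consistency_rules")
}

#' Enforce minimum bout durations on a predicted hypnogram
#'
#' Iteratively removes bouts shorter than their stage's minimum: at each
#' step the shortest violating bout (earliest on ties) is relabeled to
#' whichever neighboring bout's stage has the higher mean class score over
#' the violating epochs, and adjacent equal-stage bouts are merged. Bouts
#' at the recording edge take their single neighbor. The result contains
#' no sub-minimum bouts and no stage absent from the input. ARTIFACT and
#' UNDETERMINED runs are never relabeled and never absorb a neighbor.
#'
#' @param h A predicted [hypnogram()], normally carrying a `"scores"`
#'   attribute from [predict_stages()].
#' @param rules A [consistency_rules()] object.
#' @param scores Optional `n_epochs x n_stages` score matrix; defaults to
#'   `attr(h, "scores")`. When no scores are available, ties go to the
#'   preceding neighbor.
#' @return The smoothed [hypnogram()] (scores attribute preserved).
#' @export
apply_consistency_rules <- function(h, rules, scores = attr(h, "scores")) {
  stopifnot(inherits(h, "hypnogram"), inherits(rules, "consistency_rules"))
  labels <- as.character(h)
  n <- length(labels)
  minimo <- function(st) {
    if (st %in% SPECIAL_LABELS) return(1L)
    if (st %in% names(rules)) unname(rules[[st]]) else 1L
  }
  mean_score <- function(stage, from, to) {
    if (is.null(scores) || !stage %in% colnames(scores)) return(0)
    mean(scores[from:to, stage])
  }

  r <- rle(labels)
  bouts <- data.frame(stage = r$values, len = r$lengths,
                      stringsAsFactors = FALSE)
  bouts$end <- cumsum(bouts$len)
  bouts$start <- bouts$end - bouts$len + 1L
  bouts$frozen <- FALSE

  repeat {
    req <- vapply(bouts$stage, minimo, 1L)
    viol <- which(bouts$len < req & !bouts$frozen &
                    !(bouts$stage %in% SPECIAL_LABELS))
    if (length(viol) == 0L) break
    i <- viol[order(bouts$len[viol], viol)][1L]

    nbr <- c(if (i > 1L) i - 1L, if (i < nrow(bouts)) i + 1L)
    nbr <- nbr[!(bouts$stage[nbr] %in% SPECIAL_LABELS)]
    if (length(nbr) == 0L) { bouts$frozen[i] <- TRUE; next }
    if (length(nbr) == 2L) {
      s_prev <- mean_score(bouts$stage[nbr[1L]], bouts$start[i], bouts$end[i])
      s_next <- mean_score(bouts$stage[nbr[2L]], bouts$start[i], bouts$end[i])
      nbr <- if (s_next > s_prev) nbr[2L] else nbr[1L]  # tie -> previous
    }
    bouts$stage[i] <- bouts$stage[nbr]

    # merge runs of equal stages around i
    keep <- rep(TRUE, nrow(bouts))
    j <- i
    while (j > 1L && bouts$stage[j - 1L] == bouts$stage[i]) {
      keep[j] <- FALSE
      bouts$len[j - 1L] <- bouts$len[j - 1L] + bouts$len[j]
      bouts$end[j - 1L] <- bouts$end[j]
      bouts$frozen[j - 1L] <- FALSE
      j <- j - 1L
    }
    tail_i <- i
    while (tail_i < nrow(bouts) &&
           bouts$stage[tail_i + 1L] == bouts$stage[j]) {
      keep[tail_i + 1L] <- FALSE
      bouts$len[j] <- bouts$len[j] + bouts$len[tail_i + 1L]
      bouts$end[j] <- bouts$end[tail_i + 1L]
      tail_i <- tail_i + 1L
    }
    bouts <- bouts[keep, , drop = FALSE]
    rownames(bouts) <- NULL
  }

  out <- hypnogram(rep(bouts$stage, bouts$len), hypnogram_vocab(h),
                   grid = hypnogram_grid(h))
  attr(out, "scores") <- scores
  out
}
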