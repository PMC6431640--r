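#' Per-stage confusion counts
#'
#' Counts true positives, false positives and false negatives per stage
#' over the evaluated epochs: those not in `exclusions` and not labeled
#' ARTIFACT/UNDETERMINED in the reference. A prediction equal to the
#' reference is a TP for that stage; otherwise the epoch is an FN for the
#' reference stage and an FP for the predicted stage.
#'
#' @param predicted,reference [hypnogram()]s on the same grid and
#'   vocabulary.
#' @param exclusions Integer vector of 1-based epoch indices to ignore
#'   (e.g. training epochs, transition epochs).
#' @return Object of class `stage_counts`: data.frame with columns
#'   `stage`, `TP`, `FP`, `FN` and attribute `n_evaluated`.
#' @export
confusion_counts <- function(predicted, reference, exclusions = integer()) {
  stopifnot(inherits(predicted, "hypnogram"),
            inherits(reference, "hypnogram"))
  gp <- hypnogram_grid(predicted); gr <- hypnogram_grid(reference)
  if (gp$n_epochs != gr$n_epochs || gp$epoch_length != gr$epoch_length)
    stopf("predicted and reference hypnograms are on different grids")
  vocab <- hypnogram_vocab(reference)
  if (!identical(as.character(hypnogram_vocab(predicted)),
                 as.character(vocab)))
    stopf("predicted and reference hypnograms use different vocabularies")
  if (length(exclusions) &&
      (min(exclusions) < 1L || max(exclusions) > gp$n_epochs))
    stopf("exclusions outside 1..%d", gp$n_epochs)

  use <- rep(TRUE, gp$n_epochs)
  use[exclusions] <- FALSE
  use[unclass(reference) %in% SPECIAL_LABELS] <- FALSE
  p <- unclass(predicted)[use]
  r <- unclass(reference)[use]
  stages <- as.character(vocab)
  tp <- fp <- fn <- stats::setNames(integer(length(stages)), stages)
  hit <- p == r
  for (st in stages) {
    tp[st] <- sum(hit & r == st)
    fp[st] <- sum(!hit & p == st)
    fn[st] <- sum(!hit & r == st)
  }
  structure(data.frame(stage = stages, TP = unname(tp), FP = unname(fp),
                       FN = unname(fn), stringsAsFactors = FALSE),
            n_evaluated = sum(use),
            class = c("stage_counts", "data.frame"))
}

#' Sensitivity, precision and F-measure from confusion counts
#'
#' `sensitivity = TP / (TP + FN)`, `precision = TP / (TP + FP)`, and
#' `F = 2 * sensitivity * precision / (sensitivity + precision)`. Any 0/0
#' ratio is defined as 0, and F is 0 when sensitivity + precision is 0,
#' so absent stages score 0 rather than NaN.
#'
#' @param TP,FP,FN Non-negative counts (vectorized).
#' @return data.frame with columns `sensitivity`, `precision`, `F`.
#' @export
f_measure <- function(TP, FP, FN) {
  if (any(c(TP, FP, FN) < 0)) stopf("counts must be non-negative")
  s <- ifelse(TP + FN > 0, TP / (TP + FN), 0)
  p <- ifelse(TP + FP > 0, TP / (TP + FP), 0)
  f <- ifelse(s + p > 0, 2 * s * p / (s + p), 0)
  data.frame(sensitivity = s, precision = p, F = f)
}

#' Overall F-measure across stages
#'
#' The default aggregation is the micro-average: TP, FP and FN are pooled
#' across stages and the F formula applied to the pooled counts (on
#' single-label-per-epoch data this equals epoch accuracy). The
#' macro-average (unweighted mean of per-stage F) is available for
#' inspection.
#'
#' @param counts A `stage_counts` object.
#' @param average `"micro"` (default) or `"macro"`.
#' @return Overall F-measure (scalar).
#' @export
overall_f <- function(counts, average = c("micro", "macro")) {
  stopifnot(inherits(counts, "stage_counts"))
  average <- match.arg(average)
  if (attr(counts, "n_evaluated") == 0L)
    stopf("no evaluated epochs: overall F undefined")
  if (average == "micro") {
    f_measure(sum(counts$TP), sum(counts$FP), sum(counts$FN))$F
  } else {
    mean(f_measure(counts$TP, counts$FP, counts$FN)$F)
  }
}

#' Rate an F-measure against agreement bands
#'
#' Bands (inclusive at the lower edge): intra-scorer >= 0.9, excellent
#' >= 0.85, strong >= 0.8, average >= 0.7, inadequate < 0.7.
#'
#' @param f F-measure(s) in `[0, 1]`.
#' @return Character vector of rating labels.
#' @export
rate_f <- function(f) {
  if (any(!is.finite(f)) || any(f < 0 | f > 1))
    stopf("F-measure must lie in [0, 1]")
  cut_labels <- c("inadequate", "average", "strong", "excellent",
                  "intra-scorer")
  as.character(cut(f, breaks = c(-Inf, 0.7, 0.8, 0.85, 0.9, Inf),
                   labels = cut_labels, right = FALSE))
}

#' Hedges' g effect size
#'
#' `g = (M1 - M2) / SD_pooled` with
#' `SD_pooled = sqrt(((n1-1) SD1^2 + (n2-1) SD2^2) / (n1 + n2 - 2))`.
#' The magnitude is classified on `|g|`: miniscule < 0.2, small
#' 0.2 <= g < 0.5, medium 0.5 <= g < 0.8, large >= 0.8. The small-sample
#' correction factor is off by default (the plain pooled-SD form is the
#' one reported in the sleep-scoring validation literature).
#'
#' @param m1,sd1,n1 Mean, SD and size of group 1 (n >= 2).
#' @param m2,sd2,n2 Mean, SD and size of group 2 (n >= 2).
#' @param correction Apply the small-sample correction
#'   `J = 1 - 3 / (4 (n1 + n2) - 9)`.
#' @return List with `g`, `magnitude`, `sd_pooled`, and `degenerate`
#'   (TRUE when the pooled SD is 0 with unequal means, in which case `g`
#'   is `NaN`).
#' @export
hedges_g <- function(m1, sd1, n1, m2, sd2, n2, correction = FALSE) {
  if (n1 < 2 || n2 < 2) stopf("both groups need n >= 2")
  if (sd1 < 0 || sd2 < 0) stopf("SDs must be >= 0")
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  degenerate <- FALSE
  if (sp == 0) {
    if (m1 == m2) g <- 0
    else { g <- NaN; degenerate <- TRUE }
  } else {
    g <- (m1 - m2) / sp
    if (correction) g <- g * (1 - 3 / (4 * (n1 + n2) - 9))
  }
  magnitude <- if (degenerate) NA_character_ else g_magnitude(g)
  list(g = g, magnitude = magnitude, sd_pooled = sp, degenerate = degenerate)
}

g_magnitude <- function(g) {
  a <- abs(g)
  if (a < 0.2) "miniscule" else if (a < 0.5) "small" else
    if (a < 0.8) "medium" else "large"
}

#' Reclassify human sleep stages
#'
#' Label-wise simplification schemes for the human vocabulary:
#' `N1_TO_WAKE` (N1 -> W), `N1_TO_N2` (N1 -> N2), `W1NREM23` (N1 -> W,
#' N2/N3 -> NREM) and `NREM123` (N1/N2/N3 -> NREM). `NONE` is the
#' identity. Special labels pass through. Apply the same scheme to the
#' predicted and the reference hypnogram before evaluating.
#'
#' @param h A [hypnogram()] on the human vocabulary.
#' @param scheme Scheme name.
#' @return The reclassified [hypnogram()] with the updated vocabulary.
#' @export
reclassify <- function(h, scheme = c("NONE", "N1_TO_WAKE", "N1_TO_N2",
                                     "W1NREM23", "NREM123")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(h, "hypnogram"))
  if (scheme == "NONE") return(h)
  vocab <- as.character(hypnogram_vocab(h))
  needed <- c("W", "N1", "N2", "N3", "REM")
  if (!all(needed %in% vocab))
    stopf("scheme %s requires the human vocabulary (W,N1,N2,N3,REM)",
          scheme)
  map <- switch(scheme,
    N1_TO_WAKE = c(N1 = "W"),
    N1_TO_N2 = c(N1 = "N2"),
    W1NREM23 = c(N1 = "W", N2 = "NREM", N3 = "NREM"),
    NREM123 = c(N1 = "NREM", N2 = "NREM", N3 = "NREM"))
  labels <- unclass(h)
  hit <- labels %in% names(map)
  labels[hit] <- map[labels[hit]]
  new_vocab <- unique(ifelse(vocab %in% names(map), map[vocab], vocab))
  out <- hypnogram(labels, stage_vocabulary(new_vocab),
                   grid = hypnogram_grid(h))
  out
}

#' Evaluate agreement between predicted and reference hypnograms
#'
#' The full agreement report: per-stage sensitivity, precision, F-measure
#' and rating, overall (micro) F with rating, the macro-average F, and
#' the excluded-epoch fraction. Exclusions are the union of (i) the
#' transition epochs of the *predicted* (automated) hypnogram when
#' `exclude_transitions` is on — the corresponding reference epochs are
#' simply not analyzed — (ii) any `exclude_epochs` (typically training
#' epochs), and (iii) reference ARTIFACT/UNDETERMINED epochs. When a
#' reclassification `scheme` is given it is applied identically to both
#' hypnograms first.
#'
#' @param predicted,reference Aligned [hypnogram()]s.
#' @param exclude_transitions Exclude predicted-hypnogram transition
#'   epochs (first/last epoch of each bout).
#' @param exclude_epochs Integer epoch indices to exclude (e.g. the
#'   training set's epochs).
#' @param scheme Reclassification scheme (see [reclassify()]).
#' @param transitions_from `"predicted"` (default, the standard protocol)
#'   or `"reference"`.
#' @param provenance Optional named list recorded verbatim in the report
#'   (channel preset, training size/seed, ...).
#' @return Object of class `agreement_report`.
#' @export
evaluate_agreement <- function(predicted, reference,
                               exclude_transitions = FALSE,
                               exclude_epochs = integer(),
                               scheme = "NONE",
                               transitions_from = c("predicted",
                                                    "reference"),
                               provenance = list()) {
  transitions_from <- match.arg(transitions_from)
  if (scheme != "NONE") {
    predicted <- reclassify(predicted, scheme)
    reference <- reclassify(reference, scheme)
  }
  n <- hypnogram_grid(reference)$n_epochs
  excl <- as.integer(exclude_epochs)
  if (exclude_transitions) {
    src <- if (transitions_from == "predicted") predicted else reference
    excl <- union(excl, which(tag_transition_epochs(src)))
  }
  counts <- confusion_counts(predicted, reference, excl)
  per_stage <- cbind(counts,
                     f_measure(counts$TP, counts$FP, counts$FN))
  per_stage$rating <- rate_f(per_stage$F)
  f_micro <- overall_f(counts, "micro")
  f_macro <- overall_f(counts, "macro")
  excluded <- union(excl, which(unclass(reference) %in% SPECIAL_LABELS))
  structure(
    list(per_stage = per_stage,
         overall_f = f_micro,
         overall_rating = rate_f(f_micro),
         macro_f = f_macro,
         excluded_fraction = length(excluded) / n,
         n_evaluated = attr(counts, "n_evaluated"),
         options = c(list(exclude_transitions = exclude_transitions,
                          scheme = scheme,
                          transitions_from = transitions_from),
                     provenance)),
    class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> overall F = %.3f (%s), macro F = %.3f\n",
              x$overall_f, x$overall_rating, x$macro_f))
  cat(sprintf("  evaluated %d epochs; excluded fraction %.1f%%\n",
              x$n_evaluated, 100 * x$excluded_fraction))
  df <- x$per_stage
  df[c("sensitivity", "precision", "F")] <-
    lapply(df[c("sensitivity", "precision", "F")], round, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Flatten an agreement report to a data.frame
#'
#' One row per stage plus an `overall` row; suitable for CSV export.
#'
#' @param x An `agreement_report`.
#' @param ... Unused.
#' @return data.frame.
#' @export
as.data.frame.agreement_report <- function(x, ...) {
  ps <- x$per_stage
  overall <- data.frame(stage = "overall", TP = sum(ps$TP),
                        FP = sum(ps$FP), FN = sum(ps$FN),
                        sensitivity = NA, precision = NA,
                        F = x$overall_f, rating = x$overall_rating,
                        stringsAsFactors = FALSE)
  out <- rbind(ps, overall)
  out$excluded_fraction <- x$excluded_fraction
  out
}

#' Training-set-size response curve
#'
#' For each training size and replicate: draw a fresh seeded training
#' sample, fit the classifier, predict the whole recording, and evaluate
#' against the reference (training epochs excluded). Results are
#' aggregated as mean and SEM of the per-stage and overall F-measures.
#'
#' @param features A `feature_matrix` of the recording (or a
#'   `psg_recording`, in which case features are extracted with `config`).
#' @param reference Reference [hypnogram()].
#' @param sizes Integer vector of training sizes per stage.
#' @param replicates Replicates per size.
#' @param seed Base seed; each size x replicate uses a derived sub-seed.
#' @param rules Optional [consistency_rules()] applied to predictions.
#' @param config Channel configuration when `features` is a recording.
#' @param ntree Trees per forest.
#' @return data.frame with columns `size`, `replicate`, `stage`
#'   (including `"overall"`), `F` — plus the aggregated `curve` attribute:
#'   data.frame `size`, `stage`, `mean_f`, `sem_f`, `n`.
#' @export
training_size_curve <- function(features, reference, sizes,
                                replicates = 3L, seed = 1L, rules = NULL,
                                config = channel_config("ALL"),
                                ntree = 300L) {
  if (inherits(features, "psg_recording"))
    features <- extract_features(features, hypnogram_grid(reference),
                                 config)
  stopifnot(length(sizes) >= 1L, replicates >= 1L)
  rows <- list()
  k <- 0L
  for (s in sizes) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      sub_seed <- derive_seed(seed, k)
      ts <- sample_training_set(reference, s, sub_seed)
      model <- fit_stage_model(features, ts, seed = sub_seed,
                               ntree = ntree)
      pred <- predict_stages(model, features, rules = rules)
      rep_ <- evaluate_agreement(pred, reference,
                                 exclude_epochs = ts$epoch)
      rows[[k]] <- data.frame(
        size = s, replicate = r,
        stage = c(rep_$per_stage$stage, "overall"),
        F = c(rep_$per_stage$F, rep_$overall_f),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  agg <- stats::aggregate(F ~ size + stage, out, function(v)
    c(mean = mean(v), sem = stats::sd(v) / sqrt(length(v)), n = length(v)))
  curve <- data.frame(size = agg$size, stage = agg$stage,
                      mean_f = agg$F[, "mean"], sem_f = agg$F[, "sem"],
                      n = agg$F[, "n"])
  curve$sem_f[is.na(curve$sem_f)] <- 0
  curve <- curve[order(curve$stage, curve$size), ]
  rownames(curve) <- NULL
  attr(out, "curve") <- curve
  out
}

#' Single-channel ablation
#'
#' Re-scores the same recording under several channel configurations,
#' holding the training epoch indices fixed so that only the features
#' differ between configurations.
#'
#' @param rec A [recording()].
#' @param reference Reference [hypnogram()].
#' @param presets List of [channel_config()]s or preset names; names of
#'   the list name the reports.
#' @param size_per_stage Training size per stage; default from the epoch
#'   length.
#' @param seed Seed for the (shared) training draw and the fits.
#' @param rules Optional [consistency_rules()].
#' @param exclude_transitions Passed to [evaluate_agreement()].
#' @param ntree Trees per forest.
#' @return Named list of `agreement_report`s, one per preset.
#' @export
channel_ablation <- function(rec, reference, presets,
                             size_per_stage = NULL, seed = 1L,
                             rules = NULL, exclude_transitions = FALSE,
                             ntree = 300L) {
  stopifnot(inherits(rec, "psg_recording"))
  grid <- hypnogram_grid(reference)
  ts <- sample_training_set(reference, size_per_stage, seed,
                            recording_id = rec$id)
  if (is.null(names(presets)))
    names(presets) <- vapply(presets, function(p)
      if (is.character(p)) p else p$preset, "")
  out <- vector("list", length(presets))
  names(out) <- names(presets)
  for (i in seq_along(presets)) {
    feats <- extract_features(rec, grid, presets[[i]])
    model <- fit_stage_model(feats, ts, seed = seed, ntree = ntree)
    pred <- predict_stages(model, feats, rules = rules)
    out[[i]] <- evaluate_agreement(
      pred, reference, exclude_transitions = exclude_transitions,
      exclude_epochs = ts$epoch,
      provenance = list(preset = names(presets)[i],
                        training_size = attr(ts, "size"),
                        seed = seed))
  }
  out
}

#' Compare two groups of agreement scores
#'
#' Two-sided Student's t-test (paired or independent) plus Hedges' g.
#' The significance threshold is `0.05 / bonferroni_m`, mirroring the
#' selective Bonferroni use in validation protocols (two planned paired
#' tests give a threshold of 0.025).
#'
#' @param a,b Numeric score vectors; equal lengths when `paired`.
#' @param paired Paired or independent design.
#' @param bonferroni_m Number of planned comparisons the alpha is split
#'   over (1 = no correction).
#' @return List with `t`, `df`, `p`, `alpha`, `significant`, `g`,
#'   `magnitude`, `degenerate`.
#' @export
compare_groups <- function(a, b, paired = FALSE, bonferroni_m = 1L) {
  if (length(a) < 2L || length(b) < 2L) stopf("both groups need n >= 2")
  if (paired && length(a) != length(b))
    stopf("paired comparison requires equal group lengths")
  degenerate <- paired && stats::sd(a - b) == 0
  if (degenerate) {
    tt <- list(statistic = NaN, parameter = length(a) - 1L, p.value = NA)
  } else {
    tt <- stats::t.test(a, b, paired = paired, var.equal = !paired)
  }
  g <- hedges_g(mean(a), stats::sd(a), length(a),
                mean(b), stats::sd(b), length(b))
  alpha <- 0.05 / bonferroni_m
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alpha = alpha,
       significant = !degenerate && tt$p.value < alpha,
       g = g$g, magnitude = g$magnitude, degenerate = degenerate)
}
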