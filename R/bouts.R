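#' Segment a hypnogram into bouts
#'
#' A bout is a maximal run of consecutive epochs sharing one label. Runs
#' of ARTIFACT/UNDETERMINED form segments of their own, so an artifact
#' interrupting a stage splits it into two bouts. The segments tile the
#' whole grid exactly.
#'
#' @param h A [hypnogram()].
#' @return data.frame with columns `stage`, `start`, `end` (1-based,
#'   inclusive) and `length` (epochs), in temporal order.
#' @export
segment_bouts <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  r <- rle(as.character(h))
  end <- cumsum(r$lengths)
  data.frame(stage = r$values,
             start = end - r$lengths + 1L,
             end = end,
             length = r$lengths,
             stringsAsFactors = FALSE)
}

#' Tag transition epochs
#'
#' Transition epochs are the first and the last epoch of each bout (a
#' length-1 bout is tagged once). Bouts at the recording edges are treated
#' like any other, so the tagged count equals the sum over bouts of
#' `min(2, bout length)`.
#'
#' @param h A [hypnogram()].
#' @return Logical vector, one flag per epoch, with attribute `source`
#'   recording which hypnogram it came from.
#' @export
tag_transition_epochs <- function(h) {
  b <- segment_bouts(h)
  mask <- rep(FALSE, hypnogram_grid(h)$n_epochs)
  mask[b$start] <- TRUE
  mask[b$end] <- TRUE
  attr(mask, "source") <- "hypnogram"
  mask
}
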