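#' Special hypnogram labels
#'
#' Epochs carrying one of these labels are never counted as vigilance
#' stages: they are excluded from training-set sampling and from agreement
#' evaluation, although the classifier still emits a prediction for them.
#'
#' @format Character vector of length 2: `ARTIFACT`, `UNDETERMINED`.
#' @export
SPECIAL_LABELS <- c("ARTIFACT", "UNDETERMINED")

#' Construct a signal channel
#'
#' A single physiological time series (EEG, EMG, EOG, ECG, accelerometer or
#' temperature) sampled at a fixed rate. The modality drives which features
#' are extracted from the channel; when not given it is inferred from the
#' label prefix (`"EMG1"` is EMG, `"EEG Cz"` is EEG, anything unrecognized
#' is `OTHER`).
#'
#' @param label Channel label (character scalar).
#' @param samples Numeric vector of samples; must be finite.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param modality One of `"EEG"`, `"EMG"`, `"EOG"`, `"ECG"`, `"ACC"`,
#'   `"TEMP"`, `"OTHER"`, or `NULL` to infer from the label.
#' @param passband Optional numeric length-2 vector `(low, high)` in Hz,
#'   recorded as metadata only.
#' @return An object of class `signal_channel`.
#' @export
signal_channel <- function(label, samples, sampling_rate, modality = NULL,
                           passband = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label))
    stopf("'label' must be a non-empty character scalar")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stopf("'sampling_rate' must be a positive scalar (Hz)")
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stopf("channel '%s' has no samples", label)
  if (!all(is.finite(samples)))
    stopf("channel '%s' contains non-finite samples", label)
  modality <- modality %||% infer_modality(label)
  modality <- match.arg(modality,
                        c("EEG", "EMG", "EOG", "ECG", "ACC", "TEMP", "OTHER"))
  structure(
    list(label = label, modality = modality,
         sampling_rate = as.numeric(sampling_rate),
         samples = samples, passband = passband),
    class = "signal_channel")
}

#' Infer channel modality from a label prefix
#'
#' @param label Channel label.
#' @param overrides Optional named character vector mapping exact labels to
#'   modalities, taking precedence over the prefix rule (montage names such
#'   as `"C3:A2"` vary by laboratory and carry no modality prefix).
#' @return Modality string.
#' @export
infer_modality <- function(label, overrides = NULL) {
  if (!is.null(overrides) && label %in% names(overrides))
    return(unname(overrides[[label]]))
  up <- toupper(label)
  for (m in c("EEG", "EMG", "EOG", "ECG", "ACC", "TEMP"))
    if (startsWith(up, m)) return(m)
  "OTHER"
}

#' Construct a multichannel recording
#'
#' @param channels List of [signal_channel()] objects (at least one). All
#'   channels must span the same duration to within one sample period.
#' @param id Recording identifier.
#' @return An object of class `psg_recording` with fields `id`, `channels`
#'   (named by label) and `duration` (seconds).
#' @export
recording <- function(channels, id = "recording") {
  if (inherits(channels, "signal_channel")) channels <- list(channels)
  if (length(channels) == 0L) stopf("a recording needs at least one channel")
  if (!all(vapply(channels, inherits, TRUE, "signal_channel")))
    stopf("'channels' must be a list of signal_channel objects")
  durs <- vapply(channels, function(ch) length(ch$samples) / ch$sampling_rate,
                 0)
  tol <- max(vapply(channels, function(ch) 1 / ch$sampling_rate, 0))
  if (diff(range(durs)) > tol + 1e-9)
    stopf("channels span different durations (%.3f..%.3f s)",
          min(durs), max(durs))
  names(channels) <- vapply(channels, `[[`, "", "label")
  if (anyDuplicated(names(channels)))
    stopf("duplicate channel labels: %s",
          paste(unique(names(channels)[duplicated(names(channels))]),
                collapse = ", "))
  structure(list(id = id, channels = channels, duration = min(durs)),
            class = "psg_recording")
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording '%s'> %.1f s, %d channel(s)\n",
              x$id, x$duration, length(x$channels)))
  for (ch in x$channels)
    cat(sprintf("  %-12s %-5s %g Hz, %d samples\n", ch$label, ch$modality,
                ch$sampling_rate, length(ch$samples)))
  invisible(x)
}

#' Stage vocabularies
#'
#' The ordered set of vigilance-stage labels a hypnogram may use. Two
#' conventional vocabularies are provided: the human AASM set
#' (`W, N1, N2, N3, REM`) and the animal set (`W, NREM, REM`). The order
#' matters: prediction ties are broken toward the earlier label.
#'
#' @param labels Ordered character vector of unique stage labels; must not
#'   contain the special labels `ARTIFACT`/`UNDETERMINED`.
#' @return Object of class `stage_vocabulary` (a character vector).
#' @export
stage_vocabulary <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1L || anyDuplicated(labels))
    stopf("stage labels must be unique and non-empty")
  if (any(labels %in% SPECIAL_LABELS))
    stopf("special labels cannot be vocabulary stages")
  structure(labels, class = "stage_vocabulary")
}

#' @rdname stage_vocabulary
#' @export
vocab_human <- function() stage_vocabulary(c("W", "N1", "N2", "N3", "REM"))

#' @rdname stage_vocabulary
#' @export
vocab_animal <- function() stage_vocabulary(c("W", "NREM", "REM"))

#' Construct an epoch grid
#'
#' Epochs are uniform, half-open time windows: epoch i (1-based) covers
#' `[(i-1) * L, i * L)` seconds. A trailing partial epoch is dropped, so
#' `n_epochs = floor(duration / epoch_length)`.
#'
#' @param epoch_length Epoch length in seconds (> 0); conventional values
#'   are 4, 10 and 30 s.
#' @param n_epochs Number of epochs (>= 1).
#' @return Object of class `epoch_grid`.
#' @export
epoch_grid <- function(epoch_length, n_epochs) {
  if (!is.numeric(epoch_length) || epoch_length <= 0)
    stopf("'epoch_length' must be > 0 seconds")
  n_epochs <- as.integer(n_epochs)
  if (is.na(n_epochs) || n_epochs < 1L) stopf("'n_epochs' must be >= 1")
  structure(list(epoch_length = as.numeric(epoch_length),
                 n_epochs = n_epochs),
            class = "epoch_grid")
}

#' Derive the epoch grid of a recording
#'
#' @param x A `psg_recording`, or a numeric duration in seconds.
#' @param epoch_length Epoch length in seconds (> 0).
#' @return An [epoch_grid()] with `floor(duration / epoch_length)` epochs.
#' @export
make_epoch_grid <- function(x, epoch_length) {
  duration <- if (inherits(x, "psg_recording")) x$duration else as.numeric(x)
  if (!is.numeric(epoch_length) || length(epoch_length) != 1L ||
      epoch_length <= 0)
    stopf("'epoch_length' must be a positive scalar (seconds)")
  if (duration < epoch_length)
    stopf("recording (%.3f s) is shorter than one epoch (%g s)",
          duration, epoch_length)
  # guard against floating-point shortfall (e.g. 86400/4 -> 21599.999...)
  n <- floor(duration / epoch_length + 1e-9)
  epoch_grid(epoch_length, n)
}

#' Construct a hypnogram
#'
#' One stage label per epoch on an epoch grid. Labels must belong to the
#' vocabulary or be one of the special labels (`ARTIFACT`, `UNDETERMINED`).
#'
#' @param labels Character vector, one label per epoch.
#' @param grid An [epoch_grid()]; defaults to a grid inferred from
#'   `length(labels)` and `epoch_length`.
#' @param vocabulary A [stage_vocabulary()].
#' @param epoch_length Used only when `grid` is missing.
#' @return Object of class `hypnogram`: the label vector with attributes
#'   `grid` and `vocabulary`.
#' @export
hypnogram <- function(labels, vocabulary, grid = NULL, epoch_length = NULL) {
  labels <- as.character(labels)
  if (is.null(grid)) {
    if (is.null(epoch_length))
      stopf("supply either 'grid' or 'epoch_length'")
    grid <- epoch_grid(epoch_length, length(labels))
  }
  if (!inherits(grid, "epoch_grid")) stopf("'grid' must be an epoch_grid")
  if (!inherits(vocabulary, "stage_vocabulary"))
    stopf("'vocabulary' must be a stage_vocabulary")
  if (length(labels) != grid$n_epochs)
    stopf("hypnogram has %d labels but the grid has %d epochs",
          length(labels), grid$n_epochs)
  bad <- !(labels %in% c(vocabulary, SPECIAL_LABELS))
  if (any(bad))
    stopf("unknown stage label(s): %s (first at epoch %d)",
          paste(unique(labels[bad]), collapse = ", "), which(bad)[1L])
  structure(labels, grid = grid, vocabulary = vocabulary,
            class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  g <- attr(x, "grid")
  tab <- table(factor(unclass(x), levels = c(attr(x, "vocabulary"),
                                             SPECIAL_LABELS)))
  cat(sprintf("<hypnogram> %d epochs x %g s\n", g$n_epochs, g$epoch_length))
  print(tab[tab > 0 | names(tab) %in% attr(x, "vocabulary")])
  invisible(x)
}

hypnogram_grid <- function(h) attr(h, "grid")
hypnogram_vocab <- function(h) attr(h, "vocabulary")

#' Epochs excluded from training and evaluation
#'
#' Indices (1-based) of epochs labeled `ARTIFACT` or `UNDETERMINED` in a
#' manually scored hypnogram. Such epochs are excluded from training-set
#' sampling and from agreement evaluation, but still receive an automated
#' prediction.
#'
#' @param h A [hypnogram()].
#' @return Sorted integer vector of epoch indices.
#' @export
excluded_epochs <- function(h) {
  stopifnot(inherits(h, "hypnogram"))
  which(unclass(h) %in% SPECIAL_LABELS)
}

## ---------------------------------------------------------------- EDF I/O

edf_pad <- function(x, width) {
  x <- substr(gsub("[^ -~]", " ", as.character(x)), 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to a 16-bit EDF file
#'
#' Plain EDF (not EDF+): a 256-byte fixed header, 256 bytes per signal, and
#' contiguous data records of little-endian 16-bit integers. Physical
#' scaling is set per channel from the sample range, so a write/read round
#' trip preserves values to within the 16-bit quantization step.
#'
#' @param rec A [recording()].
#' @param path Output file path.
#' @param record_duration Data-record duration in seconds; every channel's
#'   `sampling_rate * record_duration` must be a whole number.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, record_duration = 1) {
  stopifnot(inherits(rec, "psg_recording"))
  ns <- length(rec$channels)
  spr <- vapply(rec$channels, function(ch) ch$sampling_rate * record_duration,
                0)
  if (any(abs(spr - round(spr)) > 1e-9))
    stopf("record_duration %g s gives fractional samples per record",
          record_duration)
  spr <- as.integer(round(spr))
  n_rec <- as.integer(floor(rec$duration / record_duration + 1e-9))
  if (n_rec < 1L) stopf("recording shorter than one data record")

  # physical limits are rounded outward to values whose 8-char ASCII header
  # representation parses back exactly, so read-back scaling is lossless
  round_out <- function(x, up) {
    if (x == 0) return("0")
    p <- 10^(floor(log10(abs(x))) - 3)
    v <- if (up) ceiling(x / p) * p else floor(x / p) * p
    for (d in 7:1) {
      s <- formatC(v, digits = d, format = "g")
      if (nchar(s) <= 8) return(s)
    }
    formatC(v, digits = 1, format = "g")
  }
  pmin <- pmax <- numeric(ns)
  pmin_s <- pmax_s <- character(ns)
  dig <- vector("list", ns)
  for (i in seq_len(ns)) {
    x <- rec$channels[[i]]$samples[seq_len(spr[i] * n_rec)]
    pmin_s[i] <- round_out(min(x), up = FALSE)
    pmax_s[i] <- round_out(max(x), up = TRUE)
    lo <- as.numeric(pmin_s[i]); hi <- as.numeric(pmax_s[i])
    if (hi - lo < 1e-12) {
      pmax_s[i] <- round_out(lo + 1, TRUE)
      hi <- as.numeric(pmax_s[i])
    }
    pmin[i] <- lo; pmax[i] <- hi
    d <- round((x - lo) / (hi - lo) * 65535 - 32768)
    dig[[i]] <- as.integer(pmin(pmax(d, -32768), 32767))
  }

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(rec$id, 80),
    edf_pad("hypnoscore synthetic", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (ns + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_pad(format(record_duration), 8),
    edf_pad(ns, 4))
  fld <- function(get, width)
    paste(vapply(seq_len(ns), function(i) edf_pad(get(i), width), ""),
          collapse = "")
  hdr <- paste0(
    hdr,
    fld(function(i) rec$channels[[i]]$label, 16),
    fld(function(i) "", 80),
    fld(function(i) "uV", 8),
    fld(function(i) pmin_s[i], 8),
    fld(function(i) pmax_s[i], 8),
    fld(function(i) "-32768", 8),
    fld(function(i) "32767", 8),
    fld(function(i) {
      pb <- rec$channels[[i]]$passband
      if (is.null(pb)) "" else sprintf("HP:%g LP:%g", pb[1], pb[2])
    }, 80),
    fld(function(i) spr[i], 8),
    fld(function(i) "", 32))
  writeChar(hdr, con, eos = NULL, useBytes = TRUE)

  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      idx <- ((r - 1L) * spr[i] + 1L):(r * spr[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

edf_num <- function(x) {
  v <- suppressWarnings(as.numeric(trimws(x)))
  if (is.na(v)) stopf("malformed EDF header field: '%s'", x)
  v
}

#' Read a 16-bit EDF file
#'
#' Parses the fixed EDF header, applies per-channel physical scaling, and
#' infers each channel's modality from its label prefix (override with
#' `modality_overrides`). EDF+ annotation channels and discontinuous
#' records are not supported.
#'
#' @param path Path to an EDF file.
#' @param id Recording id; defaults to the file's patient field.
#' @param modality_overrides Named character vector mapping channel labels
#'   to modalities (see [infer_modality()]).
#' @return A [recording()].
#' @export
read_edf <- function(path, id = NULL, modality_overrides = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  sz <- file.size(path)
  if (sz < 256) stopf("not an EDF file (truncated header): %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  pull <- function(s, from, len) substr(s, from, from + len - 1L)
  patient <- trimws(pull(fixed, 9, 80))
  hdr_bytes <- edf_num(pull(fixed, 185, 8))
  n_rec <- edf_num(pull(fixed, 237, 8))
  rec_dur <- edf_num(pull(fixed, 245, 8))
  ns <- as.integer(edf_num(pull(fixed, 253, 4)))
  if (ns < 1L) stopf("EDF declares zero signals: %s", path)
  if (hdr_bytes != 256 * (ns + 1))
    stopf("EDF header size field inconsistent with signal count")
  if (sz < hdr_bytes) stopf("EDF file truncated before data records")

  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  blk <- function(offset, width) {
    start <- offset * ns
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, start + (i - 1L) * width + 1L,
                    start + i * width)), "")
  }
  labels <- blk(0, 16)
  pmin <- as.numeric(blk(16 + 80 + 8, 8))
  pmax <- as.numeric(blk(16 + 80 + 8 + 8, 8))
  dmin <- as.numeric(blk(16 + 80 + 8 + 16, 8))
  dmax <- as.numeric(blk(16 + 80 + 8 + 24, 8))
  prefilter <- blk(16 + 80 + 8 + 32, 80)
  spr <- as.integer(as.numeric(blk(16 + 80 + 8 + 32 + 80, 8)))
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr))))
    stopf("malformed EDF signal header")

  rec_bytes <- sum(spr) * 2
  if (n_rec < 0) n_rec <- floor((sz - hdr_bytes) / rec_bytes)
  if (sz - hdr_bytes < n_rec * rec_bytes)
    stopf("EDF declares %d records but file holds only %.0f",
          n_rec, (sz - hdr_bytes) / rec_bytes)

  raw <- readBin(con, "integer", n = sum(spr) * n_rec, size = 2L,
                 signed = TRUE, endian = "little")
  # de-interleave records
  offsets <- c(0L, cumsum(spr))
  channels <- vector("list", ns)
  for (i in seq_len(ns)) {
    take <- outer(offsets[i] + seq_len(spr[i]),
                  (seq_len(n_rec) - 1L) * sum(spr), `+`)
    d <- raw[as.vector(take)]
    gain <- (pmax[i] - pmin[i]) / (dmax[i] - dmin[i])
    phys <- (d - dmin[i]) * gain + pmin[i]
    pb <- NULL
    m <- regmatches(prefilter[i],
                    regexec("HP:([0-9.]+) LP:([0-9.]+)", prefilter[i]))[[1]]
    if (length(m) == 3) pb <- as.numeric(m[2:3])
    channels[[i]] <- signal_channel(
      label = labels[i], samples = phys,
      sampling_rate = spr[i] / rec_dur,
      modality = infer_modality(labels[i], modality_overrides),
      passband = pb)
  }
  recording(channels, id = id %||% if (nzchar(patient)) patient else
    basename(path))
}

## ------------------------------------------------------------ hypnogram I/O

#' Read a hypnogram from text
#'
#' Two dialects are accepted: a CSV with header `epoch_index,onset_s,stage`
#' (optionally a `transition` column, which is ignored on read), or a
#' headerless file with one stage token per line (comma-separated tokens on
#' a line are also accepted). Lines starting with `#` are skipped. Tokens
#' are mapped through `token_map` and then validated against the
#' vocabulary; an unknown token is an error naming its line.
#'
#' @param path Input file.
#' @param vocabulary A [stage_vocabulary()].
#' @param epoch_length Epoch length in seconds of the target grid.
#' @param token_map Named character vector of token aliases applied before
#'   validation. The default maps `R` to `REM` and common artifact markers
#'   to the special labels.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, vocabulary, epoch_length,
                           token_map = c(R = "REM", ART = "ARTIFACT",
                                         A = "ARTIFACT", UND = "UNDETERMINED",
                                         U = "UNDETERMINED")) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stopf("empty hypnogram file: %s", path)

  header <- grepl("stage", tolower(lines[1L])) && grepl(",", lines[1L])
  if (header) {
    df <- utils::read.csv(text = paste(lines, collapse = "\n"),
                          stringsAsFactors = FALSE)
    if (!"stage" %in% names(df))
      stopf("hypnogram CSV lacks a 'stage' column: %s", path)
    tokens <- as.character(df$stage)
    token_line <- line_no[-1L]
  } else {
    parts <- strsplit(lines, ",", fixed = TRUE)
    tokens <- trimws(unlist(parts))
    token_line <- rep(line_no, lengths(parts))
  }
  mapped <- ifelse(tokens %in% names(token_map),
                   token_map[tokens], tokens)
  bad <- !(mapped %in% c(vocabulary, SPECIAL_LABELS))
  if (any(bad))
    stopf("unknown stage label '%s' at line %d of %s",
          tokens[bad][1L], token_line[bad][1L], path)
  hypnogram(mapped, vocabulary, epoch_length = epoch_length)
}

#' Write a hypnogram as CSV
#'
#' Writes the `epoch_index,onset_s,stage` dialect (1-based epoch index,
#' onset in seconds). Extra per-epoch columns (e.g. a transition mask) can
#' be appended, and comment lines (config provenance) are prefixed with `#`.
#'
#' @param h A [hypnogram()].
#' @param path Output file.
#' @param extra Optional named list of per-epoch vectors to append as
#'   columns.
#' @param comments Optional character vector written as `#`-prefixed header
#'   lines.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(h, path, extra = NULL, comments = NULL) {
  stopifnot(inherits(h, "hypnogram"))
  g <- hypnogram_grid(h)
  df <- data.frame(epoch_index = seq_len(g$n_epochs),
                   onset_s = (seq_len(g$n_epochs) - 1L) * g$epoch_length,
                   stage = unclass(h))
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a recording from one-column-per-channel CSV
#'
#' Text import for labs exporting plain text rather than EDF: a CSV whose
#' first line is a comment of the form `# sampling_rate: <Hz>` followed by
#' a header of channel labels and one row per sample (all channels share
#' the sampling rate in this dialect).
#'
#' @param path Input file.
#' @param sampling_rate Sampling rate in Hz; overrides the header line.
#' @param id Recording id.
#' @return A [recording()].
#' @export
read_recording_csv <- function(path, sampling_rate = NULL, id = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  if (is.null(sampling_rate)) {
    m <- regmatches(first, regexec("sampling_rate:\\s*([0-9.]+)", first))[[1]]
    if (length(m) != 2)
      stopf("no sampling_rate header in %s and none supplied", path)
    sampling_rate <- as.numeric(m[2])
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (ncol(df) < 1L || nrow(df) < 1L) stopf("no channel data in %s", path)
  chans <- lapply(names(df), function(nm)
    signal_channel(nm, df[[nm]], sampling_rate))
  recording(chans, id = id %||% basename(path))
}
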