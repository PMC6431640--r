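#' Default EEG frequency bands
#'
#' Delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-16 and beta 16-30 Hz.
#' Bands are clipped to each channel's Nyquist frequency at extraction
#' time; a band lying entirely above Nyquist is dropped for that channel.
#'
#' @return Named list of `(low, high)` Hz pairs.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
       sigma = c(12, 16), beta = c(16, 30))
}

#' Channel configuration for feature extraction
#'
#' Selects which channels of a recording feed the classifier. Named
#' presets mirror the standard ablation configurations: `ALL` (every
#' channel), `ONE_EEG` (a single EEG channel, by default the first),
#' `EOG_ONLY` (the two EOG channels), `EEG_EMG`, `EEG_ONLY`, `EMG_ONLY`,
#' `EEG_ACC` and `ACC_ONLY`. `CUSTOM` takes explicit labels via `include`.
#'
#' @param preset Preset name.
#' @param include Character vector of channel labels (`CUSTOM` preset).
#' @param eeg_channel For `ONE_EEG`: label of the EEG channel to keep.
#' @return Object of class `channel_config`.
#' @export
channel_config <- function(preset = c("ALL", "ONE_EEG", "EOG_ONLY",
                                      "EEG_EMG", "EEG_ONLY", "EMG_ONLY",
                                      "EEG_ACC", "ACC_ONLY", "CUSTOM"),
                           include = NULL, eeg_channel = NULL) {
  preset <- match.arg(preset)
  if (preset == "CUSTOM" && length(include) == 0L)
    stopf("CUSTOM preset requires 'include' labels")
  structure(list(preset = preset, include = include,
                 eeg_channel = eeg_channel),
            class = "channel_config")
}

#' Resolve a channel configuration against a recording
#'
#' @param config A [channel_config()] or a preset name.
#' @param rec A [recording()].
#' @return Character vector of channel labels (>= 1), in recording order.
#' @export
resolve_channels <- function(config, rec) {
  if (is.character(config)) config <- channel_config(config)
  stopifnot(inherits(config, "channel_config"),
            inherits(rec, "psg_recording"))
  labels <- names(rec$channels)
  mods <- vapply(rec$channels, `[[`, "", "modality")
  by_mod <- function(...) labels[mods %in% c(...)]
  out <- switch(config$preset,
    ALL = labels,
    ONE_EEG = {
      eeg <- by_mod("EEG")
      if (length(eeg) == 0L) character()
      else if (is.null(config$eeg_channel)) eeg[1L]
      else {
        if (!config$eeg_channel %in% eeg)
          stopf("EEG channel '%s' not present", config$eeg_channel)
        config$eeg_channel
      }
    },
    EOG_ONLY = by_mod("EOG"),
    EEG_EMG = by_mod("EEG", "EMG"),
    EEG_ONLY = by_mod("EEG"),
    EMG_ONLY = by_mod("EMG"),
    EEG_ACC = by_mod("EEG", "ACC"),
    ACC_ONLY = by_mod("ACC"),
    CUSTOM = {
      missing <- setdiff(config$include, labels)
      if (length(missing))
        stopf("configured channel(s) absent: %s",
              paste(missing, collapse = ", "))
      labels[labels %in% config$include]
    })
  if (length(out) == 0L)
    stopf("preset %s resolves to no channels in recording '%s'",
          config$preset, rec$id)
  out
}

# Averaged modified periodogram (Welch) per epoch.
# Returns list(freq, psd) where psd is n_freq x n_epochs, one-sided,
# averaged over Hann-tapered segments with 50% overlap within each epoch.
welch_psd <- function(samples, fs, epoch_length, n_epochs, window_s,
                      chunk_epochs = 2000L) {
  eps_len <- as.integer(round(epoch_length * fs))
  win <- as.integer(round(window_s * fs))
  if (win > eps_len)
    stopf("epoch (%g s) shorter than spectral window (%g s)",
          epoch_length, window_s)
  step <- max(1L, win %/% 2L)
  nw <- (eps_len - win) %/% step + 1L
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(win) / (win + 1))  # Hann
  u <- sum(taper^2)
  n_freq <- win %/% 2L + 1L
  freq <- (seq_len(n_freq) - 1L) * fs / win

  # per-epoch window start offsets (within epoch), 0-based
  w_off <- (seq_len(nw) - 1L) * step
  psd <- matrix(0, n_freq, n_epochs)
  for (e0 in seq(1L, n_epochs, by = chunk_epochs)) {
    e1 <- min(e0 + chunk_epochs - 1L, n_epochs)
    epochs <- e0:e1
    # sample index of each window start: (epoch-1)*eps_len + offset
    starts <- rep((epochs - 1L) * eps_len, each = nw) + w_off
    idx <- outer(seq_len(win), starts, `+`)  # win x (nw * n_chunk)
    seg <- matrix(samples[idx], nrow = win)
    seg <- (seg - rep(colMeans(seg), each = win)) * taper
    spec <- abs(stats::mvfft(seg))^2 / (fs * u)
    spec <- spec[seq_len(n_freq), , drop = FALSE]
    if (n_freq > 2L)
      spec[2:(n_freq - 1L), ] <- 2 * spec[2:(n_freq - 1L), ]
    # average the nw windows of each epoch
    grp <- rep(seq_along(epochs), each = nw)
    acc <- t(rowsum(t(spec), grp)) / nw
    psd[, epochs] <- acc
  }
  list(freq = freq, psd = psd)
}

# Integrate a one-sided PSD over [lo, hi) Hz. Returns vector over epochs.
band_power <- function(freq, psd, lo, hi) {
  df <- freq[2L] - freq[1L]
  sel <- freq >= lo & freq < hi
  if (!any(sel)) return(rep(0, ncol(psd)))
  colSums(psd[sel, , drop = FALSE]) * df
}

# Spectral edge frequency: frequency below which `q` of total power lies.
spectral_edge <- function(freq, psd, q = 0.95) {
  cs <- apply(psd, 2L, cumsum)
  tot <- cs[nrow(cs), ]
  tot[tot <= 0] <- 1
  idx <- max.col(t(cs) / tot >= q, ties.method = "first")
  freq[idx]
}

# Zero-crossing rate per epoch of a mean-removed signal, per second.
zero_crossings <- function(samples, fs, epoch_length, n_epochs) {
  eps_len <- as.integer(round(epoch_length * fs))
  m <- matrix(samples[seq_len(eps_len * n_epochs)], nrow = eps_len)
  m <- m - rep(colMeans(m), each = eps_len)
  s <- sign(m)
  colSums(s[-1L, , drop = FALSE] * s[-eps_len, , drop = FALSE] < 0) /
    epoch_length
}

epoch_matrix <- function(samples, fs, epoch_length, n_epochs) {
  eps_len <- as.integer(round(epoch_length * fs))
  matrix(samples[seq_len(eps_len * n_epochs)], nrow = eps_len)
}

LOG_FLOOR <- 1e-12

#' Extract per-epoch features from a recording
#'
#' Converts every epoch of the configured channels into a fixed-length
#' numeric vector. Per EEG/EOG channel: log absolute and relative band
#' powers (see [default_bands()]) from an averaged modified periodogram
#' (Hann-tapered segments, 50% overlap), the log delta/theta ratio, the
#' 95% spectral edge frequency, and the zero-crossing rate. Per EMG
#' channel: log RMS amplitude and log high-band (> 30 Hz) power. Per EOG
#' pair: the lag-0 cross-correlation per epoch. Per ACC channel: log
#' magnitude variance and log mean absolute first difference. Per TEMP
#' channel: mean and slope. ECG/OTHER channels contribute log RMS and
#' zero-crossing rate. All log-power features are z-scored per recording
#' (columns of the returned matrix); the scaling is recorded so that new
#' data can be placed on the same scale.
#'
#' @param rec A [recording()].
#' @param grid An [epoch_grid()] (see [make_epoch_grid()]).
#' @param config A [channel_config()] or preset name; default `ALL`.
#' @param bands Named list of `(low, high)` Hz pairs.
#' @param window_s Welch segment length in seconds; default 2 s (with 50%
#'   overlap this still averages 3 segments within a 4 s epoch while
#'   keeping 0.5 Hz resolution across the delta band; 1 s windows resolve
#'   delta too coarsely for short epochs). For epochs under 4 s the
#'   window shrinks to half the epoch.
#' @return A `feature_matrix`: numeric matrix `n_epochs x n_features` with
#'   unique column names `<channel>.<descriptor>`, and attributes `grid`,
#'   `channels`, and `scaling` (list with `center`, `scale`, `scaled`).
#' @export
extract_features <- function(rec, grid, config = channel_config("ALL"),
                             bands = default_bands(), window_s = NULL) {
  stopifnot(inherits(rec, "psg_recording"), inherits(grid, "epoch_grid"))
  labels <- resolve_channels(config, rec)
  L <- grid$epoch_length
  n <- grid$n_epochs
  if (is.null(window_s)) window_s <- if (L < 4) L / 2 else 2

  cols <- list()        # named list of per-epoch numeric vectors
  is_log_power <- c()   # parallel logical: z-score this column?

  add <- function(name, values, scale_it) {
    cols[[name]] <<- values
    is_log_power[name] <<- scale_it
  }
  lg <- function(x) log(pmax(x, LOG_FLOOR))

  eog_epochs <- list()  # per-EOG-channel epoch matrices for the pair xcorr

  for (lab in labels) {
    ch <- rec$channels[[lab]]
    fs <- ch$sampling_rate
    need <- as.integer(round(L * fs)) * n
    if (length(ch$samples) < need)
      stopf("channel '%s' too short for %d epochs of %g s", lab, n, L)
    mod <- ch$modality
    if (mod %in% c("EEG", "EOG")) {
      nyq <- fs / 2
      use <- Filter(function(b) b[1] < nyq, bands)
      if (length(use) < length(bands))
        warnf("channel '%s': band(s) above Nyquist (%g Hz) dropped",
              lab, nyq)
      use <- lapply(use, function(b) c(b[1], min(b[2], nyq)))
      w <- welch_psd(ch$samples, fs, L, n, window_s)
      bp <- vapply(use, function(b) band_power(w$freq, w$psd, b[1], b[2]),
                   numeric(n))
      if (is.null(dim(bp))) bp <- matrix(bp, nrow = n)
      tot <- rowSums(bp)
      rel <- bp / ifelse(tot > 0, tot, 1)
      rel[tot <= 0, ] <- 1 / ncol(bp)  # dead epoch: flat profile
      for (j in seq_along(use)) {
        bn <- names(use)[j]
        add(paste(lab, "abs", bn, sep = "."), lg(bp[, j]), TRUE)
        add(paste(lab, "rel", bn, sep = "."), rel[, j], FALSE)
      }
      if (all(c("delta", "theta") %in% names(use))) {
        d <- which(names(use) == "delta"); t_ <- which(names(use) == "theta")
        add(paste(lab, "dt_ratio", sep = "."),
            lg(bp[, d]) - lg(bp[, t_]), FALSE)
      }
      add(paste(lab, "sef95", sep = "."),
          spectral_edge(w$freq, w$psd, 0.95), FALSE)
      add(paste(lab, "zcr", sep = "."),
          zero_crossings(ch$samples, fs, L, n), FALSE)
      if (mod == "EOG")
        eog_epochs[[lab]] <- epoch_matrix(ch$samples, fs, L, n)
    } else if (mod == "EMG") {
      m <- epoch_matrix(ch$samples, fs, L, n)
      rms <- sqrt(colMeans(m^2))
      add(paste(lab, "log_rms", sep = "."), lg(rms), TRUE)
      nyq <- fs / 2
      if (nyq > 32) {
        w <- welch_psd(ch$samples, fs, L, n, window_s)
        add(paste(lab, "hf_power", sep = "."),
            lg(band_power(w$freq, w$psd, 30, nyq)), TRUE)
      } else {
        warnf("channel '%s': Nyquist %g Hz too low for the >30 Hz EMG band",
              lab, nyq)
      }
    } else if (mod == "ACC") {
      m <- epoch_matrix(ch$samples, fs, L, n)
      v <- colMeans(m^2) - colMeans(m)^2
      mad1 <- colMeans(abs(m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE]))
      add(paste(lab, "log_var", sep = "."), lg(v), TRUE)
      add(paste(lab, "log_mad", sep = "."), lg(mad1), TRUE)
    } else if (mod == "TEMP") {
      m <- epoch_matrix(ch$samples, fs, L, n)
      tt <- (seq_len(nrow(m)) - 1) / fs
      tt <- tt - mean(tt)
      add(paste(lab, "mean", sep = "."), colMeans(m), FALSE)
      add(paste(lab, "slope", sep = "."),
          colSums(m * tt) / sum(tt^2), FALSE)
    } else {  # ECG, OTHER
      m <- epoch_matrix(ch$samples, fs, L, n)
      add(paste(lab, "log_rms", sep = "."), lg(sqrt(colMeans(m^2))), TRUE)
      add(paste(lab, "zcr", sep = "."),
          zero_crossings(ch$samples, fs, L, n), FALSE)
    }
  }

  if (length(eog_epochs) >= 2L) {
    a <- eog_epochs[[1L]]; b <- eog_epochs[[2L]]
    if (nrow(a) == nrow(b)) {
      ac <- a - rep(colMeans(a), each = nrow(a))
      bc <- b - rep(colMeans(b), each = nrow(b))
      denom <- sqrt(colSums(ac^2) * colSums(bc^2))
      xc <- colSums(ac * bc) / ifelse(denom > 0, denom, 1)
      add(paste(names(eog_epochs)[1L], names(eog_epochs)[2L], "xcorr0",
                sep = "."), xc, FALSE)
    } else {
      warnf("EOG pair has mismatched sampling rates; cross-correlation skipped")
    }
  }

  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  scaled <- names(cols)[is_log_power[names(cols)]]
  center <- scale_ <- stats::setNames(numeric(length(scaled)), scaled)
  for (nm in scaled) {
    mu <- mean(mat[, nm]); sd_ <- stats::sd(mat[, nm])
    if (!is.finite(sd_) || sd_ < 1e-12) sd_ <- 1
    mat[, nm] <- (mat[, nm] - mu) / sd_
    center[nm] <- mu; scale_[nm] <- sd_
  }
  stopifnot(all(is.finite(mat)))
  structure(mat, grid = grid, channels = labels,
            scaling = list(center = center, scale = scale_, scaled = scaled),
            class = c("feature_matrix", class(mat)))
}
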