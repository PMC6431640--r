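#' Synthetic polysomnography specification
#'
#' Species presets bundling the epoch length, stage vocabulary, a
#' semi-Markov bout model (per-stage mean bout durations, zero
#' self-transition stage weights) and stage-conditional signal parameters
#' (relative EEG band-power profile over delta/theta/alpha/sigma/beta,
#' EMG/EOG/ACC amplitude levels, broadband noise floor).
#'
#' Presets: `rodent` (4 s epochs, W/NREM/REM; EEG + nuchal EMG at 128 Hz),
#' `human` (30 s epochs, W/N1/N2/N3/REM; two EEG, two EOG and a chin EMG
#' at 128 Hz) and `avian` (4 s epochs, W/NREM/REM; EEG at 128 Hz plus a
#' head-movement accelerometer at 64 Hz, with short REM episodes whose
#' geometric bout-length distribution has its 95th percentile at 16 s —
#' avian REM episodes rarely exceed that).
#'
#' @param preset `"rodent"`, `"human"` or `"avian"`.
#' @param ... Named overrides of any preset field (e.g. `noise_floor`,
#'   `mean_bout_s`, `emg_level`).
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(preset = c("rodent", "human", "avian"), ...) {
  preset <- match.arg(preset)
  band_profile <- function(...) {
    m <- rbind(...)
    colnames(m) <- c("delta", "theta", "alpha", "sigma", "beta")
    m / rowSums(m)
  }
  spec <- switch(preset,
    rodent = list(
      preset = "rodent", epoch_length = 4,
      vocabulary = vocab_animal(),
      mean_bout_s = c(W = 120, NREM = 160, REM = 80),
      transition = rbind(W = c(W = 0, NREM = 0.9, REM = 0.1),
                         NREM = c(W = 0.6, NREM = 0, REM = 0.4),
                         REM = c(W = 0.8, NREM = 0.2, REM = 0)),
      eeg_profile = band_profile(W = c(0.15, 0.40, 0.20, 0.10, 0.15),
                                 NREM = c(0.70, 0.10, 0.08, 0.08, 0.04),
                                 REM = c(0.08, 0.62, 0.15, 0.10, 0.05)),
      emg_level = c(W = 1.0, NREM = 0.45, REM = 0.12),
      eog_level = NULL, acc_level = NULL,
      channels = list(
        list(label = "EEG1", modality = "EEG", fs = 128),
        list(label = "EMG1", modality = "EMG", fs = 128))),
    human = list(
      preset = "human", epoch_length = 30,
      vocabulary = vocab_human(),
      mean_bout_s = c(W = 150, N1 = 60, N2 = 600, N3 = 360, REM = 300),
      transition = rbind(
        W = c(W = 0, N1 = 0.70, N2 = 0.20, N3 = 0.05, REM = 0.05),
        N1 = c(W = 0.30, N1 = 0, N2 = 0.60, N3 = 0, REM = 0.10),
        N2 = c(W = 0.20, N1 = 0.10, N2 = 0, N3 = 0.40, REM = 0.30),
        N3 = c(W = 0.20, N1 = 0.10, N2 = 0.70, N3 = 0, REM = 0),
        REM = c(W = 0.40, N1 = 0.30, N2 = 0.30, N3 = 0, REM = 0)),
      eeg_profile = band_profile(W = c(0.15, 0.15, 0.40, 0.10, 0.20),
                                 N1 = c(0.25, 0.45, 0.15, 0.10, 0.05),
                                 N2 = c(0.35, 0.25, 0.10, 0.25, 0.05),
                                 N3 = c(0.70, 0.15, 0.05, 0.07, 0.03),
                                 REM = c(0.15, 0.50, 0.15, 0.10, 0.10)),
      emg_level = c(W = 1.0, N1 = 0.5, N2 = 0.4, N3 = 0.35, REM = 0.1),
      eog_level = c(W = 0.8, N1 = 0.6, N2 = 0.2, N3 = 0.1, REM = 1.0),
      acc_level = NULL,
      channels = list(
        list(label = "EEG Cz", modality = "EEG", fs = 128),
        list(label = "EEG C3", modality = "EEG", fs = 128),
        list(label = "EOG L", modality = "EOG", fs = 128),
        list(label = "EOG R", modality = "EOG", fs = 128),
        list(label = "EMG chin", modality = "EMG", fs = 128))),
    avian = list(
      preset = "avian", epoch_length = 4,
      vocabulary = vocab_animal(),
      # REM mean 7 s => geometric p = 4/7 per epoch; P(len <= 4 epochs =
      # 16 s) = 1 - (1-p)^4 = 0.966, so the 95th percentile is <= 16 s.
      mean_bout_s = c(W = 60, NREM = 40, REM = 7),
      transition = rbind(W = c(W = 0, NREM = 0.95, REM = 0.05),
                         NREM = c(W = 0.5, NREM = 0, REM = 0.5),
                         REM = c(W = 0.4, NREM = 0.6, REM = 0)),
      eeg_profile = band_profile(W = c(0.15, 0.35, 0.25, 0.10, 0.15),
                                 NREM = c(0.60, 0.18, 0.10, 0.08, 0.04),
                                 REM = c(0.10, 0.55, 0.18, 0.09, 0.08)),
      emg_level = NULL, eog_level = NULL,
      acc_level = c(W = 1.0, NREM = 0.2, REM = 0.08),
      channels = list(
        list(label = "EEG1", modality = "EEG", fs = 128),
        list(label = "ACC1", modality = "ACC", fs = 64))))
  spec$dispersion <- 0          # 0 = geometric bout lengths; > 0 = nbinom size
  spec$noise_floor <- 0.15      # broadband noise amplitude added to EEG
  spec$amp_jitter <- 0.1        # sd of per-epoch log-amplitude jitter
  dots <- list(...)
  for (nm in names(dots)) spec[[nm]] <- dots[[nm]]
  stages <- as.character(spec$vocabulary)
  stopifnot(identical(rownames(spec$transition), stages),
            all(diag(spec$transition) == 0),
            all(abs(rowSums(spec$transition) - 1) < 1e-9),
            all(abs(rowSums(spec$eeg_profile) - 1) < 1e-9))
  class(spec) <- "synthetic_spec"
  spec
}

#' Simulate a bout-structured hypnogram
#'
#' Semi-Markov draw: starting from a uniformly chosen stage, sample a bout
#' length (geometric with the stage's mean, minimum 1 epoch; negative
#' binomial when the spec's `dispersion` is > 0), emit the bout, then pick
#' the next stage from the transition weights (zero self-transition),
#' truncating the final bout at `n_epochs`.
#'
#' @param spec A [synthetic_spec()].
#' @param n_epochs Number of epochs (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @return A [hypnogram()].
#' @export
generate_hypnogram <- function(spec, n_epochs, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), n_epochs >= 1L)
  stages <- as.character(spec$vocabulary)
  if (any(rowSums(spec$transition) <= 0))
    stopf("degenerate transition weights (zero-weight row)")
  mean_ep <- stats::setNames(
    pmax(1, spec$mean_bout_s[stages] / spec$epoch_length), stages)
  labels <- with_seed(seed, {
    out <- character(0)
    st <- stages[sample.int(length(stages), 1L)]
    while (length(out) < n_epochs) {
      m <- mean_ep[[st]]
      len <- if (spec$dispersion > 0) {
        1L + stats::rnbinom(1L, size = spec$dispersion, mu = m - 1)
      } else if (m <= 1) 1L else {
        1L + stats::rgeom(1L, prob = 1 / m)
      }
      out <- c(out, rep(st, len))
      st <- sample(stages, 1L, prob = spec$transition[st, ])
    }
    out[seq_len(n_epochs)]
  })
  hypnogram(labels, spec$vocabulary, epoch_length = spec$epoch_length)
}

# Frequency-domain amplitude gains realizing a relative band-power profile
# for white-noise shaping; returns a length-ns symmetric gain vector with
# unit output variance. `noise_floor` is the fraction of total power spread
# flat across the whole spectrum; the band profile carries the rest.
band_gains <- function(ns, fs, weights, bands, noise_floor = 0) {
  freq <- (seq_len(ns) - 1L) * fs / ns
  freq <- pmin(freq, fs - freq)  # two-sided -> folded frequency
  a2 <- rep(noise_floor / ns, ns)
  nyq <- fs / 2
  for (b in names(bands)) {
    lo <- bands[[b]][1]; hi <- min(bands[[b]][2], nyq)
    if (lo >= nyq) next
    sel <- freq >= lo & freq < hi
    if (any(sel))
      a2[sel] <- a2[sel] + (1 - noise_floor) * weights[[b]] / sum(sel)
  }
  a <- sqrt(a2)
  a / sqrt(mean(a2))
}

# Shape per-epoch white noise in the frequency domain, chunked over epochs.
shaped_noise <- function(n_epochs, ns, gains_by_stage, stage_idx,
                         chunk = 4000L) {
  out <- matrix(0, ns, n_epochs)
  for (e0 in seq(1L, n_epochs, by = chunk)) {
    e1 <- min(e0 + chunk - 1L, n_epochs)
    m <- e1 - e0 + 1L
    w <- matrix(stats::rnorm(ns * m), ns, m)
    f <- stats::mvfft(w)
    for (s in seq_along(gains_by_stage)) {
      cols <- which(stage_idx[e0:e1] == s)
      if (length(cols))
        f[, cols] <- f[, cols] * gains_by_stage[[s]]
    }
    out[, e0:e1] <- Re(stats::mvfft(f, inverse = TRUE)) / ns
  }
  out
}

#' Synthesize stage-conditional signals for a hypnogram
#'
#' Per epoch, EEG is band-limited Gaussian noise shaped to the stage's
#' relative band-power profile (plus a broadband noise floor); EMG is
#' broadband noise whose amplitude follows the stage's EMG level (wake >
#' NREM > REM in the presets); EOG is slow (0.2-3 Hz) noise and ACC white
#' noise at their stage levels. A small lognormal per-epoch amplitude
#' jitter is applied throughout. This is additive noise synthesis — only
#' the spectral/amplitude contrast between stages is modeled, not
#' waveform morphology.
#'
#' @param h A [hypnogram()] whose vocabulary matches the spec.
#' @param spec A [synthetic_spec()].
#' @param seed Integer seed; same inputs and seed give identical samples.
#' @param id Recording id.
#' @return A [recording()].
#' @export
generate_signals <- function(h, spec, seed = 1L, id = NULL) {
  stopifnot(inherits(h, "hypnogram"), inherits(spec, "synthetic_spec"))
  stages <- as.character(spec$vocabulary)
  if (!identical(as.character(hypnogram_vocab(h)), stages))
    stopf("hypnogram vocabulary does not match the spec")
  n <- hypnogram_grid(h)$n_epochs
  L <- hypnogram_grid(h)$epoch_length
  stage_idx <- match(unclass(h), stages)
  bands <- default_bands()

  channels <- with_seed(seed, lapply(spec$channels, function(chspec) {
    fs <- chspec$fs
    ns <- as.integer(round(L * fs))
    jitter <- exp(stats::rnorm(n, 0, spec$amp_jitter))
    sig <- switch(chspec$modality,
      EEG = {
        gains <- lapply(stages, function(st)
          band_gains(ns, fs, spec$eeg_profile[st, ], bands,
                     spec$noise_floor))
        m <- shaped_noise(n, ns, gains, stage_idx)
        m * rep(jitter, each = ns)
      },
      EOG = {
        lv <- spec$eog_level[stages][stage_idx]
        gains <- list(band_gains(ns, fs, c(slow = 1),
                                 list(slow = c(0.2, 3)), 0.05))
        m <- shaped_noise(n, ns, gains, rep(1L, n))
        m * rep(lv * jitter, each = ns)
      },
      EMG = {
        lv <- spec$emg_level[stages][stage_idx]
        m <- matrix(stats::rnorm(ns * n), ns, n)
        m * rep(lv * jitter, each = ns)
      },
      ACC = {
        lv <- spec$acc_level[stages][stage_idx]
        m <- matrix(stats::rnorm(ns * n), ns, n)
        m * rep(lv * jitter, each = ns)
      },
      stopf("unsupported synthetic modality '%s'", chspec$modality))
    signal_channel(chspec$label, as.vector(sig), fs,
                   modality = chspec$modality)
  }))
  recording(channels, id = id %||% paste0("synthetic-", spec$preset))
}

#' Simulate a complete synthetic recording with ground truth
#'
#' Convenience wrapper: draws a hypnogram with [generate_hypnogram()] and
#' synthesizes its signals with [generate_signals()].
#'
#' @param spec A [synthetic_spec()] or preset name.
#' @param n_epochs Number of epochs; alternatively give `hours`.
#' @param hours Recording length in hours (used when `n_epochs` missing).
#' @param seed Integer seed.
#' @return List with elements `recording`, `hypnogram`, `spec`.
#' @export
simulate_psg <- function(spec, n_epochs = NULL, hours = NULL, seed = 1L) {
  if (is.character(spec)) spec <- synthetic_spec(spec)
  if (is.null(n_epochs)) {
    if (is.null(hours)) stopf("give 'n_epochs' or 'hours'")
    n_epochs <- as.integer(floor(hours * 3600 / spec$epoch_length))
  }
  h <- generate_hypnogram(spec, n_epochs, seed)
  rec <- generate_signals(h, spec, derive_seed(seed, 1L))
  list(recording = rec, hypnogram = h, spec = spec)
}
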