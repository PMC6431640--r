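# Shared fixtures, built in code and memoized across test files.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# A short rodent-preset recording with ground truth and features.
rodent_fixture <- function() {
  fixture("rodent_2h", function() {
    sim <- simulate_psg("rodent", hours = 2, seed = 424)
    grid <- make_epoch_grid(sim$recording, sim$spec$epoch_length)
    feats <- extract_features(sim$recording, grid, channel_config("ALL"))
    list(sim = sim, grid = grid, feats = feats)
  })
}

# A tiny two-channel sine/noise recording for I/O tests.
tiny_recording <- function(duration = 60, fs = 128) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  recording(list(
    signal_channel("EEG1", 50 * sin(2 * pi * 2 * t), fs,
                   passband = c(0.3, 30)),
    signal_channel("EMG1", stats::rnorm(length(t), sd = 10), fs)),
    id = "tiny")
}

random_hypnogram <- function(n, vocab = vocab_animal(),
                             epoch_length = 4,
                             p_special = 0) {
  pool <- as.character(vocab)
  if (p_special > 0) pool <- c(pool, SPECIAL_LABELS)
  labels <- sample(pool, n, replace = TRUE,
                   prob = c(rep((1 - p_special) / length(vocab),
                                length(vocab)),
                            if (p_special > 0)
                              rep(p_special / 2, 2)))
  hypnogram(labels, vocab, epoch_length = epoch_length)
}
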