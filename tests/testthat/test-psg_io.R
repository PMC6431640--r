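test_that("epoch grids floor the duration and reject bad input", {
  rec <- tiny_recording(duration = 61)
  g <- make_epoch_grid(rec, 30)
  expect_equal(g$n_epochs, 2L)
  # duration bracketing invariant
  expect_true(g$n_epochs * 30 <= rec$duration)
  expect_true(rec$duration < (g$n_epochs + 1) * 30)

  expect_equal(make_epoch_grid(30 * 3600, 4)$n_epochs, 27000L)
  expect_equal(make_epoch_grid(24 * 3600, 4)$n_epochs, 21600L)
  expect_error(make_epoch_grid(rec, 0), "positive")
  expect_error(make_epoch_grid(10, 30), "shorter")
})

test_that("modality is inferred from the label prefix with overrides", {
  expect_equal(infer_modality("EMG1"), "EMG")
  expect_equal(infer_modality("eeg Cz"), "EEG")
  expect_equal(infer_modality("Temp brain"), "TEMP")
  expect_equal(infer_modality("C3:A2"), "OTHER")
  expect_equal(infer_modality("C3:A2", c("C3:A2" = "EEG")), "EEG")
})

test_that("EDF write/read round-trips within 16-bit quantization", {
  set.seed(11)
  rec <- tiny_recording(duration = 60)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)

  expect_equal(length(back$channels), 2L)
  expect_equal(names(back$channels), c("EEG1", "EMG1"))
  expect_equal(length(back$channels$EEG1$samples), 60 * 128)
  expect_equal(back$channels$EMG1$modality, "EMG")
  expect_equal(back$channels$EEG1$sampling_rate, 128)
  for (ch in names(rec$channels)) {
    rng <- diff(range(rec$channels[[ch]]$samples))
    q <- rng / 65535  # one digital step
    expect_lt(max(abs(back$channels[[ch]]$samples -
                        rec$channels[[ch]]$samples)), q)
  }
  expect_equal(back$channels$EEG1$passband, c(0.3, 30))
  unlink(path)
})

test_that("an independent EDF reader agrees with the package writer", {
  rec <- tiny_recording(duration = 10)
  path <- tempfile(fileext = ".edf")
  write_edf(rec, path)
  out <- tempfile(fileext = ".csv")
  script <- sprintf(
    "import mne, numpy as np\nraw = mne.io.read_raw_edf(%s, preload=True, verbose='error')\nnp.savetxt(%s, raw.get_data().T, delimiter=',')\nprint(','.join(raw.ch_names))",
    deparse(path), deparse(out))
  res <- suppressWarnings(
    system2("python", "-", input = script, stdout = TRUE, stderr = TRUE))
  expect_true(file.exists(out))
  ch_line <- utils::tail(res, 1)
  expect_equal(strsplit(ch_line, ",")[[1]], c("EEG1", "EMG1"))
  ext <- utils::read.csv(out, header = FALSE)
  # mne scales EDF uV to volts
  expect_equal(ext[[1]] * 1e6, rec$channels$EEG1$samples,
               tolerance = 1e-3)
  unlink(c(path, out))
})

test_that("malformed EDF inputs raise format errors", {
  path <- tempfile(fileext = ".edf")
  writeBin(raw(100), path)
  expect_error(read_edf(path), "truncated")
  unlink(path)

  rec <- tiny_recording(duration = 10)
  write_edf(rec, path)
  # truncate the data section: declared records now exceed file length
  sz <- file.size(path)
  con <- file(path, "r+b")
  truncated <- readBin(con, "raw", sz - 4000)
  close(con)
  writeBin(truncated, path)
  expect_error(read_edf(path), "records")
  unlink(path)
  expect_error(read_edf(tempfile()), "not found")
})

test_that("hypnogram text dialects are read and validated", {
  vocab <- vocab_human()
  p <- tempfile()
  writeLines(c("W", "N1", "N2", "N3", "R"), p)
  h <- read_hypnogram(p, vocab, 30)
  expect_s3_class(h, "hypnogram")
  expect_equal(length(h), 5L)
  expect_equal(as.character(h)[5], "REM")

  writeLines(c("W", "Q", "N2"), p)
  expect_error(read_hypnogram(p, vocab, 30), "'Q' at line 2")

  writeLines(c("W", "ART", "N2", "UND"), p)
  h2 <- read_hypnogram(p, vocab, 30)
  expect_equal(as.character(h2), c("W", "ARTIFACT", "N2", "UNDETERMINED"))

  writeLines(character(0), p)
  expect_error(read_hypnogram(p, vocab, 30), "empty")
  unlink(p)
})

test_that("hypnogram CSV round trip preserves labels and comments", {
  h <- hypnogram(c("W", "NREM", "NREM", "REM", "ARTIFACT"),
                 vocab_animal(), epoch_length = 4)
  p <- tempfile(fileext = ".csv")
  write_hypnogram(h, p, comments = "config_hash: abc123",
                  extra = list(transition = c(1, 1, 1, 1, 1)))
  expect_true(any(grepl("config_hash", readLines(p))))
  back <- read_hypnogram(p, vocab_animal(), 4)
  expect_equal(as.character(back), as.character(h))
  unlink(p)
})

test_that("excluded epochs are the ARTIFACT/UNDETERMINED indices", {
  h <- hypnogram(c("W", "ARTIFACT", "NREM", "UNDETERMINED", "REM"),
                 vocab_animal(), epoch_length = 4)
  expect_equal(excluded_epochs(h), c(2L, 4L))
  clean <- hypnogram(rep("W", 5), vocab_animal(), epoch_length = 4)
  expect_length(excluded_epochs(clean), 0L)
  allbad <- hypnogram(rep("ARTIFACT", 4), vocab_animal(), epoch_length = 4)
  expect_equal(excluded_epochs(allbad), 1:4)
  # idempotent subset of the grid
  expect_true(all(excluded_epochs(h) %in% seq_along(h)))
  expect_identical(excluded_epochs(h), excluded_epochs(h))
})

test_that("channel CSV import honors the sampling-rate header", {
  p <- tempfile(fileext = ".csv")
  writeLines(c("# sampling_rate: 64",
               "EEG1,EMG1",
               paste(round(stats::rnorm(128 * 2), 4),
                     round(stats::rnorm(128 * 2), 4), sep = ",")), p)
  rec <- read_recording_csv(p)
  expect_equal(rec$channels$EEG1$sampling_rate, 64)
  expect_equal(rec$duration, 4)
  unlink(p)
})
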