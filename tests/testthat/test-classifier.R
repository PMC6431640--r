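# A linearly separable two-stage feature matrix built by construction.
separable_features <- function(n = 200, seed = 21) {
  set.seed(seed)
  x <- rbind(matrix(stats::rnorm(n / 2 * 3, mean = -3, sd = 0.3), ncol = 3),
             matrix(stats::rnorm(n / 2 * 3, mean = 3, sd = 0.3), ncol = 3))
  colnames(x) <- c("f1", "f2", "f3")
  structure(x, grid = epoch_grid(4, n),
            class = c("feature_matrix", class(x)))
}

separable_training <- function(n = 200) {
  vocab <- vocab_animal()
  labels <- c(rep("W", n / 2), rep("NREM", n / 2))
  structure(data.frame(recording = "sep",
                       epoch = seq_len(n),
                       stage = labels, stringsAsFactors = FALSE),
            seed = 1L, vocabulary = vocab,
            class = c("training_set", "data.frame"))
}

test_that("a separable fixture is classified perfectly at training epochs", {
  f <- separable_features()
  ts <- separable_training()
  m <- fit_stage_model(f, ts, seed = 3, ntree = 100)
  pred <- predict_stages(m, f)
  expect_equal(as.character(pred)[ts$epoch], ts$stage)
  scores <- attr(pred, "scores")
  expect_equal(dim(scores), c(200L, 3L))
  expect_true(all(abs(rowSums(scores) - 1) < 1e-9))
})

test_that("fitting is deterministic given the seed", {
  f <- separable_features()
  ts <- separable_training()
  m1 <- fit_stage_model(f, ts, seed = 7, ntree = 100)
  m2 <- fit_stage_model(f, ts, seed = 7, ntree = 100)
  expect_identical(attr(predict_stages(m1, f), "scores"),
                   attr(predict_stages(m2, f), "scores"))
})

test_that("degenerate training inputs are rejected", {
  f <- separable_features()
  ts <- separable_training()
  ts_one <- ts[ts$stage == "W", ]
  attributes(ts_one) <- attributes(ts)[c("seed", "vocabulary")]
  class(ts_one) <- c("training_set", "data.frame")
  expect_error(fit_stage_model(f, ts_one, seed = 1), "single stage")

  ts_bad <- ts
  ts_bad$epoch[1] <- 10000L
  expect_error(fit_stage_model(f, ts_bad, seed = 1), "outside")
})

test_that("prediction rejects mismatched feature names", {
  f <- separable_features()
  ts <- separable_training()
  m <- fit_stage_model(f, ts, seed = 3, ntree = 50)
  f2 <- f
  colnames(f2) <- c("f1", "f2", "other")
  expect_error(predict_stages(m, f2), "feature names")
})

test_that("consistency rules convert seconds to epochs by ceiling", {
  r <- consistency_rules(c(W = 4, NREM = 8, REM = 8), 4)
  expect_equal(unname(r[c("W", "NREM", "REM")]), c(1L, 2L, 2L))
  r12 <- consistency_rules(c(W = 12, NREM = 12, REM = 12), 4)
  expect_true(all(r12 == 3L))  # 12 s at 4 s epochs = 3 epochs
  r10 <- consistency_rules(c(REM = 10), 4)
  expect_equal(unname(r10[["REM"]]), 3L)
})

make_pred <- function(labels, scores = NULL, vocab = vocab_animal()) {
  h <- hypnogram(labels, vocab, epoch_length = 4)
  if (!is.null(scores)) attr(h, "scores") <- scores
  h
}

test_that("a sub-minimum bout is merged into the higher-scoring neighbor", {
  labels <- c("NREM", "NREM", "REM", "NREM", "NREM")
  h <- make_pred(labels)
  rules <- consistency_rules(c(NREM = 8, REM = 8), 4)
  out <- apply_consistency_rules(h, rules)
  expect_equal(as.character(out), rep("NREM", 5))

  # with scores favoring W on the violating epoch, merge follows scores
  labels2 <- c("W", "W", "REM", "NREM", "NREM")
  sc <- matrix(0.1, 5, 3, dimnames = list(NULL, c("W", "NREM", "REM")))
  sc[3, ] <- c(0.45, 0.10, 0.45)
  out2 <- apply_consistency_rules(make_pred(labels2, sc), rules)
  expect_equal(as.character(out2), c("W", "W", "W", "NREM", "NREM"))
})

test_that("smoothing yields no sub-minimum bouts and invents no stage", {
  set.seed(14)
  rules <- consistency_rules(c(W = 4, NREM = 8, REM = 12), 4)
  for (i in 1:20) {
    h <- random_hypnogram(300)
    sc <- matrix(stats::runif(300 * 3), 300, 3,
                 dimnames = list(NULL, c("W", "NREM", "REM")))
    out <- apply_consistency_rules(h, rules, scores = sc)
    b <- segment_bouts(out)
    req <- c(W = 1L, NREM = 2L, REM = 3L)[b$stage]
    expect_true(all(b$length >= req))
    expect_true(all(unique(as.character(out)) %in%
                      unique(as.character(h))))
  }
})

test_that("rules with all minima at one epoch are the identity", {
  h <- random_hypnogram(100)
  rules <- consistency_rules(c(W = 4, NREM = 4, REM = 4), 4)
  expect_equal(as.character(apply_consistency_rules(h, rules)),
               as.character(h))
})

test_that("ARTIFACT runs split bouts and are never relabeled", {
  labels <- c("NREM", "ARTIFACT", "REM", "NREM", "NREM")
  h <- make_pred(labels)
  rules <- consistency_rules(c(NREM = 8, REM = 8), 4)
  out <- apply_consistency_rules(h, rules)
  expect_equal(as.character(out)[2], "ARTIFACT")
  # the REM singleton merged into the NREM side, not the artifact
  expect_equal(as.character(out), c("NREM", "ARTIFACT", "NREM", "NREM",
                                    "NREM"))
})
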