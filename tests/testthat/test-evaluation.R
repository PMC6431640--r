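ahyp <- function(labels) hypnogram(labels, vocab_animal(), epoch_length = 4)

test_that("confusion counts match hand-derived examples", {
  ref <- ahyp(c("W", "W", "REM"))
  pred <- ahyp(c("W", "REM", "REM"))
  cc <- confusion_counts(pred, ref)
  expect_equal(cc$TP[cc$stage == "W"], 1L)
  expect_equal(cc$FN[cc$stage == "W"], 1L)
  expect_equal(cc$FP[cc$stage == "W"], 0L)
  expect_equal(cc$TP[cc$stage == "REM"], 1L)
  expect_equal(cc$FP[cc$stage == "REM"], 1L)
  expect_equal(cc$FN[cc$stage == "REM"], 0L)

  cc2 <- confusion_counts(pred, ref, exclusions = 2L)
  expect_equal(cc2$FN[cc2$stage == "W"], 0L)
  expect_equal(cc2$FP[cc2$stage == "REM"], 0L)
  expect_equal(sum(cc2$TP), 2L)

  same <- ahyp(rep(c("W", "NREM"), 5))
  cc3 <- confusion_counts(same, same)
  expect_equal(sum(cc3$TP), 10L)
  expect_true(all(cc3$FP == 0L) && all(cc3$FN == 0L))

  expect_error(confusion_counts(ahyp(c("W", "W")), ref), "grids")
})

test_that("confusion counts agree with a brute-force double loop", {
  brute <- function(pred, ref, excl) {
    stages <- as.character(vocab_animal())
    out <- matrix(0L, length(stages), 3,
                  dimnames = list(stages, c("TP", "FP", "FN")))
    for (i in seq_along(ref)) {
      if (i %in% excl) next
      r <- as.character(ref)[i]; p <- as.character(pred)[i]
      if (r %in% SPECIAL_LABELS) next
      if (p == r) out[r, "TP"] <- out[r, "TP"] + 1L
      else {
        out[r, "FN"] <- out[r, "FN"] + 1L
        if (p %in% stages) out[p, "FP"] <- out[p, "FP"] + 1L
      }
    }
    out
  }
  set.seed(99)
  for (i in 1:25) {
    n <- sample(20:120, 1)
    ref <- random_hypnogram(n, p_special = 0.1)
    pred <- random_hypnogram(n)
    excl <- sample.int(n, size = sample(0:5, 1))
    cc <- confusion_counts(pred, ref, excl)
    expected <- brute(pred, ref, excl)
    expect_equal(as.integer(cc$TP), unname(expected[, "TP"]))
    expect_equal(as.integer(cc$FP), unname(expected[, "FP"]))
    expect_equal(as.integer(cc$FN), unname(expected[, "FN"]))
    # marginal identities over evaluated epochs
    expect_equal(sum(cc$TP + cc$FN), attr(cc, "n_evaluated"))
    expect_equal(sum(cc$TP + cc$FP), attr(cc, "n_evaluated"))
  }
})

test_that("F-measure follows the harmonic-mean formulas with 0/0 = 0", {
  r <- f_measure(8, 2, 2)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$precision, 0.8)
  expect_equal(r$F, 0.8)

  expect_equal(f_measure(0, 3, 5)$F, 0)
  expect_equal(f_measure(0, 0, 0)$F, 0)
  # s = p = x implies F = x
  for (x in c(0.1, 0.5, 0.9)) {
    tp <- x * 100
    r <- f_measure(tp, 100 - tp, 100 - tp)
    expect_equal(r$F, x)
  }
  # F between min and max of s and p
  set.seed(4)
  counts <- matrix(sample(0:20, 60, replace = TRUE), ncol = 3)
  fm <- f_measure(counts[, 1], counts[, 2], counts[, 3])
  ok <- fm$sensitivity + fm$precision > 0
  expect_true(all(fm$F[ok] >= pmin(fm$sensitivity, fm$precision)[ok] - 1e-12))
  expect_true(all(fm$F[ok] <= pmax(fm$sensitivity, fm$precision)[ok] + 1e-12))
  expect_true(all(fm$F >= 0 & fm$F <= 1))
  expect_error(f_measure(-1, 0, 0), "non-negative")
})

test_that("micro overall F pools counts and equals epoch accuracy", {
  ref <- ahyp(c("W", "W", "REM"))
  pred <- ahyp(c("W", "REM", "REM"))
  cc <- confusion_counts(pred, ref)
  expect_equal(overall_f(cc), 2 / 3)

  set.seed(12)
  for (i in 1:10) {
    ref <- random_hypnogram(80)
    pred <- random_hypnogram(80)
    cc <- confusion_counts(pred, ref)
    acc <- mean(as.character(pred) == as.character(ref))
    expect_equal(overall_f(cc), acc)
  }
  perfect <- confusion_counts(ref, ref)
  expect_equal(overall_f(perfect), 1)
})

test_that("F ratings use inclusive lower band edges", {
  expect_equal(rate_f(0.92), "intra-scorer")
  expect_equal(rate_f(0.9), "intra-scorer")
  expect_equal(rate_f(0.85), "excellent")
  expect_equal(rate_f(0.8), "strong")
  expect_equal(rate_f(0.7), "average")
  expect_equal(rate_f(0.69), "inadequate")
  expect_equal(rate_f(c(0, 1)), c("inadequate", "intra-scorer"))
  expect_error(rate_f(1.2), "0, 1")
})

test_that("Hedges' g uses the pooled SD and magnitude bands", {
  r <- hedges_g(1.0, 0.5, 8, 0.0, 0.5, 8)
  expect_equal(r$g, 2.0)
  expect_equal(r$magnitude, "large")

  sw <- hedges_g(0.0, 0.5, 8, 1.0, 0.5, 8)
  expect_equal(sw$g, -2.0)
  expect_equal(sw$magnitude, "large")

  expect_equal(hedges_g(0.5, 0.2, 5, 0.5, 0.3, 7)$g, 0)
  expect_equal(hedges_g(0.5, 0.2, 5, 0.5, 0.3, 7)$magnitude, "miniscule")

  deg <- hedges_g(1, 0, 4, 0, 0, 4)
  expect_true(deg$degenerate)
  expect_true(is.nan(deg$g))
  same <- hedges_g(1, 0, 4, 1, 0, 4)
  expect_equal(same$g, 0)

  expect_equal(hedges_g(0.3, 1, 10, 0, 1, 10)$magnitude, "small")
  expect_equal(hedges_g(0.6, 1, 10, 0, 1, 10)$magnitude, "medium")
  expect_error(hedges_g(1, 0.1, 1, 0, 0.1, 5), "n >= 2")

  # small-sample correction shrinks toward zero
  expect_lt(hedges_g(1, 0.5, 5, 0, 0.5, 5, correction = TRUE)$g,
            hedges_g(1, 0.5, 5, 0, 0.5, 5)$g)
})

test_that("reclassification schemes map the human stages", {
  h <- hypnogram(c("W", "N1", "N2", "N3", "REM"), vocab_human(),
                 epoch_length = 30)
  expect_equal(as.character(reclassify(h, "N1_TO_N2")),
               c("W", "N2", "N2", "N3", "REM"))
  expect_equal(as.character(reclassify(h, "N1_TO_WAKE")),
               c("W", "W", "N2", "N3", "REM"))
  expect_equal(as.character(reclassify(h, "W1NREM23")),
               c("W", "W", "NREM", "NREM", "REM"))
  expect_equal(as.character(reclassify(h, "NREM123")),
               c("W", "NREM", "NREM", "NREM", "REM"))
  expect_identical(reclassify(h, "NONE"), h)
  expect_equal(as.character(hypnogram_vocab <- attr(reclassify(h, "NREM123"),
                                                    "vocabulary")),
               c("W", "NREM", "REM"))
  animal <- ahyp(c("W", "NREM"))
  expect_error(reclassify(animal, "NREM123"), "human vocabulary")
  # special labels pass through
  h2 <- hypnogram(c("N1", "ARTIFACT"), vocab_human(), epoch_length = 30)
  expect_equal(as.character(reclassify(h2, "NREM123")),
               c("NREM", "ARTIFACT"))
})

test_that("reclassify-then-evaluate commutes with label pre-mapping", {
  set.seed(31)
  for (scheme in c("N1_TO_WAKE", "N1_TO_N2", "W1NREM23", "NREM123")) {
    ref <- random_hypnogram(60, vocab_human(), 30)
    pred <- random_hypnogram(60, vocab_human(), 30)
    via_eval <- evaluate_agreement(pred, ref, scheme = scheme)
    direct <- evaluate_agreement(reclassify(pred, scheme),
                                 reclassify(ref, scheme))
    expect_equal(via_eval$per_stage$F, direct$per_stage$F)
    expect_equal(via_eval$overall_f, direct$overall_f)
  }
})

test_that("transition exclusion uses the predicted hypnogram's bouts", {
  pred <- ahyp(c("W", "W", "NREM", "NREM", "NREM", "W"))
  ref <- ahyp(c("W", "NREM", "NREM", "NREM", "NREM", "W"))
  # predicted bout interiors: only epoch 4; agreement there is perfect
  with_excl <- evaluate_agreement(pred, ref, exclude_transitions = TRUE)
  expect_equal(with_excl$overall_f, 1.0)
  expect_equal(with_excl$n_evaluated, 1L)

  without <- evaluate_agreement(pred, ref)
  expect_equal(without$overall_f, 5 / 6)

  ident <- evaluate_agreement(ref, ref, exclude_transitions = TRUE)
  expect_equal(ident$overall_f, 1.0)
  expect_true(all(ident$per_stage$F[ident$per_stage$TP +
                                      ident$per_stage$FN > 0] == 1))
})

test_that("agreement reports carry ratings, exclusions and provenance", {
  pred <- ahyp(c("W", "W", "NREM", "NREM", "NREM", "W"))
  ref <- ahyp(c("W", "NREM", "NREM", "NREM", "NREM", "ARTIFACT"))
  rep_ <- evaluate_agreement(pred, ref, exclude_epochs = 1L,
                             provenance = list(preset = "ALL"))
  # epoch 1 excluded by hand, epoch 6 is reference artifact
  expect_equal(rep_$n_evaluated, 4L)
  expect_equal(rep_$excluded_fraction, 2 / 6)
  expect_equal(rep_$options$preset, "ALL")
  df <- as.data.frame(rep_)
  expect_equal(df$stage[nrow(df)], "overall")
  expect_true(all(df$F >= 0 & df$F <= 1))
})

test_that("group comparison combines the t-test and Hedges' g", {
  set.seed(6)
  a <- stats::rnorm(12, 1, 0.5)
  b <- a - 0.5  # constant shift, paired
  r <- compare_groups(a, b, paired = TRUE)
  expect_true(r$degenerate)  # zero-variance differences flagged

  b2 <- stats::rnorm(12, 0.5, 0.5)
  r2 <- compare_groups(a, b2, paired = TRUE, bonferroni_m = 2L)
  expect_equal(r2$alpha, 0.025)
  ref_t <- stats::t.test(a, b2, paired = TRUE)
  expect_equal(r2$t, unname(ref_t$statistic))
  expect_equal(r2$p, ref_t$p.value)

  r3 <- compare_groups(a, a, paired = FALSE)
  expect_equal(r3$g, 0)
  expect_equal(r3$magnitude, "miniscule")

  # equal-SD groups differing by a shift: g = shift / SD
  x <- c(0.8, 1.0, 1.2, 1.4); y <- x - 0.5
  rg <- compare_groups(x, y, paired = FALSE)
  expect_equal(rg$g, 0.5 / stats::sd(x))
})
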