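test_that("repeat intervals paint residues with the out-of-scope rule", {
  ch <- line_chain(30)
  iv <- data.frame(start = 10, end = 19, class = 3)
  expect_equal(repeats_to_residue_labels(iv, ch),
               c(rep(0L, 9), rep(3L, 10), rep(0L, 11)))
  # class outside the solenoid scope maps to non-solenoid
  iv2 <- data.frame(start = 10, end = 19, class = "TIM-barrel")
  expect_equal(repeats_to_residue_labels(iv2, ch), rep(0L, 30))
  # class names are accepted
  iv3 <- data.frame(start = 1, end = 5, class = "alpha-solenoid")
  expect_equal(repeats_to_residue_labels(iv3, ch)[1:6],
               c(rep(3L, 5), 0L))
  # intervals beyond the register clip with a warning
  iv4 <- data.frame(start = 25, end = 40, class = 1)
  expect_warning(lab <- repeats_to_residue_labels(iv4, ch), "clipped")
  expect_equal(sum(lab == 1L), 6L)
})

test_that("overlapping intervals resolve by last-writer, matching the painter oracle", {
  set.seed(23)
  ch <- line_chain(40)
  for (rep in 1:20) {
    k <- sample(1:5, 1)
    iv <- data.frame(start = sample(1:35, k, TRUE))
    iv$end <- pmin(iv$start + sample(0:10, k, TRUE), 40)
    iv$class <- sample(c(1:3, 0L, 7L), k, TRUE)
    got <- suppressWarnings(repeats_to_residue_labels(iv, ch))
    want <- brute_paint_intervals(iv, ch$residues$resno, ch$residues$present)
    expect_identical(got, want)
  }
})

test_that("metrics match the worked 4-residue example", {
  rep4 <- score_labels(c(3L, 3L, 0L, 0L), c(3L, 0L, 0L, 0L))
  expect_equal(unname(rep4$precision[4]), 1.0)
  expect_equal(unname(rep4$recall[4]), 0.5)
  expect_equal(unname(rep4$f1[4]), 2 / 3)
  binrep <- score_labels(binarize_labels(c(3L, 3L, 0L, 0L)),
                         binarize_labels(c(3L, 0L, 0L, 0L)))
  expect_equal(binrep$mcc, 1 / sqrt(3), tolerance = 1e-12)
})

test_that("perfect and degenerate predictors hit the metric boundaries", {
  l <- c(0L, 1L, 1L, 2L, 3L, 3L, 0L)
  perfect <- score_labels(l, l)
  expect_true(all(perfect$precision[perfect$support > 0] == 1))
  expect_true(all(perfect$recall[perfect$support > 0] == 1))
  expect_equal(perfect$mcc, 1)
  allzero <- score_labels(l, rep(0L, 7))
  expect_equal(allzero$mcc, 0)
})

test_that("class-4 positions are excluded from scoring", {
  rep4 <- score_labels(c(3L, 4L, 0L, 4L), c(3L, 0L, 0L, 1L))
  expect_equal(rep4$n_scored, 2L)
  expect_equal(sum(rep4$confusion), 2)
  expect_equal(rep4$mcc, 1)
})

test_that("metrics equal the brute-force implementation on random label pairs", {
  set.seed(29)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    true <- sample(0:4, n, TRUE, prob = c(0.45, 0.2, 0.1, 0.2, 0.05))
    pred <- sample(0:3, n, TRUE)
    got <- score_labels(true, pred)
    want <- brute_metrics(true, pred)
    expect_equal(unname(got$confusion), want$confusion, ignore_attr = TRUE)
    expect_equal(unname(got$precision), want$precision, tolerance = 1e-10)
    expect_equal(unname(got$recall), want$recall, tolerance = 1e-10)
    expect_equal(unname(got$f1), want$f1, tolerance = 1e-10)
    expect_equal(got$mcc, want$mcc, tolerance = 1e-10)
  }
})

test_that("MCC is invariant under a consistent class permutation", {
  set.seed(37)
  true <- sample(0:3, 200, TRUE)
  pred <- sample(0:3, 200, TRUE)
  perm <- c(2L, 0L, 3L, 1L)
  expect_equal(score_labels(true, pred)$mcc,
               score_labels(perm[true + 1L], perm[pred + 1L])$mcc,
               tolerance = 1e-12)
})

test_that("binary collapse maps solenoid classes to 1 and keeps 4 excluded", {
  expect_equal(binarize_labels(c(0L, 1L, 2L, 3L)), c(0L, 1L, 1L, 1L))
  expect_equal(binarize_labels(rep(0L, 4)), rep(0L, 4))
  expect_equal(binarize_labels(c(1L, 4L)), c(1L, 4L))
  # composition with score_labels gives the 2-class brute force result
  set.seed(41)
  true <- sample(0:4, 150, TRUE)
  pred <- sample(0:3, 150, TRUE)
  got <- score_labels(binarize_labels(true), binarize_labels(pred))
  want <- brute_metrics(binarize_labels(true), binarize_labels(pred))
  expect_equal(got$mcc, want$mcc, tolerance = 1e-12)
  expect_equal(unname(got$f1[1:2]), want$f1[1:2], tolerance = 1e-12)
})

test_that("macro F1 skips zero-support classes", {
  rep4 <- score_labels(c(1L, 1L, 0L), c(1L, 1L, 0L))   # no class 2 or 3
  expect_equal(macro_f1(rep4), 1.0)
  expect_true(rep4$zero_support[3])
})
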