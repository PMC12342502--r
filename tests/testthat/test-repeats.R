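test_that("anchors split a predicted region into half-open repeats", {
  ch <- line_chain(70)
  classes <- rep(0L, 70)
  classes[10:59] <- 3L                       # region [10, 59]
  pred <- fake_prediction(classes, ch)
  rs <- split_repeats(pred, c(10, 20, 30, 40, 50), ch)
  iv <- t(vapply(rs$repeats, function(r) r$interval, c(start = 1L, end = 1L)))
  expect_equal(iv[, "start"], c(10L, 20L, 30L, 40L, 50L))
  expect_equal(iv[, "end"], c(19L, 29L, 39L, 49L, 59L))
  # trailing partial repeat kept when >= 3 residues
  classes2 <- rep(0L, 70)
  classes2[10:24] <- 1L
  rs2 <- split_repeats(fake_prediction(classes2, ch), c(10, 20), ch)
  expect_equal(length(rs2$repeats), 2L)
  expect_equal(rs2$repeats[[2]]$interval, c(start = 20L, end = 24L))
  # a 2-residue tail is dropped
  classes3 <- rep(0L, 70)
  classes3[10:21] <- 1L
  rs3 <- split_repeats(fake_prediction(classes3, ch), c(10, 20), ch)
  expect_equal(length(rs3$repeats), 1L)
})

test_that("invalid anchors are rejected", {
  ch <- line_chain(50)
  classes <- rep(0L, 50)
  classes[10:29] <- 3L
  classes[35:49] <- 3L                       # second, separate run
  pred <- fake_prediction(classes, ch)
  expect_error(split_repeats(pred, c(20, 10), ch), "increasing")
  expect_error(split_repeats(pred, c(5, 15), ch), "solenoid residues")
  expect_error(split_repeats(pred, c(10, 40), ch), "runs")
  expect_error(split_repeats(pred, 10, ch), "2 anchors")
})

test_that("kabsch recovers rigid transforms and matches the quaternion oracle", {
  set.seed(43)
  A <- matrix(rnorm(30, sd = 5), 10, 3)
  expect_lt(kabsch(A, A)$rmsd, 1e-9)
  # rigidly moved copy: zero RMSD, proper rotation recovered
  R <- solseg:::random_rotation()
  B <- A %*% R + matrix(rep(c(3, -2, 7), each = 10), 10, 3)
  fit <- kabsch(A, B)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_lt(max(abs(fit$A_aligned - B)), 1e-6)
  # symmetry of the minimized RMSD
  A2 <- A + matrix(rnorm(30, sd = 0.5), 10, 3)
  expect_equal(kabsch(A, A2)$rmsd, kabsch(A2, A)$rmsd, tolerance = 1e-9)
  # brute-force quaternion-grid oracle on random pairs
  for (rep in 1:5) {
    X <- matrix(rnorm(30, sd = 4), 10, 3)
    Y <- matrix(rnorm(30, sd = 4), 10, 3)
    expect_equal(kabsch(X, Y)$rmsd, brute_superposition_rmsd(X, Y),
                 tolerance = 1e-4)
  }
  expect_error(kabsch(A[1:2, ], A[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch(line, line), "collinear")
})

test_that("tm_score follows the formula with the d0 clamp", {
  set.seed(47)
  A <- matrix(rnorm(60, sd = 5), 20, 3)
  expect_equal(tm_score(A, A), 1.0)
  # L = 15 clamps d0 to exactly 0.5
  A15 <- matrix(rnorm(45, sd = 5), 15, 3)
  B15 <- A15 + matrix(rnorm(45, sd = 0.3), 15, 3)
  d <- sqrt(rowSums((A15 - B15)^2))
  expect_equal(tm_score(A15, B15, superpose = FALSE),
               mean(1 / (1 + (d / 0.5)^2)), tolerance = 1e-12)
  # random superposed pair equals direct evaluation
  B <- A + matrix(rnorm(60, sd = 1), 20, 3)
  al <- kabsch(A, B)$A_aligned
  expect_equal(tm_score(A, B), brute_tm(al, B), tolerance = 1e-12)
})

test_that("similarity matrices on jitter-free solenoids are tight and symmetric", {
  g <- solenoid_geometry(3, repeat_length = 34L, n_repeats = 5L,
                         jitter_sd = 0, seed = 3)
  sol <- make_solenoid(g)
  pred <- fake_prediction(sol$labels, sol$chain)
  rs <- split_repeats(pred, sol$repeat_boundaries, sol$chain)
  expect_equal(length(rs$repeats), 5L)
  sim <- similarity_matrices(rs)
  expect_lt(max(sim$rmsd), 0.1)
  expect_equal(sim$rmsd, t(sim$rmsd), tolerance = 1e-6)
  expect_equal(sim$tm, t(sim$tm), tolerance = 1e-6)
  expect_true(all(diag(sim$rmsd) == 0))
  expect_true(all(diag(sim$tm) == 1))
  expect_gt(min(sim$tm), 0.9)
})

test_that("alignment counts tally residues per position, ignoring gaps", {
  counts <- alignment_counts(rep("NI", 4))
  expect_equal(counts[1, "N"], 4L)
  expect_equal(counts[2, "I"], 4L)
  expect_equal(sum(counts), 8L)
  counts2 <- alignment_counts(c("DN", "KN", "SN", "EN", "DN"))
  expect_equal(counts2[1, "D"], 2L)
  expect_equal(counts2[1, c("K", "S", "E")], c(K = 1L, S = 1L, E = 1L))
  expect_equal(counts2[2, "N"], 5L)
  counts3 <- alignment_counts(c("-A", "-A"))
  expect_equal(sum(counts3[1, ]), 0L)
  expect_error(alignment_counts(c("AB", "ABC")), "ragged")
})

test_that("repeat outputs are written as PDBs with similarity tables", {
  g <- solenoid_geometry(1, repeat_length = 18L, n_repeats = 4L,
                         jitter_sd = 0, seed = 6)
  sol <- make_solenoid(g)
  rs <- split_repeats(fake_prediction(sol$labels, sol$chain),
                      sol$repeat_boundaries, sol$chain)
  dir <- tempfile()
  write_repeat_outputs(rs, sol$chain, dir)
  expect_true(all(file.exists(file.path(dir,
    c("repeat_001.pdb", "repeat_004.pdb", "rmsd.tsv", "tm.tsv",
      "counts.tsv", "superposed.pdb")))))
  r1 <- read_chain(file.path(dir, "repeat_001.pdb"), "A")
  expect_equal(chain_length(r1), 18L)
  expect_equal(r1$residues$resno, 1:18)      # author numbering preserved
})
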