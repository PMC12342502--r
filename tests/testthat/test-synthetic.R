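test_that("solenoid length, labels and determinism follow the geometry", {
  g <- solenoid_geometry(3, repeat_length = 34L, n_repeats = 6L,
                         jitter_sd = 0, seed = 5)
  sol <- make_solenoid(g)
  expect_equal(chain_length(sol$chain), 204L)
  expect_true(all(sol$labels == 3L))
  expect_equal(sol$repeat_boundaries, seq(1L, 204L, by = 34L))
  sol2 <- make_solenoid(g)
  expect_identical(chain_xyz(sol$chain), chain_xyz(sol2$chain))
  expect_error(solenoid_geometry(3, n_repeats = 2), "n_repeats")
  expect_error(solenoid_geometry(5), "class_id")
})

test_that("consecutive C-alpha distances stay within [2.9, 4.1] A after jitter", {
  for (cls in 1:3) for (jit in c(0, 0.6)) {
    g <- solenoid_geometry(cls, jitter_sd = jit, seed = 13)
    xyz <- chain_xyz(make_solenoid(g)$chain)
    st <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
    expect_gte(min(st), 2.9)
    expect_lte(max(st), 4.1)
  }
})

test_that("distance matrices band at the repeat length", {
  # mean distance at lag = repeat length is lower than at half and 1.5x lags
  g <- solenoid_geometry(1, repeat_length = 18L, n_repeats = 6L,
                         jitter_sd = 0.3, seed = 21)
  D <- ca_distance_matrix(make_solenoid(g)$chain)
  n <- nrow(D)
  lagmean <- function(l) mean(D[cbind(seq_len(n - l), seq_len(n - l) + l)])
  expect_lt(lagmean(18), lagmean(9))
  expect_lt(lagmean(18), lagmean(27))
})

test_that("off-diagonal periodicity peaks at the repeat length for every class, not for decoys", {
  # the signal the network learns: the lag-profile of the distance matrix
  # has its minimum (tightest contact) at the construction repeat length
  best_lag <- function(D, lags) {
    n <- nrow(D)
    prof <- vapply(lags, function(l)
      mean(D[cbind(seq_len(n - l), seq_len(n - l) + l)]), 1.0)
    lags[which.min(prof)]
  }
  set.seed(31)
  for (cls in 1:3) {
    hits <- 0L
    for (k in 1:8) {
      rl <- sample(list(15:25, 20:30, 30:40)[[cls]], 1)
      g <- solenoid_geometry(cls, repeat_length = rl, n_repeats = 6L,
                             jitter_sd = runif(1, 0.2, 0.6),
                             seed = sample.int(1e6, 1))
      D <- ca_distance_matrix(make_solenoid(g)$chain)
      bl <- best_lag(D, 8:50)
      if (abs(bl - rl) <= 2L) hits <- hits + 1L
    }
    expect_gte(hits, 7L)
  }
  # decoys show no repeat-length minimum in the same band
  miss <- 0L
  for (k in 1:8) {
    D <- ca_distance_matrix(make_globular_decoy(160, seed = k)$chain)
    n <- nrow(D)
    prof <- vapply(8:50, function(l)
      mean(D[cbind(seq_len(n - l), seq_len(n - l) + l)]), 1.0)
    # a genuine solenoid band dips several Angstroms below its neighbourhood;
    # decoy profiles stay comparatively flat
    if (max(prof) - min(prof) < 8) miss <- miss + 1L
  }
  expect_gte(miss, 6L)
})

test_that("globular decoys are connected, self-avoiding and compact", {
  for (s in 1:3) {
    d <- make_globular_decoy(150, seed = s)
    expect_equal(chain_length(d$chain), 150L)
    expect_true(all(d$labels == 0L))
    xyz <- chain_xyz(d$chain)
    st <- sqrt(rowSums((xyz[-1, ] - xyz[-150, ])^2))
    expect_gte(min(st), 3.6)
    expect_lte(max(st), 4.0)
    D <- as.matrix(dist(xyz))
    D[abs(row(D) - col(D)) <= 1] <- NA      # exclude self and neighbours
    expect_gte(min(D, na.rm = TRUE), 3.0)
    rg <- sqrt(mean(rowSums(sweep(xyz, 2, colMeans(xyz))^2)))
    expect_lt(rg, 3.2 * 150^(1 / 3))        # confined to the target sphere
  }
})

test_that("composites have exact label boundaries and optional register gaps", {
  g <- solenoid_geometry(3, repeat_length = 34L, n_repeats = 6L,
                         jitter_sd = 0.3, seed = 2)
  cm <- make_composite(40, g, 40, seed = 5)
  expect_equal(chain_length(cm$chain), 284L)
  expect_equal(cm$labels, c(rep(0L, 40), rep(3L, 204), rep(0L, 40)))
  expect_equal(cm$boundaries, c(41L, 244L))
  # junction steps remain bonded
  xyz <- chain_xyz(cm$chain)
  st <- sqrt(rowSums((xyz[-1, ] - xyz[-284, ])^2))
  expect_lte(max(st), 4.1)
  cg <- make_composite(40, g, 40, seed = 5, gap = TRUE)
  absent <- !cg$chain$residues$present
  expect_equal(sum(absent), 3L)
  expect_true(all(cg$labels[absent] == 4L))
})

test_that("corpus generation honours counts, totals and byte-identical manifests", {
  corpus <- make_corpus(c(6, 2, 1, 2), seed = 42)
  expect_equal(nrow(corpus$manifest), 11L)
  expect_equal(as.integer(table(factor(corpus$manifest$category,
                                       c("decoy", "beta", "alphabeta",
                                         "alpha")))),
               c(6L, 2L, 1L, 2L))
  expect_identical(make_corpus(c(6, 2, 1, 2), seed = 42)$manifest,
                   corpus$manifest)
  # per-structure residue totals in the manifest match the members
  expect_equal(corpus$manifest$n_residues,
               unname(vapply(corpus$structures[corpus$manifest$id],
                             function(e) chain_length(e$chain), 1L)))
  expect_true(all(c("train", "validation") %in% corpus$manifest$split))
})

test_that("a corpus survives a disk round trip", {
  corpus <- make_corpus(c(2, 1, 0, 1), seed = 9)
  dir <- tempfile()
  write_corpus(corpus, dir)
  for (id in corpus$manifest$id) {
    ch <- read_chain(file.path(dir, paste0(id, ".pdb")), "A")
    lab <- read_labels(file.path(dir, paste0(id, ".tsv")), ch)
    expect_equal(chain_length(ch),
                 chain_length(corpus$structures[[id]]$chain))
    expect_equal(lab, corpus$structures[[id]]$labels)
  }
})
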