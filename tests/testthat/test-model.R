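# The network itself: configuration contracts, output shapes, gradient
# correctness against finite differences, determinism and descent.

tiny_cfg <- function(...) {
  unet_config(base_filters = 2L, depth = 2L, dropout = c(0, 0),
              input_noise_sd = 0, tile_size = 16L, batch_size = 4L, ...)
}

rand_batch <- function(cfg, B = 2L, seed = 1) {
  set.seed(seed)
  tl <- cfg$tile_size
  t2 <- tl %/% 2L
  x <- array(runif(tl * tl * B), c(tl, tl, 1L, B))
  cls <- array(sample(0:4, t2 * t2 * B, TRUE), c(t2, t2, B))
  y <- array(0, c(t2, t2, 5L, B))
  for (b in seq_len(B)) y[, , , b] <- one_hot_target(cls[, , b])
  list(x = x, y = y)
}

test_that("invalid configurations are rejected", {
  expect_error(unet_config(depth = 1L), "depth")
  expect_error(unet_config(dropout = c(0.1, 0.2)), "dropout")
  expect_error(unet_config(dropout = rep(1.2, 4)), "dropout")
  expect_error(unet_config(tile_size = 40L), "output")   # not a multiple of 16
  expect_error(unet_config(tile_size = 32L, depth = 4L,
                           dropout = rep(0, 4)), "output")
})

test_that("the network maps a tile to a softmax probability stack of half size", {
  cfg <- tiny_cfg()
  set.seed(5)
  params <- solseg:::unet_init_params(cfg)
  b <- rand_batch(cfg, B = 3L)
  out <- solseg:::unet_pass(params, b$x, NULL, cfg, want_probs = TRUE)
  expect_equal(dim(out$probs), c(8L, 8L, 5L, 3L))
  sums <- apply(out$probs, c(1, 2, 4), sum)
  expect_lt(max(abs(sums - 1)), 1e-6)
  expect_true(all(out$probs >= 0 & out$probs <= 1))
  # default configuration contract: 128x128 input, 64x64x5 output shapes
  pd <- solseg:::unet_init_params(unet_config())
  expect_equal(dim(pd[[1]]), c(9L, 16L))        # 3x3 conv, 1 -> 16 filters
  expect_equal(dim(pd[[length(pd) - 1L]]), c(16L, 5L))  # 1x1 conv to 5 classes
})

test_that("doubling base_filters doubles every layer's filter count", {
  p1 <- solseg:::unet_init_params(tiny_cfg())
  set.seed(5)
  p2 <- solseg:::unet_init_params(unet_config(base_filters = 4L, depth = 2L,
                                              dropout = c(0, 0),
                                              input_noise_sd = 0,
                                              tile_size = 16L))
  w1 <- p1[seq(1, length(p1), by = 2)]
  w2 <- p2[seq(1, length(p2), by = 2)]
  expect_equal(vapply(w2[-length(w2)], ncol, 1L),
               2L * vapply(w1[-length(w1)], ncol, 1L))
  expect_equal(ncol(w2[[length(w2)]]), 5L)       # output classes fixed
})

test_that("analytic gradients match central finite differences", {
  cfg <- tiny_cfg()
  set.seed(42)
  params <- solseg:::unet_init_params(cfg)
  b <- rand_batch(cfg, B = 2L, seed = 2)
  res <- solseg:::unet_pass(params, b$x, b$y, cfg, want_grad = TRUE,
                            use_double = TRUE)
  loss_at <- function(p) solseg:::unet_pass(p, b$x, b$y, cfg,
                                            use_double = TRUE)$loss
  h <- 1e-5
  set.seed(3)
  for (li in sample(seq_along(params), 6)) {
    j <- sample(length(params[[li]]), 1)
    p2 <- params
    p2[[li]][j] <- p2[[li]][j] + h
    up <- loss_at(p2)
    p2[[li]][j] <- p2[[li]][j] - 2 * h
    dn <- loss_at(p2)
    fd <- (up - dn) / (2 * h)
    an <- res$grads[[li]][j]
    expect_lt(abs(fd - an) / max(1e-8, abs(fd) + abs(an)), 1e-4)
  }
})

test_that("training descends, checkpoints the best epoch and is seed-reproducible", {
  corpus <- list(
    a = make_solenoid(solenoid_geometry(1, n_repeats = 3, jitter_sd = 0.3,
                                        seed = 1))[c("chain", "labels")],
    b = make_globular_decoy(60, seed = 2),
    c = make_solenoid(solenoid_geometry(3, n_repeats = 3, jitter_sd = 0.3,
                                        seed = 3))[c("chain", "labels")],
    d = make_globular_decoy(70, seed = 4))
  cfg <- unet_config(base_filters = 2L, depth = 2L, dropout = c(0.1, 0.1),
                     tile_size = 32L, batch_size = 8L, seed = 7L)
  fit1 <- solenoid_net(corpus, cfg, epochs = 3)
  expect_s3_class(fit1, "solenoid_net")
  expect_equal(nrow(fit1$history), 3L)
  expect_lt(fit1$history$train_loss[3], fit1$history$train_loss[1])
  expect_equal(fit1$best_val_loss, min(fit1$history$val_loss))
  expect_equal(fit1$history$val_loss[fit1$best_epoch], fit1$best_val_loss)
  fit2 <- solenoid_net(corpus, cfg, epochs = 3)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  # inference determinism: repeated identical tiles -> identical stacks
  pred1 <- predict_chain(corpus$a$chain, model = fit1)
  pred2 <- predict_chain(corpus$a$chain, model = fit1)
  expect_identical(pred1$per_residue, pred2$per_residue)
})

test_that("a fitted model survives a save/load round trip", {
  corpus <- list(
    a = make_solenoid(solenoid_geometry(1, n_repeats = 3, jitter_sd = 0.3,
                                        seed = 1))[c("chain", "labels")],
    b = make_globular_decoy(60, seed = 2))
  cfg <- unet_config(base_filters = 2L, depth = 2L, dropout = c(0, 0),
                     tile_size = 32L, batch_size = 8L, seed = 7L)
  fit <- solenoid_net(corpus, cfg, epochs = 1)
  dir <- tempfile()
  save_model(fit, dir)
  fit2 <- load_model(dir)
  expect_equal(fit2$config$tile_size, 32L)
  p1 <- predict_chain(corpus$a$chain, model = fit)
  p2 <- predict_chain(corpus$a$chain, model = fit2)
  expect_equal(p1$per_residue, p2$per_residue)
})
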