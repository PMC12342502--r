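# Model fitting: corpus -> trained segmentation network, with validation-loss
# checkpointing and early stopping. The returned object follows the classic
# modelling idiom: print/summary/predict/plot methods on a classed fit.

#' Fit the solenoid segmentation network
#'
#' Trains the encoder-decoder network on a labelled corpus of chains. Each
#' chain's C-alpha distance matrix is normalized, padded and cropped into
#' training tiles (random diagonal crops, `ceiling(n/64)` per chain per
#' epoch); the validation structures contribute fixed overlapping tiles.
#' Optimisation is Adam on the categorical cross-entropy over all five label
#' channels; after every epoch the validation loss is evaluated and the
#' parameters with the lowest validation loss are retained (checkpointing);
#' training stops early when validation loss has not improved for
#' `config$early_stop_patience` epochs. Fully reproducible given the seed.
#'
#' @param corpus A [make_corpus()] result, or a list of `list(chain, labels)`
#'   entries.
#' @param config A [unet_config()].
#' @param val_fraction Fraction of structures held out for validation (at
#'   least one structure).
#' @param seed Seed for the train/validation split, initialisation, cropping,
#'   shuffling, input noise and dropout. Defaults to `config$seed`.
#' @param epochs Optional cap on training epochs (defaults to
#'   `config$max_epochs`).
#' @param anneal_epochs Horizon (in epochs) the learning-rate anneal is
#'   planned over; defaults to `epochs`. Setting it larger than `epochs`
#'   trains partway into the anneal and stops — the schedule analogue of
#'   early stopping.
#' @param verbose Print per-epoch losses?
#'
#' @return An object of class `solenoid_net`: the best parameters, the
#'   configuration, the per-epoch training history, and the split.
#' @export
solenoid_net <- function(corpus, config = unet_config(), val_fraction = 0.2,
                         seed = config$seed, epochs = config$max_epochs,
                         anneal_epochs = epochs, verbose = FALSE) {
  entries <- if (inherits(corpus, "solseg_corpus")) corpus$structures else corpus
  if (length(entries) < 2L) stop("need at least 2 structures to split")
  set.seed(seed)
  n <- length(entries)
  # stratify the held-out split by generator category when known, so the
  # checkpointing validation loss reflects every class
  strata <- if (inherits(corpus, "solseg_corpus"))
    corpus$manifest$category[match(names(entries), corpus$manifest$id)]
  else rep("all", n)
  val_idx <- sort(unlist(lapply(split(seq_len(n), strata), function(ix) {
    sample(ix, max(1L, round(val_fraction * length(ix))))
  }), use.names = FALSE))
  if (length(val_idx) >= n) val_idx <- val_idx[1L]
  ids <- names(entries)
  if (is.null(ids)) ids <- sprintf("structure_%03d", seq_len(n))

  tl <- config$tile_size
  pairs <- lapply(entries, function(e)
    prepare_pair(e$chain, validate_labels(e$labels, chain_length(e$chain)), tl))
  train_pairs <- pairs[-val_idx]
  val_tiles <- unlist(lapply(pairs[val_idx], inference_tiles), recursive = FALSE)

  params <- unet_init_params(config)
  m <- lapply(params, function(p) p * 0)
  v <- m
  tstep <- 0L
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  batches_of <- function(k, bs) split(seq_len(k), ceiling(seq_len(k) / bs))

  eval_loss <- function(tiles) {
    tot <- 0
    for (ix in batches_of(length(tiles), config$batch_size)) {
      b <- tiles_to_batch(tiles[ix])
      tot <- tot + unet_pass(params, b$x, b$y, config)$loss * length(ix)
    }
    tot / length(tiles)
  }

  # crops per structure per epoch: one per central-window length, so
  # per-structure sampling stays proportional to chain length at any tile
  n_crops <- vapply(train_pairs, function(p)
    as.integer(ceiling(p$n_residues / (tl / 2))), 1L)
  n_epochs <- min(epochs, config$max_epochs)
  steps_per_epoch <- ceiling(sum(n_crops) / config$batch_size)
  total_steps <- max(anneal_epochs, n_epochs) * steps_per_epoch

  stale <- 0L
  for (epoch in seq_len(n_epochs)) {
    crops <- unlist(lapply(seq_along(train_pairs), function(i) {
      replicate(n_crops[i], random_training_crop(train_pairs[[i]]),
                simplify = FALSE)
    }), recursive = FALSE)
    crops <- crops[sample(length(crops))]
    tr_loss <- 0
    for (ix in batches_of(length(crops), config$batch_size)) {
      b <- tiles_to_batch(crops[ix])
      step_seed <- sample.int(.Machine$integer.max, 1L)
      res <- unet_pass(params, b$x, b$y, config, training = TRUE,
                       seed = step_seed, want_grad = TRUE)
      if (!is.finite(res$loss))
        stop("non-finite training loss at epoch ", epoch,
             "; inspect the corpus or lower the learning rate")
      tr_loss <- tr_loss + res$loss * length(ix)
      tstep <- tstep + 1L
      lr <- scheduled_lr(config, tstep, total_steps)
      upd <- adam_update(params, res$grads, m, v, tstep, lr,
                         clip = config$grad_clip)
      params <- upd$params; m <- upd$m; v <- upd$v
    }
    tr_loss <- tr_loss / length(crops)
    vl <- eval_loss(val_tiles)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = tr_loss,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f%s", epoch, tr_loss, vl,
                      if (vl < best$loss) "  *" else ""))
    if (vl < best$loss) {
      best <- list(loss = vl, params = params, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
      if (stale >= config$early_stop_patience) break
    }
  }
  structure(list(params = best$params, config = config, history = hist,
                 best_epoch = best$epoch, best_val_loss = best$loss,
                 train_ids = ids[-val_idx], val_ids = ids[val_idx],
                 seed = seed),
            class = "solenoid_net")
}

#' @export
print.solenoid_net <- function(x, ...) {
  cat(sprintf("<solenoid_net> tile %d, base filters %d, depth %d; %d parameters\n",
              x$config$tile_size, x$config$base_filters, x$config$depth,
              sum(vapply(x$params, length, 1L))))
  cat(sprintf("  trained %d epochs on %d structures (%d validation); best validation loss %.4f at epoch %d\n",
              nrow(x$history), length(x$train_ids) + length(x$val_ids),
              length(x$val_ids), x$best_val_loss, x$best_epoch))
  invisible(x)
}

#' @export
summary.solenoid_net <- function(object, ...) {
  print(object)
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
plot.solenoid_net <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "categorical cross-entropy", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("training", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' Per-tile class-probability predictions
#'
#' Runs the network in inference mode (noise and dropout inactive) over a
#' list of tiles, preserving order.
#'
#' @param model A fitted [solenoid_net()] (or an [oracle_model()]).
#' @param tiles Tiles from [inference_tiles()].
#' @return A list of `tile/2 x tile/2 x 5` probability arrays.
#' @export
predict_tiles <- function(model, tiles) UseMethod("predict_tiles")

#' @export
predict_tiles.solenoid_net <- function(model, tiles) {
  out <- vector("list", length(tiles))
  bs <- model$config$batch_size
  done <- 0L
  for (ix in split(seq_along(tiles), ceiling(seq_along(tiles) / bs))) {
    b <- tiles_to_batch(tiles[ix], with_target = FALSE)
    probs <- unet_pass(model$params, b$x, NULL, model$config,
                       want_probs = TRUE)$probs
    for (k in seq_along(ix)) out[[ix[k]]] <- probs[, , , k]
    done <- done + length(ix)
  }
  out
}

#' Save / load a fitted network
#'
#' The parameters are stored as an RDS file together with a plain-text JSON
#' sidecar of the configuration and training history, so a model directory
#' is self-describing.
#'
#' @param model A [solenoid_net()] fit.
#' @param dir Model directory (created if needed).
#' @return `dir` (for `save_model`) or the restored `solenoid_net`.
#' @export
save_model <- function(model, dir) {
  stopifnot(inherits(model, "solenoid_net"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model$params, file.path(dir, "weights.rds"))
  meta <- list(config = unclass(model$config), history = model$history,
               best_epoch = model$best_epoch,
               best_val_loss = model$best_val_loss,
               train_ids = model$train_ids, val_ids = model$val_ids,
               seed = model$seed)
  jsonlite::write_json(meta, file.path(dir, "model.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "model.json"),
                              simplifyVector = TRUE)
  cfg <- do.call(unet_config, c(
    meta$config[c("base_filters", "depth", "dropout", "input_noise_sd",
                  "learning_rate", "batch_size", "max_epochs",
                  "early_stop_patience", "tile_size", "grad_clip",
                  "warmup_steps", "lr_schedule", "seed")]))
  structure(list(params = readRDS(file.path(dir, "weights.rds")),
                 config = cfg, history = as.data.frame(meta$history),
                 best_epoch = meta$best_epoch,
                 best_val_loss = meta$best_val_loss,
                 train_ids = meta$train_ids, val_ids = meta$val_ids,
                 seed = meta$seed),
            class = "solenoid_net")
}
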