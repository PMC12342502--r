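# Network configuration, parameter initialisation and low-level passes.
# The heavy lifting (im2col convolutions, pooling, transposed convolutions,
# softmax cross-entropy and its gradient) lives in src/unet.cpp.

#' Segmentation network configuration
#'
#' Hyperparameters of the encoder-decoder network that segments C-alpha
#' distance-matrix tiles into per-pixel solenoid classes. Defaults follow the
#' published training recipe: additive Gaussian input noise with standard
#' deviation `1e-4`, 3x3 stride-1 ELU convolutions with filter counts doubling
#' per encoder block from `base_filters`, 2x2 stride-2 max pooling and
#' transposed convolutions, dropout per block, Adam at learning rate 0.01,
#' batch size 64 and up to 100 epochs with early stopping and checkpointing on
#' validation loss.
#'
#' @param base_filters Filters in the first encoder block; doubled in each
#'   subsequent block.
#' @param depth Number of encoder blocks (poolings), mirrored by the
#'   decoder. The prediction is read from the central crop of the final
#'   full-resolution feature map, so a `tile_size` x `tile_size` tile yields
#'   a `tile_size/2` x `tile_size/2` x 5 class-probability map aligned with
#'   the tile's central target window.
#' @param dropout Numeric vector of length `depth`: fraction of activations
#'   dropped after the convolutions of each encoder block; mirrored in the
#'   decoder, with the last value also applied at the bottleneck.
#' @param input_noise_sd Standard deviation of the additive Gaussian noise
#'   applied to input tiles during training (regularisation; inactive at
#'   inference).
#' @param learning_rate Adam learning rate.
#' @param batch_size Tiles per gradient step.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before training stops.
#' @param tile_size Side length of the square input tile. Must be a multiple
#'   of `2^depth` with at least 4 pixels at the bottleneck.
#' @param grad_clip Global-norm gradient clipping threshold (stabilises the
#'   aggressive default learning rate on small corpora); `Inf` disables.
#' @param warmup_steps Linear learning-rate warmup over this many gradient
#'   steps (0 disables); avoids the early divergence an Adam step size of
#'   0.01 otherwise causes on freshly initialised weights.
#' @param lr_schedule Annealing of the learning rate after warmup:
#'   `"cosine"` (default) anneals from the nominal value to 5% of it at the
#'   final planned step — the nominal 0.01 sits above the stable regime for
#'   this network, so constant-rate training oscillates without converging,
#'   while a gradual anneal passes through the productive range; `"exp"`
#'   decays exponentially to 2%; `"constant"` keeps the nominal value.
#' @param seed Integer seed controlling initialisation, cropping, shuffling,
#'   noise and dropout; identical seeds give identical training runs.
#'
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(base_filters = 16L, depth = 4L,
                        dropout = c(0.1, 0.1, 0.2, 0.2),
                        input_noise_sd = 1e-4, learning_rate = 0.01,
                        batch_size = 64L, max_epochs = 100L,
                        early_stop_patience = 10L, tile_size = 128L,
                        grad_clip = 1, warmup_steps = 30L,
                        lr_schedule = c("cosine", "exp", "constant"),
                        seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  base_filters <- as.integer(base_filters)
  depth <- as.integer(depth)
  if (base_filters < 1L) stop("base_filters must be >= 1")
  if (depth < 2L) stop("depth must be >= 2")
  if (length(dropout) != depth)
    stop("dropout must have one fraction per encoder block (length ", depth, ")")
  if (any(dropout < 0 | dropout >= 1)) stop("dropout fractions must lie in [0, 1)")
  tile_size <- as.integer(tile_size)
  if (tile_size %% 2L^depth != 0L || tile_size / 2L^depth < 4L)
    stop("configuration cannot yield a ", tile_size / 2L, "x", tile_size / 2L,
         " output: tile_size must be a multiple of 2^depth with >= 4 bottleneck pixels")
  structure(list(base_filters = base_filters, depth = depth, dropout = dropout,
                 input_noise_sd = input_noise_sd,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 tile_size = tile_size, grad_clip = grad_clip,
                 warmup_steps = as.integer(warmup_steps),
                 lr_schedule = lr_schedule, seed = as.integer(seed)),
            class = "unet_config")
}

# Filters of encoder block i (1-based).
block_filters <- function(config, i) config$base_filters * 2L^(i - 1L)

# He-normal initialised weight matrix (rows = fan-in).
he_weight <- function(nrow, ncol, fan_in = nrow) {
  matrix(rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

# Parameter list in the fixed order the C++ pass expects:
# encoder blocks (W1,b1,W2,b2), bottleneck (W1,b1,W2,b2),
# decoder blocks (Wt,bt,W1,b1,W2,b2), output 1x1 conv (W,b).
unet_init_params <- function(config) {
  d <- config$depth
  f <- config$base_filters
  p <- list()
  add_conv <- function(p, cin, cout) {
    c(p, list(he_weight(9L * cin, cout), numeric(cout)))
  }
  for (i in seq_len(d)) {
    cin <- if (i == 1L) 1L else block_filters(config, i - 1L)
    p <- add_conv(p, cin, block_filters(config, i))
    p <- add_conv(p, block_filters(config, i), block_filters(config, i))
  }
  fb <- f * 2L^d
  p <- add_conv(p, block_filters(config, d), fb)
  p <- add_conv(p, fb, fb)
  for (i in seq_len(d)) {
    fs <- f * 2L^(d - i)                       # filters after this block
    p <- c(p, list(he_weight(4L * 2L * fs, fs, fan_in = 2L * fs),
                   numeric(fs)))               # transposed convolution
    p <- add_conv(p, 2L * fs, fs)              # after skip concatenation
    p <- add_conv(p, fs, fs)
  }
  p <- c(p, list(he_weight(f, 5L, fan_in = f), numeric(5L)))
  p
}

unet_cfg_list <- function(config) {
  list(depth = config$depth, dropout = as.numeric(config$dropout),
       noise_sd = config$input_noise_sd)
}

# One forward/backward pass over a batch. x: (T, T, 1, B) array;
# y: (T/2, T/2, 5, B) one-hot array or NULL. Returns list(loss, grads?, probs?).
unet_pass <- function(params, x, y, config, training = FALSE, seed = 0L,
                      want_grad = FALSE, want_probs = FALSE,
                      use_double = FALSE) {
  cpp_unet_pass(params, x, y, unet_cfg_list(config), training,
                as.integer(seed), want_grad, want_probs, use_double)
}

# Learning rate at a given step: linear warmup, then the configured anneal
# from the nominal rate towards its floor at the final planned step.
scheduled_lr <- function(config, step, total_steps) {
  lr <- config$learning_rate
  w <- config$warmup_steps
  if (w > 0 && step <= w) return(lr * step / w)
  if (total_steps <= w) return(lr)
  frac <- min((step - w) / max(total_steps - w, 1), 1)
  switch(config$lr_schedule,
         exp = lr * 0.02^frac,
         cosine = {
           floor_lr <- 0.05 * lr
           floor_lr + (lr - floor_lr) * 0.5 * (1 + cos(pi * frac))
         },
         lr)
}

# Adam update with global-norm gradient clipping (fused in C++);
# returns list(params, m, v).
adam_update <- function(params, grads, m, v, t, lr, clip = Inf,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  cpp_adam_update(params, grads, m, v, as.integer(t), lr, clip, beta1, beta2,
                  eps)
}
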