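# Training crops and overlapping inference slices of the padded matrices.
# Tiles slide along the main diagonal only: a tile at offset o is the block
# [o, o+tile) x [o, o+tile) of the padded matrix (0-based offsets), and its
# central target window is [o + tile/4, o + 3*tile/4).

#' One random training crop centred on the main diagonal
#'
#' Draws the tile offset uniformly from the integers `[0, total - tile]` and
#' extracts the tile-sized distance-matrix slice plus the central label
#' window of half the side length (data augmentation by random cropping).
#'
#' @param pair A [normalize_and_pad()] result.
#' @return A list with `input` (tile x tile numeric), `target`
#'   (tile/2 x tile/2 integer) and the 0-based `offset`.
#' @export
random_training_crop <- function(pair) {
  tl <- pair$tile
  off <- sample.int(pair$total - tl + 1L, 1L) - 1L
  extract_tile(pair, off)
}

#' Overlapping inference tiles covering the whole diagonal
#'
#' Tiles are placed at offsets 0, tile/2, tile, ..., total - tile, so their
#' central windows are disjoint and together cover `[tile/4, total - tile/4)`
#' — which contains every real residue's diagonal cell under the padding rule.
#'
#' @param pair A [normalize_and_pad()] result.
#' @return List of tiles as in [random_training_crop()], in offset order.
#' @export
inference_tiles <- function(pair) {
  tl <- pair$tile
  offs <- seq(0L, pair$total - tl, by = tl %/% 2L)
  lapply(offs, function(o) extract_tile(pair, o))
}

extract_tile <- function(pair, offset) {
  tl <- pair$tile
  sl <- offset + seq_len(tl)
  ctr <- offset + tl %/% 4L + seq_len(tl %/% 2L)
  list(input = pair$dist[sl, sl], target = pair$labels[ctr, ctr],
       offset = as.integer(offset))
}

#' One-hot encode a label target
#'
#' @param target Integer matrix with values in 0..4.
#' @return An array of shape `dim(target) x 5`; channel c+1 is the indicator
#'   of class c, so channels sum to 1 at every pixel.
#' @export
one_hot_target <- function(target) {
  if (any(!target %in% 0:4))
    stop("label value error: classes must be integers in 0..4")
  d <- dim(target)
  oh <- array(0, c(d, 5L))
  for (c in 0:4) {
    ch <- matrix(0, d[1], d[2])
    ch[target == c] <- 1
    oh[, , c + 1L] <- ch
  }
  oh
}

# Index (1-based) of the inference tile whose central window contains padded
# diagonal index q (1-based), and the pixel position within that window.
tile_for_index <- function(q, tile) {
  k <- (q - 1L - tile %/% 4L) %/% (tile %/% 2L)  # 0-based tile index
  pixel <- q - (k * (tile %/% 2L) + tile %/% 4L)
  list(tile = as.integer(k + 1L), pixel = as.integer(pixel))
}

# Assemble a list of tiles into the batch arrays the network consumes.
tiles_to_batch <- function(tiles, with_target = TRUE) {
  tl <- nrow(tiles[[1]]$input)
  B <- length(tiles)
  x <- array(0, c(tl, tl, 1L, B))
  for (i in seq_len(B)) x[, , 1L, i] <- tiles[[i]]$input
  if (!with_target) return(list(x = x, y = NULL))
  t2 <- tl %/% 2L
  y <- array(0, c(t2, t2, 5L, B))
  for (i in seq_len(B)) y[, , , i] <- one_hot_target(tiles[[i]]$target)
  list(x = x, y = y)
}
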