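# C-alpha distance matrix, segmentation-mask label matrix, normalization and
# block-aligned padding.

#' C-alpha distance matrix over the chain register
#'
#' Entry (i, j) is the Euclidean distance in Angstroms between the C-alpha
#' atoms at register positions i and j when both are modelled. Entries
#' involving an absent position are filled with 0; the class-4 channel of the
#' label matrix, not a distance sentinel, marks those cells as invalid.
#'
#' @param chain A [chain_structure()].
#' @return An n x n numeric matrix, n = register length.
#' @export
ca_distance_matrix <- function(chain) {
  xyz <- chain_xyz(chain)
  n <- nrow(xyz)
  p <- which(chain$residues$present)
  D <- matrix(0, n, n)
  if (length(p) > 1)
    D[p, p] <- as.matrix(stats::dist(xyz[p, , drop = FALSE]))
  D
}

#' Label matrix (segmentation mask) from per-residue classes
#'
#' Pixel (i, j) carries the shared solenoid class of residues i and j: the
#' class c in {1, 2, 3} if both residues have class c, 4 if either residue is
#' missing (class 4), and 0 otherwise. The diagonal therefore equals the
#' per-residue labels themselves.
#'
#' @param labels Integer class vector (values in 0..4).
#' @return An n x n integer matrix.
#' @export
build_label_matrix <- function(labels) {
  labels <- validate_labels(labels)
  n <- length(labels)
  A <- matrix(labels, n, n)
  B <- t(A)
  M <- matrix(0L, n, n)
  same <- A == B & A >= 1L & A <= 3L
  M[same] <- A[same]
  M[A == 4L | B == 4L] <- 4L
  M
}

#' Normalize a distance matrix and pad both matrices to a block-aligned size
#'
#' The distance matrix is divided by its largest real (non-missing) entry, so
#' real values lie in `[0, 1]` with maximum exactly 1 whenever any real
#' off-diagonal distance exists. Both matrices are then pre-padded by
#' `tile/4` rows/columns and post-padded so the total side length is
#' `tile * ceiling((n + tile/2) / tile)`. Padded cells carry label 4 and
#' distance 0. This padding guarantees that every real diagonal position
#' falls into exactly one central window of the stride-`tile/2` inference
#' tiling.
#'
#' @param dist Raw distance matrix from [ca_distance_matrix()].
#' @param labmat Label matrix from [build_label_matrix()] (same shape).
#' @param tile Tile side length (default 128).
#'
#' @return An object of class `padded_pair` with fields `dist`, `labels`,
#'   `n_residues`, `pre_pad`, `total`, `max_distance`, `tile`.
#' @export
normalize_and_pad <- function(dist, labmat, tile = 128L) {
  tile <- as.integer(tile)
  stopifnot(tile >= 4L, tile %% 4L == 0L)
  n <- nrow(dist)
  if (!is.matrix(dist) || ncol(dist) != n ||
      !is.matrix(labmat) || any(dim(labmat) != c(n, n)))
    stop("dist and labmat must be square matrices of identical shape")
  real <- labmat != 4L
  if (!any(real)) stop("no real distances: chain has no modelled residues")
  mx <- max(dist[real])
  nd <- if (mx > 0) dist / mx else dist
  nd[!real] <- 0
  pre <- tile %/% 4L
  total <- tile * as.integer(ceiling((n + tile / 2) / tile))
  D <- matrix(0, total, total)
  L <- matrix(4L, total, total)
  idx <- pre + seq_len(n)
  D[idx, idx] <- nd
  L[idx, idx] <- labmat
  structure(list(dist = D, labels = L, n_residues = n, pre_pad = pre,
                 total = total, max_distance = mx, tile = tile),
            class = "padded_pair")
}

#' @export
print.padded_pair <- function(x, ...) {
  cat(sprintf("<padded_pair> %d residues, padded %dx%d (pre-pad %d), max distance %.2f A, tile %d\n",
              x$n_residues, x$total, x$total, x$pre_pad, x$max_distance,
              x$tile))
  invisible(x)
}

# Build the padded pair for one (chain, labels) record at a given tile size.
prepare_pair <- function(chain, labels, tile) {
  normalize_and_pad(ca_distance_matrix(chain), build_label_matrix(labels),
                    tile = tile)
}

#' Write a matrix as a plain-text TSV grid (debug/fixture helper)
#' @param m A matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
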