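# Repeat splitting from user-supplied anchor indices, Kabsch superposition,
# TM-score, pairwise similarity matrices and alignment count tables.

#' Split a predicted solenoid region into repeat units at anchor indices
#'
#' Anchors are register indices of structurally equivalent positions, one per
#' repeat (as recorded by clicking equivalent residues in a structure
#' viewer). Repeat k spans `[anchor_k, anchor_{k+1})` intersected with the
#' contiguous run of identically-classified predicted solenoid residues
#' containing the anchors; the final partial repeat `[anchor_last, run end]`
#' is kept when it has at least 3 residues.
#'
#' @param pred A [predict_chain()] result.
#' @param anchors Strictly increasing register indices (>= 2), all inside one
#'   contiguous run of a single predicted solenoid class.
#' @param chain The [chain_structure()] the prediction came from (for
#'   coordinates and sequences).
#' @return An object of class `repeat_set`: intervals (half-open, register
#'   indices), per-repeat coordinates and one-letter sequences.
#' @export
split_repeats <- function(pred, anchors, chain) {
  stopifnot(inherits(pred, "prediction_result"))
  anchors <- as.integer(anchors)
  if (length(anchors) < 2L) stop("need at least 2 anchors")
  if (any(diff(anchors) <= 0L)) stop("anchors must be strictly increasing")
  cls <- register_classes(pred)
  acls <- cls[anchors]
  if (any(is.na(acls)) || any(acls == 0L))
    stop("anchors must lie on predicted solenoid residues")
  if (length(unique(acls)) != 1L)
    stop("anchors span different solenoid classes")
  # contiguous run of the anchor class containing the first anchor
  run <- cls == acls[1] & !is.na(cls)
  r <- rle(run)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ri <- which(r$values & starts <= anchors[1] & ends >= anchors[1])
  lo <- starts[ri]; hi <- ends[ri]
  if (any(anchors < lo | anchors > hi))
    stop("anchors span different solenoid runs")
  bounds <- c(anchors, hi + 1L)
  iv <- cbind(start = bounds[-length(bounds)], end = bounds[-1] - 1L)
  if (iv[nrow(iv), "end"] - iv[nrow(iv), "start"] + 1L < 3L)
    iv <- iv[-nrow(iv), , drop = FALSE]
  xyz <- chain_xyz(chain)
  res <- chain$residues
  repeats <- lapply(seq_len(nrow(iv)), function(k) {
    sel <- iv[k, "start"]:iv[k, "end"]
    sel <- sel[res$present[sel]]
    list(interval = iv[k, ], pos = sel, xyz = xyz[sel, , drop = FALSE],
         resno = res$resno[sel],
         seq = paste(bio3d::aa321(res$resid[sel]), collapse = ""))
  })
  structure(list(repeats = repeats, chain_id = chain$chain_id,
                 class_id = acls[1]),
            class = "repeat_set")
}

#' @export
print.repeat_set <- function(x, ...) {
  cat(sprintf("<repeat_set> chain %s, class %s: %d repeats of lengths %s\n",
              x$chain_id, class_names()[x$class_id + 1L], length(x$repeats),
              paste(vapply(x$repeats, function(r) length(r$pos), 1L),
                    collapse = ", ")))
  invisible(x)
}

#' Optimal rigid superposition of two paired point sets (Kabsch)
#'
#' Closed-form least-squares superposition via the SVD of the covariance
#' matrix, with a proper rotation enforced (determinant +1).
#'
#' @param A,B Equal-length n x 3 coordinate matrices (n >= 3, not collinear).
#' @return A list with `rotation` (3 x 3), `translation` (length 3; the map
#'   is `B ~ A %*% rotation + translation`), `rmsd` in Angstroms, and
#'   `A_aligned` (A after superposition onto B).
#' @export
kabsch <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B) || ncol(A) != 3 || ncol(B) != 3)
    stop("A and B must be equal-length n x 3 matrices")
  if (nrow(A) < 3) stop("degenerate input: need at least 3 points")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  if (any(svd(A0)$d[2] < 1e-8, svd(B0)$d[2] < 1e-8))
    stop("degenerate input: points are collinear")
  H <- t(A0) %*% B0
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  Aal <- A0 %*% R
  rmsd <- sqrt(mean(rowSums((Aal - B0)^2)))
  list(rotation = R, translation = cb - ca %*% R, rmsd = rmsd,
       A_aligned = sweep(Aal, 2, cb, `+`))
}

#' TM-score of a superposed pair of equal-length C-alpha sets
#'
#' `TM = mean(1 / (1 + (d_i/d0)^2))` over residues, with
#' `d0 = 1.24 * (L - 15)^(1/3) - 1.8` clamped to at least 0.5 Angstroms
#' (which makes d0 exactly 0.5 for L <= 21), normalised by the length L of
#' the target repeat.
#'
#' @param A,B Equal-length n x 3 matrices.
#' @param superpose Superpose with [kabsch()] first (default TRUE); if FALSE
#'   the coordinates are scored as given.
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(A, B, superpose = TRUE) {
  A <- as.matrix(A); B <- as.matrix(B)
  L <- nrow(B)
  if (superpose) A <- kabsch(A, B)$A_aligned
  d0 <- max(1.24 * max(L - 15, 0)^(1 / 3) - 1.8, 0.5)
  d <- sqrt(rowSums((A - B)^2))
  mean(1 / (1 + (d / d0)^2))
}

#' Pairwise RMSD and TM-score similarity matrices over a repeat set
#'
#' Every repeat pair is superposed with [kabsch()]; unequal-length repeats
#' are compared over the first `min(length)` residues of each (a note is
#' emitted), keeping the computation deterministic without an internal
#' alignment search.
#'
#' @param rs A [split_repeats()] result with at least 2 repeats.
#' @return An object of class `similarity_matrices` with symmetric `rmsd`
#'   (zero diagonal) and `tm` (unit diagonal) matrices.
#' @export
similarity_matrices <- function(rs) {
  stopifnot(inherits(rs, "repeat_set"))
  R <- length(rs$repeats)
  if (R < 2) stop("need at least 2 repeats")
  lens <- vapply(rs$repeats, function(r) nrow(r$xyz), 1L)
  if (any(lens < 3)) stop("every repeat must have at least 3 residues")
  if (length(unique(lens)) > 1)
    message("repeats differ in length; comparing common-length prefixes")
  rmsd <- matrix(0, R, R)
  tm <- diag(R)
  for (i in seq_len(R - 1)) for (j in (i + 1):R) {
    m <- min(lens[i], lens[j])
    A <- rs$repeats[[i]]$xyz[seq_len(m), , drop = FALSE]
    B <- rs$repeats[[j]]$xyz[seq_len(m), , drop = FALSE]
    fit <- kabsch(A, B)
    rmsd[i, j] <- rmsd[j, i] <- fit$rmsd
    t1 <- tm_score(fit$A_aligned, B, superpose = FALSE)
    tm[i, j] <- tm[j, i] <- t1
  }
  dimnames(rmsd) <- dimnames(tm) <-
    list(paste0("repeat_", seq_len(R)), paste0("repeat_", seq_len(R)))
  structure(list(rmsd = rmsd, tm = tm), class = "similarity_matrices")
}

#' @export
print.similarity_matrices <- function(x, ...) {
  cat("<similarity_matrices>\nRMSD (A):\n")
  print(round(x$rmsd, 3))
  cat("TM-score:\n")
  print(round(x$tm, 3))
  invisible(x)
}

#' Position-by-amino-acid count table of aligned repeat sequences
#'
#' Entry (p, aa) counts the repeats in which amino acid `aa` is observed at
#' alignment position p; gap characters (`-`) are not counted, so row sums
#' never exceed the number of sequences.
#'
#' @param sequences Character vector of equal-length (gapped) sequences.
#' @return Integer matrix, positions x amino acids.
#' @export
alignment_counts <- function(sequences) {
  if (!length(sequences)) stop("no sequences")
  nc <- nchar(sequences)
  if (length(unique(nc)) != 1)
    stop("ragged input: aligned sequences must have equal length")
  L <- nc[1]
  mat <- do.call(rbind, strsplit(sequences, ""))
  counts <- matrix(0L, L, length(AA1), dimnames = list(seq_len(L), AA1))
  for (p in seq_len(L)) {
    tb <- table(mat[, p])
    tb <- tb[names(tb) %in% AA1]
    counts[p, names(tb)] <- as.integer(tb)
  }
  counts
}

#' Write repeat-splitting outputs to a directory
#'
#' Writes per-repeat PDB files (`repeat_001.pdb`, ... with original author
#' numbering), a superposed multi-model PDB, `rmsd.tsv`, `tm.tsv`, and
#' `counts.tsv` (prefix-aligned sequence counts).
#'
#' @param rs A [split_repeats()] result.
#' @param chain The source [chain_structure()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_repeat_outputs <- function(rs, chain, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- chain$residues
  for (k in seq_along(rs$repeats)) {
    r <- rs$repeats[[k]]
    sub <- chain_structure(chain$chain_id, res$resno[r$pos], res$icode[r$pos],
                           res$resid[r$pos], r$xyz, rep(TRUE, length(r$pos)))
    write_chain_pdb(sub, file.path(dir, sprintf("repeat_%03d.pdb", k)))
  }
  sim <- similarity_matrices(rs)
  utils::write.table(sim$rmsd, file.path(dir, "rmsd.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(sim$tm, file.path(dir, "tm.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)
  m <- min(vapply(rs$repeats, function(r) nchar(r$seq), 1L))
  seqs <- vapply(rs$repeats, function(r) substr(r$seq, 1, m), "")
  utils::write.table(alignment_counts(seqs), file.path(dir, "counts.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  # superposed multi-model PDB: every repeat's prefix aligned onto repeat 1
  ref <- rs$repeats[[1]]$xyz[seq_len(m), , drop = FALSE]
  lines <- character(0)
  for (k in seq_along(rs$repeats)) {
    r <- rs$repeats[[k]]
    xyz <- r$xyz[seq_len(m), , drop = FALSE]
    al <- if (k == 1) xyz else kabsch(xyz, ref)$A_aligned
    tmp <- tempfile(fileext = ".pdb")
    sub <- chain_structure(chain$chain_id, r$resno[seq_len(m)],
                           rep("", m), res$resid[r$pos][seq_len(m)], al,
                           rep(TRUE, m))
    write_chain_pdb(sub, tmp)
    body <- grep("^ATOM", readLines(tmp), value = TRUE)
    unlink(tmp)
    lines <- c(lines, sprintf("MODEL     %4d", k), body, "ENDMDL")
  }
  writeLines(c(lines, "END"), file.path(dir, "superposed.pdb"))
  invisible(dir)
}
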