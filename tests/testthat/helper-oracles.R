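# Independent brute-force oracles the implementation is checked against.
# These deliberately use the most literal formulation of each definition and
# share no code with the package internals.

# Explicit double-loop Euclidean distance matrix.
brute_distance_matrix <- function(xyz, present) {
  n <- nrow(xyz)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (present[i] && present[j])
      D[i, j] <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
  }
  D
}

# Pairwise label-matrix rule applied cell by cell.
brute_label_matrix <- function(labels) {
  n <- length(labels)
  M <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- labels[i]; b <- labels[j]
    M[i, j] <- if (a == 4L || b == 4L) 4L
    else if (a == b && a %in% 1:3) a
    else 0L
  }
  M
}

# Confusion matrix, per-class one-vs-rest metrics and Gorodkin MCC computed
# from first principles.
brute_metrics <- function(true, pred) {
  keep <- true != 4L & pred != 4L
  true <- true[keep]; pred <- pred[keep]
  K <- 4L
  cm <- matrix(0, K, K)
  for (a in 0:3) for (b in 0:3) cm[a + 1, b + 1] <- sum(true == a & pred == b)
  prec <- rec <- f1 <- numeric(K)
  for (c in seq_len(K)) {
    tp <- cm[c, c]
    prec[c] <- if (sum(cm[, c]) > 0) tp / sum(cm[, c]) else 0
    rec[c] <- if (sum(cm[c, ]) > 0) tp / sum(cm[c, ]) else 0
    f1[c] <- if (prec[c] + rec[c] > 0) 2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  s <- sum(cm)
  num <- sum(diag(cm)) * s - sum(rowSums(cm) * colSums(cm))
  den <- sqrt(s^2 - sum(colSums(cm)^2)) * sqrt(s^2 - sum(rowSums(cm)^2))
  list(confusion = cm, precision = prec, recall = rec, f1 = f1,
       mcc = if (den > 0) num / den else 0)
}

# Last-writer interval painter.
brute_paint_intervals <- function(intervals, resno, present) {
  labels <- rep(0L, length(resno))
  for (i in seq_len(nrow(intervals))) {
    cls <- intervals$class[i]
    if (!(is.numeric(cls) && cls %in% 1:3)) cls <- 0L
    for (p in seq_along(resno))
      if (resno[p] >= intervals$start[i] && resno[p] <= intervals$end[i])
        labels[p] <- as.integer(cls)
  }
  labels[!present] <- 4L
  labels
}

# Best rigid superposition RMSD by quaternion sampling plus local refinement;
# independent of the closed-form solution.
brute_superposition_rmsd <- function(A, B, n_grid = 2000) {
  A0 <- sweep(A, 2, colMeans(A))
  B0 <- sweep(B, 2, colMeans(B))
  quat_rot <- function(q) {
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
             2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
             2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
           3, 3, byrow = TRUE)
  }
  obj_q <- function(q) sqrt(mean(rowSums((A0 %*% t(quat_rot(q)) - B0)^2)))
  qs <- matrix(rnorm(4 * n_grid), ncol = 4)
  vals <- apply(qs, 1, obj_q)
  best <- qs[which.min(vals), ]
  opt <- stats::optim(best, obj_q, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Direct evaluation of the TM-score formula on already-superposed sets.
brute_tm <- function(A, B) {
  L <- nrow(B)
  d0 <- max(1.24 * max(L - 15, 0)^(1 / 3) - 1.8, 0.5)
  mean(1 / (1 + (rowSums((A - B)^2)) / d0^2))
}
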