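# Benchmark metric machinery: converting repeat-interval predictions from
# third-party detectors to the per-residue scheme, per-class
# precision/recall/F1, the multiclass Matthews correlation coefficient, and
# the binary solenoid/non-solenoid collapse.

#' Convert repeat-interval predictions to per-residue labels
#'
#' Third-party detectors report repeats as residue intervals, optionally with
#' a class. Residues inside an interval receive its class; intervals whose
#' class is outside the solenoid scope (anything other than 1, 2, 3 or the
#' matching class names) are treated as non-solenoid; residues in no interval
#' are non-solenoid. Where intervals of different classes overlap, the later
#' interval wins. Intervals are in author numbering with inclusive ends;
#' parts outside the chain register are clipped with a warning.
#'
#' @param intervals Data frame with columns `start`, `end`, `class` (integer
#'   or name; anything unrecognised maps to 0).
#' @param chain The [chain_structure()] the intervals refer to.
#' @return Integer label vector over the chain register (absent positions 4).
#' @export
repeats_to_residue_labels <- function(intervals, chain) {
  res <- chain$residues
  n <- nrow(res)
  labels <- rep(0L, n)
  if (nrow(intervals)) {
    for (i in seq_len(nrow(intervals))) {
      cls <- interval_class(intervals$class[i])
      lo <- intervals$start[i]
      hi <- intervals$end[i]
      sel <- which(res$resno >= lo & res$resno <= hi)
      if (!length(sel) || lo < min(res$resno) || hi > max(res$resno))
        warning("interval ", lo, "-", hi,
                " extends outside the chain register; clipped")
      labels[sel] <- cls
    }
  }
  labels[!res$present] <- 4L
  labels
}

interval_class <- function(x) {
  if (is.numeric(x) && x %in% 1:3) return(as.integer(x))
  key <- tolower(gsub("[^a-z/]", "", tolower(as.character(x))))
  m <- c("beta" = 1L, "betasolenoid" = 1L,
         "alpha/beta" = 2L, "alphabeta" = 2L, "alphabetasolenoid" = 2L,
         "alpha" = 3L, "alphasolenoid" = 3L)
  if (key %in% names(m)) m[[key]] else 0L
}

#' Score per-residue predictions against ground truth
#'
#' One-vs-rest precision, recall and F1 per class in {0, 1, 2, 3} (0 when the
#' denominator is 0, with a zero-support flag; macro averages skip
#' zero-support classes), the multiclass Matthews correlation coefficient
#' from the full confusion matrix (Gorodkin's covariance generalisation),
#' and the confusion matrix itself (rows = true class, columns = predicted).
#' Positions where either vector carries class 4 (missing) are excluded from
#' scoring.
#'
#' @param true,pred Integer label vectors of equal length (values 0..4).
#' @return An object of class `metrics_report`.
#' @export
score_labels <- function(true, pred) {
  true <- validate_labels(true)
  pred <- validate_labels(pred, length(true))
  keep <- true != 4L & pred != 4L
  true <- true[keep]
  pred <- pred[keep]
  K <- 4L
  cm <- matrix(0, K, K, dimnames = list(true = 0:3, pred = 0:3))
  for (i in seq_along(true)) cm[true[i] + 1L, pred[i] + 1L] <-
    cm[true[i] + 1L, pred[i] + 1L] + 1
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / pmax(colSums(cm), 1), 0)
  rec <- ifelse(support > 0, tp / pmax(support, 1), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  # Gorodkin multiclass MCC from the confusion matrix
  s <- sum(cm)
  c_ <- sum(tp)
  tvec <- rowSums(cm)   # true occurrences per class
  pvec <- colSums(cm)   # predicted occurrences per class
  num <- c_ * s - sum(tvec * pvec)
  den <- sqrt(s^2 - sum(pvec^2)) * sqrt(s^2 - sum(tvec^2))
  mcc <- if (den > 0) num / den else 0
  structure(list(precision = prec, recall = rec, f1 = f1,
                 support = support, zero_support = support == 0,
                 mcc = mcc, confusion = cm, n_scored = length(true)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d residues scored, MCC %.4f\n", x$n_scored,
              x$mcc))
  tab <- data.frame(class = class_names(),
                    precision = round(x$precision, 4),
                    recall = round(x$recall, 4), f1 = round(x$f1, 4),
                    support = x$support)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Macro-averaged F1 over a set of classes
#'
#' Zero-support classes are skipped, matching common classification-report
#' conventions.
#'
#' @param report A [score_labels()] result.
#' @param classes Which classes to average over (default solenoid classes
#'   1..3).
#' @return Macro F1 (NA if every requested class has zero support).
#' @export
macro_f1 <- function(report, classes = 1:3) {
  i <- classes + 1L
  i <- i[!report$zero_support[i]]
  if (!length(i)) return(NA_real_)
  mean(report$f1[i])
}

#' Collapse labels to binary solenoid / non-solenoid
#'
#' Classes 1..3 map to 1, class 0 to 0; class 4 (missing) is preserved so
#' that [score_labels()] continues to exclude those positions.
#'
#' @param labels Integer label vector.
#' @return Integer vector with values in {0, 1, 4}.
#' @export
binarize_labels <- function(labels) {
  labels <- validate_labels(labels)
  out <- ifelse(labels %in% 1:3, 1L, labels)
  as.integer(out)
}
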