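#' @include AllClasses.R
NULL

metricColumns <- c("Accuy", "Precn", "Recal", "Fscore", "AUCscore")

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes.
#'
#' @param yTrue,yPred integer labels in `[1, n]`.
#' @param n number of classes.
#' @param classNames optional dimnames.
#' @return an `n x n` integer matrix of counts.
#' @export
#' @examples
#' confusionMatrix(c(1, 1, 2), c(1, 2, 2), 2)
confusionMatrix <- function(yTrue, yPred, n, classNames = NULL) {
  if (length(yTrue) != length(yPred)) {
    stop("yTrue and yPred differ in length")
  }
  if (length(yTrue) &&
      (min(c(yTrue, yPred)) < 1L || max(c(yTrue, yPred)) > n)) {
    stop("labels must lie in [1, n]")
  }
  cm <- matrix(tabulate((yTrue - 1L) * n + yPred, nbins = n * n),
               nrow = n, byrow = TRUE)
  if (!is.null(classNames)) dimnames(cm) <- list(classNames, classNames)
  cm
}

#' Per-class accuracy, precision, recall and F-score
#'
#' One-vs-rest metrics in percent for each class `c`: `TP = cm[c, c]`,
#' precision `TP / colsum`, recall `TP / rowsum`, accuracy
#' `(TP + TN) / total`, F-score the harmonic mean of the row's precision
#' and recall. Ratios of the form 0/0 are reported as 0 and flagged.
#'
#' @param cm confusion matrix from [confusionMatrix()].
#' @return numeric matrix (classes x 4 metric columns) with a logical
#'   `"flags"` attribute marking 0/0 cells.
#' @export
#' @examples
#' perClassMetrics(matrix(c(3, 2, 1, 4), 2, 2, byrow = TRUE))
perClassMetrics <- function(cm) {
  if (!length(cm) || sum(cm) == 0) stop("empty confusion matrix")
  if (nrow(cm) < 2L) stop("at least 2 classes required")
  n <- nrow(cm)
  total <- sum(cm)
  tp <- diag(cm)
  rowS <- rowSums(cm)
  colS <- colSums(cm)
  fn <- rowS - tp
  fp <- colS - tp
  tn <- total - tp - fn - fp
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(rownames(cm), metricColumns[1:4]))
  safeRatio <- function(num, den, col) {
    bad <- den == 0
    flags[bad, col] <<- TRUE
    out <- ifelse(bad, 0, num / pmax(den, 1))
    out
  }
  acc <- (tp + tn) / total * 100
  prec <- safeRatio(tp, colS, "Precn") * 100
  rec <- safeRatio(tp, rowS, "Recal") * 100
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  flags[, "Fscore"] <- prec + rec == 0
  out <- cbind(Accuy = acc, Precn = prec, Recal = rec, Fscore = f1)
  rownames(out) <- rownames(cm)
  attr(out, "flags") <- flags
  out
}

#' One-vs-rest AUC per class
#'
#' Rank-based (Mann-Whitney) area under the ROC curve of the class-`c`
#' score for class-`c` samples against the rest, with ties averaged.
#' Classes absent from `yTrue` (or covering all of it) get `NA` and are
#' excluded from macro averages.
#'
#' @param yTrue integer labels in `[1, n]`.
#' @param scores numeric matrix, one row per sample, one column per
#'   class (rows typically sum to 1).
#' @return numeric vector of per-class AUCs in percent (`NA` where
#'   undefined).
#' @export
#' @examples
#' aucOvr(c(1, 1, 2, 2),
#'        matrix(c(.9, .1, .8, .2, .3, .7, .2, .8), 4, 2, TRUE))
aucOvr <- function(yTrue, scores) {
  scores <- as.matrix(scores)
  n <- ncol(scores)
  vapply(seq_len(n), function(k) {
    pos <- yTrue == k
    nPos <- sum(pos)
    nNeg <- sum(!pos)
    if (nPos == 0L || nNeg == 0L) return(NA_real_)
    r <- rank(scores[, k])
    auc <- (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
    auc * 100
  }, numeric(1))
}

#' Unweighted macro average of a metric block
#'
#' @param metrics numeric matrix, classes x metrics; `NA` cells (flagged
#'   AUCs) are excluded from their column's mean only.
#' @return named numeric vector, one mean per column.
#' @export
macroAverage <- function(metrics) {
  if (!nrow(metrics)) stop("no metric rows")
  colMeans(metrics, na.rm = TRUE)
}

#' Micro accuracy of a confusion matrix
#'
#' `100 * trace / total`; equals `100 -` the classifier error rate on
#' the same predictions.
#'
#' @param cm confusion matrix.
#' @return percent accuracy.
#' @export
microAccuracy <- function(cm) 100 * sum(diag(cm)) / sum(cm)

#' Classifier error rate
#'
#' The tuning fitness: `100 * misclassified / total`.
#'
#' @param yTrue,yPred integer labels.
#' @return percent error in `[0, 100]`.
#' @export
#' @examples
#' classifierErrorRate(rep(1, 8), c(rep(1, 6), 2, 2)) # 25
classifierErrorRate <- function(yTrue, yPred) {
  if (!length(yTrue)) stop("empty evaluation set")
  if (length(yTrue) != length(yPred)) {
    stop("yTrue and yPred differ in length")
  }
  100 * mean(yTrue != yPred)
}

#' Build a per-class evaluation report
#'
#' Combines [perClassMetrics()] and [aucOvr()] into the Table-layout
#' block (class rows x Accuy/Precn/Recal/Fscore/AUCscore columns).
#'
#' @param yTrue integer labels.
#' @param yPred integer predictions.
#' @param scores score matrix for [aucOvr()] (may be `NULL`; AUC is then
#'   `NA`).
#' @param classNames class names, in label order.
#' @param split split tag, e.g. `"80:20 test"`.
#' @return an [EvaluationReport-class].
#' @export
buildReport <- function(yTrue, yPred, scores = NULL, classNames,
                        split = "test") {
  n <- length(classNames)
  cm <- confusionMatrix(yTrue, yPred, n, classNames)
  base <- perClassMetrics(cm)
  auc <- if (is.null(scores)) rep(NA_real_, n) else aucOvr(yTrue, scores)
  metrics <- cbind(base, AUCscore = auc)
  flags <- cbind(attr(base, "flags"), AUCscore = is.na(auc))
  new("EvaluationReport",
    metrics = metrics, flags = flags, classNames = classNames,
    split = split
  )
}

#' Report table with macro-average row
#'
#' @param report an [EvaluationReport-class].
#' @return numeric matrix with one row per class plus an `"Average"`
#'   row (unweighted means; undefined AUCs excluded from the AUC mean).
#' @export
reportTable <- function(report) {
  avg <- macroAverage(report@metrics)
  rbind(report@metrics, Average = avg)
}

#' Write an evaluation report
#'
#' CSV columns follow the standard table layout: `Class, Accuy, Precn,
#' Recal, Fscore, AUCscore`, one row per class plus the `Average` row.
#' An optional JSON mirror carries the same numbers plus the split tag.
#'
#' @param report an [EvaluationReport-class].
#' @param csvPath output CSV path.
#' @param jsonPath optional JSON path.
#' @return `csvPath`, invisibly.
#' @export
writeReport <- function(report, csvPath, jsonPath = NULL) {
  tab <- reportTable(report)
  df <- data.frame(Class = rownames(tab), round(tab, 2),
                   check.names = FALSE)
  utils::write.csv(df, csvPath, row.names = FALSE)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(
      list(split = report@split,
           metrics = as.data.frame(cbind(Class = rownames(tab),
                                         as.data.frame(tab)))),
      jsonPath, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(csvPath)
}
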