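# ROC curves, AUC and predictive error.

coerce_pm1 <- function(labels) {
  if (is.logical(labels)) return(ifelse(labels, 1, -1))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(-1, 1))) stop("numeric labels must be -1/+1")
    return(labels)
  }
  stop("labels must be -1/+1 or logical")
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the decision threshold over the distinct score values, giving the
#' staircase ROC curve from (0, 0) to (1, 1); tied scores enter as a single
#' diagonal segment, so the trapezoidal area equals the Mann-Whitney
#' probability that a random positive outranks a random negative, with ties
#' counted one half.
#'
#' @param scores Numeric decision scores, larger favouring the positive
#'   class.
#' @param labels -1/+1 (or logical) labels; both classes must be present.
#' @return A `roc_result` with `thresholds`, `fpr`, `tpr` and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- coerce_pm1(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (!all(is.finite(scores))) stop("scores must be finite")
  npos <- sum(labels > 0)
  nneg <- sum(labels < 0)
  if (npos == 0 || nneg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- labels[ord] > 0
  grp <- cumsum(!duplicated(s))          # tie groups of distinct scores
  tp <- cumsum(pos)
  fp <- cumsum(!pos)
  last <- which(grp != c(grp[-1], -1))   # last index within each group
  tpr <- c(0, tp[last] / npos)
  fpr <- c(0, fp[last] / nneg)
  auc <- sum((fpr[-1] - fpr[-length(fpr)]) *
               (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(thresholds = c(Inf, unique(s)), fpr = fpr, tpr = tpr,
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Export ROC curve points as TSV
#'
#' @param x A `roc_result`.
#' @param path Output path.
#' @export
write_roc_points <- function(x, path) {
  stopifnot(inherits(x, "roc_result"))
  write.table(data.frame(threshold = x$thresholds, fpr = x$fpr, tpr = x$tpr),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Macro-averaged one-vs-rest AUC for multiclass probabilities
#'
#' Each class's probability column is used as the score of a one-vs-rest
#' binary problem; the per-class AUCs are averaged with equal weight.
#' Classes absent from `labels` are skipped with a warning.
#'
#' @param proba `n x c` probability matrix with class names as columns.
#' @param labels Character vector (or factor / [label_set()]) of true
#'   classes.
#' @return The macro-average AUC.
#' @export
multiclass_auc <- function(proba, labels) {
  if (inherits(labels, "label_set")) labels <- labels$labels
  labels <- as.character(labels)
  classes <- colnames(proba)
  if (is.null(classes)) stop("probability matrix needs class column names")
  present <- classes %in% labels
  if (!any(present)) stop("no class in `labels` matches the columns")
  if (!all(present))
    warning("class(es) absent from labels, skipped: ",
            paste(classes[!present], collapse = ", "))
  aucs <- vapply(classes[present], function(cl) {
    roc_auc(proba[, cl], ifelse(labels == cl, 1, -1))$auc
  }, numeric(1))
  mean(aucs)
}

#' Misclassification rate
#'
#' @param predicted,actual Equal-length label vectors.
#' @return Fraction of mismatches, in `[0, 1]`.
#' @export
predictive_error <- function(predicted, actual) {
  if (length(predicted) != length(actual)) stop("length mismatch")
  mean(as.character(predicted) != as.character(actual))
}
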