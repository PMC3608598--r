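# Cross-validated selection of the sparsity weight and the repeated
# stratified-split evaluation protocol with per-feature relevance counts.

#' Default candidate grid for the sparsity weight
#'
#' @return Numeric vector `c(0.5, 1, 2, ..., 10, 15, 20)`.
#' @export
default_lam_grid <- function() c(0.5, 1:10, 15, 20)

# stratified fold assignment; every class must be able to reach >= 2 folds
# so that no training split loses a class entirely
stratified_folds <- function(labels, k) {
  labels <- as.character(labels)
  n <- length(labels)
  if (k < 2L) stop("need at least 2 folds")
  if (k > n) stop("more folds than samples")
  sizes <- table(labels)
  if (any(sizes < 2L))
    stop("class(es) with fewer than 2 samples cannot be stratified: ",
         paste(names(sizes)[sizes < 2], collapse = ", "),
         "; use a smaller k or more data")
  if (k == n) return(sample(n))                       # leave-one-out
  folds <- integer(n)
  for (cl in names(sizes)) {
    idx <- which(labels == cl)
    folds[idx] <- if (length(idx) >= k)
      sample(rep(seq_len(k), length.out = length(idx)))
    else
      sample(seq_len(k), length(idx))
  }
  folds
}

# stratified train/test split by fraction
stratified_split <- function(labels, fraction) {
  labels <- as.character(labels)
  train <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    ntr <- max(1L, min(length(idx) - 1L, round(length(idx) * fraction)))
    sample(idx, ntr)
  }), use.names = FALSE)
  sort(train)
}

fit_any <- function(X, labels, lam, reference = NULL) {
  if (length(labels$classes) == 2L)
    fit_binary(X, labels, lam)
  else
    fit_multiclass(X, labels, lam, reference = reference)
}

predict_labels <- function(model, X) {
  if (inherits(model, "lpsvm_binary")) {
    model$classes[ifelse(predict_binary(model, X) > 0, 1L, 2L)]
  } else {
    predict_class(model, X)
  }
}

test_auc <- function(model, X, labels) {
  if (inherits(model, "lpsvm_binary")) {
    y <- ifelse(labels$labels == model$classes[1], 1, -1)
    if (length(unique(y)) < 2L) return(NA_real_)
    roc_auc(decision_binary(model, X), y)$auc
  } else {
    multiclass_auc(predict_proba(model, X), labels)
  }
}

subset_labels <- function(labels, idx) {
  label_set(labels$labels[idx], samples = labels$samples[idx],
            classes = labels$classes)
}

#' Select the sparsity weight by stratified k-fold cross-validation
#'
#' For each candidate `lambda` the model is fitted on `k - 1` folds and the
#' misclassification error measured on the held-out fold; the `lambda` with
#' the smallest mean test error wins, ties going to the *largest* (sparsest)
#' candidate.  `folds = n` gives leave-one-out.
#'
#' @param Xt Transformed feature matrix or [abundance_table()].
#' @param labels A [label_set()] (or factor / character vector).
#' @param lam_grid Candidate `lambda` values.
#' @param folds Number of folds `k` (stratified by class).
#' @param seed Integer seed making the fold assignment reproducible.
#' @param reference Reference class for multiclass fits.
#' @return A `cv_report` with `lam_grid`, `mean_error`, `se_error`,
#'   `best_lam`, `folds` and `seed`.
#' @export
cv_lambda <- function(Xt, labels, lam_grid = default_lam_grid(), folds = 10,
                      seed = NULL, reference = NULL) {
  X <- as_transformed_matrix(Xt)
  labels <- as_label_set(labels)
  if (length(lam_grid) == 0 || any(lam_grid < 0))
    stop("lam_grid must be nonempty and nonnegative")
  run <- function() {
    fold_id <- stratified_folds(labels$labels, folds)
    err <- matrix(NA_real_, folds, length(lam_grid))
    for (f in seq_len(folds)) {
      tr <- which(fold_id != f)
      te <- which(fold_id == f)
      if (length(te) == 0L) next                      # small-class fold gap
      ltr <- subset_labels(labels, tr)
      lte <- subset_labels(labels, te)
      for (g in seq_along(lam_grid)) {
        model <- fit_any(X[tr, , drop = FALSE], ltr, lam_grid[g],
                         reference = reference)
        err[f, g] <- predictive_error(
          predict_labels(model, X[te, , drop = FALSE]), lte$labels)
      }
    }
    err
  }
  err <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  mean_error <- colMeans(err, na.rm = TRUE)
  se_error <- apply(err, 2, function(e) {
    e <- e[!is.na(e)]
    sd(e) / sqrt(length(e))
  })
  best <- max(which(mean_error == min(mean_error)))
  structure(list(lam_grid = as.numeric(lam_grid), mean_error = mean_error,
                 se_error = se_error, best_lam = lam_grid[best],
                 folds = folds, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report (%d-fold): best lambda = %g (error %.4f)\n",
              x$folds, x$best_lam,
              x$mean_error[match(x$best_lam, x$lam_grid)]))
  invisible(x)
}

#' Repeated stratified-split evaluation with relevance counts
#'
#' The data are split into a training and a test part `repeats` times; per
#' repeat the sparsity weight is (optionally) re-selected by
#' cross-validation *on the training part only*, the model fitted, the
#' selected features recorded, and test error and AUC measured.  A
#' feature's relevance count is the number of repeats in which it received
#' a nonzero coefficient.
#'
#' @param Xt Transformed feature matrix or [abundance_table()].
#' @param labels A [label_set()] (or factor / character vector).
#' @param lam Fixed `lambda`, or `"cv"` to re-select per repeat.
#' @param repeats Number of random splits `R`.
#' @param split_fraction Fraction of samples used for training.
#' @param lam_grid,folds Cross-validation settings when `lam = "cv"`.
#' @param seed Integer seed; the same seed reproduces the report exactly.
#' @param reference Reference class for multiclass fits.
#' @return A `relevance_report` with per-feature `counts`, `repeats`,
#'   `split_fraction`, `mean_test_error`, `mean_test_auc`, `seed` and a
#'   `per_repeat` data frame (chosen lambda, number selected, test error,
#'   test AUC).
#' @export
repeated_split_eval <- function(Xt, labels, lam = "cv", repeats = 100,
                                split_fraction = 0.5,
                                lam_grid = default_lam_grid(), folds = 10,
                                seed = NULL, reference = NULL) {
  X <- as_transformed_matrix(Xt)
  labels <- as_label_set(labels)
  if (repeats < 1L) stop("repeats must be >= 1")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must be in (0, 1)")
  feat <- colnames(X)
  if (is.null(feat)) feat <- paste0("F", seq_len(ncol(X)))
  run <- function() {
    counts <- stats::setNames(integer(length(feat)), feat)
    per <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      tr <- stratified_split(labels$labels, split_fraction)
      te <- setdiff(seq_along(labels$labels), tr)
      ltr <- subset_labels(labels, tr)
      lte <- subset_labels(labels, te)
      lam_r <- lam
      if (identical(lam, "cv")) {
        cv_seed <- sample.int(.Machine$integer.max, 1)
        lam_r <- cv_lambda(X[tr, , drop = FALSE], ltr, lam_grid = lam_grid,
                           folds = folds, seed = cv_seed,
                           reference = reference)$best_lam
      }
      model <- fit_any(X[tr, , drop = FALSE], ltr, lam_r,
                       reference = reference)
      sel <- selected_features(model)
      counts[sel] <- counts[sel] + 1L
      per[[r]] <- data.frame(
        repeat_id = r, lam = lam_r, n_selected = length(sel),
        test_error = predictive_error(
          predict_labels(model, X[te, , drop = FALSE]), lte$labels),
        test_auc = test_auc(model, X[te, , drop = FALSE], lte))
    }
    list(counts = counts, per = do.call(rbind, per))
  }
  out <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  structure(list(counts = out$counts, repeats = repeats,
                 split_fraction = split_fraction,
                 mean_test_error = mean(out$per$test_error),
                 mean_test_auc = mean(out$per$test_auc),
                 seed = seed, lam = lam, per_repeat = out$per),
            class = "relevance_report")
}

#' @export
print.relevance_report <- function(x, ...) {
  cat(sprintf(
    "relevance_report: %d repeats (train fraction %.2f), mean error %.3f, mean AUC %.3f\n",
    x$repeats, x$split_fraction, x$mean_test_error, x$mean_test_auc))
  top <- sort(x$counts[x$counts > 0], decreasing = TRUE)
  top <- utils::head(top, 10)
  if (length(top))
    cat("top features:",
        paste(sprintf("%s (%d)", names(top), top), collapse = ", "), "\n")
  invisible(x)
}
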