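# Fitting, prediction and feature extraction for the binary L1 LP-SVM and
# the multiclass joint-penalty LP-SVM.

# hinge + penalty objectives, used for the post-fit re-evaluation identity
binary_objective <- function(Xt, y, beta0, beta, lam) {
  sum(pmax(0, 1 - y * (as.matrix(Xt) %*% beta + beta0))) + lam * sum(abs(beta))
}

multiclass_objective <- function(Xt, Y, beta0, B, lam) {
  f <- as.matrix(Xt) %*% B + matrix(beta0, nrow(Xt), length(beta0),
                                    byrow = TRUE)
  sum(pmax(0, 1 - Y * f)) + lam * sum(apply(abs(B), 1, max))
}

#' One-against-rest class encoding
#'
#' Encodes `c` classes as a `n x (c-1)` matrix `Y` with `y_ik = +1` if
#' sample `i` belongs to class `k` and `-1` otherwise.  The reference class
#' (last, by default) gets no column: its parameters are pinned at zero, as
#' the softmax normalization makes one class redundant.
#'
#' @param labels A [label_set()] (or factor / character vector).
#' @param reference Class used as the reference; default the last class in
#'   first-appearance order.
#' @return A `class_encoding` with fields `Y`, `classes` (reference last)
#'   and `reference`.
#' @export
encode_labels <- function(labels, reference = NULL) {
  labels <- as_label_set(labels)
  classes <- labels$classes
  if (length(classes) < 2L) stop("need at least 2 classes")
  tab <- table(factor(labels$labels, levels = classes))
  if (any(tab == 0))
    stop("class(es) with zero samples: ",
         paste(names(tab)[tab == 0], collapse = ", "))
  if (!is.null(reference)) {
    if (!reference %in% classes) stop("unknown reference class: ", reference)
    classes <- c(setdiff(classes, reference), reference)
  }
  K <- length(classes) - 1L
  Y <- vapply(classes[seq_len(K)],
              function(cl) ifelse(labels$labels == cl, 1, -1),
              numeric(length(labels$labels)))
  Y <- matrix(Y, ncol = K, dimnames = list(labels$samples, classes[seq_len(K)]))
  structure(list(Y = Y, classes = classes, reference = classes[K + 1L]),
            class = "class_encoding")
}

as_label_set <- function(labels) {
  if (inherits(labels, "label_set")) return(labels)
  label_set(as.character(labels),
            samples = if (!is.null(names(labels))) names(labels) else
              paste0("S", seq_along(labels)),
            classes = if (is.factor(labels)) levels(droplevels(labels)) else
              NULL)
}

as_transformed_matrix <- function(Xt) {
  if (inherits(Xt, "abundance_table")) Xt$values else as.matrix(Xt)
}

#' Fit the binary L1-penalized LP-SVM
#'
#' Minimizes the soft-margin hinge loss plus `lam` times the L1 norm of the
#' coefficients (intercept unpenalized) by linear programming.  The larger
#' `lam`, the sparser the model.
#'
#' @param Xt Transformed feature matrix (n x m) or an [abundance_table()].
#' @param y Labels: -1/+1 vector, or a two-class [label_set()] (first class
#'   maps to +1).
#' @param lam Sparsity weight `lambda >= 0`.
#' @param transform Transform recorded for later prediction from raw counts.
#' @param backend,tol,max_iter Passed to [solve_lp()].
#' @return An `lpsvm_binary` model with `beta0`, `beta`, `lam`,
#'   `feature_ids`, `transform` and the attained `objective`.
#' @export
fit_binary <- function(Xt, y, lam, transform = "arcsine",
                       backend = "ipm", tol = 1e-9, max_iter = 200) {
  X <- as_transformed_matrix(Xt)
  classes <- NULL
  if (inherits(y, "label_set") || is.factor(y) || is.character(y)) {
    ls <- as_label_set(y)
    if (length(ls$classes) != 2L)
      stop("fit_binary needs exactly 2 classes, got ", length(ls$classes))
    classes <- ls$classes
    y <- ifelse(ls$labels == ls$classes[1], 1, -1)
  }
  m <- ncol(X)
  lp <- assemble_binary_lp(X, y, lam)
  sol <- solve_lp(lp, backend = backend, tol = tol, max_iter = max_iter)
  if (sol$status != "optimal")
    stop("LP solve failed with status '", sol$status, "'")
  beta <- sol$variables[lp$var_map$u] - sol$variables[lp$var_map$v]
  beta0 <- sol$variables[lp$var_map$intercept_pos] -
    sol$variables[lp$var_map$intercept_neg]
  # interior-point optima are approximately sparse; snap sub-threshold
  # coefficients so that prediction and the reported support agree
  beta[abs(beta) < 1e-6 * max(1, max(abs(beta)))] <- 0
  obj <- binary_objective(X, y, beta0, beta, lam)
  if (abs(obj - sol$objective_value) > 1e-6 * (1 + abs(obj)))
    warning(sprintf("objective re-evaluation mismatch: %.10g vs %.10g",
                    obj, sol$objective_value))
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("F", seq_len(m))
  structure(list(beta0 = beta0, beta = stats::setNames(beta, ids),
                 lam = lam, transform = transform, feature_ids = ids,
                 classes = classes, objective = obj, solver = sol$backend,
                 iterations = sol$iterations),
            class = "lpsvm_binary")
}

#' @export
print.lpsvm_binary <- function(x, ...) {
  cat(sprintf("L1 LP-SVM (binary): %d features, lambda = %g, %d selected\n",
              length(x$beta), x$lam, length(selected_features(x))))
  invisible(x)
}

#' Decision scores of a binary model
#'
#' `f(x) = beta0 + sum_j beta_j x_j` per sample.
#'
#' @param model An `lpsvm_binary` model.
#' @param Xt Transformed feature matrix with matching feature columns.
#' @return Numeric vector of scores.
#' @export
decision_binary <- function(model, Xt) {
  X <- as_transformed_matrix(Xt)
  if (!is.null(colnames(X)) && !identical(colnames(X), model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(X)))
      stop("feature mismatch; missing: ",
           paste(setdiff(model$feature_ids, colnames(X)), collapse = ", "))
    X <- X[, model$feature_ids, drop = FALSE]
  }
  if (ncol(X) != length(model$beta)) stop("feature count mismatch")
  drop(X %*% model$beta + model$beta0)
}

#' Predicted -1/+1 labels of a binary model
#'
#' A score of exactly zero predicts +1 (documented tie rule).
#'
#' @inheritParams decision_binary
#' @return Numeric vector of -1/+1 labels.
#' @export
predict_binary <- function(model, Xt) {
  ifelse(decision_binary(model, Xt) >= 0, 1, -1)
}

#' Fit the multiclass LP-SVM with joint L-infinity,1 penalty
#'
#' One-against-rest subproblems are fitted jointly: the penalty
#' `lambda * sum_j max_k |beta_jk|` charges each feature once for its
#' largest coefficient across subproblems, so all per-class classifiers
#' share one sparse feature set.  The reference class (last) has its
#' parameters pinned at zero.
#'
#' @param Xt Transformed feature matrix (n x m) or an [abundance_table()].
#' @param labels A [label_set()] (or factor / character vector), `c >= 2`
#'   classes.
#' @param lam Sparsity weight `lambda >= 0`.
#' @param reference Reference class; default the last in first-appearance
#'   order.
#' @param transform Transform recorded for later prediction from raw counts.
#' @param tol,max_iter Interior-point control.
#' @param degeneracy_eps Cost perturbation for the zero-cost split columns.
#' @return An `lpsvm_multiclass` model with `classes` (reference last),
#'   `beta0` (length c-1), coefficient matrix `B` (m x (c-1)), `lam`,
#'   `feature_ids`, `transform` and the attained `objective`.
#' @export
fit_multiclass <- function(Xt, labels, lam, reference = NULL,
                           transform = "arcsine", tol = 1e-9, max_iter = 200,
                           degeneracy_eps = 1e-9) {
  X <- as_transformed_matrix(Xt)
  if (lam < 0) stop("lam must be nonnegative")
  enc <- encode_labels(labels, reference = reference)
  K <- ncol(enc$Y)
  # retry ladder as in solve_lp: a stronger split-column perturbation
  # rescues the rare stall on highly degenerate (near-zero-model) optima
  for (a in list(c(degeneracy_eps, tol), c(1e-6, tol), c(1e-6, 100 * tol))) {
    r <- ipm_solve_joint_svm(X, enc$Y, lam, a[1] * max(1, lam), a[2],
                             max_iter)
    if (r$status == "optimal") break
  }
  if (r$status != "optimal")
    stop("LP solve failed with status '", r$status, "'")
  ids <- colnames(X)
  if (is.null(ids)) ids <- paste0("F", seq_len(ncol(X)))
  B <- matrix(r$B, ncol = K,
              dimnames = list(ids, enc$classes[seq_len(K)]))
  rowmax <- apply(abs(B), 1, max)
  B[rowmax < 1e-6 * max(1, max(rowmax)), ] <- 0    # snap, as in fit_binary
  beta0 <- as.numeric(r$beta0)
  obj <- multiclass_objective(X, enc$Y, beta0, B, lam)
  if (abs(obj - r$objective) > 1e-6 * (1 + abs(obj)))
    warning(sprintf("objective re-evaluation mismatch: %.10g vs %.10g",
                    obj, r$objective))
  structure(list(classes = enc$classes, reference = enc$reference,
                 beta0 = beta0, B = B, lam = lam, transform = transform,
                 feature_ids = ids, objective = obj,
                 iterations = r$iterations),
            class = "lpsvm_multiclass")
}

#' @export
print.lpsvm_multiclass <- function(x, ...) {
  cat(sprintf(
    "joint L-inf,1 LP-SVM: %d classes (ref '%s'), %d features, lambda = %g, %d selected\n",
    length(x$classes), x$reference, nrow(x$B), x$lam,
    length(selected_features(x))))
  invisible(x)
}

multiclass_scores <- function(model, Xt) {
  X <- as_transformed_matrix(Xt)
  if (!is.null(colnames(X)) && !identical(colnames(X), model$feature_ids)) {
    if (!all(model$feature_ids %in% colnames(X)))
      stop("feature mismatch; missing: ",
           paste(setdiff(model$feature_ids, colnames(X)), collapse = ", "))
    X <- X[, model$feature_ids, drop = FALSE]
  }
  f <- X %*% model$B + matrix(model$beta0, nrow(X), ncol(model$B),
                              byrow = TRUE)
  cbind(f, 0)  # reference class score pinned at 0
}

#' Class-membership probabilities from a multiclass model
#'
#' Scores are mapped through the multinomial-logit (softmax) transform with
#' the reference class pinned at score zero:
#' `p_k = exp(f_k) / sum_l exp(f_l)`.  Rows sum to one.
#'
#' @param model An `lpsvm_multiclass` model.
#' @param Xt Transformed feature matrix.
#' @return `n x c` probability matrix, columns in `model$classes` order.
#' @export
predict_proba <- function(model, Xt) {
  f <- multiclass_scores(model, Xt)
  f <- f - apply(f, 1, max)        # overflow guard
  p <- exp(f)
  p <- p / rowSums(p)
  colnames(p) <- model$classes
  p
}

#' Predicted class labels from a multiclass model
#'
#' The argmax of the class probabilities (equivalently of the raw scores);
#' ties go to the earliest class in `model$classes` order.
#'
#' @inheritParams predict_proba
#' @return Character vector of class labels.
#' @export
predict_class <- function(model, Xt) {
  p <- predict_proba(model, Xt)
  model$classes[apply(p, 1, which.max)]
}

#' Features retained by a fitted model
#'
#' Interior-point solutions are approximately rather than exactly sparse;
#' coefficients below `threshold * max(1, max |coef|)` are treated as zero.
#' For multiclass models a feature counts as selected when the largest
#' absolute coefficient in its row exceeds the threshold.
#'
#' @param model A fitted model.
#' @param threshold Relative snap tolerance (default `1e-6`).
#' @param ... Unused.
#' @return Character vector of feature identifiers, ordered by coefficient
#'   magnitude, descending.
#' @export
selected_features <- function(model, threshold = 1e-6, ...) {
  UseMethod("selected_features")
}

#' @rdname selected_features
#' @export
selected_features.lpsvm_binary <- function(model, threshold = 1e-6, ...) {
  mag <- abs(model$beta)
  thr <- threshold * max(1, max(mag))
  names(sort(mag[mag > thr], decreasing = TRUE))
}

#' @rdname selected_features
#' @export
selected_features.lpsvm_multiclass <- function(model, threshold = 1e-6, ...) {
  mag <- apply(abs(model$B), 1, max)
  names(mag) <- model$feature_ids
  thr <- threshold * max(1, max(mag))
  names(sort(mag[mag > thr], decreasing = TRUE))
}

#' High-level fit from counts and labels
#'
#' Composes the preprocessing pipeline (relative abundance, then the chosen
#' variance-stabilizing transform) with the binary or multiclass LP-SVM,
#' picked by the number of classes.  `transform = "auto"` consults
#' [choose_transform()].
#'
#' @param counts A [count_table()].
#' @param labels A [label_set()]; aligned to `counts` by sample identifier.
#' @param lam Sparsity weight.
#' @param transform `"arcsine"` (default), `"sqrt"`, `"none"` or `"auto"`.
#' @param reference Reference class for multiclass fits.
#' @param ... Passed to [fit_binary()] / [fit_multiclass()].
#' @return An `lpsvm_binary` or `lpsvm_multiclass` model.
#' @export
fit_lpsvm <- function(counts, labels, lam, transform = "arcsine",
                      reference = NULL, ...) {
  stopifnot(inherits(counts, "count_table"))
  labels <- align_labels(as_label_set(labels), counts)
  rel <- to_relative_abundance(counts)
  if (identical(transform, "auto")) transform <- choose_transform(rel)
  ab <- apply_transform(rel, transform)
  if (length(labels$classes) == 2L && is.null(reference))
    fit_binary(ab$values, labels, lam, transform = transform, ...)
  else
    fit_multiclass(ab$values, labels, lam, reference = reference,
                   transform = transform, ...)
}

#' @export
predict.lpsvm_binary <- function(object, newdata,
                                 type = c("class", "score"), ...) {
  type <- match.arg(type)
  Xt <- prepare_newdata(object, newdata)
  if (type == "score") return(decision_binary(object, Xt))
  pred <- predict_binary(object, Xt)
  if (!is.null(object$classes))
    object$classes[ifelse(pred > 0, 1L, 2L)]
  else pred
}

#' @export
predict.lpsvm_multiclass <- function(object, newdata,
                                     type = c("class", "prob"), ...) {
  type <- match.arg(type)
  Xt <- prepare_newdata(object, newdata)
  if (type == "prob") predict_proba(object, Xt)
  else predict_class(object, Xt)
}

# re-apply the recorded transform when predicting from raw counts; relative
# abundance uses the new sample's own row sum (no training-set coupling)
prepare_newdata <- function(model, newdata) {
  if (inherits(newdata, "count_table")) {
    ab <- apply_transform(to_relative_abundance(newdata), model$transform)
    ab$values
  } else {
    as_transformed_matrix(newdata)
  }
}
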