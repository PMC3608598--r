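# Poisson-Gamma (negative-binomial) count simulator with planted
# discriminative features.  Rates are drawn fresh per sample-feature cell
# from Gamma(shape, scale), counts as Poisson(rate), so each feature's
# marginal is negative binomial with mean gamma_mean and variance
# gamma_mean + gamma_var.

#' Specify a planted-feature count simulation
#'
#' Counts arise as Poisson draws with Gamma-distributed rates (mean
#' `gamma_mean`, variance `gamma_var`; shape `gamma_mean^2 / gamma_var`,
#' scale `gamma_var / gamma_mean`).  The first `n_relevant` features are
#' class-discriminative: their Gamma scale is multiplied by an effect
#' factor that depends on the sample's class.
#'
#' `effect` is either a length-`n_classes` vector (one multiplier per
#' class, shared by all planted features) or an `n_relevant x n_classes`
#' matrix giving each planted feature its own abundance profile across
#' classes.  The default plants strong, realistic profiles: for two classes
#' every planted feature is 100-fold elevated in the second class; for more
#' classes the abundance levels (equally spaced on the arcsine-transformed
#' proportion scale, top effect 100) are assigned cyclically so that every
#' planted feature takes every level and each class is separable
#' one-against-rest.
#'
#' @param n_per_class Samples per class.
#' @param n_classes Number of classes `c`.
#' @param n_features Number of features `m`.
#' @param n_relevant Number of planted discriminative features (the first
#'   `n_relevant` columns).
#' @param gamma_mean,gamma_var Mean and variance of the Gamma rate
#'   distribution.
#' @param effect Effect multipliers (see Details); `NULL` for the default.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A `sim_spec`.
#' @export
sim_spec <- function(n_per_class = 50, n_classes = 2, n_features = 1000,
                     n_relevant = 5, gamma_mean = 100, gamma_var = 1000,
                     effect = NULL, seed = NULL) {
  if (n_per_class < 1 || n_classes < 2 || n_features < 1)
    stop("need n_per_class >= 1, n_classes >= 2, n_features >= 1")
  if (n_relevant > n_features) stop("n_relevant exceeds n_features")
  if (gamma_mean <= 0 || gamma_var <= 0)
    stop("gamma_mean and gamma_var must be positive")
  if (is.null(effect))
    effect <- default_effect(n_classes, n_features, n_relevant)
  if (is.matrix(effect)) {
    if (!all(dim(effect) == c(n_relevant, n_classes)))
      stop("effect matrix must be n_relevant x n_classes")
  } else if (length(effect) != n_classes) {
    stop("effect vector must have one entry per class")
  }
  if (any(effect <= 0)) stop("effect multipliers must be positive")
  structure(list(n_per_class = n_per_class, n_classes = n_classes,
                 n_features = n_features, n_relevant = n_relevant,
                 gamma_mean = gamma_mean, gamma_var = gamma_var,
                 effect = effect, seed = seed),
            class = "sim_spec")
}

# Effect levels equally spaced on the arcsine-transformed expected-proportion
# scale between 1 and `top`, assigned cyclically across planted features.
default_effect <- function(n_classes, n_features, n_relevant, top = 100) {
  if (n_classes == 2L) return(c(1, top))
  theta <- function(e) asin(sqrt(e / ((n_features - n_relevant) +
                                        n_relevant * e)))
  th <- seq(theta(1), theta(top), length.out = n_classes)
  p <- sin(th)^2
  levels <- (n_features - n_relevant) * p / (1 - n_relevant * p)
  shift <- function(lv, s) lv[((seq_len(n_classes) - 1 + s) %% n_classes) + 1]
  t(vapply(seq_len(n_relevant), function(j) {
    # cyclic shifts of the level ladder; once exhausted, shifts of the
    # reversed ladder, so no two planted features share a profile
    if (j <= n_classes) shift(levels, j - 1)
    else shift(rev(levels), j - n_classes - 1)
  }, numeric(n_classes)))
}

#' @export
print.sim_spec <- function(x, ...) {
  cat(sprintf(
    "sim_spec: %d classes x %d samples, %d features (%d planted), Gamma(mean %g, var %g)\n",
    x$n_classes, x$n_per_class, x$n_features, x$n_relevant,
    x$gamma_mean, x$gamma_var))
  invisible(x)
}

#' The two study simulation designs
#'
#' @return A list with a binary spec (2 x 50 samples, 1000 features, 5
#'   planted) and a four-class spec (4 x 50, otherwise identical).
#' @export
default_sim_specs <- function() {
  list(binary = sim_spec(n_per_class = 50, n_classes = 2,
                         n_features = 1000, n_relevant = 5),
       fourclass = sim_spec(n_per_class = 50, n_classes = 4,
                            n_features = 1000, n_relevant = 5))
}

#' Simulate a planted-feature metagenomic count dataset
#'
#' @param spec A [sim_spec()].
#' @return A `sim_dataset` with `counts` ([count_table()]), `labels`
#'   ([label_set()]), `true_features` (identifiers of the planted
#'   features) and the `spec` echo.
#' @export
simulate_counts <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  shape <- spec$gamma_mean^2 / spec$gamma_var
  scale <- spec$gamma_var / spec$gamma_mean
  effmat <- if (is.matrix(spec$effect)) spec$effect else
    matrix(spec$effect, nrow = max(spec$n_relevant, 1L),
           ncol = spec$n_classes, byrow = TRUE)
  n <- spec$n_per_class * spec$n_classes
  m <- spec$n_features
  classes <- paste0("C", seq_len(spec$n_classes))
  cl <- rep(seq_len(spec$n_classes), each = spec$n_per_class)
  draw <- function() {
    counts <- matrix(0, n, m)
    for (g in seq_len(spec$n_classes)) {
      rows <- which(cl == g)
      for (j in seq_len(m)) {
        eff <- if (j <= spec$n_relevant) effmat[j, g] else 1
        rate <- rgamma(length(rows), shape = shape, scale = scale * eff)
        counts[rows, j] <- rpois(length(rows), rate)
      }
    }
    counts
  }
  counts <- if (is.null(spec$seed)) draw() else
    withr::with_seed(spec$seed, draw())
  features <- sprintf("OTU%04d", seq_len(m))
  samples <- sprintf("S%03d", seq_len(n))
  structure(list(
    counts = count_table(counts, samples = samples, features = features),
    labels = label_set(classes[cl], samples = samples, classes = classes),
    true_features = features[seq_len(spec$n_relevant)],
    spec = spec),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  print(x$spec)
  print(x$counts)
  invisible(x)
}

#' Run the planted-feature simulation study
#'
#' Per repeat a fresh dataset is simulated, proportions are
#' arcsine-transformed, the samples are split into stratified training and
#' test halves, the sparsity weight is selected by cross-validation on the
#' training half only, the model is fitted and the held-out half scored.
#' Reported are per-repeat test AUC (macro one-vs-rest for multiclass),
#' test error, the number of selected features and the recovery count of
#' each planted feature.
#'
#' @param spec A [sim_spec()]; its `seed` is ignored in favour of the
#'   per-repeat seed schedule derived from `seed`.
#' @param repeats Number of simulated repeats.
#' @param lam_grid Candidate sparsity weights for the training-only CV.
#' @param folds CV folds within the training half.
#' @param split_fraction Fraction of samples in the training half.
#' @param seed Integer master seed for the dataset/split/CV schedule.
#' @return A `simulation_study` with `per_repeat`, planted-feature
#'   `recovery` counts, `mean_test_auc`, `mean_selected`,
#'   `mean_test_error`, and echoes of the settings.
#' @export
simulation_study <- function(spec, repeats = 20, lam_grid = 1:10, folds = 2,
                             split_fraction = 0.5, seed = 1) {
  stopifnot(inherits(spec, "sim_spec"))
  run <- function() {
    data_seeds <- sample.int(.Machine$integer.max, repeats)
    recovery <- stats::setNames(integer(spec$n_relevant),
                                sprintf("OTU%04d", seq_len(spec$n_relevant)))
    per <- vector("list", repeats)
    for (r in seq_len(repeats)) {
      spec_r <- spec
      spec_r$seed <- data_seeds[r]
      ds <- simulate_counts(spec_r)
      ab <- transform_arcsine(to_relative_abundance(ds$counts))
      tr <- stratified_split(ds$labels$labels, split_fraction)
      te <- setdiff(seq_along(ds$labels$labels), tr)
      ltr <- subset_labels(ds$labels, tr)
      lte <- subset_labels(ds$labels, te)
      Xtr <- ab$values[tr, , drop = FALSE]
      Xte <- ab$values[te, , drop = FALSE]
      cv_seed <- sample.int(.Machine$integer.max, 1)
      lam_r <- cv_lambda(Xtr, ltr, lam_grid = lam_grid, folds = folds,
                         seed = cv_seed)$best_lam
      model <- fit_any(Xtr, ltr, lam_r)
      sel <- selected_features(model)
      hit <- intersect(ds$true_features, sel)
      recovery[hit] <- recovery[hit] + 1L
      per[[r]] <- data.frame(
        repeat_id = r, lam = lam_r, n_selected = length(sel),
        n_planted_recovered = length(hit),
        test_error = predictive_error(predict_labels(model, Xte),
                                      lte$labels),
        test_auc = test_auc(model, Xte, lte))
    }
    list(per = do.call(rbind, per), recovery = recovery)
  }
  out <- withr::with_seed(seed, run())
  structure(list(per_repeat = out$per, recovery = out$recovery,
                 mean_test_auc = mean(out$per$test_auc),
                 mean_selected = mean(out$per$n_selected),
                 mean_test_error = mean(out$per$test_error),
                 repeats = repeats, lam_grid = as.numeric(lam_grid),
                 folds = folds, split_fraction = split_fraction,
                 seed = seed, spec = spec),
            class = "simulation_study")
}

#' @export
print.simulation_study <- function(x, ...) {
  cat(sprintf(
    "simulation_study (%d classes, %d repeats): mean AUC %.4f, mean error %.4f, mean selected %.2f\n",
    x$spec$n_classes, x$repeats, x$mean_test_auc, x$mean_test_error,
    x$mean_selected))
  cat("planted-feature recovery:",
      paste(sprintf("%s %d/%d", names(x$recovery), x$recovery, x$repeats),
            collapse = ", "), "\n")
  invisible(x)
}
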