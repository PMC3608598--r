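# Count preprocessing: relative abundances and variance-stabilizing
# transforms.  Counts and percentage data have mean-dependent variance
# (Poisson / binomial / negative-binomial behaviour); proportions are
# variance-stabilized with sqrt(p) or arcsin(sqrt(p)) before model fitting.
# Bartlett's test across samples guides the transform choice.

#' Construct an abundance table
#'
#' @param values Numeric matrix, samples in rows.
#' @param samples,features Identifiers; default dimnames.
#' @param stage One of `"relative"`, `"sqrt_transformed"`,
#'   `"arcsine_transformed"`.
#' @return An object of class `abundance_table`.
#' @export
abundance_table <- function(values, samples = rownames(values),
                            features = colnames(values),
                            stage = c("relative", "sqrt_transformed",
                                      "arcsine_transformed")) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(samples)) samples <- paste0("S", seq_len(nrow(values)))
  if (is.null(features)) features <- paste0("F", seq_len(ncol(values)))
  lim <- switch(stage, relative = 1, sqrt_transformed = 1,
                arcsine_transformed = pi / 2)
  if (any(!is.finite(values)) || any(values < 0) || any(values > lim + 1e-9))
    stop(sprintf("values outside [0, %.6g] for stage '%s'", lim, stage))
  if (stage == "relative") {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > 1e-12)
    if (length(bad))
      stop("relative-abundance rows must sum to 1; offending sample: ",
           samples[bad[1]])
  }
  dimnames(values) <- list(samples, features)
  structure(list(samples = as.character(samples),
                 features = as.character(features),
                 values = values, stage = stage),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table [%s]: %d samples x %d features\n",
              x$stage, length(x$samples), length(x$features)))
  invisible(x)
}

#' Convert raw counts to relative abundances
#'
#' Each sample's counts are divided by its total read count, adjusting for
#' sequencing-depth differences: `p_ij = x_ij / sum_j x_ij`.
#'
#' @param table A [count_table()].
#' @return An [abundance_table()] at stage `"relative"`.
#' @export
to_relative_abundance <- function(table) {
  stopifnot(inherits(table, "count_table"))
  rs <- rowSums(table$counts)
  if (any(rs == 0))
    stop("sample(s) with zero total count: ",
         paste(table$samples[rs == 0], collapse = ", "))
  abundance_table(table$counts / rs, samples = table$samples,
                  features = table$features, stage = "relative")
}

#' Square-root transform of relative abundances
#'
#' @param table An [abundance_table()] at stage `"relative"`.
#' @return The table with `sqrt(p)` values, stage `"sqrt_transformed"`.
#' @export
transform_sqrt <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage != "relative")
    stop("transform_sqrt expects stage 'relative', got '", table$stage, "'")
  abundance_table(sqrt(table$values), samples = table$samples,
                  features = table$features, stage = "sqrt_transformed")
}

#' Arcsine (angular) transform of relative abundances
#'
#' The classical variance-stabilizing transform for proportions,
#' `arcsin(sqrt(p))` in radians, mapping `[0, 1]` onto `[0, pi/2]`.
#'
#' @param table An [abundance_table()] at stage `"relative"`.
#' @return The transformed table, stage `"arcsine_transformed"`.
#' @export
transform_arcsine <- function(table) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage != "relative")
    stop("transform_arcsine expects stage 'relative', got '", table$stage, "'")
  v <- table$values
  if (any(v < 0) || any(v > 1)) stop("proportions must lie in [0, 1]")
  abundance_table(asin(sqrt(v)), samples = table$samples,
                  features = table$features, stage = "arcsine_transformed")
}

#' Apply a named transform to a relative-abundance table
#'
#' @param table An [abundance_table()] at stage `"relative"`.
#' @param transform `"none"`, `"sqrt"` or `"arcsine"`.
#' @return The (possibly untransformed) abundance table.
#' @export
apply_transform <- function(table, transform = c("arcsine", "sqrt", "none")) {
  transform <- match.arg(transform)
  switch(transform,
         none = table,
         sqrt = transform_sqrt(table),
         arcsine = transform_arcsine(table))
}

#' Bartlett's test of variance homogeneity across samples
#'
#' Each sample (row) is one group; the observations are its feature values.
#' The statistic is chi-squared with `n - 1` degrees of freedom under
#' homogeneity.
#'
#' @param table An [abundance_table()] (any stage) or a numeric matrix with
#'   samples in rows.
#' @return A `bartlett_result` with `statistic`, `df`, `p_value` and the
#'   per-sample `group_variances`.
#' @export
bartlett_homogeneity <- function(table) {
  values <- if (inherits(table, "abundance_table")) table$values else
    as.matrix(table)
  n <- nrow(values)
  m <- ncol(values)
  if (n < 2L) stop("Bartlett's test needs at least 2 samples")
  if (m < 2L) stop("within-sample variance undefined for m < 2 features")
  gv <- apply(values, 1, var)
  if (any(gv == 0))
    stop("zero within-sample variance for sample(s): ",
         paste(rownames(values)[gv == 0], collapse = ", "))
  bt <- stats::bartlett.test(split(t(values), col(t(values))))
  structure(list(statistic = unname(bt$statistic),
                 df = unname(bt$parameter),
                 p_value = unname(bt$p.value),
                 group_variances = stats::setNames(gv, rownames(values))),
            class = "bartlett_result")
}

#' @export
print.bartlett_result <- function(x, ...) {
  cat(sprintf("Bartlett homogeneity: K^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Advise which variance-stabilizing transform to use
#'
#' If Bartlett's test does not reject homogeneity at level `alpha`, no
#' transform is needed.  Under heterogeneity the square-root transform is
#' advised when the proportions occupy only one of the bands `[0, 0.3]` or
#' `[0.7, 1]` (zeros are allowed alongside the high band, being structural);
#' otherwise the arcsine transform is advised.
#'
#' @param table An [abundance_table()] at stage `"relative"`.
#' @param alpha Significance level for Bartlett's test.
#' @return `"none"`, `"sqrt"` or `"arcsine"`.
#' @export
choose_transform <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "abundance_table"))
  if (table$stage != "relative")
    stop("choose_transform expects stage 'relative', got '", table$stage, "'")
  bt <- bartlett_homogeneity(table)
  if (bt$p_value >= alpha) return("none")
  v <- table$values
  low_band <- max(v) <= 0.3
  nz <- v[v > 0]
  high_band <- length(nz) > 0 && min(nz) >= 0.7
  if (xor(low_band, high_band)) "sqrt" else "arcsine"
}
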