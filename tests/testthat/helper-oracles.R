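# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately re-derive quantities from first principles
# (direct formula evaluation, exhaustive enumeration, grid search) and never
# share code with the implementation paths they check.

# hinge + L1 objective of the binary problem, written out directly
oracle_binary_objective <- function(X, y, beta, beta0, lam) {
  total <- 0
  for (i in seq_along(y)) {
    f <- beta0 + sum(beta * X[i, ])
    total <- total + max(0, 1 - y[i] * f)
  }
  total + lam * sum(abs(beta))
}

# exhaustive grid search over (beta, beta0) for m = 1 or 2 features.
# The objective is convex piecewise-linear, so a coarse pass followed by a
# fine pass around the coarse minimizer brackets the global optimum.
oracle_grid_search <- function(X, y, lam, lim = 5, coarse = 0.05,
                               fine = 0.001) {
  m <- ncol(X)
  stopifnot(m <= 2)
  eval_grid <- function(vals) {
    g <- do.call(expand.grid, vals)
    obj <- rep(0, nrow(g))
    B <- as.matrix(g[, seq_len(m), drop = FALSE])
    b0 <- g[[m + 1]]
    f <- X %*% t(B)
    for (i in seq_along(y)) {
      obj <- obj + pmax(0, 1 - y[i] * (f[i, ] + b0))
    }
    obj <- obj + lam * rowSums(abs(B))
    list(par = as.numeric(g[which.min(obj), ]), value = min(obj))
  }
  ax <- seq(-lim, lim, by = coarse)
  pass1 <- eval_grid(rep(list(ax), m + 1))
  vals <- lapply(pass1$par, function(ctr)
    seq(ctr - 2 * coarse, ctr + 2 * coarse, by = fine))
  pass2 <- eval_grid(vals)
  pass2
}

# AUC by exhaustive positive/negative pair counting, ties worth one half
oracle_pair_auc <- function(scores, labels) {
  pos <- which(labels > 0)
  neg <- which(labels < 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1 else
      if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Bartlett's statistic straight from the textbook formula
oracle_bartlett <- function(groups) {
  k <- length(groups)
  ni <- vapply(groups, length, numeric(1))
  vi <- vapply(groups, var, numeric(1))
  N <- sum(ni)
  sp2 <- sum((ni - 1) * vi) / (N - k)
  stat <- ((N - k) * log(sp2) - sum((ni - 1) * log(vi)))
  C <- 1 + (sum(1 / (ni - 1)) - 1 / (N - k)) / (3 * (k - 1))
  list(statistic = stat / C, df = k - 1,
       p_value = pchisq(stat / C, k - 1, lower.tail = FALSE))
}

# small random binary instance on the abundance-like scale
random_binary_instance <- function(n = 6, m = 2, scale = 1) {
  X <- matrix(round(runif(n * m, -1, 1) * scale, 2), n, m)
  y <- c(-1, 1, sample(c(-1, 1), n - 2, replace = TRUE))
  list(X = X, y = y)
}

# small labelled multiclass instance guaranteed to contain every class
random_multiclass_instance <- function(n = 9, m = 3, c = 3) {
  X <- matrix(rnorm(n * m), n, m)
  cl <- c(seq_len(c), sample(seq_len(c), n - c, replace = TRUE))
  list(X = X, labels = label_set(paste0("C", cl)))
}

# tiny deterministic count fixture
toy_counts <- function() {
  count_table(rbind(s1 = c(2, 3, 5), s2 = c(1, 0, 9), s3 = c(4, 4, 2)),
              features = c("fA", "fB", "fC"))
}
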