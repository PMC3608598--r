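test_that("binary LP assembly has the prescribed shape and weights", {
  X <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6), 3, 2)
  y <- c(1, -1, 1)
  lp <- assemble_binary_lp(X, y, lam = 0.7)
  expect_length(lp$objective, 9)                    # 2m + 2 + n
  expect_equal(nrow(lp$ineq_matrix), 3)
  expect_equal(lp$objective[lp$var_map$u], rep(0.7, 2))
  expect_equal(lp$objective[lp$var_map$v], rep(0.7, 2))
  expect_equal(lp$objective[lp$var_map$slack], rep(1, 3))
  expect_equal(lp$objective[c(lp$var_map$intercept_pos,
                              lp$var_map$intercept_neg)], c(0, 0))
  expect_equal(lp$ineq_rhs, rep(1, 3))

  expect_error(assemble_binary_lp(X, c(1, 1, 1), 1), "both classes")
  expect_error(assemble_binary_lp(X, y, -1), "nonnegative")

  # at any feasible point with tight slacks, the LP objective equals the
  # hinge + L1 objective evaluated directly
  set.seed(31)
  for (i in 1:20) {
    inst <- random_binary_instance(n = 5, m = 2)
    lam <- runif(1, 0, 2)
    lp <- assemble_binary_lp(inst$X, inst$y, lam)
    beta <- rnorm(2)
    b0 <- rnorm(1)
    f <- inst$X %*% beta + b0
    z <- numeric(length(lp$objective))
    z[lp$var_map$u] <- pmax(beta, 0)
    z[lp$var_map$v] <- pmax(-beta, 0)
    z[lp$var_map$intercept_pos] <- max(b0, 0)
    z[lp$var_map$intercept_neg] <- max(-b0, 0)
    z[lp$var_map$slack] <- pmax(0, 1 - inst$y * f)
    expect_equal(sum(lp$objective * z),
                 oracle_binary_objective(inst$X, inst$y, beta, b0, lam),
                 tolerance = 1e-12)
  }
})

test_that("multiclass LP assembly matches the stated bookkeeping", {
  set.seed(32)
  X <- matrix(rnorm(12), 4, 3)
  Y <- cbind(c(1, -1, -1, 1), c(-1, 1, -1, -1))
  lp <- assemble_multiclass_lp(X, Y, lam = 2)
  expect_length(lp$objective, 27)        # 12 uv + 4 intercepts + 8 slack + 3 t
  expect_equal(nrow(lp$ineq_matrix), 20) # 8 hinge + 12 box
  expect_equal(lp$objective[lp$var_map$rowmax], rep(2, 3))
  expect_equal(lp$objective[lp$var_map$slack], rep(1, 8))
  expect_equal(sum(lp$objective[c(lp$var_map$u, lp$var_map$v)]), 0)

  expect_error(assemble_multiclass_lp(X, cbind(rep(1, 4)), 1), "degenerate")
})

test_that("the interior-point backend solves simple programs exactly", {
  # minimize z subject to z >= 3
  lp <- linear_program(1, matrix(1, 1, 1), 3, var_map = list(z = 1L))
  sol <- solve_lp(lp)
  expect_identical(sol$status, "optimal")
  expect_equal(sol$objective_value, 3, tolerance = 1e-7)

  # infeasible: -z >= 1 with z >= 0
  bad <- linear_program(1, matrix(-1, 1, 1), 1, var_map = list(z = 1L))
  expect_identical(solve_lp(bad)$status, "infeasible")
})

test_that("interior-point and simplex backends agree on random programs", {
  skip_if_not_installed("pracma")
  set.seed(33)
  tried <- 0
  for (i in 1:30) {
    n <- sample(2:6, 1)
    p <- sample(2:6, 1)
    A <- matrix(round(runif(n * p, 0.1, 2), 2), n, p)
    b <- round(runif(n, 0.5, 3), 2)
    cc <- round(runif(p, 0.1, 2), 2)
    lp <- linear_program(cc, A, b, var_map = list(z = seq_len(p)))
    ref <- tryCatch(suppressWarnings(solve_lp(lp, backend = "simplex")),
                    error = function(e) NULL)
    if (is.null(ref) || ref$status != "optimal") next  # simplex pivot failure
    tried <- tried + 1
    sol <- solve_lp(lp, backend = "ipm")
    expect_identical(sol$status, "optimal")
    expect_equal(sol$objective_value, ref$objective_value,
                 tolerance = 1e-6)
  }
  expect_gte(tried, 15)
})

test_that("the 1D binary fit matches the exhaustive grid-search oracle", {
  X <- matrix(c(-1, 1), 2, 1)
  y <- c(-1, 1)
  lp <- assemble_binary_lp(X, y, 0.1)
  sol <- solve_lp(lp)
  ora <- oracle_grid_search(X, y, 0.1)
  expect_equal(sol$objective_value, ora$value, tolerance = 1e-3)
})

test_that("optimal slacks equal the hinge residuals exactly", {
  set.seed(34)
  for (i in 1:10) {
    inst <- random_binary_instance(n = 6, m = 2)
    lam <- runif(1, 0.05, 1)
    lp <- assemble_binary_lp(inst$X, inst$y, lam)
    sol <- solve_lp(lp)
    expect_identical(sol$status, "optimal")
    beta <- sol$variables[lp$var_map$u] - sol$variables[lp$var_map$v]
    b0 <- sol$variables[lp$var_map$intercept_pos] -
      sol$variables[lp$var_map$intercept_neg]
    hinge <- pmax(0, 1 - inst$y * (inst$X %*% beta + b0))
    expect_equal(sol$variables[lp$var_map$slack], as.numeric(hinge),
                 tolerance = 1e-6)
  }
})

test_that("at the multiclass optimum t_j equals the row-maximum coefficient", {
  set.seed(35)
  for (i in 1:8) {
    inst <- random_multiclass_instance(n = 8, m = 3, c = 3)
    lam <- runif(1, 0.1, 1)
    model <- fit_multiclass(inst$X, inst$labels, lam)
    enc <- encode_labels(inst$labels)
    lp <- assemble_multiclass_lp(inst$X, enc$Y, lam)
    sol <- solve_lp(lp)
    expect_identical(sol$status, "optimal")
    tvec <- sol$variables[lp$var_map$rowmax]
    B <- matrix(sol$variables[lp$var_map$u] - sol$variables[lp$var_map$v],
                ncol = ncol(enc$Y))
    expect_equal(tvec, apply(abs(B), 1, max), tolerance = 1e-6)
    # the structured solver attains the same optimum as the generic backend
    expect_equal(model$objective, sol$objective_value, tolerance = 1e-6)
  }
})

test_that("the optimum respects the lambda ladder monotonicity", {
  set.seed(36)
  for (rep in 1:4) {
    inst <- random_binary_instance(n = 8, m = 2)
    ladder <- sort(runif(8, 0.01, 3))
    objs <- pens <- numeric(length(ladder))
    for (g in seq_along(ladder)) {
      lp <- assemble_binary_lp(inst$X, inst$y, ladder[g])
      sol <- solve_lp(lp)
      beta <- sol$variables[lp$var_map$u] - sol$variables[lp$var_map$v]
      objs[g] <- sol$objective_value
      pens[g] <- sum(abs(beta))
    }
    expect_true(all(diff(objs) >= -1e-7))
    expect_true(all(diff(pens) <= 1e-7))
  }
})
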