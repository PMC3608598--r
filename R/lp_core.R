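# Assembly of the two SVM optimization problems as standard-form linear
# programs (min c'z s.t. A z >= b, z >= 0) and a pluggable solver contract.
# Free parameters (coefficients, intercepts) are represented by nonnegative
# splits u - v so that every backend sees one uniform bound structure.

#' Construct a linear program in standard inequality form
#'
#' Represents `minimize objective . z` subject to `ineq_matrix %*% z >=
#' ineq_rhs` and `z >= 0`.  `var_map` names the semantic block each slice of
#' the variable vector plays (coefficient splits, intercept splits, slacks,
#' row bounds); the slices must be disjoint and cover the vector.
#'
#' @param objective Nonnegative cost vector.
#' @param ineq_matrix Constraint matrix `A`.
#' @param ineq_rhs Right-hand side `b`.
#' @param var_map Named list of integer index vectors.
#' @return An object of class `linear_program`.
#' @export
linear_program <- function(objective, ineq_matrix, ineq_rhs, var_map) {
  ineq_matrix <- as.matrix(ineq_matrix)
  p <- length(objective)
  if (ncol(ineq_matrix) != p)
    stop("objective length and constraint columns disagree")
  if (nrow(ineq_matrix) != length(ineq_rhs))
    stop("constraint rows and right-hand side disagree")
  if (any(objective < 0)) stop("objective coefficients must be nonnegative")
  idx <- as.integer(sort(unlist(var_map, use.names = FALSE)))
  if (!identical(idx, seq_len(p)))
    stop("var_map slices must be disjoint and cover all variables")
  structure(list(objective = as.numeric(objective),
                 ineq_matrix = ineq_matrix,
                 ineq_rhs = as.numeric(ineq_rhs),
                 var_lower = rep(0, p), var_upper = rep(Inf, p),
                 var_map = var_map),
            class = "linear_program")
}

#' @export
print.linear_program <- function(x, ...) {
  cat(sprintf("linear_program: %d variables, %d inequality constraints\n",
              length(x$objective), nrow(x$ineq_matrix)))
  cat("blocks:", paste(sprintf("%s[%d]", names(x$var_map),
                               lengths(x$var_map)), collapse = " "), "\n")
  invisible(x)
}

#' Assemble the binary L1-penalized SVM as a linear program
#'
#' Encodes `minimize sum_i xi_i + lambda * sum_j (u_j + v_j)` subject to
#' `y_i (sum_j (u_j - v_j) x_ij + b+ - b-) + xi_i >= 1`, all variables
#' nonnegative, with `beta = u - v` and unpenalized intercept `b+ - b-`.
#' The program has `2m + 2 + n` variables and `n` constraints.
#'
#' @param Xt Transformed feature matrix (n x m).
#' @param y Numeric labels in `{-1, +1}`.
#' @param lam Regularization weight `lambda >= 0`.
#' @return A [linear_program()] with blocks `u`, `v`, `intercept_pos`,
#'   `intercept_neg`, `slack`.
#' @export
assemble_binary_lp <- function(Xt, y, lam) {
  Xt <- as.matrix(Xt)
  n <- nrow(Xt)
  m <- ncol(Xt)
  if (length(y) != n) stop("labels and rows disagree")
  if (!all(y %in% c(-1, 1))) stop("y must be coded -1/+1")
  if (length(unique(y)) < 2L) stop("both classes must be present")
  if (lam < 0) stop("lam must be nonnegative")
  yX <- y * Xt
  A <- cbind(yX, -yX, y, -y, diag(n))
  linear_program(
    objective = c(rep(lam, 2 * m), 0, 0, rep(1, n)),
    ineq_matrix = A,
    ineq_rhs = rep(1, n),
    var_map = list(u = seq_len(m), v = m + seq_len(m),
                   intercept_pos = 2 * m + 1L, intercept_neg = 2 * m + 2L,
                   slack = 2 * m + 2L + seq_len(n)))
}

#' Assemble the multiclass joint L-infinity,1 SVM as a linear program
#'
#' Encodes `minimize sum_ik xi_ik + lambda * sum_j t_j` subject to the
#' one-against-rest hinge constraints for the `c - 1` encoded subproblems and
#' the box constraints `-t_j <= beta_jk <= t_j`, realizing the
#' L-infinity,1 penalty (`t_j = max_k |beta_jk|` at the optimum).  The
#' program has `2m(c-1) + 2(c-1) + n(c-1) + m` variables and
#' `n(c-1) + 2m(c-1)` constraints.
#'
#' @param Xt Transformed feature matrix (n x m).
#' @param Y One-against-rest encoding matrix (n x (c-1)) with entries -1/+1.
#' @param lam Regularization weight `lambda >= 0`.
#' @return A [linear_program()] with blocks `u`, `v`, `intercept_pos`,
#'   `intercept_neg`, `slack`, `rowmax`.
#' @export
assemble_multiclass_lp <- function(Xt, Y, lam) {
  Xt <- as.matrix(Xt)
  Y <- as.matrix(Y)
  n <- nrow(Xt)
  m <- ncol(Xt)
  K <- ncol(Y)
  if (nrow(Y) != n) stop("encoding rows and feature rows disagree")
  if (!all(Y %in% c(-1, 1))) stop("Y must be coded -1/+1")
  if (lam < 0) stop("lam must be nonnegative")
  for (k in seq_len(K))
    if (length(unique(Y[, k])) < 2L)
      stop("subproblem ", k, " is degenerate: one sign absent")
  nv <- 2 * m * K + 2 * K + n * K + m
  iu <- function(j, k) (k - 1) * m + j
  iv <- function(j, k) m * K + (k - 1) * m + j
  ibp <- function(k) 2 * m * K + k
  ibm <- function(k) 2 * m * K + K + k
  ixi <- function(i, k) 2 * m * K + 2 * K + (k - 1) * n + i
  it <- function(j) 2 * m * K + 2 * K + n * K + j
  A <- matrix(0, n * K + 2 * m * K, nv)
  row <- 0L
  for (k in seq_len(K)) for (i in seq_len(n)) {
    row <- row + 1L
    A[row, iu(seq_len(m), k)] <- Y[i, k] * Xt[i, ]
    A[row, iv(seq_len(m), k)] <- -Y[i, k] * Xt[i, ]
    A[row, ibp(k)] <- Y[i, k]
    A[row, ibm(k)] <- -Y[i, k]
    A[row, ixi(i, k)] <- 1
  }
  for (k in seq_len(K)) for (j in seq_len(m)) {       # t_j - beta_jk >= 0
    row <- row + 1L
    A[row, it(j)] <- 1
    A[row, iu(j, k)] <- -1
    A[row, iv(j, k)] <- 1
  }
  for (k in seq_len(K)) for (j in seq_len(m)) {       # t_j + beta_jk >= 0
    row <- row + 1L
    A[row, it(j)] <- 1
    A[row, iu(j, k)] <- 1
    A[row, iv(j, k)] <- -1
  }
  obj <- rep(0, nv)
  obj[ixi(seq_len(n), rep(seq_len(K), each = n))] <- 1
  obj[it(seq_len(m))] <- lam
  linear_program(
    objective = obj,
    ineq_matrix = A,
    ineq_rhs = c(rep(1, n * K), rep(0, 2 * m * K)),
    var_map = list(u = seq_len(m * K), v = m * K + seq_len(m * K),
                   intercept_pos = 2 * m * K + seq_len(K),
                   intercept_neg = 2 * m * K + K + seq_len(K),
                   slack = 2 * m * K + 2 * K + seq_len(n * K),
                   rowmax = 2 * m * K + 2 * K + n * K + seq_len(m)))
}

#' Solve a linear program
#'
#' The default backend is the package's dense interior-point solver
#' (Mehrotra predictor-corrector on the normal equations); `"simplex"`
#' delegates to [boot::simplex()] and suits small programs only.  An optimal
#' solution is re-verified for feasibility independently of the backend.
#'
#' Zero-cost columns arising from +/- splits of free parameters leave the
#' dual with no strict interior; the interior-point backend perturbs such
#' costs by `degeneracy_eps` internally and always reports the objective of
#' the *unperturbed* program.
#'
#' @param lp A [linear_program()].
#' @param backend `"ipm"` or `"simplex"`.
#' @param tol Interior-point convergence tolerance.
#' @param max_iter Iteration cap.
#' @param degeneracy_eps Cost perturbation applied to zero-cost columns
#'   (interior-point backend only).
#' @return An `lp_solution` with `variables`, `objective_value`, `status`
#'   (`optimal`, `infeasible`, `unbounded` or `numerical_failure`),
#'   `backend`, `iterations` and `accuracy`.
#' @export
solve_lp <- function(lp, backend = c("ipm", "simplex"), tol = 1e-9,
                     max_iter = 200, degeneracy_eps = 1e-9) {
  stopifnot(inherits(lp, "linear_program"))
  backend <- match.arg(backend)
  cc <- lp$objective
  if (backend == "ipm") {
    # retry ladder: highly degenerate programs (e.g. a dominating penalty
    # zeroing all coefficients) can stall at the default perturbation; a
    # stronger perturbation restores a well-conditioned central path
    attempts <- list(c(degeneracy_eps, tol),
                     c(1e-6, tol),
                     c(1e-6, 100 * tol))
    for (a in attempts) {
      cpert <- cc
      cpert[cpert == 0] <- a[1] * max(1, max(cc))
      r <- ipm_solve_dense(lp$ineq_matrix, lp$ineq_rhs, cpert, a[2],
                           max_iter)
      if (r$status == "optimal" || r$status == "infeasible" ||
          r$status == "unbounded") break
    }
    sol <- list(variables = as.numeric(r$variables),
                objective_value = sum(cc * r$variables),
                status = r$status, backend = backend,
                iterations = r$iterations, accuracy = r$accuracy)
  } else {
    if (!requireNamespace("pracma", quietly = TRUE))
      stop("backend 'simplex' needs the pracma package")
    bs <- pracma::linprog(cc, A = -lp$ineq_matrix, b = -lp$ineq_rhs,
                          maxiter = max(200, 20 * length(cc)),
                          maximize = FALSE)
    status <- if (isTRUE(bs$errno == 1)) "optimal" else
      if (isTRUE(bs$errno %in% c(-3, -4))) "infeasible" else
        if (isTRUE(bs$errno == -2)) "unbounded" else "numerical_failure"
    sol <- list(variables = as.numeric(bs$x),
                objective_value = unname(bs$fval),
                status = status, backend = backend,
                iterations = NA_integer_, accuracy = NA_real_)
  }
  if (sol$status == "optimal") {
    viol <- max(c(lp$ineq_rhs - lp$ineq_matrix %*% sol$variables, 0))
    tol_feas <- 1e-6 * (1 + max(abs(lp$ineq_rhs)))
    if (viol > tol_feas || min(sol$variables) < -tol_feas)
      sol$status <- "numerical_failure"
  }
  class(sol) <- "lp_solution"
  sol
}

#' @export
print.lp_solution <- function(x, ...) {
  cat(sprintf("lp_solution [%s/%s]: objective %.8g (%s iterations)\n",
              x$backend, x$status, x$objective_value,
              format(x$iterations)))
  invisible(x)
}
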