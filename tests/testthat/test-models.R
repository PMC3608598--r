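test_that("one-against-rest encoding drops the reference class", {
  enc <- encode_labels(label_set(c("A", "B", "A")))
  expect_equal(dim(enc$Y), c(3L, 1L))
  expect_equal(unname(enc$Y[, 1]), c(1, -1, 1))
  expect_identical(enc$reference, "B")

  enc3 <- encode_labels(label_set(c("A", "B", "C")))
  expect_equal(unname(enc3$Y), rbind(c(1, -1), c(-1, 1), c(-1, -1)))
  expect_true(all(rowSums(enc3$Y == 1) <= 1))

  # configurable reference moves to the last position
  enc_ref <- encode_labels(label_set(c("A", "B", "C", "A", "B", "C")),
                           reference = "A")
  expect_identical(enc_ref$classes, c("B", "C", "A"))
  expect_identical(enc_ref$reference, "A")
})

test_that("binary fits recover separable structure and obey the objective identity", {
  X <- matrix(c(-1, -1, 1, 1), 4, 1)
  y <- c(-1, -1, 1, 1)
  model <- fit_binary(X, y, lam = 0.1)
  expect_gt(model$beta[1], 0)
  expect_equal(unname(predict_binary(model, X)), y)
  ora <- oracle_grid_search(X, y, 0.1)
  expect_equal(model$objective, ora$value, tolerance = 1e-3)

  # the re-evaluated hinge + penalty matches the LP optimum on random fits
  set.seed(41)
  for (i in 1:15) {
    inst <- random_binary_instance(n = 7, m = 2)
    lam <- runif(1, 0.05, 2)
    m <- fit_binary(inst$X, inst$y, lam)
    expect_equal(oracle_binary_objective(inst$X, inst$y, m$beta, m$beta0, lam),
                 m$objective, tolerance = 1e-6)
  }
})

test_that("a dominating penalty forces the all-zero coefficient vector", {
  set.seed(42)
  inst <- random_binary_instance(n = 10, m = 2)
  m <- fit_binary(inst$X, inst$y, lam = 1000)
  expect_equal(max(abs(m$beta)), 0, tolerance = 1e-6)
  expect_length(selected_features(m), 0)

  inst3 <- random_multiclass_instance(n = 9, m = 3, c = 3)
  m3 <- fit_multiclass(inst3$X, inst3$labels, lam = 1000)
  expect_equal(max(abs(m3$B)), 0, tolerance = 1e-6)
  expect_length(selected_features(m3), 0)
})

test_that("duplicating samples with doubled lambda reproduces the fit", {
  set.seed(43)
  inst <- random_binary_instance(n = 6, m = 2)
  m1 <- fit_binary(inst$X, inst$y, lam = 0.4)
  m2 <- fit_binary(rbind(inst$X, inst$X), c(inst$y, inst$y), lam = 0.8)
  expect_equal(m2$objective, 2 * m1$objective, tolerance = 1e-6)
  expect_equal(unname(m2$beta), unname(m1$beta), tolerance = 1e-4)
})

test_that("binary and c = 2 multiclass formulations are equivalent", {
  set.seed(44)
  for (i in 1:10) {
    inst <- random_binary_instance(n = 8, m = 3)
    labels <- label_set(ifelse(inst$y > 0, "pos", "neg"),
                        classes = c("pos", "neg"))
    lam <- runif(1, 0.05, 1.5)
    mb <- fit_binary(inst$X, inst$y, lam)
    mm <- fit_multiclass(inst$X, labels, lam)
    expect_equal(mm$objective, mb$objective, tolerance = 1e-6)
    expect_identical(predict_class(mm, inst$X),
                     ifelse(predict_binary(mb, inst$X) > 0, "pos", "neg"))
  }
})

test_that("decision scores are affine and the sign rule is deterministic", {
  model <- structure(list(beta0 = 0.7, beta = c(f1 = 0, f2 = 0),
                          lam = 1, transform = "none",
                          feature_ids = c("f1", "f2"), classes = NULL),
                     class = "lpsvm_binary")
  X <- matrix(rnorm(6), 3, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(decision_binary(model, X)), rep(0.7, 3))

  model$beta <- c(f1 = 2, f2 = -1)
  e1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(decision_binary(model, e1)), 0.7 + 2)

  # affine combination identity
  x1 <- X[1, , drop = FALSE]
  x2 <- X[2, , drop = FALSE]
  a <- 0.3
  expect_equal(unname(decision_binary(model, a * x1 + (1 - a) * x2)),
               a * decision_binary(model, x1) +
                 (1 - a) * decision_binary(model, x2),
               tolerance = 1e-12)

  model$beta0 <- 0
  expect_equal(unname(predict_binary(model, e1)), 1)
  zero <- matrix(c(0, 0), 1, 2, dimnames = list(NULL, c("f1", "f2")))
  expect_equal(unname(predict_binary(model, zero)), 1)   # tie -> +1
  expect_error(decision_binary(model, matrix(0, 1, 3,
    dimnames = list(NULL, c("f1", "fX", "fY")))), "mismatch")
})

test_that("softmax probabilities are exact on analytic cases", {
  mk <- function(beta0, B, classes) {
    structure(list(classes = classes, reference = classes[length(classes)],
                   beta0 = beta0, B = B, lam = 1, transform = "none",
                   feature_ids = rownames(B)),
              class = "lpsvm_multiclass")
  }
  B <- matrix(0, 2, 2, dimnames = list(c("f1", "f2"), c("A", "B")))
  m <- mk(c(0, 0), B, c("A", "B", "C"))
  X <- matrix(rnorm(4), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  p <- predict_proba(m, X)
  expect_equal(unname(p), matrix(1 / 3, 2, 3), tolerance = 1e-12)
  expect_identical(predict_class(m, X), c("A", "A"))     # tie -> earliest

  m2 <- mk(0, matrix(0, 2, 1, dimnames = list(c("f1", "f2"), "A")),
           c("A", "B"))
  expect_equal(unname(predict_proba(m2, X)[1, ]), c(0.5, 0.5))

  m3 <- mk(c(log(2), log(1)),
           matrix(0, 2, 2, dimnames = list(c("f1", "f2"), c("A", "B"))),
           c("A", "B", "C"))
  expect_equal(unname(predict_proba(m3, X)[1, ]), c(0.5, 0.25, 0.25),
               tolerance = 1e-12)

  # argmax over probabilities equals argmax over raw scores; rows sum to 1
  set.seed(45)
  B4 <- matrix(rnorm(6), 2, 3,
               dimnames = list(c("f1", "f2"), c("A", "B", "C")))
  m4 <- mk(rnorm(3), B4, c("A", "B", "C", "D"))
  p4 <- predict_proba(m4, X)
  expect_equal(unname(rowSums(p4)), c(1, 1), tolerance = 1e-12)
  expect_true(all(p4 > 0 & p4 < 1))
  raw <- cbind(X %*% B4 + matrix(m4$beta0, 2, 3, byrow = TRUE), 0)
  expect_equal(apply(p4, 1, which.max), apply(raw, 1, which.max))

  # large scores do not overflow
  m5 <- mk(c(2000, 0), matrix(0, 2, 2,
                              dimnames = list(c("f1", "f2"), c("A", "B"))),
           c("A", "B", "C"))
  p5 <- predict_proba(m5, X)
  expect_false(any(is.nan(p5)))
  expect_equal(unname(p5[1, 1]), 1, tolerance = 1e-12)
})

test_that("selected features follow the relative snap threshold", {
  model <- structure(list(beta0 = 0, beta = c(a = 0, b = 0.5, c = -3),
                          lam = 1, transform = "none",
                          feature_ids = c("a", "b", "c"), classes = NULL),
                     class = "lpsvm_binary")
  expect_identical(selected_features(model), c("c", "b"))

  B <- matrix(c(0, 0.4, 1e-9, 2e-7), 2, 2,
              dimnames = list(c("r1", "r2"), NULL))
  mm <- structure(list(classes = c("A", "B", "C"), reference = "C",
                       beta0 = c(0, 0), B = B, lam = 1, transform = "none",
                       feature_ids = c("r1", "r2")),
                  class = "lpsvm_multiclass")
  expect_identical(selected_features(mm), "r2")   # max_k rule, r1 snapped
})

test_that("lambda ladders make fitted models monotonically sparser", {
  set.seed(46)
  ladder <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)
  pairs_total <- 0
  pairs_mono <- 0
  for (rep in 1:5) {
    inst <- random_binary_instance(n = 10, m = 3)
    pens <- nsel <- numeric(length(ladder))
    for (g in seq_along(ladder)) {
      m <- fit_binary(inst$X, inst$y, ladder[g])
      pens[g] <- sum(abs(m$beta))
      nsel[g] <- length(selected_features(m))
    }
    expect_true(all(diff(pens) <= 1e-7))
    pairs_total <- pairs_total + length(ladder) - 1
    pairs_mono <- pairs_mono + sum(diff(nsel) <= 0)
  }
  expect_gte(pairs_mono / pairs_total, 0.9)
})

test_that("permuting non-reference class order permutes probability columns", {
  set.seed(47)
  inst <- random_multiclass_instance(n = 12, m = 3, c = 3)
  m1 <- fit_multiclass(inst$X, inst$labels, lam = 0.3)
  relabeled <- label_set(inst$labels$labels,
                         samples = inst$labels$samples,
                         classes = c("C2", "C1", "C3"))
  m2 <- fit_multiclass(inst$X, relabeled, lam = 0.3)
  p1 <- predict_proba(m1, inst$X)
  p2 <- predict_proba(m2, inst$X)
  expect_equal(p2[, colnames(p1)], p1, tolerance = 1e-5)
})
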