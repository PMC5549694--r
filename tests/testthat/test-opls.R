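# Core OPLS fitting, prediction and cross-validation behaviour.

test_that("center_scale handles uv, pareto and degenerate columns", {
  x <- cbind(a = c(1, 2, 3, 4), b = rep(5, 4), c = c(0, 4, 8, 12))
  cs <- center_scale(x, mode = "uv")
  expect_equal(unname(apply(cs$x[, c(1, 3)], 2, sd)), c(1, 1))
  expect_equal(unname(cs$x[, 2]), rep(0, 4))   # constant column centred
  expect_true(cs$degenerate[2])
  expect_equal(unname(cs$x_scale[2]), 1)

  cs2 <- center_scale(cbind(a = c(0, 4, 8, 12, 1)), mode = "pareto")
  expect_equal(unname(cs2$x_scale), sqrt(sd(c(0, 4, 8, 12, 1))))

  cs3 <- center_scale(x, y = c(1, 0, 1, 0), mode = "none")
  expect_equal(unname(cs3$x[, 1]), c(1, 2, 3, 4) - 2.5)
  expect_equal(cs3$y_scale, 1)
})

test_that("with no orthogonal components OPLS equals NIPALS PLS1", {
  for (seed in 1:10) {
    inst <- random_instance(seed)
    fit <- opls(inst$X, inst$y, n_ortho = 0)
    expect_equal(unname(predict(fit, inst$Xnew)),
                 nipals_pls1_predict(inst$X, inst$y, inst$Xnew),
                 tolerance = 1e-8)
  }
})

test_that("k = 0 predictions match an external PLS implementation", {
  skip_if_not_installed("mixOmics")
  inst <- random_instance(303, n = 18, m = 12)
  fit <- opls(inst$X, inst$y, n_ortho = 0)
  mo <- mixOmics::pls(inst$X, inst$y, ncomp = 1, scale = TRUE,
                      mode = "regression")
  expect_equal(unname(predict(fit, inst$Xnew)),
               unname(drop(predict(mo, inst$Xnew)$predict[, 1, 1])),
               tolerance = 1e-8)
})

test_that("noiseless y-spanned data are represented exactly at k = 0", {
  set.seed(5)
  y <- rnorm(20)
  b <- runif(6, 0.5, 2)
  X <- outer(y, b)
  fit <- opls(X, y, n_ortho = 0)
  expect_equal(fit$r2y, 1, tolerance = 1e-8)
  expect_equal(unname(predict(fit, X)), y, tolerance = 1e-8)
})

test_that("decomposition and orthogonality invariants hold on random fits", {
  for (seed in c(2, 9, 31)) {
    inst <- random_instance(seed, n = 16, m = 24)
    k <- sample(1:3, 1)
    fit <- opls(inst$X, inst$y, n_ortho = k)
    cs <- center_scale(inst$X, inst$y, mode = "uv")
    # reconstruction: t1 p1' + To Po' + E == scaled X
    recon <- tcrossprod(fit$t1, fit$p1) +
      tcrossprod(fit$To, fit$Po) + fit$E
    expect_lt(max(abs(recon - cs$x)), 1e-8)
    yc <- cs$y
    expect_lt(max(abs(crossprod(fit$To, yc))), 1e-8)   # To' y = 0
    expect_lt(max(abs(crossprod(fit$To, fit$t1))), 1e-8)
    expect_lt(max(abs(crossprod(fit$Wo, fit$w))), 1e-8)
    expect_equal(sqrt(sum(fit$w^2)), 1, tolerance = 1e-10)
    expect_equal(unname(apply(fit$Wo, 2, function(v) sqrt(sum(v^2)))),
                 rep(1, k), tolerance = 1e-10)
    # orthogonal scores are uncorrelated with the centred response
    expect_lt(max(abs(cor(fit$To, yc))), 1e-8)
  }
})

test_that("training-row prediction reproduces stored scores and fitted y", {
  inst <- random_instance(12, n = 14, m = 10)
  fit <- opls(inst$X, inst$y, n_ortho = 2)
  sc <- predict(fit, inst$X, type = "scores")
  expect_equal(unname(sc$t1), unname(fit$t1), tolerance = 1e-8)
  expect_equal(sc$To, fit$To, tolerance = 1e-8)
  # a sample at the training column means predicts the mean response
  sc0 <- predict(fit, matrix(fit$x_mean, 1), type = "scores")
  expect_equal(unname(sc0$t1), 0, tolerance = 1e-10)
  expect_equal(unname(sc0$y_hat), fit$y_mean, tolerance = 1e-10)
})

test_that("the model collapses to linear coefficients", {
  inst <- random_instance(8, n = 20, m = 12)
  fit <- opls(inst$X, inst$y, n_ortho = 3)
  b <- coef(fit)
  yh <- b[1] + drop(inst$Xnew %*% b[-1])
  expect_equal(unname(yh), unname(predict(fit, inst$Xnew)),
               tolerance = 1e-10)
})

test_that("class coding, sign convention and classification threshold", {
  set.seed(77)
  y <- rep(c(0, 1), each = 10)
  X <- cbind(matrix(rnorm(20 * 5), 20), y * 2 + rnorm(20, sd = 0.1))
  fit <- opls(X, y, n_ortho = 1)
  expect_identical(fit$kind, "class")
  expect_gt(mean(fit$t1[y == 1]), mean(fit$t1[y == 0]))
  expect_gt(fit$q1, 0)

  calls <- classify(c(a = 0.9, b = 0.1, c = 0.5))
  expect_equal(as.integer(calls), c(1L, 0L, 1L))
  expect_equal(unname(attr(calls, "ties")), 3L)
  expect_error(classify(0.7, kind = "continuous"), "class")

  # factor responses: second level is the positive class
  fit2 <- opls(X, factor(ifelse(y == 1, "malignant", "benign")), n_ortho = 1)
  expect_equal(fit2$t1, fit$t1, tolerance = 1e-10)
})

test_that("degenerate fits are rejected with clear errors", {
  inst <- random_instance(4, n = 10, m = 6)
  expect_error(opls(inst$X, rep(1, 10)), "constant")
  expect_error(opls(inst$X, inst$y, n_ortho = 8), "n_ortho")
  expect_error(predict(opls(inst$X, inst$y, n_ortho = 1),
                       inst$Xnew[, 1:3]), "columns")
})

test_that("venetian-blind cross-validation: Q2 <= R2 and sane errors", {
  for (seed in c(1, 6)) {
    inst <- random_instance(seed, n = 21, m = 15)
    ev <- cv_opls(inst$X, inst$y, n_ortho = 1, folds = 7)
    expect_lte(ev$q2y, ev$r2y + 1e-6)
  }
  # noiseless rank-1 data generalize almost perfectly
  set.seed(2)
  y <- rnorm(21); X <- outer(y, runif(8, 0.5, 2))
  ev <- cv_opls(X, y, n_ortho = 0, folds = 7)
  expect_gt(ev$q2y, 0.9)
  # a fold with < 2 samples is refused
  expect_error(cv_opls(X[1:8, ], y[1:8], n_ortho = 0, folds = 7), "fold")
})

test_that("autofit adds components only while Q2 improves", {
  set.seed(10)
  y <- rnorm(28)
  # pure y-spanned X plus tiny noise: no orthogonal structure
  X0 <- outer(y, runif(10, 0.5, 2)) + matrix(rnorm(280, sd = 1e-3), 28)
  expect_equal(as.integer(autofit_opls(X0, y, max_ortho = 4)), 0L)
  expect_equal(as.integer(autofit_opls(X0, y, max_ortho = 0)), 0L)

  # one strong y-orthogonal factor: at least one component is kept
  g <- rnorm(28); g <- g - y * sum(g * y) / sum(y^2)
  X1 <- outer(y, runif(12, 0.5, 1.5)) + 6 * outer(g, runif(12, 0.5, 1.5)) +
    matrix(rnorm(28 * 12, sd = 0.05), 28)
  expect_gte(as.integer(autofit_opls(X1, y, max_ortho = 4)), 1L)
})

test_that("adding an orthogonal component never lowers training R2Y", {
  inst <- random_instance(19, n = 18, m = 25)
  r2 <- sapply(0:3, function(k) opls(inst$X, inst$y, n_ortho = k)$r2y)
  expect_true(all(diff(r2) >= -1e-10))
})
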