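# Independent oracles and shared fixtures.

# Classical iterative NIPALS PLS1 (1 latent variable), written as the
# textbook power loop with a convergence test -- an independent code path
# from the package's closed-form predictive component.
nipals_pls1_predict <- function(X, y, Xnew, tol = 1e-12, maxit = 1000L) {
  xm <- colMeans(X)
  xs <- apply(X, 2L, stats::sd); xs[xs == 0] <- 1
  Xs <- sweep(sweep(X, 2L, xm), 2L, xs, "/")
  ym <- mean(y); ysd <- stats::sd(y)
  ys <- (y - ym) / ysd
  u <- ys
  w_old <- rep(0, ncol(X))
  q <- 0
  for (it in seq_len(maxit)) {
    w <- drop(crossprod(Xs, u))
    w <- w / sqrt(sum(w^2))
    tt <- drop(Xs %*% w)
    q <- sum(ys * tt) / sum(tt^2)
    u <- ys * q
    if (sqrt(sum((w - w_old)^2)) < tol) break
    w_old <- w
  }
  b <- q * w
  drop(sweep(sweep(Xnew, 2L, xm), 2L, xs, "/") %*% b) * ysd + ym
}

# small random regression instance
random_instance <- function(seed, n = NULL, m = NULL) {
  set.seed(seed)
  n <- n %||% sample(6:20, 1L)
  m <- m %||% sample(3:30, 1L)
  list(X = matrix(stats::rnorm(n * m), n,
                  dimnames = list(NULL, paste0("V", seq_len(m)))),
       y = stats::rnorm(n),
       Xnew = matrix(stats::rnorm(5L * m), 5L,
                     dimnames = list(NULL, paste0("V", seq_len(m)))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small, fast synthetic configuration for tests that only need the
# pipeline to run, not the full-resolution benchmark
small_cfg <- function(seed = 1L, ...) {
  synthetic_config(seed = seed,
                   acquisition = acquisition_params(n_points = 2048L), ...)
}

# the frozen default benchmark and its trained pipeline, computed once
# per test session and shared across files
.fixtures <- new.env(parent = emptyenv())

cached_benchmark <- function() {
  if (is.null(.fixtures$bm)) .fixtures$bm <- default_benchmark()
  .fixtures$bm
}

cached_run <- function() {
  if (is.null(.fixtures$run)) {
    bm <- cached_benchmark()
    .fixtures$run <- run_train(bm$train$spectra, bm$train$labels)
  }
  .fixtures$run
}

cached_blinded <- function() {
  if (is.null(.fixtures$blinded)) {
    bm <- cached_benchmark()
    .fixtures$blinded <- run_blinded_test(cached_run(), bm$test$spectra,
                                          bm$test$labels)
  }
  .fixtures$blinded
}

# apex position of the isolated creatine-like line at 3.03 ppm, measured
# inside a fixed 2.98-3.08 ppm window
apex_near_3ppm <- function(s) {
  win <- which(s$ppm <= 3.08 & s$ppm >= 2.98)
  win[which.max(s$intensity[win])]
}
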