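# Orthogonal projections to latent structures (OPLS) regression and
# discriminant analysis, single response, written from first principles.
#
# Model:  X = t1 p1' + To Po' + E ,  y = t1 q1 + f
# with one predictive component (t1) and n_ortho orthogonal components
# (To) capturing y-uncorrelated variation. Fitting deflates X by the
# orthogonal components, then extracts the predictive component as in
# PLS1: w = X'y / (y'y) normalized, t1 = X w.

#' Centre and scale a data matrix and response
#'
#' Columns of X (and y) are mean-centred and scaled: `"uv"` divides by the
#' column standard deviation (unit variance), `"pareto"` by its square
#' root, `"none"` leaves centred columns unscaled. Zero-variance columns
#' are centred, given scale 1 and flagged rather than failing.
#'
#' @param x Numeric matrix or [feature_matrix()].
#' @param y Numeric response (optional).
#' @param mode `"uv"`, `"pareto"` or `"none"`.
#' @return List with `x`, `y`, `x_mean`, `x_scale`, `y_mean`, `y_scale`
#'   and `degenerate` (logical flag per column).
#' @export
center_scale <- function(x, y = NULL, mode = c("uv", "pareto", "none")) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  x_mean <- colMeans(x)
  sds <- apply(x, 2L, stats::sd)
  degenerate <- sds == 0
  x_scale <- switch(mode, uv = sds, pareto = sqrt(sds),
                    none = rep(1, length(sds)))
  x_scale[degenerate | x_scale == 0] <- 1
  xs <- sweep(sweep(x, 2L, x_mean), 2L, x_scale, "/")
  out <- list(x = xs, x_mean = x_mean, x_scale = x_scale,
              degenerate = degenerate, mode = mode)
  if (!is.null(y)) {
    y <- as.numeric(y)
    out$y_mean <- mean(y)
    ysd <- stats::sd(y)
    out$y_scale <- switch(mode, uv = ysd, pareto = sqrt(ysd), none = 1)
    if (!is.finite(out$y_scale) || out$y_scale == 0) out$y_scale <- 1
    out$y <- (y - out$y_mean) / out$y_scale
  }
  out
}

norm2 <- function(v) sqrt(sum(v^2))

# core fit on an already centred/scaled X and y
opls_core <- function(Xs, ys, n_ortho) {
  n <- nrow(Xs); m <- ncol(Xs)
  k <- as.integer(n_ortho)
  if (k < 0L || k >= min(n, m) - 1L)
    stop("n_ortho must satisfy 0 <= k < min(n, m) - 1", call. = FALSE)
  X <- Xs
  To <- matrix(0, n, k); Po <- matrix(0, m, k); Wo <- matrix(0, m, k)
  for (a in seq_len(k)) {
    w <- crossprod(X, ys) / sum(ys^2)
    w <- w / norm2(w)
    t <- X %*% w
    p <- crossprod(X, t) / sum(t^2)
    wo <- p - drop(crossprod(w, p)) * w   # w'w = 1
    nwo <- norm2(wo)
    if (nwo < 1e-12)
      stop("orthogonal component ", a, " is degenerate (X is y-spanned); ",
           "reduce n_ortho", call. = FALSE)
    wo <- wo / nwo
    to <- X %*% wo
    po <- crossprod(X, to) / sum(to^2)
    X <- X - tcrossprod(to, po)
    To[, a] <- to; Po[, a] <- po; Wo[, a] <- wo
  }
  w <- crossprod(X, ys) / sum(ys^2)
  w <- w / norm2(w)
  t1 <- drop(X %*% w)
  p1 <- drop(crossprod(X, t1) / sum(t1^2))
  q1 <- sum(ys * t1) / sum(t1^2)
  if (q1 < 0) {  # sign convention: higher t1 goes with higher y (malignant)
    w <- -w; t1 <- -t1; p1 <- -p1; q1 <- -q1
  }
  E <- X - tcrossprod(t1, p1)
  F <- ys - t1 * q1
  list(w = drop(w), t1 = t1, p1 = p1, q1 = q1,
       To = To, Po = Po, Wo = Wo, E = E, F = F)
}

#' Fit an OPLS model
#'
#' Fits a single-response OPLS model with one predictive and `n_ortho`
#' orthogonal components. With a 0/1 class response this is OPLS-DA; with
#' a continuous response, OPLS regression. Orthogonal components are
#' extracted first (each from the loading's component orthogonal to the
#' predictive weight, deflating X), then the predictive component is the
#' PLS1 component of the deflated matrix. The predictive score sign is
#' fixed so that higher `t1` corresponds to higher response (for class
#' responses: malignant).
#'
#' @param x Predictor matrix ([feature_matrix()] or numeric matrix),
#'   samples in rows.
#' @param y Response: a [response_vector()], a numeric vector (0/1 coding
#'   is treated as benign/malignant classes), or a two-level factor whose
#'   second level codes the positive (malignant) class.
#' @param n_ortho Number of orthogonal components (default 3).
#' @param scale Scaling mode, `"uv"` (default), `"pareto"` or `"none"`.
#' @return Object of class `opls` with weights (`w`, `Wo`), loadings
#'   (`p1`, `q1`, `Po`), scores (`t1`, `To`), residuals (`E`, `F`),
#'   scaling constants, per-component score variances and fit statistics
#'   `r2y`, `r2x`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40 * 8), 40)
#' y <- as.numeric(x[, 1] + rnorm(40, sd = 0.3) > 0)
#' m <- opls(x, y, n_ortho = 1)
#' summary(m)
#' @export
opls <- function(x, y, n_ortho = 3L, scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  if (inherits(x, "feature_matrix") && inherits(y, "response_vector"))
    y <- match_response(x, y)
  kind <- if (is.factor(y)) {
    if (nlevels(y) != 2L) stop("factor response must have 2 levels",
                               call. = FALSE)
    y <- as.numeric(y) - 1
    "class"
  } else response_kind(y)
  yv <- as.numeric(y)
  if (length(yv) != nrow(x)) stop("length(y) must equal nrow(x)",
                                  call. = FALSE)
  if (stats::sd(yv) == 0) stop("response is constant", call. = FALSE)
  if (nrow(x) < 3L) stop("need at least 3 samples", call. = FALSE)
  cs <- center_scale(x, yv, mode = scale)
  fit <- opls_core(cs$x, cs$y, n_ortho)
  scores <- cbind(p = fit$t1, o = fit$To)
  A <- 1L + as.integer(n_ortho)
  ss_tot <- sum(cs$y^2)
  r2y <- 1 - sum(fit$F^2) / ss_tot
  r2x <- 1 - sum(fit$E^2) / sum(cs$x^2)
  s0 <- if (nrow(x) > A + 1L && ncol(x) > A)
    sqrt(sum(fit$E^2) / ((nrow(x) - A - 1L) * (ncol(x) - A))) else NA_real_
  structure(list(
    n_ortho = as.integer(n_ortho), kind = kind, scaling_mode = scale,
    w = fit$w, p1 = fit$p1, q1 = fit$q1,
    t1 = stats::setNames(fit$t1, rownames(x)),
    To = fit$To, Po = fit$Po, Wo = fit$Wo,
    x_mean = cs$x_mean, x_scale = cs$x_scale,
    y_mean = cs$y_mean, y_scale = cs$y_scale,
    degenerate_columns = which(cs$degenerate),
    E = fit$E, F = fit$F,
    score_variances = apply(scores, 2L, stats::var),
    s0 = s0, r2y = r2y, r2x = r2x,
    n = nrow(x), m = ncol(x),
    bin_centers = if (inherits(x, "feature_matrix")) bin_centers(x) else NULL,
    y = stats::setNames(yv, rownames(x))),
    class = "opls")
}

# centre/scale new data and remove the orthogonal variation; returns the
# filtered scaled matrix plus orthogonal scores
opls_filter <- function(object, newdata) {
  x <- as.matrix(newdata)
  if (ncol(x) != object$m)
    stop("newdata has ", ncol(x), " columns; model expects ", object$m,
         call. = FALSE)
  xs <- sweep(sweep(x, 2L, object$x_mean), 2L, object$x_scale, "/")
  k <- object$n_ortho
  To <- matrix(0, nrow(xs), k)
  for (a in seq_len(k)) {
    to <- drop(xs %*% object$Wo[, a])
    xs <- xs - outer(to, object$Po[, a])
    To[, a] <- to
  }
  list(x = xs, To = To)
}

#' Predict from an OPLS model
#'
#' Applies the stored centring/scaling, sequentially removes the
#' orthogonal variation, projects onto the predictive weight and maps the
#' predictive score back to response units.
#'
#' @param object An [opls()] fit.
#' @param newdata Matrix (or [feature_matrix()]) with the model's columns.
#'   Omitted: the training data are reproduced from the stored scores.
#' @param type `"response"` (numeric prediction), `"class"` (0/1 call at
#'   the 0.5 threshold; class models only) or `"scores"` (list with `t1`,
#'   `To` and `y_hat`).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.opls <- function(object, newdata = NULL,
                         type = c("response", "class", "scores"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    t1 <- object$t1
    To <- object$To
  } else {
    fl <- opls_filter(object, newdata)
    t1 <- stats::setNames(drop(fl$x %*% object$w), rownames(newdata))
    To <- fl$To
  }
  y_hat <- t1 * object$q1 * object$y_scale + object$y_mean
  switch(type,
         response = y_hat,
         class = classify(y_hat, kind = object$kind),
         scores = list(t1 = t1, To = To, y_hat = y_hat))
}

#' Threshold a predicted class response into class calls
#'
#' Calls malignant (1) iff the predicted response is at least 0.5; an
#' exact tie at 0.5 is called malignant (sensitivity-favouring) and
#' reported via the `"ties"` attribute.
#'
#' @param y_hat Numeric predictions on the 0/1 response scale.
#' @param kind Must be `"class"`; a continuous model cannot be thresholded.
#' @return Integer 0/1 vector with attribute `ties` (indices predicted at
#'   exactly 0.5).
#' @export
classify <- function(y_hat, kind = "class") {
  if (!identical(kind, "class"))
    stop("classify() requires a class-response model", call. = FALSE)
  calls <- as.integer(y_hat >= 0.5)
  structure(stats::setNames(calls, names(y_hat)),
            ties = which(y_hat == 0.5))
}

#' @export
fitted.opls <- function(object, ...) predict(object)

#' @export
residuals.opls <- function(object, ...) {
  stats::setNames(object$F * object$y_scale, names(object$t1))
}

#' Regression coefficients of an OPLS model
#'
#' The prediction is linear in the input spectrum, so the model collapses
#' to an intercept plus one coefficient per bin on the raw intensity
#' scale; `predict()` and `intercept + x %*% coef` agree to machine
#' precision.
#'
#' @param object An [opls()] fit.
#' @param ... Unused.
#' @return Named numeric vector: `(Intercept)` followed by per-bin
#'   coefficients.
#' @export
coef.opls <- function(object, ...) {
  m <- object$m
  M <- diag(m)
  # sequential orthogonal filtering is the matrix product of the
  # per-component deflations, in extraction order
  for (a in seq_len(object$n_ortho))
    M <- M %*% (diag(m) - tcrossprod(object$Wo[, a], object$Po[, a]))
  beta_s <- drop(M %*% object$w) * object$q1   # scaled space
  b <- object$y_scale * beta_s / object$x_scale
  c("(Intercept)" = object$y_mean - sum(b * object$x_mean),
    stats::setNames(b, names(object$x_mean)))
}

#' @export
print.opls <- function(x, ...) {
  cat(sprintf("OPLS%s model: 1 predictive + %d orthogonal component(s)\n",
              if (x$kind == "class") "-DA" else "", x$n_ortho))
  cat(sprintf("  n = %d samples, m = %d variables, scaling = %s\n",
              x$n, x$m, x$scaling_mode))
  cat(sprintf("  R2Y = %.3f, R2X = %.3f\n", x$r2y, x$r2x))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  structure(list(model = object,
                 r2y = object$r2y, r2x = object$r2x,
                 score_variances = object$score_variances,
                 degenerate_columns = object$degenerate_columns),
            class = "summary.opls")
}

#' @export
print.summary.opls <- function(x, ...) {
  print(x$model)
  cat("  score variances:",
      paste(sprintf("%.3g", x$score_variances), collapse = ", "), "\n")
  if (length(x$degenerate_columns))
    cat("  zero-variance columns (centred, unscaled):",
        length(x$degenerate_columns), "\n")
  invisible(x)
}

#' Score plot of an OPLS model
#'
#' Plots the predictive score `t1` against the first orthogonal score
#' (or sample index when `n_ortho = 0`), colouring by class for
#' discriminant models.
#'
#' @param x An [opls()] fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.opls <- function(x, ...) {
  t1 <- x$t1
  yo <- if (x$n_ortho >= 1L) x$To[, 1L] else seq_along(t1)
  col <- if (x$kind == "class") ifelse(x$y == 1, "firebrick", "steelblue")
         else "black"
  graphics::plot(t1, yo, col = col, pch = 19,
                 xlab = "t1 (predictive score)",
                 ylab = if (x$n_ortho >= 1L) "to1 (orthogonal score)"
                        else "sample index", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}
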