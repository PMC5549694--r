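# Cross-validated fit metrics, component-count selection, permutation
# null and confusion metrics.

#' Cross-validated Q2Y and training R2Y
#'
#' Deterministic venetian-blind cross-validation: row i goes to fold
#' `((i - 1) mod folds) + 1`. For each fold the FULL pipeline downstream
#' of the feature matrix (centring, scaling and all components) is refit
#' on the in-fold rows and the held-out rows are predicted.
#' `Q2Y = 1 - PRESS / SS_tot` with PRESS the summed squared out-of-fold
#' errors and SS_tot the total response sum of squares about the
#' full-data mean; `R2Y` is from the full-data fit.
#'
#' @param x Predictor matrix.
#' @param y Response (numeric / [response_vector()] / 2-level factor).
#' @param n_ortho Orthogonal components.
#' @param folds Number of folds (default 7).
#' @param scale Scaling mode.
#' @return Object of class `eval_report` with `r2y`, `q2y`, `folds`.
#' @export
cv_opls <- function(x, y, n_ortho = 3L, folds = 7L,
                    scale = c("uv", "pareto", "none")) {
  scale <- match.arg(scale)
  if (is.factor(y)) y <- as.numeric(y) - 1
  yv <- as.numeric(y)
  n <- nrow(x)
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  fold <- ((seq_len(n) - 1L) %% folds) + 1L
  sizes <- tabulate(fold, folds)
  if (any(sizes < 2L))
    stop("venetian-blind folds leave a fold with < 2 samples (n = ", n, ")",
         call. = FALSE)
  press <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (stats::sd(yv[tr]) == 0)
      stop("fold ", f, " leaves a constant training response", call. = FALSE)
    fit <- opls(x[tr, , drop = FALSE], yv[tr], n_ortho = n_ortho,
                scale = scale)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    press <- press + sum((yv[!tr] - pred)^2)
  }
  full <- opls(x, yv, n_ortho = n_ortho, scale = scale)
  ss_tot <- sum((yv - mean(yv))^2)
  structure(list(r2y = full$r2y, q2y = 1 - press / ss_tot,
                 folds = as.integer(folds), n = n, n_ortho = full$n_ortho),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("evaluation report (n = %d)\n", x$n))
  if (!is.null(x$q2y))
    cat(sprintf("  R2Y = %.3f, Q2Y = %.3f (%d-fold CV, %d orthogonal comp.)\n",
                x$r2y, x$q2y, x$folds, x$n_ortho))
  if (!is.null(x$confusion)) {
    cm <- x$confusion
    cat(sprintf("  confusion: TP=%d FP=%d TN=%d FN=%d\n",
                cm["tp"], cm["fp"], cm["tn"], cm["fn"]))
    cat(sprintf("  sensitivity = %.1f%%, specificity = %.1f%%\n",
                x$sensitivity, x$specificity))
  }
  invisible(x)
}

#' Choose the number of orthogonal components by cross-validation
#'
#' Starting at zero, adds an orthogonal component while Q2Y improves by
#' more than `min_gain` (default 0.01 absolute), and returns the last
#' count before the improvement stalls.
#'
#' @inheritParams cv_opls
#' @param max_ortho Upper bound on components (default 10).
#' @param min_gain Minimum Q2Y improvement to keep adding (default 0.01).
#' @return Integer component count; the Q2Y path is attached as
#'   attribute `"q2_path"`.
#' @export
autofit_opls <- function(x, y, max_ortho = 10L, folds = 7L,
                         scale = c("uv", "pareto", "none"),
                         min_gain = 0.01) {
  scale <- match.arg(scale)
  max_ortho <- min(max_ortho, min(nrow(x), ncol(x)) - 2L)
  q2 <- cv_opls(x, y, n_ortho = 0L, folds = folds, scale = scale)$q2y
  path <- q2
  k <- 0L
  while (k < max_ortho) {
    q2_next <- tryCatch(
      cv_opls(x, y, n_ortho = k + 1L, folds = folds, scale = scale)$q2y,
      error = function(e) -Inf)
    path <- c(path, q2_next)
    if (!(q2_next > q2 + min_gain)) break
    k <- k + 1L
    q2 <- q2_next
  }
  structure(k, q2_path = path)
}

#' Permutation null distribution of Q2Y
#'
#' Refits the cross-validated model on randomly permuted responses; the
#' resulting Q2Y distribution is the overfitting null against which the
#' real Q2Y is judged.
#'
#' @inheritParams cv_opls
#' @param n_perm Number of permutations (default 50).
#' @param seed RNG seed for the permutations.
#' @return Numeric vector of Q2Y values, one per permutation.
#' @export
permutation_q2 <- function(x, y, n_ortho = 3L, folds = 7L, n_perm = 50L,
                           scale = c("uv", "pareto", "none"), seed = 1L) {
  scale <- match.arg(scale)
  if (is.factor(y)) y <- as.numeric(y) - 1
  yv <- as.numeric(y)
  set.seed(seed)
  vapply(seq_len(n_perm), function(i)
    cv_opls(x, sample(yv), n_ortho = n_ortho, folds = folds,
            scale = scale)$q2y,
    numeric(1))
}

#' Confusion counts and rates for binary class calls
#'
#' @param truth 0/1 true classes (1 = malignant).
#' @param calls 0/1 predicted classes.
#' @return Object of class `eval_report` with `confusion`
#'   (`tp`, `fp`, `tn`, `fn`), `sensitivity` = TP/(TP+FN) and
#'   `specificity` = TN/(TN+FP), both in percent.
#' @export
confusion_metrics <- function(truth, calls) {
  truth <- as.integer(truth); calls <- as.integer(calls)
  stopifnot(length(truth) == length(calls),
            all(truth %in% 0:1), all(calls %in% 0:1))
  tp <- sum(truth == 1 & calls == 1); fn <- sum(truth == 1 & calls == 0)
  tn <- sum(truth == 0 & calls == 0); fp <- sum(truth == 0 & calls == 1)
  structure(list(confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn)
                               else NA_real_,
                 specificity = if (tn + fp > 0) 100 * tn / (tn + fp)
                               else NA_real_,
                 n = length(truth)),
            class = "eval_report")
}
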