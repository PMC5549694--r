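# Model diagnostics: DModX (residual distance to the model plane),
# Hotelling's T2 on the scores, and loading-correlation interpretation of
# the predictive component.

#' DModX: normalized residual distance to the model
#'
#' For sample i with X-residual row e_i over m variables and A = 1 + k
#' total components, `s_i = sqrt(sum(e_i^2) / (m - A))` and
#' `DModX_i = s_i / s_0`, where
#' `s_0 = sqrt(sum(E^2) / ((n - A - 1)(m - A)))` is the pooled training
#' residual SD. New samples are normalized by the training `s_0`. The
#' control limit at level `alpha` comes from the F distribution of the
#' squared ratio.
#'
#' @param model An [opls()] fit.
#' @param newdata Optional matrix on the model's columns; default uses the
#'   training residuals.
#' @param alpha Significance level for the control limit (default 0.05).
#' @return List with `dmodx` (per sample), `crit` and `alpha`.
#' @export
dmodx <- function(model, newdata = NULL, alpha = 0.05) {
  A <- 1L + model$n_ortho
  if (model$m <= A) stop("m must exceed the number of components",
                         call. = FALSE)
  if (!is.finite(model$s0) || model$s0 == 0)
    stop("training residual SD is degenerate", call. = FALSE)
  E <- if (is.null(newdata)) model$E else {
    fl <- opls_filter(model, newdata)
    t1 <- drop(fl$x %*% model$w)
    fl$x - tcrossprod(t1, model$p1)
  }
  s_i <- sqrt(rowSums(E^2) / (model$m - A))
  d <- stats::setNames(s_i / model$s0,
                       if (is.null(newdata)) names(model$t1)
                       else rownames(newdata))
  crit <- sqrt(stats::qf(1 - alpha, model$m - A,
                         (model$n - A - 1L) * (model$m - A)))
  list(dmodx = d, crit = crit, alpha = alpha)
}

#' Hotelling's T2 of score vectors
#'
#' `T2_i = sum_a t_ia^2 / var(t_a)` over the A = 1 + k components, with
#' per-component score variances taken from the training fit (sample
#' variance, n - 1 denominator). The control limit is
#' `A (n - 1) / (n - A) * F(1 - alpha; A, n - A)`.
#'
#' @param model An [opls()] fit.
#' @param scores Optional n x A matrix `cbind(t1, To)`; default uses the
#'   training scores.
#' @param alpha Significance level (default 0.05).
#' @return List with `t2` (per sample), `crit` and `alpha`.
#' @export
hotelling_t2 <- function(model, scores = NULL, alpha = 0.05) {
  A <- 1L + model$n_ortho
  n <- model$n
  if (n <= A) stop("n must exceed the number of components", call. = FALSE)
  if (is.null(scores)) scores <- cbind(model$t1, model$To)
  scores <- as.matrix(scores)
  if (ncol(scores) != A)
    stop("scores must have 1 + n_ortho columns", call. = FALSE)
  v <- model$score_variances
  t2 <- rowSums(sweep(scores^2, 2L, v, "/"))
  crit <- A * (n - 1) / (n - A) * stats::qf(1 - alpha, A, n - A)
  list(t2 = t2, crit = crit, alpha = alpha)
}

#' Correlation of each variable with the predictive component
#'
#' For each bin j, the Pearson correlation and covariance between the
#' scaled column X_j and the predictive score t1 — the basis of the
#' S-plot-style interpretation of which spectral regions drive the
#' discrimination. For class models the default orientation flips the
#' sign so that benign-predictive bins are positive (plot "above the
#' axis"); `orient = "raw"` keeps the correlation with t1 as is
#' (malignant-predictive positive, since higher t1 is malignant).
#' Zero-variance bins get correlation 0 and are flagged.
#'
#' @param model An [opls()] fit.
#' @param x The (training) predictor matrix the model was fitted on.
#' @param orient `"benign"` (default for class models) or `"raw"`.
#' @return data.frame with `bin_center` (when known), `correlation`,
#'   `covariance` and `degenerate`.
#' @export
loading_correlations <- function(model, x, orient = c("benign", "raw")) {
  orient <- match.arg(orient)
  xs <- sweep(sweep(as.matrix(x), 2L, model$x_mean), 2L, model$x_scale, "/")
  t1 <- if (is.null(rownames(xs)) || is.null(names(model$t1)))
    model$t1 else model$t1[rownames(xs)]
  sds <- apply(xs, 2L, stats::sd)
  degenerate <- sds == 0
  r <- rep(0, ncol(xs)); cv <- rep(0, ncol(xs))
  ok <- !degenerate
  r[ok] <- drop(stats::cor(xs[, ok, drop = FALSE], t1))
  cv[ok] <- drop(stats::cov(xs[, ok, drop = FALSE], t1))
  if (orient == "benign") {
    if (model$kind != "class")
      stop("benign orientation applies to class models only", call. = FALSE)
    r <- -r; cv <- -cv   # higher t1 = malignant, so flip for benign-positive
  }
  data.frame(bin_center = if (!is.null(model$bin_centers)) model$bin_centers
             else seq_len(ncol(xs)),
             correlation = r, covariance = cv, degenerate = degenerate)
}
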