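# End-to-end study workflow: train on one cohort, blindly predict a
# later cohort, report confusion metrics, and run the tissue-age control
# analysis. Normalization/alignment references, the binning window and
# all scaling constants derive from the training cohort only.

#' Study design
#'
#' Declares the train/test split and modelling settings of a blinded
#' classification study.
#'
#' @param train_ids,test_ids Disjoint character vectors of sample ids.
#' @param n_ortho Orthogonal components for the model (default 3).
#' @param preprocess A [preprocess_config()].
#' @param scale Scaling mode for the model.
#' @param folds Cross-validation folds (default 7).
#' @return Object of class `study_design`.
#' @export
study_design <- function(train_ids, test_ids, n_ortho = 3L,
                         preprocess = preprocess_config(),
                         scale = "uv", folds = 7L) {
  if (length(intersect(train_ids, test_ids)))
    stop("train and test ids must be disjoint", call. = FALSE)
  structure(list(train_ids = as.character(train_ids),
                 test_ids = as.character(test_ids),
                 n_ortho = as.integer(n_ortho), preprocess = preprocess,
                 scale = scale, folds = as.integer(folds)),
            class = "study_design")
}

label_response <- function(labels, ids, kind = "class") {
  idx <- match(ids, labels$sample_id)
  if (anyNA(idx))
    stop("labels missing for: ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  vals <- if (kind == "class") labels$code[idx]
          else labels$months_since_extraction[idx]
  response_vector(vals, sample_ids = ids, kind = kind)
}

#' Train the classification model on a cohort
#'
#' Runs the full pipeline on the training cohort: preprocessing (with the
#' alignment reference, PQN reference and binning window fitted on these
#' spectra), an OPLS-DA fit with `n_ortho` orthogonal components,
#' venetian-blind cross-validation, and DModX / Hotelling's T2
#' diagnostics.
#'
#' @param spectra List of [spectrum1d()] for the training cohort.
#' @param labels Label data.frame (see [read_labels()]) covering all
#'   training ids with both classes present.
#' @param design A [study_design()]; `NULL` derives one from the data
#'   with default settings.
#' @return Object of class `opls_run`: `model`, `eval` (R2Y/Q2Y),
#'   `diagnostics` (`dmodx`, `t2`), `fm`, `refs` (training-derived
#'   preprocessing constants), `design`, `log`.
#' @export
run_train <- function(spectra, labels, design = NULL) {
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (is.null(design))
    design <- study_design(ids, character(0))
  y <- label_response(labels, ids, kind = "class")
  if (length(unique(y)) < 2L)
    stop("training set contains a single class", call. = FALSE)
  pp <- preprocess_spectra(spectra, design$preprocess)
  model <- opls(pp$fm, y, n_ortho = design$n_ortho, scale = design$scale)
  eval <- cv_opls(pp$fm, as.numeric(y), n_ortho = design$n_ortho,
                  folds = design$folds, scale = design$scale)
  diag <- list(dmodx = dmodx(model), t2 = hotelling_t2(model))
  log <- c(pp$log,
           sprintf("model: OPLS-DA, 1 + %d components, %s scaling, n = %d",
                   design$n_ortho, design$scale, length(spectra)),
           sprintf("fit: R2Y = %.4f, Q2Y = %.4f (%d-fold venetian blind)",
                   eval$r2y, eval$q2y, design$folds),
           "replaced manual phase/baseline steps: automated operators only")
  structure(list(model = model, eval = eval, diagnostics = diag,
                 fm = pp$fm, refs = pp$refs, design = design,
                 dilution = pp$dilution, align_report = pp$align_report,
                 log = log),
            class = "opls_run")
}

#' @export
print.opls_run <- function(x, ...) {
  cat("Trained OPLS-DA pipeline\n")
  print(x$model)
  cat(sprintf("  7-fold Q2Y = %.3f\n", x$eval$q2y))
  invisible(x)
}

#' Blindly classify a test cohort and unseal its labels
#'
#' Preprocesses the test spectra with the training-derived constants
#' (alignment reference, binning window, PQN reference, model scaling),
#' predicts and writes the class calls to `predictions_path`, records the
#' file's MD5 hash, and only then evaluates the sealed labels into
#' confusion counts, sensitivity and specificity.
#'
#' @param run An [run_train()] result.
#' @param spectra_test List of [spectrum1d()] for the test cohort; ids
#'   must not overlap the training ids.
#' @param labels_sealed Label data.frame for the test ids (read after
#'   predictions are written).
#' @param predictions_path Where to write the prediction CSV (default a
#'   temporary file).
#' @return `eval_report` with confusion counts, sensitivity and
#'   specificity in percent, plus `predictions` (data.frame), `y_hat`,
#'   `prediction_hash` and `log`.
#' @export
run_blinded_test <- function(run, spectra_test, labels_sealed,
                             predictions_path = tempfile(fileext = ".csv")) {
  stopifnot(inherits(run, "opls_run"))
  ids <- vapply(spectra_test, `[[`, "", "sample_id")
  overlap <- intersect(ids, names(run$model$t1))
  if (length(overlap))
    stop("test ids overlap the training set: ",
         paste(overlap, collapse = ", "), call. = FALSE)
  pp <- preprocess_spectra(spectra_test, run$design$preprocess,
                           refs = run$refs)
  y_hat <- predict(run$model, pp$fm)
  calls <- classify(y_hat)
  pred <- data.frame(sample_id = ids, y_hat = as.numeric(y_hat),
                     call = ifelse(calls == 1, "malignant", "benign"),
                     stringsAsFactors = FALSE)
  utils::write.table(pred, predictions_path, sep = ",", row.names = FALSE,
                     quote = FALSE)
  hash <- unname(tools::md5sum(predictions_path))   # recorded pre-unsealing
  truth <- label_response(labels_sealed, ids, kind = "class")
  report <- confusion_metrics(as.numeric(truth), calls)
  report$predictions <- pred
  report$y_hat <- y_hat
  report$prediction_hash <- hash
  report$log <- c(sprintf("predictions written to %s (md5 %s) before labels read",
                          predictions_path, hash),
                  sprintf("confusion: TP=%d FP=%d TN=%d FN=%d",
                          report$confusion["tp"], report$confusion["fp"],
                          report$confusion["tn"], report$confusion["fn"]))
  report
}

#' Tissue-age control analysis
#'
#' Refits the identical pipeline with a continuous response — months
#' since tissue extraction — instead of the class indicator, reporting
#' the cross-validated Q2Y on the training cohort and, when a test cohort
#' is given, the correlation between predicted and true age. With ages
#' independent of the spectra this control should show no predictive
#' ability.
#'
#' @param spectra Training spectra.
#' @param labels Label data.frame with `months_since_extraction` for all
#'   training ids.
#' @param design A [study_design()] (default settings when `NULL`).
#' @param spectra_test,labels_test Optional blinded test cohort.
#' @return List with `q2y`, `r2y`, `model`, and when a test cohort is
#'   given `test_cor` (Pearson r between predicted and true age) and
#'   `test_predictions`.
#' @export
run_age_control <- function(spectra, labels, design = NULL,
                            spectra_test = NULL, labels_test = NULL) {
  ids <- vapply(spectra, `[[`, "", "sample_id")
  if (is.null(design)) design <- study_design(ids, character(0))
  ages <- label_response(labels, ids, kind = "continuous")
  if (stats::sd(ages) == 0) stop("ages are constant", call. = FALSE)
  pp <- preprocess_spectra(spectra, design$preprocess)
  model <- opls(pp$fm, ages, n_ortho = design$n_ortho, scale = design$scale)
  eval <- cv_opls(pp$fm, as.numeric(ages), n_ortho = design$n_ortho,
                  folds = design$folds, scale = design$scale)
  out <- list(q2y = eval$q2y, r2y = eval$r2y, model = model, refs = pp$refs)
  if (!is.null(spectra_test)) {
    ids_t <- vapply(spectra_test, `[[`, "", "sample_id")
    pp_t <- preprocess_spectra(spectra_test, design$preprocess,
                               refs = pp$refs)
    pred <- predict(model, pp_t$fm)
    truth <- label_response(labels_test, ids_t, kind = "continuous")
    out$test_cor <- stats::cor(as.numeric(pred), as.numeric(truth))
    out$test_predictions <- data.frame(sample_id = ids_t,
                                       predicted_months = as.numeric(pred),
                                       true_months = as.numeric(truth))
  }
  out
}
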