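# Delimited-text readers/writers for spectra, label tables and feature
# matrices, plus JSON model serialization. Field separator is inferred
# from the file extension (.csv -> comma, anything else -> tab) unless
# given explicitly.

infer_sep <- function(path, sep = NULL) {
  if (!is.null(sep)) return(sep)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a table of spectra
#'
#' Reads 1D spectra from delimited text. In the `wide` dialect the first
#' column is the ppm axis and every remaining column one sample; in the
#' `long` dialect the columns are `sample_id`, `ppm`, `intensity`.
#' Ascending axes are reversed to the descending convention.
#'
#' @param path File path.
#' @param dialect `"wide"` or `"long"`.
#' @param sep Field separator; inferred from the extension when `NULL`.
#' @return List of [spectrum1d()] objects.
#' @export
read_spectra_table <- function(path, dialect = c("wide", "long"), sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- infer_sep(path, sep)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (dialect == "wide") {
    if (ncol(df) < 2L) stop("wide spectra table needs >= 2 columns",
                            call. = FALSE)
    ids <- colnames(df)[-1L]
    if (anyDuplicated(ids))
      stop("duplicate sample ids in header: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
    for (j in seq_along(df)) {
      col <- suppressWarnings(as.numeric(df[[j]]))
      bad <- which(is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric or missing value at row %d, column %d (%s)",
                     bad[1L], j, colnames(df)[j]), call. = FALSE)
      df[[j]] <- col
    }
    ppm <- df[[1L]]
    lapply(ids, function(id) spectrum1d(id, ppm, df[[id]]))
  } else {
    need <- c("sample_id", "ppm", "intensity")
    if (!all(need %in% colnames(df)))
      stop("long spectra table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    for (v in c("ppm", "intensity")) {
      col <- suppressWarnings(as.numeric(df[[v]]))
      bad <- which(is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric or missing value at row %d, column %s",
                     bad[1L], v), call. = FALSE)
      df[[v]] <- col
    }
    lapply(split(df, factor(df$sample_id, levels = unique(df$sample_id))),
           function(d) spectrum1d(d$sample_id[1L], d$ppm, d$intensity))
  }
}

#' Write a table of spectra
#'
#' Inverse of [read_spectra_table()]; `wide` requires all spectra to share
#' one ppm axis.
#'
#' @param spectra List of [spectrum1d()] objects.
#' @inheritParams read_spectra_table
#' @return Invisibly, `path`.
#' @export
write_spectra_table <- function(path, spectra, dialect = c("wide", "long"),
                                sep = NULL) {
  dialect <- match.arg(dialect)
  sep <- infer_sep(path, sep)
  if (dialect == "wide") {
    ppm <- spectra[[1L]]$ppm
    for (s in spectra)
      if (!isTRUE(all.equal(s$ppm, ppm, tolerance = 0)))
        stop("wide dialect requires a shared ppm axis", call. = FALSE)
    m <- do.call(cbind, lapply(spectra, `[[`, "intensity"))
    df <- data.frame(ppm = ppm, m, check.names = FALSE)
    colnames(df) <- c("ppm", vapply(spectra, `[[`, "", "sample_id"))
  } else {
    df <- do.call(rbind, lapply(spectra, function(s)
      data.frame(sample_id = s$sample_id, ppm = s$ppm,
                 intensity = s$intensity)))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a feature matrix
#'
#' CSV with a `sample_id` first column and bin-centre ppm values as the
#' remaining header fields, printed with 10 significant digits so
#' 0.04-ppm-wide bins round-trip losslessly.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  df <- data.frame(sample_id = rownames(fm),
                   unclass(fm)[, , drop = FALSE], check.names = FALSE)
  colnames(df) <- c("sample_id", format_ppm(bin_centers(fm)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  df <- utils::read.table(path, header = TRUE, sep = ",",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != length(header))
    stop("header length does not match data width", call. = FALSE)
  centers <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(centers)) stop("non-numeric bin centre in header", call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("non-numeric or missing cell in feature matrix", call. = FALSE)
  feature_matrix(vals, centers, sample_ids = df[[1L]])
}

#' Read a sample label table
#'
#' CSV with columns `sample_id`, `class` (`benign`/`malignant`) and
#' optionally `months_since_extraction`.
#'
#' @param path File path.
#' @return data.frame with `sample_id`, `class`, numeric `code`
#'   (0 benign / 1 malignant) and `months_since_extraction` (NA if absent).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = infer_sep(path),
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "class") %in% colnames(df)))
    stop("label table needs columns sample_id, class", call. = FALSE)
  cls <- tolower(df$class)
  if (!all(cls %in% c("benign", "malignant")))
    stop("class must be 'benign' or 'malignant'", call. = FALSE)
  data.frame(sample_id = as.character(df$sample_id), class = cls,
             code = as.numeric(cls == "malignant"),
             months_since_extraction =
               if ("months_since_extraction" %in% colnames(df))
                 as.numeric(df$months_since_extraction) else NA_real_,
             stringsAsFactors = FALSE)
}

#' Write a sample label table
#' @param labels data.frame as returned by [read_labels()].
#' @param path File path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(
    labels[, intersect(c("sample_id", "class", "months_since_extraction"),
                       colnames(labels))],
    path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize / restore a fitted OPLS model as JSON
#'
#' One JSON document holding every model field (weights, loadings, scores,
#' scaling constants, residuals, scaling mode), full double precision.
#'
#' @param model An [opls()] fit.
#' @param path File path.
#' @return `write_opls_json` returns `path` invisibly; `read_opls_json`
#'   the restored `opls` object.
#' @export
write_opls_json <- function(model, path) {
  stopifnot(inherits(model, "opls"))
  x <- unclass(model)
  x$package_version <- as.character(utils::packageVersion("oplsnmr"))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor", null = "null", na = "null")
  invisible(path)
}

#' @rdname write_opls_json
#' @export
read_opls_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$package_version <- NULL
  for (f in c("To", "Po", "Wo", "E"))
    if (!is.null(x[[f]]) && !is.matrix(x[[f]]))
      x[[f]] <- matrix(unlist(x[[f]]), nrow = NROW(x[[f]]))
  x$n_ortho <- as.integer(x$n_ortho)
  structure(x, class = "opls")
}
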