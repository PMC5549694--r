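# Data model for 1D 1H-NMR spectra, binned feature matrices and responses.
# ppm axes are stored descending (standard NMR display orientation);
# ascending input is reversed on construction and the conversion flagged.

#' Acquisition parameters of a 1D NMR experiment
#'
#' Bundles the parameters needed to reconstruct the chemical-shift (ppm)
#' axis of an acquired 1D spectrum: number of real data points, spectral
#' width in Hz, spectrometer frequency in MHz, and the carrier offset
#' (centre of the spectral window, here the water presaturation frequency)
#' in ppm.
#'
#' @param n_points Number of data points (default 32768, i.e. "32K").
#' @param spectral_width Spectral width in Hz (default 6200).
#' @param spectrometer_freq Spectrometer frequency in MHz (default 400).
#' @param center_ppm Carrier offset in ppm at the centre of the window
#'   (default 4.7, the water presaturation offset).
#' @return An object of class `acquisition_params`.
#' @examples
#' ppm_axis(acquisition_params())[1:3]
#' @export
acquisition_params <- function(n_points = 32768L, spectral_width = 6200,
                               spectrometer_freq = 400, center_ppm = 4.7) {
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 2L)
    stop("n_points must be an integer >= 2", call. = FALSE)
  if (!is.finite(spectral_width) || spectral_width <= 0)
    stop("spectral_width must be > 0", call. = FALSE)
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0)
    stop("spectrometer_freq must be > 0", call. = FALSE)
  structure(list(n_points = n_points, spectral_width = spectral_width,
                 spectrometer_freq = spectrometer_freq,
                 center_ppm = center_ppm),
            class = "acquisition_params")
}

#' Chemical-shift axis from acquisition parameters
#'
#' Builds the uniformly spaced, descending ppm axis implied by a set of
#' acquisition parameters. The total span is
#' `spectral_width / spectrometer_freq` ppm (Hz divided by MHz), centred
#' on `center_ppm`; endpoints are `center_ppm +/- span/2`.
#'
#' @param params An [acquisition_params()] object.
#' @return Numeric vector of length `n_points`, strictly descending.
#' @examples
#' p <- acquisition_params(n_points = 5, spectral_width = 4,
#'                         spectrometer_freq = 1, center_ppm = 10)
#' ppm_axis(p)  # 12 11 10 9 8
#' @export
ppm_axis <- function(params) {
  stopifnot(inherits(params, "acquisition_params"))
  span <- params$spectral_width / params$spectrometer_freq
  seq(params$center_ppm + span / 2, params$center_ppm - span / 2,
      length.out = params$n_points)
}

#' A single 1D spectrum
#'
#' Carrier of one sample's intensity trace on a ppm axis. The axis must be
#' strictly monotone; ascending axes are reversed to the package's
#' descending convention and the object flagged with attribute
#' `"reversed"`.
#'
#' @param sample_id Sample identifier (single string).
#' @param ppm Strictly monotone numeric chemical-shift axis.
#' @param intensity Numeric intensities, same length as `ppm`, all finite.
#' @return An object of class `spectrum1d` with elements `sample_id`,
#'   `ppm` (descending) and `intensity`.
#' @export
spectrum1d <- function(sample_id, ppm, intensity) {
  if (length(sample_id) != 1L || !nzchar(sample_id))
    stop("sample_id must be a single non-empty string", call. = FALSE)
  if (length(ppm) != length(intensity))
    stop("ppm and intensity must have equal length", call. = FALSE)
  if (anyNA(ppm) || anyNA(intensity) || !all(is.finite(intensity)))
    stop("ppm and intensity must be finite and non-missing", call. = FALSE)
  d <- diff(ppm)
  reversed <- FALSE
  if (all(d > 0)) {        # ascending input: flip to descending
    ppm <- rev(ppm); intensity <- rev(intensity); reversed <- TRUE
  } else if (!all(d < 0)) {
    stop("ppm axis must be strictly monotone", call. = FALSE)
  }
  structure(list(sample_id = as.character(sample_id),
                 ppm = as.numeric(ppm), intensity = as.numeric(intensity)),
            class = "spectrum1d", reversed = reversed)
}

#' @export
print.spectrum1d <- function(x, ...) {
  cat(sprintf("<spectrum1d> %s: %d points, %.3f .. %.3f ppm\n",
              x$sample_id, length(x$ppm), max(x$ppm), min(x$ppm)))
  invisible(x)
}

#' Binned feature matrix (the X-matrix)
#'
#' n samples by m bins of summed spectral intensity, with the bin-centre
#' ppm value of each column. This is the predictor matrix handed to
#' [opls()].
#'
#' @param values Numeric n x m matrix, no missing values.
#' @param bin_centers Strictly monotone numeric vector of length m.
#' @param sample_ids Character vector of length n (defaults to rownames).
#' @return An object of class `feature_matrix`: the matrix with
#'   `sample_ids` as rownames and a `bin_centers` attribute.
#' @export
feature_matrix <- function(values, bin_centers, sample_ids = rownames(values)) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("feature matrix must not contain missing values",
                          call. = FALSE)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("feature matrix needs at least 2 samples and 2 bins", call. = FALSE)
  if (length(bin_centers) != ncol(values))
    stop("bin_centers length must equal number of columns", call. = FALSE)
  d <- diff(bin_centers)
  if (!(all(d > 0) || all(d < 0)))
    stop("bin_centers must be strictly monotone", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in feature matrix", call. = FALSE)
  rownames(values) <- as.character(sample_ids)
  colnames(values) <- format_ppm(bin_centers)
  structure(values, bin_centers = as.numeric(bin_centers),
            class = c("feature_matrix", "matrix"))
}

#' @export
print.feature_matrix <- function(x, ...) {
  bc <- attr(x, "bin_centers")
  cat(sprintf("<feature_matrix> %d samples x %d bins (%.3f .. %.3f ppm)\n",
              nrow(x), ncol(x), max(bc), min(bc)))
  invisible(x)
}

#' Bin centres of a feature matrix
#' @param fm A [feature_matrix()].
#' @return Numeric vector of bin-centre ppm values.
#' @export
bin_centers <- function(fm) attr(fm, "bin_centers")

# ppm formatted with enough significant digits that 0.04-wide bins never
# collide on re-read
format_ppm <- function(x) formatC(x, format = "g", digits = 10)

#' Per-sample response vector (the Y-vector)
#'
#' Either a 0/1 class indicator (0 = benign, 1 = malignant) or a
#' continuous response such as months since tissue extraction.
#'
#' @param values Numeric vector; for `kind = "class"` only 0 and 1.
#' @param sample_ids Character ids, same length and order as `values`.
#' @param kind `"class"` or `"continuous"`.
#' @return Object of class `response_vector` (a named numeric vector with
#'   a `kind` attribute).
#' @export
response_vector <- function(values, sample_ids = names(values),
                            kind = c("class", "continuous")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (anyNA(values)) stop("response contains missing values", call. = FALSE)
  if (kind == "class" && !all(values %in% c(0, 1)))
    stop("class responses must be coded 0 (benign) / 1 (malignant)",
         call. = FALSE)
  if (!is.null(sample_ids)) {
    if (length(sample_ids) != length(values))
      stop("sample_ids length mismatch", call. = FALSE)
    names(values) <- as.character(sample_ids)
  }
  structure(values, kind = kind, class = "response_vector")
}

response_kind <- function(y) {
  k <- attr(y, "kind")
  if (!is.null(k)) return(k)
  if (all(y %in% c(0, 1))) "class" else "continuous"
}

# align a response to a feature matrix row-for-row by sample id
match_response <- function(fm, y) {
  if (is.null(names(y)) || is.null(rownames(fm))) return(y)
  idx <- match(rownames(fm), names(y))
  if (anyNA(idx))
    stop("response is missing sample ids: ",
         paste(setdiff(rownames(fm), names(y)), collapse = ", "),
         call. = FALSE)
  structure(as.numeric(y)[idx], names = rownames(fm),
            kind = response_kind(y), class = "response_vector")
}
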