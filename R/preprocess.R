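# Spectral standardization: recursive segment-wise peak alignment (RSPA),
# fixed-width binning, probabilistic quotient normalization (PQN), and an
# optional automated polynomial baseline operator. Pipeline order is fixed:
# (baseline) -> align -> bin -> normalize.

#' Preprocessing configuration
#'
#' @param bin_width Bin width in ppm (default 0.04).
#' @param ppm_window `c(low, high)` ppm window retained for binning;
#'   `NULL` (default) uses the full extent of the spectrum axis.
#' @param exclude_regions List of `c(low, high)` ppm intervals whose bins
#'   are dropped after binning (default none).
#' @param bin_stat Aggregate per bin: `"sum"` (canonical) or `"mean"`.
#' @param pqn_enabled Apply probabilistic quotient normalization.
#' @param pqn_prenormalize_area Total area each spectrum is scaled to
#'   before quotient estimation (default 100).
#' @param rspa_max_shift Maximum per-segment shift in points (default 10).
#' @param rspa_min_segment Minimum segment length in points (default 50).
#' @param rspa_corr_gain_min Minimum correlation gain for a segment shift
#'   to be applied / recursion to continue (default 0.01).
#' @param baseline_enabled Apply polynomial baseline correction first.
#' @param baseline_degree Polynomial degree for the baseline (0..5).
#' @return Object of class `preprocess_config`.
#' @export
preprocess_config <- function(bin_width = 0.04, ppm_window = NULL,
                              exclude_regions = list(),
                              bin_stat = c("sum", "mean"),
                              pqn_enabled = TRUE, pqn_prenormalize_area = 100,
                              rspa_max_shift = 10L, rspa_min_segment = 50L,
                              rspa_corr_gain_min = 0.01,
                              baseline_enabled = FALSE, baseline_degree = 2L) {
  bin_stat <- match.arg(bin_stat)
  if (!is.finite(bin_width) || bin_width <= 0)
    stop("bin_width must be > 0", call. = FALSE)
  if (!is.null(ppm_window) &&
      (length(ppm_window) != 2L || ppm_window[1L] >= ppm_window[2L]))
    stop("ppm_window must be c(low, high) with low < high", call. = FALSE)
  if (rspa_max_shift < 0L) stop("rspa_max_shift must be >= 0", call. = FALSE)
  if (rspa_min_segment < 3L) stop("rspa_min_segment must be >= 3", call. = FALSE)
  structure(list(bin_width = bin_width, ppm_window = ppm_window,
                 exclude_regions = exclude_regions, bin_stat = bin_stat,
                 pqn_enabled = pqn_enabled,
                 pqn_prenormalize_area = pqn_prenormalize_area,
                 rspa_max_shift = as.integer(rspa_max_shift),
                 rspa_min_segment = as.integer(rspa_min_segment),
                 rspa_corr_gain_min = rspa_corr_gain_min,
                 baseline_enabled = baseline_enabled,
                 baseline_degree = as.integer(baseline_degree)),
            class = "preprocess_config")
}

## ---- baseline -------------------------------------------------------------

#' Automated polynomial baseline correction
#'
#' Subtracts a polynomial fitted to iteratively re-selected low-intensity
#' points (points above the current fit plus one residual SD are dropped
#' from the fit until the support stabilises). A simple automated stand-in
#' for interactive baseline correction; off by default in the pipeline.
#'
#' @param s A [spectrum1d()].
#' @param degree Polynomial degree, 0..5.
#' @param max_iter Maximum re-selection iterations.
#' @return Baseline-corrected [spectrum1d()].
#' @export
baseline_correct <- function(s, degree = 2L, max_iter = 20L) {
  stopifnot(inherits(s, "spectrum1d"))
  degree <- as.integer(degree)
  if (degree < 0L || degree > 5L) stop("degree must be in 0..5", call. = FALSE)
  x <- seq_along(s$intensity) / length(s$intensity)
  y <- s$intensity
  keep <- rep(TRUE, length(y))
  fit <- rep(mean(y), length(y))
  for (it in seq_len(max_iter)) {
    fit <- if (degree == 0L) rep(mean(y[keep]), length(y)) else {
      co <- stats::lm.fit(stats::poly(x, degree, raw = TRUE,
                                      simple = TRUE)[keep, , drop = FALSE] |>
                            (\(m) cbind(1, m))(), y[keep])$coefficients
      co[is.na(co)] <- 0
      drop(cbind(1, stats::poly(x, degree, raw = TRUE, simple = TRUE)) %*% co)
    }
    s2 <- stats::sd(y[keep] - fit[keep])
    if (!is.finite(s2) || s2 == 0) break
    keep_new <- y <= fit + s2
    if (all(keep_new == keep)) break
    keep <- keep_new
    if (sum(keep) <= degree + 1L) break
  }
  spectrum1d(s$sample_id, s$ppm, y - fit)
}

## ---- RSPA alignment -------------------------------------------------------

# Pearson correlation that is 0 (not NA) for degenerate segments
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

# shift a segment by s points (positive = toward higher index), vacated
# edge points filled by boundary-value repetition
shift_segment <- function(seg, s) {
  n <- length(seg)
  if (s == 0L) return(seg)
  if (s > 0L) c(rep(seg[1L], s), seg[seq_len(n - s)])
  else c(seg[(1L - s):n], rep(seg[n], -s))
}

# best integer shift of seg against ref in -max_shift..max_shift;
# ties broken toward the smallest |shift|, then toward the positive one
best_segment_shift <- function(seg, ref, max_shift) {
  shifts <- seq.int(-max_shift, max_shift)
  shifts <- shifts[order(abs(shifts), -sign(shifts))]
  cors <- vapply(shifts, function(s) safe_cor(shift_segment(seg, s), ref),
                 numeric(1))
  best <- which.max(cors)
  list(shift = shifts[best], cor = cors[best],
       cor0 = cors[shifts == 0L])
}

rspa_align_one <- function(intensity, ref, ppm, cfg) {
  records <- list()
  x <- intensity
  recurse <- function(lo, hi, depth) {
    len <- hi - lo + 1L
    if (len < cfg$rspa_min_segment || len <= cfg$rspa_max_shift) return()
    seg <- x[lo:hi]; rseg <- ref[lo:hi]
    bs <- best_segment_shift(seg, rseg, cfg$rspa_max_shift)
    gain <- bs$cor - bs$cor0
    applied <- bs$shift != 0L && gain >= cfg$rspa_corr_gain_min
    if (applied) {
      shifted <- shift_segment(seg, bs$shift)
      x[lo:hi] <<- shifted
      delta <- sum(shifted) - sum(seg)
    } else delta <- 0
    records[[length(records) + 1L]] <<- data.frame(
      ppm_high = ppm[lo], ppm_low = ppm[hi], depth = depth,
      shift = if (applied) bs$shift else 0L,
      cor_before = bs$cor0,
      cor_after = if (applied) bs$cor else bs$cor0,
      gain = gain, applied = applied, intensity_delta = delta)
    if (gain < cfg$rspa_corr_gain_min) return()  # converged: stop recursing
    # split at the minimum-intensity interior point of the reference
    # within the middle third of the segment
    a <- lo + len %/% 3L; b <- hi - len %/% 3L
    if (b <= a) return()
    split <- (a:b)[which.min(ref[a:b])]
    recurse(lo, split, depth + 1L)
    recurse(split + 1L, hi, depth + 1L)
  }
  recurse(1L, length(x), 0L)
  list(intensity = x, report = do.call(rbind, records))
}

#' Recursive segment-wise peak alignment
#'
#' Aligns each spectrum to a reference by recursively shifting segments:
#' the whole segment is shifted by the integer offset (at most
#' `rspa_max_shift` points) that maximises its Pearson correlation with
#' the reference; the segment is then split at the minimum-intensity
#' interior point of the reference within its middle third and the halves
#' are aligned recursively, until a segment is shorter than
#' `rspa_min_segment` or the correlation gain falls below
#' `rspa_corr_gain_min`. A shift is only applied when it improves the
#' correlation by at least `rspa_corr_gain_min`; vacated edge points are
#' filled by boundary-value repetition.
#'
#' @param spectra List of [spectrum1d()] sharing one ppm axis.
#' @param reference A [spectrum1d()] on the same axis, or `"median"`
#'   (default) for the element-wise median spectrum of the cohort.
#' @param cfg A [preprocess_config()].
#' @return List with `spectra` (aligned) and `report` (one row per
#'   examined segment: ppm range, applied shift, correlation before and
#'   after, total intensity change).
#' @export
rspa_align <- function(spectra, reference = "median",
                       cfg = preprocess_config()) {
  ppm <- spectra[[1L]]$ppm
  for (s in spectra)
    if (length(s$ppm) != length(ppm) ||
        max(abs(s$ppm - ppm)) > 1e-9 * max(abs(ppm)))
      stop("all spectra must share one ppm axis", call. = FALSE)
  if (cfg$rspa_max_shift >= length(ppm))
    stop("rspa_max_shift must be smaller than the spectrum length",
         call. = FALSE)
  ref <- if (identical(reference, "median")) {
    apply(do.call(cbind, lapply(spectra, `[[`, "intensity")), 1L,
          stats::median)
  } else {
    stopifnot(inherits(reference, "spectrum1d"))
    if (max(abs(reference$ppm - ppm)) > 1e-9 * max(abs(ppm)))
      stop("reference must be on the same ppm axis", call. = FALSE)
    reference$intensity
  }
  out <- vector("list", length(spectra))
  reports <- vector("list", length(spectra))
  for (i in seq_along(spectra)) {
    r <- rspa_align_one(spectra[[i]]$intensity, ref, ppm, cfg)
    out[[i]] <- spectrum1d(spectra[[i]]$sample_id, ppm, r$intensity)
    if (!is.null(r$report)) {
      r$report$sample_id <- spectra[[i]]$sample_id
      reports[[i]] <- r$report
    }
  }
  list(spectra = out, report = do.call(rbind, reports),
       reference = spectrum1d("reference", ppm, ref))
}

## ---- binning --------------------------------------------------------------

#' Bin a spectrum into fixed-width buckets
#'
#' The bin grid is laid from the high-ppm edge of the window downward in
#' `bin_width` steps; each bin covers the half-open interval
#' `[center - w/2, center + w/2)` (closed toward lower ppm) and holds the
#' SUM of the intensities of the points falling in it (`bin_stat = "mean"`
#' averages instead). A trailing partial bin at the low-ppm end is
#' dropped, then any bins whose centres fall in `exclude_regions` are
#' removed.
#'
#' @param s A [spectrum1d()].
#' @param cfg A [preprocess_config()].
#' @return List with `values` (named numeric vector) and `centers`
#'   (descending bin-centre ppm values).
#' @export
bin_spectrum <- function(s, cfg = preprocess_config()) {
  stopifnot(inherits(s, "spectrum1d"))
  w <- cfg$bin_width
  win <- cfg$ppm_window %||% range(s$ppm)
  eps <- w * 1e-9
  if (win[1L] < min(s$ppm) - eps || win[2L] > max(s$ppm) + eps)
    stop("ppm_window lies outside the spectrum axis", call. = FALSE)
  nb <- floor((win[2L] - win[1L]) / w + 1e-9)
  if (nb < 1L) stop("ppm_window narrower than one bin", call. = FALSE)
  # point at ppm p belongs to bin i iff hi - i*w <= p < hi - (i-1)*w
  idx <- ceiling((win[2L] - s$ppm - eps) / w)
  ok <- idx >= 1L & idx <= nb
  agg <- vapply(seq_len(nb), function(i) {
    v <- s$intensity[ok & idx == i]
    if (cfg$bin_stat == "sum") sum(v) else if (length(v)) mean(v) else 0
  }, numeric(1))
  centers <- win[2L] - (seq_len(nb) - 0.5) * w
  keep <- rep(TRUE, nb)
  for (r in cfg$exclude_regions)
    keep <- keep & !(centers >= r[1L] & centers <= r[2L])
  list(values = stats::setNames(agg[keep], format_ppm(centers[keep])),
       centers = centers[keep])
}

#' Bin a cohort of spectra into a feature matrix
#'
#' @param spectra List of [spectrum1d()] sharing one ppm axis.
#' @param cfg A [preprocess_config()].
#' @return A [feature_matrix()].
#' @export
bin_spectra <- function(spectra, cfg = preprocess_config()) {
  binned <- lapply(spectra, bin_spectrum, cfg = cfg)
  feature_matrix(do.call(rbind, lapply(binned, `[[`, "values")),
                 binned[[1L]]$centers,
                 sample_ids = vapply(spectra, `[[`, "", "sample_id"))
}

## ---- PQN ------------------------------------------------------------------

#' Probabilistic quotient normalization
#'
#' Removes per-sample dilution: (1) each spectrum is scaled to total area
#' `prenormalize_area` (skipped when `NULL`); (2) the reference is the
#' element-wise median spectrum of the cohort (or a supplied reference,
#' e.g. from a training cohort); (3) per sample, quotients
#' `q_j = x_j / ref_j` are formed over bins with `ref_j > 0`; (4) the
#' dilution factor is the median quotient; (5) the sample is divided by
#' it. Negative input values are clipped to zero first (count reported).
#'
#' @param fm A [feature_matrix()] of non-negative bin values.
#' @param reference Numeric reference spectrum of length `ncol(fm)`, or
#'   `NULL` to use the cohort median (computed after steps 1-2).
#' @param prenormalize_area Total-area target for step 1, or `NULL` to
#'   skip pre-normalization.
#' @return List with `fm` (normalized [feature_matrix()]), `dilution`
#'   (median quotient per sample), `total_factor` (overall divisor per
#'   sample relative to the raw input, i.e. area factor times quotient),
#'   `reference` and `n_clipped`.
#' @export
pqn_normalize <- function(fm, reference = NULL, prenormalize_area = 100) {
  x <- unclass(fm)[, , drop = FALSE]
  n_clipped <- sum(x < 0)
  x[x < 0] <- 0
  areas <- rowSums(x)
  if (any(areas == 0))
    stop("sample(s) with zero total area: ",
         paste(rownames(x)[areas == 0], collapse = ", "), call. = FALSE)
  area_factor <- rep(1, nrow(x))
  if (!is.null(prenormalize_area)) {
    area_factor <- areas / prenormalize_area
    x <- x / area_factor
  }
  if (is.null(reference)) reference <- apply(x, 2L, stats::median)
  if (all(reference <= 0)) stop("PQN reference is all zero", call. = FALSE)
  pos <- reference > 0
  d <- apply(x, 1L, function(row) stats::median(row[pos] / reference[pos]))
  if (any(!is.finite(d) | d <= 0))
    stop("degenerate dilution factor for sample(s): ",
         paste(rownames(x)[!is.finite(d) | d <= 0], collapse = ", "),
         call. = FALSE)
  out <- feature_matrix(x / d, bin_centers(fm), sample_ids = rownames(x))
  list(fm = out, dilution = stats::setNames(d, rownames(x)),
       total_factor = stats::setNames(area_factor * d, rownames(x)),
       reference = reference, n_clipped = n_clipped)
}

## ---- pipeline -------------------------------------------------------------

#' Full preprocessing pipeline: (baseline) -> align -> bin -> normalize
#'
#' Turns raw spectra into the analysis-ready X-matrix. When `refs` is
#' supplied (from a previous training run) the alignment reference and
#' PQN reference are reused, so test cohorts are standardized with
#' training-derived constants only and no information leaks from the test
#' set.
#'
#' @param spectra List of [spectrum1d()].
#' @param cfg A [preprocess_config()].
#' @param refs `NULL`, or the `refs` element of a previous
#'   `preprocess_spectra()` result.
#' @return List with `fm` (normalized [feature_matrix()]), `align_report`,
#'   `dilution`, `refs` (alignment + PQN references and the binning
#'   window, reusable for a test cohort) and `log` (character).
#' @export
preprocess_spectra <- function(spectra, cfg = preprocess_config(),
                               refs = NULL) {
  log <- sprintf("pipeline order: %salign -> bin(%g ppm, %s) -> %s",
                 if (cfg$baseline_enabled) "baseline -> " else "",
                 cfg$bin_width, cfg$bin_stat,
                 if (cfg$pqn_enabled) "pqn" else "no normalization")
  if (cfg$baseline_enabled) {
    spectra <- lapply(spectra, baseline_correct, degree = cfg$baseline_degree)
    log <- c(log, sprintf("baseline: polynomial degree %d (automated operator)",
                          cfg$baseline_degree))
  }
  use_cfg <- cfg
  if (is.null(use_cfg$ppm_window))
    use_cfg$ppm_window <- if (!is.null(refs)) refs$ppm_window else
      range(spectra[[1L]]$ppm)
  al <- rspa_align(spectra,
                   reference = if (!is.null(refs)) refs$align_reference
                               else "median",
                   cfg = use_cfg)
  fm <- bin_spectra(al$spectra, use_cfg)
  dilution <- NULL
  pqn_ref <- if (!is.null(refs)) refs$pqn_reference else NULL
  if (cfg$pqn_enabled) {
    pq <- pqn_normalize(fm, reference = pqn_ref,
                        prenormalize_area = cfg$pqn_prenormalize_area)
    if (pq$n_clipped > 0)
      log <- c(log, sprintf("pqn: clipped %d negative values", pq$n_clipped))
    fm <- pq$fm; dilution <- pq$dilution; pqn_ref <- pq$reference
  }
  list(fm = fm, align_report = al$report, dilution = dilution,
       refs = list(align_reference = al$reference, pqn_reference = pqn_ref,
                   ppm_window = use_cfg$ppm_window),
       log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
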