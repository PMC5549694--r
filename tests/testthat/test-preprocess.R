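# Binning, PQN and RSPA behaviour on constructed spectra.

make_axis <- function(hi, lo, n) seq(hi, lo, length.out = n)

test_that("binning sums points into half-open 0.04-ppm buckets", {
  # 11 axis points spanning one bin exactly; the upper edge is excluded
  # by the half-open convention, leaving 10 points of intensity 1
  ppm <- make_axis(3.84, 3.80, 11)
  s <- spectrum1d("a", ppm, rep(1, 11))
  b <- bin_spectrum(s, preprocess_config(ppm_window = c(3.80, 3.84)))
  expect_length(b$values, 1L)
  expect_equal(unname(b$values), 10)
  expect_equal(b$centers, 3.82)

  # full default axis: floor(15.5 / 0.04) = 387 bins, partial bin dropped
  ax <- ppm_axis(acquisition_params())
  s2 <- spectrum1d("b", ax, rep(0, length(ax)))
  b2 <- bin_spectrum(s2, preprocess_config(ppm_window = range(ax)))
  expect_length(b2$values, 387L)

  # delta peak at 3.81 lands in the bin covering [3.80, 3.84)
  ppm3 <- make_axis(4.00, 3.60, 401)
  intens <- rep(0, 401); intens[which.min(abs(ppm3 - 3.81))] <- 5
  b3 <- bin_spectrum(spectrum1d("c", ppm3, intens),
                     preprocess_config(ppm_window = c(3.60, 4.00)))
  expect_equal(unname(b3$values[b3$centers == 3.82]), 5)
  expect_equal(sum(b3$values), 5)
  expect_true(all(b3$values[b3$centers != 3.82] == 0))
})

test_that("binning is linear and windows outside the axis fail", {
  ppm <- make_axis(5, 1, 500)
  set.seed(3)
  i1 <- rnorm(500); i2 <- rnorm(500)
  cfg <- preprocess_config(ppm_window = c(1, 5))
  b1 <- bin_spectrum(spectrum1d("a", ppm, i1), cfg)$values
  b2 <- bin_spectrum(spectrum1d("b", ppm, i2), cfg)$values
  b12 <- bin_spectrum(spectrum1d("c", ppm, 2 * i1 + 0.5 * i2), cfg)$values
  expect_equal(b12, 2 * b1 + 0.5 * b2, tolerance = 1e-12)

  expect_error(bin_spectrum(spectrum1d("a", ppm, i1),
                            preprocess_config(ppm_window = c(1, 9))),
               "outside")
})

test_that("excluded regions are dropped after binning", {
  ppm <- make_axis(5, 1, 500)
  cfg <- preprocess_config(ppm_window = c(1, 5),
                           exclude_regions = list(c(4.5, 5.0)))
  b <- bin_spectrum(spectrum1d("a", ppm, rep(1, 500)), cfg)
  expect_true(all(b$centers < 4.5))
  expect_length(b$values, 100L - sum(seq(4.98, by = -0.04,
                                         length.out = 100) >= 4.5))
})

test_that("PQN removes dilution: hand-computed 3-bin example", {
  fm <- feature_matrix(rbind(c(2, 4, 8), c(1, 2, 2)),
                       bin_centers = c(3, 2, 1), sample_ids = c("x", "ref"))
  out <- pqn_normalize(fm, reference = c(1, 2, 2), prenormalize_area = NULL)
  expect_equal(unname(out$dilution["x"]), 2)     # median of (2, 2, 4)
  expect_equal(unname(unclass(out$fm)["x", ]), c(1, 2, 4))
  expect_equal(unname(out$dilution["ref"]), 1)
})

test_that("PQN: identical cohort and pure-dilution cases", {
  base <- c(1, 5, 3, 2, 9)
  fm <- feature_matrix(rbind(base, base, base), bin_centers = 5:1,
                       sample_ids = c("a", "b", "c"))
  out <- pqn_normalize(fm, prenormalize_area = 100)
  expect_equal(unname(out$dilution), rep(1, 3))
  # output equals the area-prenormalized input
  expect_equal(unname(unclass(out$fm)[1, ]), base / sum(base) * 100)

  # one sample is exactly 2x the reference (pre-normalization off)
  fm2 <- feature_matrix(rbind(2 * base, base, base), bin_centers = 5:1,
                        sample_ids = c("a", "b", "c"))
  out2 <- pqn_normalize(fm2, prenormalize_area = NULL)
  expect_equal(unname(out2$dilution["a"]), 2)
  expect_equal(unname(unclass(out2$fm)["a", ]), base)
})

test_that("PQN is scale-invariant per sample with pre-normalization on", {
  set.seed(11)
  vals <- matrix(rexp(5 * 20), 5, 20)
  fm <- feature_matrix(vals, bin_centers = seq(9, by = -0.4,
                                               length.out = 20))
  ref <- pqn_normalize(fm, prenormalize_area = 100)
  for (c_mult in c(0.1, 7)) {
    vals2 <- vals; vals2[3, ] <- vals2[3, ] * c_mult
    out <- pqn_normalize(feature_matrix(vals2, bin_centers = bin_centers(fm)),
                         prenormalize_area = 100)
    expect_equal(unclass(out$fm)[3, ], unclass(ref$fm)[3, ],
                 tolerance = 1e-12)
  }
})

test_that("PQN rejects degenerate input and clips negatives", {
  fm <- feature_matrix(rbind(c(0, 0, 0), c(1, 2, 3)), bin_centers = 3:1,
                       sample_ids = c("z", "a"))
  expect_error(pqn_normalize(fm), "zero total area.*z")
  fm2 <- feature_matrix(rbind(c(-1, 2, 3), c(1, 2, 3)), bin_centers = 3:1)
  expect_equal(pqn_normalize(fm2)$n_clipped, 1L)
})

test_that("RSPA leaves a spectrum identical to the reference unchanged", {
  ppm <- make_axis(5, 1, 400)
  peak <- 10 / (1 + ((ppm - 3) / 0.05)^2)
  s <- spectrum1d("a", ppm, peak)
  cfg <- preprocess_config(rspa_min_segment = 30L)
  out <- rspa_align(list(s), reference = s, cfg = cfg)
  expect_equal(out$spectra[[1L]]$intensity, peak)
  expect_true(all(out$report$shift == 0L))
})

test_that("RSPA recovers a known displacement, matching brute force", {
  ppm <- make_axis(5, 1, 400)
  ref_int <- 10 / (1 + ((ppm - 3) / 0.05)^2)
  displaced <- c(rep(ref_int[1L], 3L), ref_int[seq_len(397L)])  # +3 points
  cfg <- preprocess_config(rspa_min_segment = 30L, rspa_max_shift = 10L)
  ref <- spectrum1d("ref", ppm, ref_int)
  out <- rspa_align(list(spectrum1d("a", ppm, displaced)),
                    reference = ref, cfg = cfg)
  expect_equal(which.max(out$spectra[[1L]]$intensity), which.max(ref_int))
  expect_equal(out$report$shift[1L], -3L)

  # brute-force check: the applied shift maximises correlation over +-10
  brute <- sapply(-10:10, function(sh) {
    idx <- seq_along(displaced) - sh
    idx <- pmin(pmax(idx, 1L), length(displaced))
    cor(displaced[idx], ref_int)
  })
  expect_equal((-10:10)[which.max(brute)], out$report$shift[1L])
})

test_that("RSPA refuses displacement beyond max_shift on a narrow peak", {
  ppm <- make_axis(5, 1, 400)
  ref_int <- rep(0, 400); ref_int[200] <- 10          # near-delta peak
  disp <- rep(0, 400); disp[215] <- 10                # displaced +15
  cfg <- preprocess_config(rspa_min_segment = 30L, rspa_max_shift = 10L)
  out <- rspa_align(list(spectrum1d("a", ppm, disp)),
                    reference = spectrum1d("r", ppm, ref_int), cfg = cfg)
  root <- out$report[out$report$depth == 0, ]
  expect_equal(root$shift, 0L)
  expect_false(root$applied)
  expect_lt(root$gain, cfg$rspa_corr_gain_min)
})

test_that("RSPA never exceeds max_shift and never lowers accepted correlations", {
  set.seed(21)
  ppm <- make_axis(9, 0, 1500)
  mk <- function() {
    i <- rep(0, 1500)
    for (c0 in c(2, 4.5, 7)) i <- i + runif(1, 5, 12) /
        (1 + ((ppm - c0 - runif(1, -0.01, 0.01)) / 0.03)^2)
    i + rnorm(1500, sd = 0.05)
  }
  spectra <- lapply(1:6, function(k) spectrum1d(paste0("s", k), ppm, mk()))
  cfg <- preprocess_config(rspa_min_segment = 40L, rspa_max_shift = 8L)
  out <- rspa_align(spectra, cfg = cfg)
  expect_true(all(abs(out$report$shift) <= 8L))
  acc <- out$report[out$report$applied, ]
  expect_true(all(acc$cor_after >= acc$cor_before))
})

test_that("RSPA rejects mismatched axes and oversized shifts", {
  s1 <- spectrum1d("a", make_axis(5, 1, 100), rep(1, 100))
  s2 <- spectrum1d("b", make_axis(6, 2, 100), rep(1, 100))
  expect_error(rspa_align(list(s1, s2)), "share one ppm axis")
  expect_error(rspa_align(list(s1), cfg = preprocess_config(
    rspa_max_shift = 100L)), "smaller than the spectrum length")
})

test_that("baseline correction removes offsets and ramps, keeping peaks", {
  ppm <- make_axis(5, 1, 500)
  flat <- spectrum1d("a", ppm, rep(3.7, 500))
  expect_equal(baseline_correct(flat, degree = 0)$intensity, rep(0, 500),
               tolerance = 1e-10)

  peak <- 20 * exp(-((ppm - 3) / 0.03)^2 / 2)
  ramp <- seq(0, 4, length.out = 500)
  bc <- baseline_correct(spectrum1d("b", ppm, peak + ramp), degree = 1)
  apex0 <- max(peak)
  apex1 <- max(bc$intensity)
  expect_lt(abs(apex1 - apex0) / apex0, 0.05)
  off_peak <- abs(ppm - 3) > 0.3
  expect_lt(max(abs(bc$intensity[off_peak])), 0.15 * apex0)

  expect_error(baseline_correct(flat, degree = 7), "0..5")
})

test_that("pipeline config defaults are validated", {
  expect_error(preprocess_config(bin_width = 0), "bin_width")
  expect_error(preprocess_config(ppm_window = c(5, 1)), "low < high")
  expect_error(preprocess_config(rspa_min_segment = 2), "rspa_min_segment")
})
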