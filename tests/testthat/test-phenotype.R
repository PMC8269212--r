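test_that("CDR matches analytic truth and vanishes without a C-D band", {
  no_cd <- corrected_spectrum(list(band_model(2930, 60, 3)))
  expect_equal(compute_cdr(no_cd$spectrum), 0)
  # bands well inside their windows: computed CDR within 1% relative
  ms <- corrected_spectrum(list(band_model(2157, 30, 1),
                                band_model(2950, 35, 3)))
  expect_lt(abs(compute_cdr(ms$spectrum) / ms$truth$true_cdr - 1), 0.01)
})

test_that("CDR is invariant to C-H normalization and to scaling", {
  ms <- corrected_spectrum(list(band_model(2157, 40, 1),
                                band_model(2930, 60, 3)),
                           noise_sd = 0.03, seed = 17)
  before <- compute_cdr(ms$spectrum)
  after <- compute_cdr(normalize_ch(ms$spectrum))
  expect_equal(before, after, tolerance = 1e-12)
  scaled <- ms$spectrum
  scaled$intensity <- 7.3 * scaled$intensity
  expect_equal(compute_cdr(scaled), before, tolerance = 1e-12)
})

test_that("CDR increases with C-D amplitude at fixed C-H", {
  cdrs <- vapply(seq(0, 2, by = 0.25), function(a) {
    ms <- corrected_spectrum(list(band_model(2157, 40, a),
                                  band_model(2930, 60, 3)))
    compute_cdr(ms$spectrum)
  }, 0)
  expect_true(all(diff(cdrs) > 0))
  expect_true(all(cdrs >= 0 & cdrs <= 1))
})

test_that("CDR requires a baseline-corrected spectrum and signal", {
  raw <- make_spectrum(test_axis, list(band_model(2930, 60, 3)))$spectrum
  expect_error(compute_cdr(raw), "baseline-corrected")
  flat <- raman_spectrum(axis_points(test_axis),
                         rep(0, length(axis_points(test_axis))),
                         state = "baseline_corrected")
  expect_error(compute_cdr(flat), "empty spectrum")
})

test_that("carotenoid detector is negative on noise, positive on bands", {
  w <- axis_points(test_axis)
  set.seed(23)
  noise <- raman_spectrum(w, rnorm(length(w), 0, 0.05),
                          state = "baseline_corrected")
  res <- detect_carotenoid(noise)
  expect_false(res$positive)
  expect_true(all(res$snr < 5))
  tmpl <- mock_band_templates(carot_amp = 20 * 0.05)
  se <- corrected_spectrum(tmpl(FALSE, TRUE), noise_sd = 0.05, seed = 24)
  expect_true(detect_carotenoid(se$spectrum)$positive)
})

test_that("carotenoid decision flips exactly at the SNR threshold", {
  w <- axis_points(test_axis)
  k <- 5; noise_sd <- 0.05
  for (amp_mult in c(2, 4.5, 4.99, 5.01, 8, 20)) {
    ms <- make_spectrum(test_axis, list(
      band_model(1521, 10, amp_mult * noise_sd, "v3"),
      band_model(1158, 6, 20 * noise_sd, "v2"),
      band_model(2930, 60, 3, "CH")))
    sp <- ms$spectrum; sp$state <- "baseline_corrected"
    res <- detect_carotenoid(sp, noise_sd_estimate = noise_sd,
                             snr_threshold_k = k)
    # brute-force per-point scan oracle for the v3 window SNR
    sel <- w >= 1500 & w <= 1550
    snr_oracle <- max(sp$intensity[sel]) / noise_sd
    expect_equal(unname(res$snr[["CAROT_V3"]]), snr_oracle)
    expect_identical(res$positive, snr_oracle >= k)
  }
})

test_that("carotenoid detector validates its noise estimate", {
  ms <- corrected_spectrum(list(band_model(2930, 60, 3)))
  expect_error(detect_carotenoid(ms$spectrum, noise_sd_estimate = 0),
               "noise sd")
})

test_that("mock-community cells classify to their phenotype of origin", {
  cells <- make_mock_community(mock_community_spec(n_cells = 24), seed = 41)
  tab <- phenotype_cells(cells, cdr_threshold = 0.05)
  for (i in seq_along(cells)) {
    expect_identical(tab$cd_positive[i], cells[[i]]$truth$d2o_labeled)
    expect_identical(tab$carotenoid_positive[i],
                     cells[[i]]$truth$carotenoid_producer)
  }
})

test_that("all four joint classes are realized and consistent", {
  quad <- data.frame(
    label = c("both", "car", "cd", "none"), proportion = rep(0.25, 4),
    d2o_labeled = c(TRUE, FALSE, TRUE, FALSE),
    carotenoid_producer = c(TRUE, TRUE, FALSE, FALSE))
  cells <- make_mock_community(mock_community_spec(quad, n_cells = 8),
                               seed = 13)
  tab <- phenotype_cells(cells)
  expect_setequal(unique(tab$joint_class),
                  c("CD+CAR+", "CD-CAR+", "CD+CAR-", "CD-CAR-"))
  expect_identical(tab$joint_class,
                   paste0(ifelse(tab$cd_positive, "CD+", "CD-"),
                          ifelse(tab$carotenoid_positive, "CAR+", "CAR-")))
})

test_that("threshold classification recovers uniform CDR truths", {
  # truths uniform on [0, 0.3], threshold 0.15, high SNR, no baseline:
  # accuracy >= 99% away from the threshold
  set.seed(71)
  true_cdr <- runif(400, 0, 0.3)
  calls <- logical(400); truths <- logical(400)
  for (i in seq_along(true_cdr)) {
    # solve amplitude so that full-Gaussian areas give the wanted CDR
    a_cd <- 3 * 60 * true_cdr[i] / (40 * (1 - true_cdr[i]))
    ms <- corrected_spectrum(list(band_model(2157, 40, a_cd),
                                  band_model(2930, 60, 3)),
                             noise_sd = 0.05, seed = 500 + i)
    calls[i] <- compute_cdr(ms$spectrum) >= 0.15
    truths[i] <- true_cdr[i] >= 0.15
  }
  clear <- abs(true_cdr - 0.15) > 0.01
  expect_gte(mean(calls[clear] == truths[clear]), 0.99)
})

test_that("classification is invariant to overall intensity scaling", {
  cells <- make_mock_community(mock_community_spec(n_cells = 8), seed = 19)
  for (cell in cells[c(1, 3, 7)]) {
    pre <- preprocess_spectrum(cell$spectrum)
    scaled_raw <- cell$spectrum
    scaled_raw$intensity <- 5 * scaled_raw$intensity
    pre2 <- preprocess_spectrum(scaled_raw)
    a <- classify_cell(pre); b <- classify_cell(pre2)
    expect_identical(a$joint_class, b$joint_class)
  }
})

test_that("sorting decisions follow the named criterion", {
  ms <- corrected_spectrum(list(band_model(2157, 40, 1),
                                band_model(2930, 60, 3)))
  ph <- classify_cell(ms$spectrum, cdr_threshold = 0.05)
  expect_true(ph$cd_positive); expect_false(ph$carotenoid_positive)
  expect_true(sort_decision(ph, "cd_band"))
  expect_false(sort_decision(ph, "carotenoid"))
  expect_true(sort_decision(ph, "morphology_passthrough"))
  expect_error(sort_decision(ph, "autofluorescence"))
})

test_that("a batch sorts exactly the cells satisfying the criterion", {
  # 33 cells, 9 of them labeled
  spec <- mock_community_spec(
    data.frame(label = c("lab", "unlab"), proportion = c(9, 24) / 33,
               d2o_labeled = c(TRUE, FALSE),
               carotenoid_producer = FALSE),
    n_cells = 33)
  tab <- phenotype_cells(make_mock_community(spec, seed = 29),
                         criterion = "cd_band")
  expect_identical(sum(tab$sort_target), 9L)
})

test_that("CDR threshold calibration follows its rule", {
  zeros <- rep(0, 25)
  expect_equal(calibrate_cdr_threshold(zeros, rule = "max"), 0)
  set.seed(55)
  ctrl <- rnorm(200, 0.02, 0.005)
  thr <- calibrate_cdr_threshold(ctrl)
  expect_equal(thr, mean(ctrl) + 3 * sd(ctrl))
  expect_equal(thr, 0.035, tolerance = 0.005)
  # monotone in the sd multiplier
  thrs <- vapply(1:5, function(m)
    calibrate_cdr_threshold(ctrl, sd_multiplier = m), 0)
  expect_true(all(diff(thrs) > 0))
  expect_error(calibrate_cdr_threshold(rnorm(10)), "20")
  expect_equal(calibrate_cdr_threshold(ctrl, rule = "fixed",
                                       fixed_value = 0.07), 0.07)
})

test_that("time-course summary recovers a saturating uptake curve", {
  truth_mean <- function(t) 0.2 * (1 - exp(-t / 6))
  set.seed(61)
  tc <- do.call(rbind, lapply(c(6, 12, 18, 24), function(t)
    data.frame(time_h = t, cdr = rnorm(100, truth_mean(t), 0.02))))
  out <- summarize_timecourse(tc)
  for (i in seq_len(4)) {
    t <- out$summary$time_h[i]
    expect_lt(abs(out$summary$mean_cdr[i] - truth_mean(t)),
              2 * 0.02 / sqrt(100) * 2)  # within 2 sd of the mean, doubled
  }
  # plateau logic on the exact saturating means: last rise is 9% of total
  exact <- do.call(rbind, lapply(c(6, 12, 18, 24), function(t)
    data.frame(time_h = t, cdr = rep(truth_mean(t), 2))))
  expect_true(summarize_timecourse(exact)$plateau)
  # still rising linearly: not plateaued
  linear <- do.call(rbind, lapply(c(6, 12, 18, 24), function(t)
    data.frame(time_h = t, cdr = rep(t / 100, 2))))
  expect_false(summarize_timecourse(linear)$plateau)
})

test_that("time-course replicates correlate and equal means plateau", {
  tc <- do.call(rbind, lapply(1:3, function(r)
    data.frame(replicate = r, time_h = rep(c(6, 12), each = 2),
               cdr = c(0.05, 0.07, 0.11, 0.13))))
  out <- summarize_timecourse(tc)
  expect_true(all(out$replicate_correlation == 1))
  eq <- data.frame(time_h = rep(c(6, 12), each = 2), cdr = rep(0.1, 4))
  expect_true(summarize_timecourse(eq)$plateau)
  bad <- data.frame(replicate = c(1, 1, 2, 2), time_h = c(6, 6, 12, 12),
                    cdr = rep(0.1, 4))
  expect_error(summarize_timecourse(bad), "time grid")
})
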