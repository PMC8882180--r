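fs_t <- 7.81

test_that("closed forms hold on constant and linear timecourses", {
  n <- round(40 * fs_t) + 1
  cc <- 2.5
  f <- extract_roi_features(rep(cc, n), fs = fs_t)
  for (nm in grep("^seg_mean", names(f), value = TRUE))
    expect_equal(unname(f[nm]), cc)
  expect_equal(unname(f["slope_5_15"]), 0)
  expect_equal(unname(f["auc_0_15"]), 15 * cc)
  expect_equal(unname(f["auc_15_40"]), 25 * cc)
  expect_equal(unname(f["sd_after_ext1"]), 0)

  a <- 0.3; b <- -0.7
  t <- (seq_len(n) - 1) / fs_t
  g <- extract_roi_features(a + b * t, fs = fs_t)
  expect_equal(unname(g["slope_5_15"]), b, tolerance = 1e-12)
})

test_that("moments, AUC and extrema match brute-force oracles", {
  skip_if_not_installed("e1071")
  spec <- quiet_spec()
  tc <- epoch_and_block_average(synth_scan_timeseries(0.5, spec))$MPFC
  x <- tc$hbo
  f <- extract_roi_features(tc)
  w <- 1:(floor(40 * fs_t))      # the [0, 40) analysis window
  t_w <- (w - 1) / fs_t

  # extrema: brute-force argmax/argmin over the window (clean response is
  # peak-then-trough)
  expect_equal(unname(f["t_ext1"]), t_w[which.max(x[w])], tolerance = 1e-10)
  expect_equal(unname(f["mag_ext1"]), max(x[w]), tolerance = 1e-10)
  i015 <- 1:(floor(15 * fs_t))
  xo <- x[i015]
  expect_equal(unname(f["skew_0_15"]), e1071::skewness(xo, type = 1),
               tolerance = 1e-10)
  expect_equal(unname(f["kurt_0_15"]), e1071::kurtosis(xo, type = 1) + 3,
               tolerance = 1e-10)
  # segment means against direct index arithmetic
  i5 <- (floor(5 * fs_t) + 1):(floor(10 * fs_t))
  expect_equal(unname(f["seg_mean_5_10"]), mean(x[i5]), tolerance = 1e-12)
  # AUC against a brute-force interval-clipping oracle for the integral of
  # the piecewise-linear interpolant (constant extension past the last
  # sample)
  n_av <- floor(40 * fs_t) + 1
  t_av <- (seq_len(n_av) - 1) / fs_t
  fi <- approxfun(t_av, x[seq_len(n_av)], rule = 2)
  clip_int <- function(a, b) {
    knots <- sort(unique(c(a, b, t_av[t_av > a & t_av < b])))
    s <- 0
    for (i in seq_len(length(knots) - 1)) {
      lo <- knots[i]; hi <- knots[i + 1]
      s <- s + (hi - lo) * (fi(lo) + fi(hi)) / 2
    }
    s
  }
  expect_equal(unname(f["auc_0_15"]), clip_int(0, 15), tolerance = 1e-10)
  expect_equal(unname(f["auc_15_40"]), clip_int(15, 40), tolerance = 1e-10)
})

test_that("shift and scale covariance of the feature map", {
  set.seed(6)
  n <- round(40 * fs_t) + 1
  x <- cumsum(rnorm(n, 0, 0.1))
  f0 <- extract_roi_features(x, fs = fs_t)
  cc <- 1.7
  fs_shift <- extract_roi_features(x + cc, fs = fs_t)
  seg <- grep("^seg_mean|^mag_ext|^mean_after", names(f0))
  expect_equal(fs_shift[seg], f0[seg] + cc, tolerance = 1e-10)
  expect_equal(unname(fs_shift["auc_0_15"] - f0["auc_0_15"]), 15 * cc,
               tolerance = 1e-8)
  expect_equal(unname(fs_shift["auc_15_40"] - f0["auc_15_40"]), 25 * cc,
               tolerance = 1e-8)
  inv <- c("slope_5_15", "skew_0_15", "kurt_0_15", "t_ext1", "t_ext2",
           "sd_after_ext1")
  expect_equal(fs_shift[inv], f0[inv], tolerance = 1e-10)

  k <- 3.2
  fk <- extract_roi_features(k * x, fs = fs_t)
  lin <- grep("^seg_mean|^mag_ext|^mean_after|^auc|^sd_after|^slope",
              names(f0))
  expect_equal(fk[lin], k * f0[lin], tolerance = 1e-10)
  expect_equal(fk[c("skew_0_15", "kurt_0_15", "t_ext1", "t_ext2")],
               f0[c("skew_0_15", "kurt_0_15", "t_ext1", "t_ext2")],
               tolerance = 1e-10)
})

test_that("features ignore data appended beyond 40 s", {
  set.seed(7)
  x <- cumsum(rnorm(round(40 * fs_t) + 1, 0, 0.1))
  f1 <- extract_roi_features(x, fs = fs_t)
  f2 <- extract_roi_features(c(x, rnorm(100, 10, 5)), fs = fs_t)
  expect_identical(f1, f2)
})

test_that("the scan feature vector has the documented structure", {
  spec <- cohort_spec(n_participants = 1, seed = 2)
  co <- generate_cohort(spec)
  tcs <- preprocess_scan(co$scans[[1]])
  fv <- build_feature_vector(tcs)
  expect_length(fv, 95L)
  expect_identical(names(fv), feature_vector_names())
  for (r in roi_order())
    expect_equal(sum(startsWith(names(fv), paste0(r, "_"))), 19L)
  # determinism
  expect_identical(fv, build_feature_vector(tcs))
  expect_error(build_feature_vector(tcs[-1]), "MPFC")
  expect_error(extract_roi_features(rnorm(100), fs = fs_t), "40 s")
})

test_that("feature_matrix selects classes and keeps metadata apart", {
  spec <- cohort_spec(n_participants = 8, seed = 31)
  co <- generate_cohort(spec)
  lab <- assemble_label_table(co$vitals, co$ccr)
  feats <- lapply(co$scans, preprocess_scan)
  feats <- lapply(feats, build_feature_vector)
  names(feats) <- vapply(co$scans, scan_key, character(1))
  fm <- feature_matrix(feats, lab$labels)
  n_imp <- sum(lab$labels$ground_truth == "impaired")
  n_pla <- sum(lab$labels$ground_truth == "placebo_negative")
  expect_equal(nrow(fm$x), n_imp + n_pla)
  expect_equal(ncol(fm$x), 95L)
  expect_equal(sum(fm$y), n_imp)
  if (any(lab$labels$ground_truth == "not_clearly_impaired")) {
    hm <- feature_matrix(feats, lab$labels, include = "not_clearly_impaired")
    expect_true(all(hm$y == 0))
  }
  expect_error(feature_matrix(feats, lab$labels, include = "nonexistent"),
               "no scans")
})
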