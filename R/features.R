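#' Names of the 19 per-ROI temporal features
#'
#' Eight 5-s segment means over 0-40 s, the 5-15 s slope, skewness and
#' kurtosis over 0-15 s, areas under the curve over 0-15 and 15-40 s, time
#' and magnitude of the first and second extremum, and the mean and standard
#' deviation after the first extremum.  The order is fixed and part of the
#' public contract.
#'
#' @return Character vector of length 19.
#' @export
roi_feature_names <- function() {
  c(sprintf("seg_mean_%d_%d", seq(0, 35, 5), seq(5, 40, 5)),
    "slope_5_15", "skew_0_15", "kurt_0_15", "auc_0_15", "auc_15_40",
    "t_ext1", "t_ext2", "mag_ext1", "mag_ext2",
    "mean_after_ext1", "sd_after_ext1")
}

#' Names of the full 95-value feature vector
#' @return Character vector of length 95 (`<ROI>_<feature>` in fixed order).
#' @export
feature_vector_names <- function() {
  as.vector(vapply(roi_order(),
                   function(r) paste(r, roi_feature_names(), sep = "_"),
                   character(19)))
}

# sample indices (1-based) for the half-open window [a, b) seconds
window_idx <- function(a, b, fs) {
  lo <- as.integer(floor(a * fs)); hi <- as.integer(floor(b * fs)) - 1L
  if (hi < lo) integer(0) else seq.int(lo, hi) + 1L
}

# integral of the piecewise-linear interpolant of (t, x) over [a, b] seconds
trapz_window <- function(t, x, a, b) {
  f <- stats::approxfun(t, x, rule = 2)
  tt <- t[t > a & t < b]
  grid <- c(a, tt, b)
  pracma::trapz(grid, f(grid))
}

# turning points: samples where the (zero-skipping) first difference changes
# sign; with prominence > 0, successive extrema must differ from the last
# kept one by at least that amount
turning_points <- function(x, prominence = 0) {
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2L) return(integer(0))
  s <- sign(d[nz])
  tp <- nz[which(s[-1] != s[-length(s)])] + 1L
  if (prominence > 0 && length(tp) > 0L) {
    kept <- tp[1]
    for (i in tp[-1])
      if (abs(x[i] - x[kept[length(kept)]]) >= prominence)
        kept <- c(kept, i)
    tp <- kept
  }
  tp
}

#' Extract the 19 temporal features from one ROI timecourse
#'
#' All windows are half-open `[a, b)` seconds mapped to sample indices
#' `floor(a*fs) .. floor(b*fs)-1` (0-based), so the eight segments partition
#' 0-40 s without overlap; AUC integrates the piecewise-linear timecourse
#' over exact second boundaries; slope is the least-squares line over
#' 5-15 s; skewness and kurtosis are plain sample moments over 0-15 s
#' (kurtosis non-excess); extrema are the first two turning points of the
#' signal (falling back to the global maximum then minimum when fewer than
#' two turning points exist, e.g. on monotone input), with mean and SD taken
#' over samples strictly after the first extremum.
#'
#' @param tc a `roi_timecourse`, or a numeric vector of HbO values sampled at
#'   `fs` starting at 0 s.
#' @param fs sampling rate (Hz); taken from `tc` when it is a timecourse.
#' @param prominence minimum absolute difference for a turning point to count
#'   as an extremum (default 0: any turning point).
#' @return Named numeric vector of length 19.
#' @export
extract_roi_features <- function(tc, fs = NULL, prominence = 0) {
  if (inherits(tc, "roi_timecourse")) {
    fs <- tc$fs
    x_full <- tc$hbo
  } else {
    x_full <- as.numeric(tc)
    if (is.null(fs)) stop("fs is required for a bare numeric timecourse")
  }
  idx40 <- window_idx(0, 40, fs)
  if (length(x_full) < max(idx40))
    stop("timecourse spans less than 40 s at fs = ", fs)
  x <- x_full[idx40]
  t_s <- (idx40 - 1L) / fs
  out <- numeric(0)
  for (k in seq(0, 35, 5)) {
    i <- window_idx(k, k + 5, fs)
    if (length(i) < 3L) stop("fewer than 3 samples in segment window")
    out[sprintf("seg_mean_%d_%d", k, k + 5)] <- mean(x_full[i])
  }
  i515 <- window_idx(5, 15, fs)
  out["slope_5_15"] <- stats::cov(t_s[i515], x[i515]) / stats::var(t_s[i515])
  i015 <- window_idx(0, 15, fs)
  m <- x[i015] - mean(x[i015])
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  out["skew_0_15"] <- if (m2 > 0) m3 / m2^1.5 else 0
  out["kurt_0_15"] <- if (m2 > 0) m4 / m2^2 else 0
  # AUCs over exact second boundaries: all samples with t <= 40 s, the
  # piecewise-linear interpolant extended constantly over any sub-sample gap
  # at the window edge
  n_av <- min(length(x_full), as.integer(floor(40 * fs)) + 1L)
  t_av <- (seq_len(n_av) - 1L) / fs
  out["auc_0_15"] <- trapz_window(t_av, x_full[seq_len(n_av)], 0, 15)
  out["auc_15_40"] <- trapz_window(t_av, x_full[seq_len(n_av)], 15, 40)
  tp <- turning_points(x, prominence)
  if (length(tp) < 2L) tp <- c(which.max(x), which.min(x))
  e1 <- tp[1]; e2 <- tp[2]
  out["t_ext1"] <- t_s[e1]; out["t_ext2"] <- t_s[e2]
  out["mag_ext1"] <- x[e1]; out["mag_ext2"] <- x[e2]
  after <- if (e1 < length(x)) x[(e1 + 1L):length(x)] else numeric(0)
  out["mean_after_ext1"] <- if (length(after) > 0) mean(after) else x[e1]
  out["sd_after_ext1"] <- if (length(after) > 1) stats::sd(after) else 0
  out[roi_feature_names()]
}

#' Assemble the 95-value feature vector for one scan
#'
#' Concatenates the 19 temporal features of each ROI in the fixed order
#' MPFC, RDLPFC, RVLPFC, LDLPFC, LVLPFC.
#'
#' @param roi_tcs named list of `roi_timecourse`s (from
#'   [epoch_and_block_average()]); all five ROIs must be present.
#' @param prominence passed to [extract_roi_features()].
#' @return Named numeric vector of length 95.
#' @export
build_feature_vector <- function(roi_tcs, prominence = 0) {
  missing_roi <- setdiff(roi_order(), names(roi_tcs))
  if (length(missing_roi) > 0L)
    stop("missing ROI timecourse(s): ", paste(missing_roi, collapse = ", "))
  out <- unlist(lapply(roi_order(), function(r) {
    f <- extract_roi_features(roi_tcs[[r]], prominence = prominence)
    names(f) <- paste(r, names(f), sep = "_")
    f
  }))
  stopifnot(length(out) == 95L, all(is.finite(out)))
  out
}

#' Build the feature matrix and label column for classifier training
#'
#' Selects scans whose ground-truth class is in `include`, maps classes to a
#' binary label (`impaired` = 1, everything else = 0), and returns the 95
#' feature columns with scan metadata kept apart from the predictors.
#'
#' @param feature_list named list (by scan key) of 95-value feature vectors.
#' @param labels label table (from [assemble_label_table()]`$labels`) with a
#'   `ground_truth` column; keys are `participant/arm/scan_index`.
#' @param include ground-truth classes to keep.
#' @return List with `x` (matrix n x 95), `y` (0/1 integer vector), `meta`
#'   (data.frame of participant_id, visit_arm, scan_index, ground_truth).
#' @export
feature_matrix <- function(feature_list, labels,
                           include = c("impaired", "placebo_negative")) {
  keys <- paste(labels$participant_id, labels$visit_arm, labels$scan_index,
                sep = "/")
  sel <- labels$ground_truth %in% include & keys %in% names(feature_list)
  if (!any(sel)) stop("no scans left after class filtering")
  keys <- keys[sel]
  x <- do.call(rbind, feature_list[keys])
  rownames(x) <- keys
  y <- as.integer(labels$ground_truth[sel] == "impaired")
  list(x = x, y = y,
       meta = labels[sel, c("participant_id", "visit_arm", "scan_index",
                            "ground_truth")])
}
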