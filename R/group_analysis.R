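#' Select the peak-dose scan for a visit
#'
#' Of the two post-dose scans, returns the one whose matched self-rated-high
#' value (vitals sample nearest the scan midpoint) is larger; ties go to
#' scan 2.  If only one post-dose scan is present it is used and flagged.
#'
#' @param vitals the visit's `vitals_series`.
#' @param available post-dose scan indices actually recorded.
#' @param scan_times_min midpoints of scans 1-3 (minutes from dosing).
#' @return List: `scan_index` (2 or 3), `deq` (named ratings used),
#'   `only_one` flag.
#' @export
select_peak_scan <- function(vitals, available = c(2L, 3L),
                             scan_times_min = c(-15, 100, 200)) {
  available <- intersect(available, 2:3)
  if (length(available) == 0L)
    stop("participant ", vitals$participant_id, " has no post-dose scan")
  s <- vitals$samples
  deq_at <- vapply(available, function(k) {
    s$deq_high[which.min(abs(s$minutes - scan_times_min[k]))]
  }, numeric(1))
  names(deq_at) <- available
  if (length(available) == 1L)
    return(list(scan_index = available, deq = deq_at, only_one = TRUE))
  best <- if (deq_at[2] > deq_at[1]) available[2] else available[1]
  list(scan_index = best, deq = deq_at, only_one = FALSE)
}

#' Matched pre/peak-dose ROI timecourse pairs for a group
#'
#' Keeps participants that have both a valid pre-dose scan and a valid
#' peak-dose scan (per [select_peak_scan()]) in the requested arm, and
#' returns their block-averaged ROI timecourses as matched pairs; excluded
#' participants are counted.
#'
#' @param roi_tcs nested list `roi_tcs[[scan_key]]` of per-ROI timecourse
#'   lists (output of [preprocess_scan()] per scan).
#' @param vitals list of `vitals_series`.
#' @param participants participant ids forming the group.
#' @param arm `"THC"` or `"placebo"`.
#' @param scan_times_min scan midpoints.
#' @return List: `pairs` (list per participant of `pre` and `peak` ROI
#'   timecourse lists plus `peak_scan`), `n_pairs`, `n_excluded`.
#' @export
matched_pairs <- function(roi_tcs, vitals, participants, arm = "THC",
                          scan_times_min = c(-15, 100, 200)) {
  vkey <- vapply(vitals, function(v)
    paste(v$participant_id, v$visit_arm, sep = "/"), character(1))
  pairs <- list()
  n_excluded <- 0L
  for (p in participants) {
    pre_key <- paste(p, arm, 1, sep = "/")
    vi <- match(paste(p, arm, sep = "/"), vkey)
    v <- if (is.na(vi)) NULL else vitals[[vi]]
    post_avail <- c(2L, 3L)[c(paste(p, arm, 2, sep = "/") %in% names(roi_tcs),
                              paste(p, arm, 3, sep = "/") %in% names(roi_tcs))]
    if (!(pre_key %in% names(roi_tcs)) || length(post_avail) == 0L ||
        is.null(v)) {
      n_excluded <- n_excluded + 1L
      next
    }
    peak <- select_peak_scan(v, post_avail, scan_times_min)
    pairs[[p]] <- list(pre = roi_tcs[[pre_key]],
                       peak = roi_tcs[[paste(p, arm, peak$scan_index,
                                             sep = "/")]],
                       peak_scan = peak$scan_index)
  }
  if (length(pairs) == 0L) stop("no matched pre/peak pairs in group")
  list(pairs = pairs, n_pairs = length(pairs), n_excluded = n_excluded)
}

#' Timepoint-wise paired t-tests with BH-FDR correction
#'
#' At every block-relative sample, a paired t-test of peak-dose minus
#' pre-dose HbO over participants; Benjamini-Hochberg step-up applied across
#' the timepoints within the ROI at level `q`.  Zero-variance timepoints get
#' p = 1 and a flag.  This is the significance-trace analysis behind the
#' group HbO figures.
#'
#' @param pairs matched pairs from [matched_pairs()].
#' @param roi ROI name.
#' @param q FDR level.
#' @return List: `t` (per-timepoint statistic), `p` (raw), `p_adj` (BH),
#'   `significant` (logical mask), `mean_diff`, `n_pairs`,
#'   `zero_variance` (flags), `time_s`.
#' @export
timepoint_paired_tests <- function(pairs, roi, q = 0.05) {
  plist <- pairs$pairs
  if (length(plist) < 3L) stop("need at least 3 matched pairs")
  pre <- vapply(plist, function(x) x$pre[[roi]]$hbo,
                numeric(length(plist[[1]]$pre[[roi]]$hbo)))
  peak <- vapply(plist, function(x) x$peak[[roi]]$hbo,
                 numeric(length(plist[[1]]$peak[[roi]]$hbo)))
  d <- peak - pre                       # timepoints x participants
  n <- ncol(d)
  mu <- rowMeans(d)
  sdd <- apply(d, 1, stats::sd)
  zero_var <- sdd == 0
  tstat <- ifelse(zero_var, 0, mu / (sdd / sqrt(n)))
  p <- ifelse(zero_var, 1,
              2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE))
  p_adj <- stats::p.adjust(p, method = "BH")
  list(t = tstat, p = p, p_adj = p_adj, significant = p_adj < q,
       mean_diff = mu, n_pairs = n, zero_variance = zero_var,
       time_s = plist[[1]]$pre[[roi]]$time_s)
}

#' Group-level HbO analysis across all ROIs
#'
#' Runs [timepoint_paired_tests()] for every ROI and summarizes how many
#' ROIs show at least one significant timepoint.
#'
#' @inheritParams timepoint_paired_tests
#' @param rois ROI names.
#' @return List per ROI of test results, with attribute
#'   `n_rois_significant`.
#' @export
group_roi_tests <- function(pairs, rois = roi_order(), q = 0.05) {
  out <- lapply(rois, function(r) timepoint_paired_tests(pairs, r, q))
  names(out) <- rois
  attr(out, "n_rois_significant") <-
    sum(vapply(out, function(x) any(x$significant), logical(1)))
  out
}
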