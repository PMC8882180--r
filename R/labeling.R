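#' Thresholds for the heart-rate / self-rated-high algorithm
#'
#' The intoxication algorithm declares a scan "intoxicated" when both the
#' self-rated high and the heart-rate rise over pre-dose baseline exceed
#' their cuts.  The DEQ cut of 50/100 follows the study's >50 split; the
#' 10 bpm rise is a conventional tachycardia-change criterion and, like the
#' matching window, is configurable.
#'
#' @param deq_high_cut exclusive DEQ "high" threshold (0-100).
#' @param hr_delta_cut minimum rise (bpm) of in-window peak heart rate over
#'   the mean pre-dose heart rate.
#' @param scan_window_min half-width (min) for matching vitals samples to a
#'   scan midpoint.
#' @return List of class `algo_thresholds`.
#' @export
algo_thresholds <- function(deq_high_cut = 50, hr_delta_cut = 10,
                            scan_window_min = 30) {
  if (deq_high_cut <= 0 || deq_high_cut >= 100)
    stop("deq_high_cut must lie in (0, 100)")
  if (hr_delta_cut < 0) stop("hr_delta_cut must be >= 0")
  structure(list(deq_high_cut = deq_high_cut, hr_delta_cut = hr_delta_cut,
                 scan_window_min = scan_window_min),
            class = "algo_thresholds")
}

#' Algorithmic intoxication call for one scan
#'
#' Returns `TRUE` iff, within `scan_time_min +/- scan_window_min`, the
#' maximum self-rated high exceeds `deq_high_cut` AND the maximum heart rate
#' exceeds the mean pre-dose heart rate by at least `hr_delta_cut`.  The
#' conjunction of a physiologic and a psychologic criterion keeps the
#' false-positive rate on placebo visits low.
#'
#' @param vitals a `vitals_series`.
#' @param scan_time_min scan midpoint, minutes from dosing.
#' @param th an [algo_thresholds()].
#' @return List: `intoxicated` (logical), `deq_max`, `hr_delta` (the two
#'   margins), `n_window_samples`.
#' @export
algorithmic_intoxication <- function(vitals, scan_time_min,
                                     th = algo_thresholds()) {
  s <- vitals$samples
  pre <- s[s$minutes <= 0, , drop = FALSE]
  if (nrow(pre) == 0L)
    stop("vitals for ", vitals$participant_id, "/", vitals$visit_arm,
         " have no pre-dose sample")
  win <- s[abs(s$minutes - scan_time_min) <= th$scan_window_min, , drop = FALSE]
  if (nrow(win) == 0L)
    stop("no vitals samples within ", th$scan_window_min, " min of the scan at ",
         scan_time_min, " min for ", vitals$participant_id, "/",
         vitals$visit_arm)
  deq_max <- max(win$deq_high)
  hr_delta <- max(win$heart_rate) - mean(pre$heart_rate)
  list(intoxicated = deq_max > th$deq_high_cut && hr_delta >= th$hr_delta_cut,
       deq_max = deq_max, hr_delta = hr_delta, n_window_samples = nrow(win))
}

#' Combine consensus rating and algorithm into ground truth
#'
#' Placebo scans are `placebo_negative`.  THC post-dose scans are `impaired`
#' only when the clinical consensus rating and the algorithm agree on
#' impairment, `not_clearly_impaired` when both agree on its absence, and
#' `discordant` otherwise (discordant scans are excluded from classifier
#' training).
#'
#' @param ccr `"impaired"`, `"not"` or `"unavailable"`.
#' @param algo logical algorithmic call.
#' @param arm `"THC"` or `"placebo"`.
#' @return One of `"impaired"`, `"not_clearly_impaired"`, `"discordant"`,
#'   `"placebo_negative"`.
#' @export
concordant_ground_truth <- function(ccr, algo, arm) {
  arm <- match.arg(arm, c("THC", "placebo"))
  if (arm == "placebo") return("placebo_negative")
  if (is.na(ccr) || ccr == "unavailable") {
    warning("CCR unavailable on a THC scan; labeling it discordant")
    return("discordant")
  }
  ccr <- match.arg(ccr, c("impaired", "not"))
  if (ccr == "impaired" && isTRUE(algo)) "impaired"
  else if (ccr == "not" && !isTRUE(algo)) "not_clearly_impaired"
  else "discordant"
}

#' Assemble the per-scan label table for a cohort
#'
#' Runs the intoxication algorithm on every post-dose scan, combines it with
#' the consensus ratings, and returns per-scan labels plus the
#' per-participant impairment pattern summary (impaired at scan 2 only,
#' scan 3 only, both, or neither).
#'
#' @param vitals list of `vitals_series` (both arms).
#' @param ccr data.frame with columns participant_id, visit_arm, scan_index,
#'   ccr_impaired (THC post-dose scans).
#' @param scan_times_min midpoints of scans 1-3, minutes from dosing.
#' @param th an [algo_thresholds()].
#' @return List with `labels` (data.frame: participant_id, visit_arm,
#'   scan_index, ccr_impaired, algo_intoxicated, deq_max, hr_delta,
#'   ground_truth) and `summary` (named counts scan2_only / scan3_only /
#'   both / neither over THC-visit participants).
#' @export
assemble_label_table <- function(vitals, ccr,
                                 scan_times_min = c(-15, 100, 200),
                                 th = algo_thresholds()) {
  rows <- list()
  for (v in vitals) {
    for (k in 2:3) {
      a <- algorithmic_intoxication(v, scan_times_min[k], th)
      cc <- if (v$visit_arm == "THC") {
        hit <- ccr$participant_id == v$participant_id &
          ccr$visit_arm == v$visit_arm & ccr$scan_index == k
        if (sum(hit) > 1L)
          stop("duplicate CCR entry for ", v$participant_id, "/",
               v$visit_arm, "/", k)
        if (any(hit)) ccr$ccr_impaired[hit] else "unavailable"
      } else NA_character_
      gt <- suppressWarnings(
        concordant_ground_truth(cc, a$intoxicated, v$visit_arm))
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = v$participant_id, visit_arm = v$visit_arm,
        scan_index = k, ccr_impaired = if (is.na(cc)) NA_character_ else cc,
        algo_intoxicated = a$intoxicated, deq_max = a$deq_max,
        hr_delta = a$hr_delta, ground_truth = gt, stringsAsFactors = FALSE)
    }
  }
  labels <- do.call(rbind, rows)
  key <- paste(labels$participant_id, labels$visit_arm, labels$scan_index)
  if (anyDuplicated(key))
    stop("duplicate (participant, arm, scan) label keys")
  thc <- labels[labels$visit_arm == "THC", , drop = FALSE]
  pattern <- vapply(unique(thc$participant_id), function(p) {
    imp <- thc$ground_truth[thc$participant_id == p] == "impaired"
    at2 <- any(imp & thc$scan_index[thc$participant_id == p] == 2)
    at3 <- any(imp & thc$scan_index[thc$participant_id == p] == 3)
    if (at2 && at3) "both" else if (at2) "scan2_only"
    else if (at3) "scan3_only" else "neither"
  }, character(1))
  summary <- c(scan2_only = sum(pattern == "scan2_only"),
               scan3_only = sum(pattern == "scan3_only"),
               both = sum(pattern == "both"),
               neither = sum(pattern == "neither"))
  list(labels = labels, summary = summary)
}
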