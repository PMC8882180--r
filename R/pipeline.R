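#' Run the full synthetic study pipeline
#'
#' Generates a synthetic cross-over cohort, preprocesses every scan to
#' block-averaged ROI timecourses, assembles ground-truth labels from the
#' simulated consensus ratings and the heart-rate/self-rated-high algorithm,
#' extracts the 95-value temporal feature vectors and sliding-window
#' connectivity sequences, cross-validates the requested classifier on
#' impaired vs post-placebo scans, evaluates the not-clearly-impaired scans
#' as an all-negative hold-out, and runs the group-level timepoint
#' statistics for the impaired and placebo groups.
#'
#' @param spec a [cohort_spec()].
#' @param model classifier for cross-validation.
#' @param k,repeats cross-validation geometry.
#' @param rnn_cfg an [rnn_config()].
#' @param band optional band-pass edges (Hz) applied before epoching
#'   (connectivity always uses the continuous HbO record).
#' @param window,skip connectivity window geometry (samples).
#' @param th an [algo_thresholds()].
#' @param do_cv,do_holdout,do_group toggles for the expensive stages.
#' @return List with `cohort`, `labels`, `roi_tcs`, `features`,
#'   `sequences`, `cv`, `holdout`, `group_impaired`, `group_placebo`.
#' @export
run_study <- function(spec = cohort_spec(), model = "ensemble",
                      k = 5, repeats = 1, rnn_cfg = rnn_config(),
                      band = NULL, window = 300, skip = 100,
                      th = algo_thresholds(),
                      do_cv = TRUE, do_holdout = TRUE, do_group = TRUE) {
  layout <- build_probe_layout()
  cohort <- generate_cohort(spec, layout)
  keys <- vapply(cohort$scans, scan_key, character(1))

  roi_tcs <- lapply(cohort$scans, preprocess_scan, layout = layout,
                    band = band)
  names(roi_tcs) <- keys

  lab <- assemble_label_table(cohort$vitals, cohort$ccr,
                              spec$scan_times_min, th)

  features <- lapply(roi_tcs, build_feature_vector)
  sequences <- lapply(cohort$scans, function(s)
    vectorize_windows(sliding_window_correlations(s, window, skip)))
  names(sequences) <- keys

  out <- list(cohort = cohort, labels = lab, roi_tcs = roi_tcs,
              features = features, sequences = sequences)

  fm <- feature_matrix(features, lab$labels,
                       include = c("impaired", "placebo_negative"))
  out$train_matrix <- fm
  if (do_cv) {
    out$cv <- cross_validate(fm$x, sequences[rownames(fm$x)], fm$y,
                             groups = fm$meta$participant_id, model = model,
                             k = k, repeats = repeats, seed = spec$seed,
                             rnn_cfg = rnn_cfg)
  }
  if (do_holdout) {
    hold <- lab$labels$ground_truth == "not_clearly_impaired"
    if (any(hold)) {
      hm <- feature_matrix(features, lab$labels,
                           include = "not_clearly_impaired")
      hold_p <- unique(hm$meta$participant_id)
      train_ok <- !(fm$meta$participant_id %in% hold_p)
      if (sum(train_ok) > 0 && length(unique(fm$y[train_ok])) == 2) {
        bundle <- train_ensemble(fm$x[train_ok, , drop = FALSE],
                                 sequences[rownames(fm$x)[train_ok]],
                                 fm$y[train_ok],
                                 groups = fm$meta$participant_id[train_ok],
                                 rnn_cfg = rnn_cfg, seed = spec$seed)
        out$holdout <- evaluate_holdout(bundle, hm$x,
                                        sequences[rownames(hm$x)],
                                        y = hm$y,
                                        groups = hm$meta$participant_id)
        out$holdout_bundle <- bundle
      }
    }
  }
  if (do_group) {
    thc_lab <- lab$labels[lab$labels$visit_arm == "THC", , drop = FALSE]
    imp_participants <- unique(thc_lab$participant_id[
      thc_lab$ground_truth == "impaired"])
    all_participants <- unique(lab$labels$participant_id)
    if (length(imp_participants) >= 3) {
      mp_imp <- matched_pairs(roi_tcs, cohort$vitals, imp_participants,
                              "THC", spec$scan_times_min)
      out$group_impaired <- group_roi_tests(mp_imp)
      out$matched_impaired <- mp_imp
    }
    mp_pla <- matched_pairs(roi_tcs, cohort$vitals, all_participants,
                            "placebo", spec$scan_times_min)
    out$group_placebo <- group_roi_tests(mp_pla)
    out$matched_placebo <- mp_pla
  }
  out
}
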