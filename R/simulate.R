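#' Canonical double-gamma hemodynamic response function
#'
#' `h(t) = dgamma(t, peak, 1) - ratio * dgamma(t, undershoot, 1)`, rescaled so
#' the impulse response peaks at 1.  Defaults place the peak near 6 s and the
#' undershoot near 16 s, the conventional canonical response.
#'
#' @param t times in seconds (>= 0).
#' @param peak_s gamma shape of the positive lobe (peak time, s).
#' @param undershoot_s gamma shape of the undershoot lobe (s).
#' @param undershoot_ratio relative undershoot amplitude.
#' @return Numeric vector, unit peak.
#' @export
hrf_double_gamma <- function(t, peak_s = 6, undershoot_s = 16,
                             undershoot_ratio = 1 / 6) {
  h <- stats::dgamma(t, shape = peak_s, rate = 1) -
    undershoot_ratio * stats::dgamma(t, shape = undershoot_s, rate = 1)
  h / max(h)
}

#' Block schedule for the n-back run
#'
#' Twelve alternating 30-s blocks (six 0-back, six 2-back) filling the
#' 6-minute run, 0-back first so every 2-back onset has pre-onset baseline
#' data.
#'
#' @param fs sampling rate (Hz).
#' @param n_blocks total number of blocks.
#' @param block_s block duration (s).
#' @param first condition of the first block.
#' @return events data.frame (`onset_sample` 1-based, `condition`,
#'   `duration_s`).
#' @export
block_schedule <- function(fs = 7.81, n_blocks = 12, block_s = 30,
                           first = "0-back") {
  onsets_s <- (seq_len(n_blocks) - 1) * block_s
  conds <- rep(c(first, setdiff(c("0-back", "2-back"), first)),
               length.out = n_blocks)
  data.frame(onset_sample = as.integer(round(onsets_s * fs)) + 1L,
             condition = conds, duration_s = block_s,
             stringsAsFactors = FALSE)
}

#' Task regressor: HRF-convolved boxcar, unit single-block peak
#'
#' Builds the predicted response shape for a given condition by convolving
#' the block boxcar with the double-gamma HRF, scaled so that the response to
#' one isolated block peaks at exactly 1; a block amplitude beta (micromolar)
#' then appears as a peak of height ~beta in the clean signal.
#'
#' @param n number of samples in the scan.
#' @param fs sampling rate (Hz).
#' @param events events data.frame as in [block_schedule()].
#' @param condition which condition drives the regressor.
#' @inheritParams hrf_double_gamma
#' @return Numeric vector of length `n`.
#' @export
task_regressor <- function(n, fs, events, condition = "2-back",
                           peak_s = 6, undershoot_s = 16,
                           undershoot_ratio = 1 / 6) {
  box <- numeric(n)
  ev <- events[events$condition == condition, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    a <- ev$onset_sample[i]
    b <- min(n, a + as.integer(round(ev$duration_s[i] * fs)) - 1L)
    box[a:b] <- 1
  }
  hl <- as.integer(round(40 * fs))
  h <- hrf_double_gamma((0:hl) / fs, peak_s, undershoot_s, undershoot_ratio)
  # scale so the response to one isolated block peaks at exactly 1
  dur <- if (nrow(ev) > 0L) ev$duration_s[1] else 30
  block_n <- max(1L, as.integer(round(dur * fs)))
  single <- numeric(block_n + hl + 1L)
  single[seq_len(block_n)] <- 1
  unit_peak <- max(stats::convolve(single, rev(h), type = "open"))
  stats::convolve(box, rev(h), type = "open")[seq_len(n)] / unit_peak
}

#' Specification of a synthetic cross-over cohort
#'
#' Defines the study conditions the generator emulates: a double-blind
#' cross-over with a THC and a placebo visit per participant, three 6-minute
#' 20-channel scans per visit (pre-dose, ~100 and ~200 min post-dose) at
#' 7.81 Hz, vitals every 20 min over [-20, 240] min, and a latent impairment
#' status that raises the 2-back HbO response, heart rate and self-rated
#' "high" after THC.
#'
#' @param n_participants cohort size.
#' @param p_impaired_given_thc probability a THC-visit participant becomes
#'   impaired; default 80/137, the study's concordant-impaired fraction.
#' @param p_scan_pattern given impairment, probabilities of being impaired at
#'   scan 2 only / scan 3 only / both, default proportional to the study's
#'   39/20/24 split.
#' @param fs,scan_duration_s,n_blocks,block_s scan geometry.
#' @param hrf_peak_s,hrf_undershoot_s,hrf_undershoot_ratio HRF shape.
#' @param beta_base baseline 2-back response amplitude (micromolar).
#' @param delta_beta amplitude increase when impaired (micromolar).
#' @param hbr_ratio HbR = -hbr_ratio * clean HbO + independent noise.
#' @param sigma_white white noise SD per channel (micromolar); the default
#'   puts the single-sample SNR of the impairment effect near 1.
#' @param drift_amp SD of the per-channel linear drift over the full scan.
#' @param amp_cardiac,amp_resp,amp_mayer amplitudes (micromolar) of shared
#'   sinusoidal physiological components at `freq_cardiac` (~1.1 Hz),
#'   `freq_resp` (~0.25 Hz) and `freq_mayer` (~0.1 Hz).
#' @param freq_cardiac,freq_resp,freq_mayer component frequencies (Hz).
#' @param hr_baseline_mean,hr_baseline_sd pre-dose heart rate distribution.
#' @param hr_delta_impaired,hr_delta_not_impaired tachycardia peak (bpm).
#' @param hr_peak_min,hr_tau_min time-to-peak and decay constant (min).
#' @param hr_noise_sd heart-rate measurement noise (bpm).
#' @param deq_peak_impaired,deq_peak_not_impaired peak self-rated high.
#' @param deq_peak_sd between-participant SD of the peak.
#' @param deq_peak_min,deq_tau_min DEQ time-to-peak and decay (min).
#' @param deq_noise_sd DEQ measurement noise.
#' @param scan_times_min nominal scan midpoints relative to dosing (min).
#' @param ccr_error_rate probability the simulated clinical consensus rating
#'   flips the latent scan-level truth.
#' @param seed master seed; named substreams (assignment, fnirs, vitals) are
#'   derived from it so, e.g., changing heart-rate parameters leaves the
#'   fNIRS series bit-identical.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20,
                        p_impaired_given_thc = 80 / 137,
                        p_scan_pattern = c(39, 20, 24) / 83,
                        fs = 7.81, scan_duration_s = 360,
                        n_blocks = 12, block_s = 30,
                        hrf_peak_s = 6, hrf_undershoot_s = 16,
                        hrf_undershoot_ratio = 1 / 6,
                        beta_base = 0.2, delta_beta = 0.3,
                        hbr_ratio = 1 / 3,
                        sigma_white = 0.3, drift_amp = 0.1,
                        amp_cardiac = 0.1, amp_resp = 0.05, amp_mayer = 0.1,
                        freq_cardiac = 1.1, freq_resp = 0.25,
                        freq_mayer = 0.1,
                        hr_baseline_mean = 70, hr_baseline_sd = 8,
                        hr_delta_impaired = 25, hr_delta_not_impaired = 5,
                        hr_peak_min = 60, hr_tau_min = 200,
                        hr_noise_sd = 3,
                        deq_peak_impaired = 75, deq_peak_not_impaired = 25,
                        deq_peak_sd = 10,
                        deq_peak_min = 100, deq_tau_min = 300,
                        deq_noise_sd = 5,
                        scan_times_min = c(-15, 100, 200),
                        ccr_error_rate = 0.1,
                        seed = 1) {
  spec <- as.list(environment())
  if (p_impaired_given_thc < 0 || p_impaired_given_thc > 1)
    stop("p_impaired_given_thc must lie in [0, 1]")
  if (abs(sum(p_scan_pattern) - 1) > 1e-8 || any(p_scan_pattern < 0))
    stop("p_scan_pattern must be a probability vector of length 3")
  amps <- c(spec$beta_base, spec$delta_beta, spec$sigma_white, spec$drift_amp,
            spec$amp_cardiac, spec$amp_resp, spec$amp_mayer)
  if (any(amps < 0)) stop("amplitudes must be >= 0")
  if (spec$scan_duration_s <= 0 || spec$fs <= 0)
    stop("scan duration and sampling rate must be positive")
  if (spec$deq_peak_impaired <= spec$deq_peak_not_impaired)
    stop("impaired DEQ peak must exceed the not-impaired peak")
  class(spec) <- "cohort_spec"
  spec
}

# Deterministic substream seed below 2^31, derived from master seed + name.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 104729L)
}

# ramp-to-peak then exponential decay, 0 pre-dose, max exactly 1 at t = peak
dose_response_shape <- function(t_min, peak_min, tau_min) {
  ifelse(t_min <= 0, 0,
         ifelse(t_min <= peak_min, t_min / peak_min,
                exp(-(t_min - peak_min) / tau_min)))
}

#' Simulate one scan's hemoglobin time series
#'
#' Clean HbO = beta * (HRF-convolved 2-back boxcar, unit block peak) +
#' linear drift + shared sinusoidal physiological components; HbO adds white
#' channel noise, HbR is `-hbr_ratio` times the clean HbO plus independent
#' white noise.  Consumes the current global RNG state.
#'
#' @param beta 2-back response amplitude (micromolar); scalar or one value
#'   per channel.
#' @param spec a [cohort_spec()] (noise and geometry fields are used).
#' @param layout probe layout (channel count).
#' @param participant_id,visit_arm,scan_index scan metadata.
#' @return A `nirs_scan` with `data_kind = "hemoglobin"`.
#' @export
synth_scan_timeseries <- function(beta, spec = cohort_spec(),
                                  layout = build_probe_layout(),
                                  participant_id = "sim", visit_arm = "THC",
                                  scan_index = 1) {
  fs <- spec$fs
  n <- as.integer(floor(spec$scan_duration_s * fs))
  nc <- n_channels(layout)
  events <- block_schedule(fs, spec$n_blocks, spec$block_s)
  if (max(events$onset_sample) > n)
    stop("block schedule does not fit within the scan duration")
  reg <- task_regressor(n, fs, events, "2-back", spec$hrf_peak_s,
                        spec$hrf_undershoot_s, spec$hrf_undershoot_ratio)
  beta <- rep_len(beta, nc)
  t_s <- (seq_len(n) - 1) / fs
  # shared physiological sinusoids, random phase per scan
  physio <- numeric(n)
  for (comp in list(c(spec$amp_cardiac, spec$freq_cardiac),
                    c(spec$amp_resp, spec$freq_resp),
                    c(spec$amp_mayer, spec$freq_mayer))) {
    if (comp[1] > 0)
      physio <- physio + comp[1] * sin(2 * pi * comp[2] * t_s +
                                         stats::runif(1, 0, 2 * pi))
  }
  clean <- outer(reg, beta) + physio
  if (spec$drift_amp > 0) {
    slopes <- stats::rnorm(nc, 0, spec$drift_amp)
    clean <- clean + outer(t_s / max(t_s), slopes)
  }
  noise1 <- matrix(stats::rnorm(n * nc, 0, spec$sigma_white), n, nc)
  noise2 <- matrix(stats::rnorm(n * nc, 0, spec$sigma_white), n, nc)
  hbo <- clean + noise1
  hbr <- -spec$hbr_ratio * clean + noise2
  new_scan(participant_id, visit_arm, scan_index, fs, "hemoglobin",
           list(hbo = hbo, hbr = hbr), events)
}

#' Simulate a visit's vitals series
#'
#' Impaired THC visits show a tachycardia bump (ramp to `hr_delta` at
#' `hr_peak_min`, then exponential decay) and a self-rated-high trajectory
#' peaking above the 50/100 split; not-impaired and placebo visits stay near
#' baseline.  DEQ values are clipped to [0, 100].  Consumes the global RNG.
#'
#' @param impaired logical latent status.
#' @param arm `"THC"` or `"placebo"`.
#' @param spec a [cohort_spec()].
#' @param participant_id id for the output.
#' @param hr_baseline optional realized baseline (bpm); drawn if `NULL`.
#' @return A `vitals_series`.
#' @export
synth_vitals <- function(impaired, arm, spec = cohort_spec(),
                         participant_id = "sim", hr_baseline = NULL) {
  minutes <- seq(-20, 240, by = 20)
  if (is.null(hr_baseline))
    hr_baseline <- stats::rnorm(1, spec$hr_baseline_mean, spec$hr_baseline_sd)
  if (arm == "placebo") {
    hr_delta <- 0; deq_peak <- 0
  } else if (impaired) {
    hr_delta <- spec$hr_delta_impaired
    deq_peak <- spec$deq_peak_impaired + stats::rnorm(1, 0, spec$deq_peak_sd)
  } else {
    hr_delta <- spec$hr_delta_not_impaired
    deq_peak <- spec$deq_peak_not_impaired +
      stats::rnorm(1, 0, spec$deq_peak_sd)
  }
  hr <- hr_baseline +
    hr_delta * dose_response_shape(minutes, spec$hr_peak_min, spec$hr_tau_min)
  deq <- deq_peak *
    dose_response_shape(minutes, spec$deq_peak_min, spec$deq_tau_min)
  if (spec$hr_noise_sd > 0)
    hr <- hr + stats::rnorm(length(minutes), 0, spec$hr_noise_sd)
  if (spec$deq_noise_sd > 0)
    deq <- deq + stats::rnorm(length(minutes), 0, spec$deq_noise_sd)
  deq <- pmin(100, pmax(0, deq))
  hr <- pmax(30, hr)
  new_vitals(participant_id, arm,
             data.frame(minutes = minutes, heart_rate = hr, deq_high = deq))
}

#' Generate a full synthetic cross-over cohort
#'
#' Every participant gets a THC and a placebo visit, each with three scans
#' (pre-dose, ~100 min, ~200 min).  A latent Bernoulli draw decides whether
#' the participant becomes impaired on the THC visit; impairment is expressed
#' at scan 2 only, scan 3 only, or both (multinomial over the study's 39/20/24
#' pattern), raising the expressed scans' 2-back amplitude from `beta_base`
#' to `beta_base + delta_beta` and driving the vitals trajectories.  A
#' simulated clinical consensus rating flips the scan-level truth with
#' probability `ccr_error_rate`, producing discordant cases.
#'
#' Randomness is split into named substreams (assignment, fnirs, vitals)
#' derived from `spec$seed`, so regenerating with the same seed is exact and
#' vitals parameters never perturb the fNIRS draws.
#'
#' @param spec a [cohort_spec()].
#' @param layout probe layout.
#' @return List with `scans` (list of `nirs_scan`), `vitals` (list of
#'   `vitals_series`), `truth` (per-participant latent truth data.frame),
#'   `ccr` (simulated consensus ratings per post-dose THC scan) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec(),
                            layout = build_probe_layout()) {
  ids <- sprintf("P%03d", seq_len(spec$n_participants))

  ## -- assignment stream: latent impairment, scan pattern, CCR errors
  set.seed(stream_seed(spec$seed, "assignment"))
  impaired_if_thc <- stats::runif(spec$n_participants) < spec$p_impaired_given_thc
  pattern <- ifelse(impaired_if_thc,
                    apply(stats::rmultinom(spec$n_participants, 1,
                                           spec$p_scan_pattern) == 1, 2, which),
                    0L)
  imp_scan2 <- impaired_if_thc & pattern %in% c(1L, 3L)
  imp_scan3 <- impaired_if_thc & pattern %in% c(2L, 3L)
  ccr_flip <- matrix(stats::runif(spec$n_participants * 2) < spec$ccr_error_rate,
                     ncol = 2)

  ## -- fnirs stream: all scan series, fixed order
  set.seed(stream_seed(spec$seed, "fnirs"))
  scans <- list()
  for (i in seq_len(spec$n_participants)) {
    for (arm in c("THC", "placebo")) {
      for (k in 1:3) {
        raised <- arm == "THC" &&
          ((k == 2 && imp_scan2[i]) || (k == 3 && imp_scan3[i]))
        beta <- spec$beta_base + if (raised) spec$delta_beta else 0
        scans[[length(scans) + 1L]] <-
          synth_scan_timeseries(beta, spec, layout, ids[i], arm, k)
      }
    }
  }

  ## -- vitals stream
  set.seed(stream_seed(spec$seed, "vitals"))
  vitals <- list()
  for (i in seq_len(spec$n_participants)) {
    base_hr <- stats::rnorm(1, spec$hr_baseline_mean, spec$hr_baseline_sd)
    vitals[[length(vitals) + 1L]] <-
      synth_vitals(impaired_if_thc[i], "THC", spec, ids[i], base_hr)
    vitals[[length(vitals) + 1L]] <-
      synth_vitals(FALSE, "placebo", spec, ids[i], base_hr)
  }

  truth <- data.frame(participant_id = ids,
                      impaired_if_thc = impaired_if_thc,
                      impaired_scan2 = imp_scan2,
                      impaired_scan3 = imp_scan3,
                      stringsAsFactors = FALSE)
  ccr <- data.frame(
    participant_id = rep(ids, each = 2),
    visit_arm = "THC",
    scan_index = rep(2:3, times = spec$n_participants),
    stringsAsFactors = FALSE)
  latent <- ifelse(ccr$scan_index == 2, imp_scan2[match(ccr$participant_id, ids)],
                   imp_scan3[match(ccr$participant_id, ids)])
  flip <- as.vector(t(ccr_flip))
  rated <- xor(latent, flip)
  ccr$ccr_impaired <- ifelse(rated, "impaired", "not")

  list(scans = scans, vitals = vitals, truth = truth, ccr = ccr, spec = spec)
}
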