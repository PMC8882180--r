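# Shared fixtures: small, fast variants of the study conditions.

# noise-free spec for deterministic forward-model checks
quiet_spec <- function(sigma_white = 0, ...) {
  cohort_spec(sigma_white = sigma_white, drift_amp = 0, amp_cardiac = 0,
              amp_resp = 0, amp_mayer = 0, hr_noise_sd = 0,
              deq_noise_sd = 0, deq_peak_sd = 0, ...)
}

# short scans (2 blocks, 70 s) for tests that only need assignment/vitals
# machinery or cheap series
short_spec <- function(...) {
  cohort_spec(scan_duration_s = 70, n_blocks = 2, ...)
}

# tiny RNN for classifier tests that exercise wiring rather than capacity
tiny_rnn <- function(input_dim = 190, ...) {
  rnn_config(input_dim = input_dim, encoder = c(16, 8), hidden = 8,
             epochs = 40, ...)
}

# matched pre/peak pairs built directly from the forward model
make_pairs <- function(n, beta_pre, beta_peak, spec, seed) {
  set.seed(seed)
  layout <- build_probe_layout()
  pairs <- list()
  for (i in seq_len(n)) {
    pre <- preprocess_scan(synth_scan_timeseries(
      beta_pre, spec, layout, sprintf("Q%03d", i), "THC", 1), layout)
    peak <- preprocess_scan(synth_scan_timeseries(
      beta_peak, spec, layout, sprintf("Q%03d", i), "THC", 2), layout)
    pairs[[sprintf("Q%03d", i)]] <- list(pre = pre, peak = peak,
                                         peak_scan = 2L)
  }
  list(pairs = pairs, n_pairs = length(pairs), n_excluded = 0L)
}

# independent Benjamini-Hochberg step-up oracle
bh_stepup <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  thresh <- q * seq_len(m) / m
  below <- which(p[ord] <= thresh)
  rej <- logical(m)
  if (length(below) > 0) rej[ord[seq_len(max(below))]] <- TRUE
  rej
}
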