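#' Modified Beer-Lambert law parameters
#'
#' Wavelengths, chromophore extinction coefficients, differential pathlength
#' factors, and per-channel source-detector distances.  Default extinction
#' coefficients are the standard tabulated HbO/HbR values at 760 and 850 nm
#' in cm^-1/(mol/L); DPF defaults to 6.0 at both wavelengths.  Concentrations
#' are reported in micromolar.
#'
#' @param wavelengths_nm two wavelengths (nm).
#' @param extinction 2x2 matrix, rows = wavelengths, columns = c(HbO, HbR),
#'   in cm^-1/(mol/L).
#' @param dpf differential pathlength factor per wavelength.
#' @param distance_cm source-detector distance, scalar or one per channel.
#' @return List of class `mbll_params`.
#' @export
mbll_params <- function(wavelengths_nm = c(760, 850),
                        extinction = matrix(c(1486.5865, 3843.707,
                                              2526.391, 1798.643),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("760", "850"),
                                                            c("HbO", "HbR"))),
                        dpf = c(6, 6), distance_cm = 3) {
  extinction <- as.matrix(extinction)
  if (!all(dim(extinction) == c(2, 2)))
    stop("extinction must be a 2x2 matrix (wavelength x chromophore)")
  if (abs(det(extinction)) < .Machine$double.eps * max(abs(extinction))^2)
    stop("extinction matrix is singular; HbO/HbR cannot be separated")
  if (any(dpf <= 0)) stop("DPF must be positive")
  if (any(distance_cm <= 0)) stop("distances must be positive")
  structure(list(wavelengths_nm = wavelengths_nm, extinction = extinction,
                 dpf = rep_len(dpf, 2), distance_cm = distance_cm),
            class = "mbll_params")
}

#' Raw intensity to optical density
#'
#' `OD(t) = -ln(I(t) / mean_t I)` per channel: the change in optical density
#' relative to the channel's temporal mean intensity.  A constant channel
#' maps to identically zero.
#'
#' @param intensity time x channel matrix of strictly positive intensities.
#' @return Matrix of the same shape.
#' @export
intensity_to_od <- function(intensity) {
  intensity <- as.matrix(intensity)
  bad <- which(intensity <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("nonpositive intensity at sample %d, channel %d",
                 bad[1, 1], bad[1, 2]))
  -log(sweep(intensity, 2, colMeans(intensity), "/"))
}

#' Optical density to hemoglobin concentration changes
#'
#' Per channel, solves the 2x2 modified Beer-Lambert system
#' `OD_lambda = eps(lambda, HbO) dHbO + eps(lambda, HbR) dHbR) * d * DPF_lambda`
#' for (dHbO, dHbR), returning concentrations in micromolar.  The mapping is
#' linear in OD.
#'
#' @param od named list of two time x channel OD matrices, one per
#'   wavelength, in the order of `params$wavelengths_nm`.
#' @param params an [mbll_params()].
#' @return List with `hbo` and `hbr` matrices (micromolar).
#' @export
od_to_hemoglobin <- function(od, params = mbll_params()) {
  stopifnot(length(od) == 2L)
  od1 <- as.matrix(od[[1]]); od2 <- as.matrix(od[[2]])
  if (!all(dim(od1) == dim(od2)))
    stop("OD matrices must share dimensions")
  d <- rep_len(params$distance_cm, ncol(od1))
  inv <- solve(params$extinction)
  # effective OD per unit pathlength, per wavelength
  y1 <- sweep(od1, 2, d * params$dpf[1], "/")
  y2 <- sweep(od2, 2, d * params$dpf[2], "/")
  list(hbo = 1e6 * (inv[1, 1] * y1 + inv[1, 2] * y2),
       hbr = 1e6 * (inv[2, 1] * y1 + inv[2, 2] * y2))
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (micromolar) to the optical-density
#' changes they would produce; inverse of [od_to_hemoglobin()].  Used to test
#' the inversion and to export raw-like data from the generator.
#'
#' @param hbo,hbr time x channel matrices (micromolar).
#' @inheritParams od_to_hemoglobin
#' @return Named list of two OD matrices (one per wavelength).
#' @export
hemoglobin_to_od <- function(hbo, hbr, params = mbll_params()) {
  hbo <- as.matrix(hbo); hbr <- as.matrix(hbr)
  d <- rep_len(params$distance_cm, ncol(hbo))
  E <- params$extinction
  out <- list()
  for (w in 1:2) {
    od <- 1e-6 * (E[w, 1] * hbo + E[w, 2] * hbr)
    out[[paste0("wl", params$wavelengths_nm[w])]] <-
      sweep(od, 2, d * params$dpf[w], "*")
  }
  out
}

#' Zero-phase band-pass filter with detrending
#'
#' Removes a linear trend (hence the DC level) per channel, then applies a
#' 3rd-order Butterworth band-pass forward and backward (`filtfilt`), so the
#' output is zero-phase and feature timing is preserved.  Defaults pass
#' 0.01-0.5 Hz, suppressing slow drift and the ~1.1 Hz cardiac band at the
#' 7.81 Hz sampling rate.
#'
#' @param x time x channel matrix (or vector).
#' @param fs sampling rate (Hz).
#' @param low_hz,high_hz band edges; `0 <= low < high < fs/2` required.
#' @param order Butterworth order.
#' @return Filtered matrix of the same shape.
#' @export
bandpass_and_detrend <- function(x, fs, low_hz = 0.01, high_hz = 0.5,
                                 order = 3) {
  if (!(low_hz >= 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("need 0 <= low_hz < high_hz < fs/2")
  x <- as.matrix(x)
  n <- nrow(x)
  t0 <- seq_len(n) - (n + 1) / 2
  # linear detrend per column (removes DC and slope)
  beta <- crossprod(t0, x) / sum(t0^2)
  x <- sweep(x, 2, colMeans(x), "-") - outer(t0, drop(beta))
  bf <- if (low_hz > 0)
    signal::butter(order, c(low_hz, high_hz) / (fs / 2), type = "pass")
  else
    signal::butter(order, high_hz / (fs / 2), type = "low")
  apply(x, 2, function(col) signal::filtfilt(bf, col))
}

#' Epoch a scan and average blocks per ROI
#'
#' Averages channels within each ROI, extracts one epoch per event of the
#' requested condition over `window` seconds (relative to onset, endpoints
#' sampled at `round(w * fs)` giving `round(diff(window) * fs) + 1` samples),
#' subtracts the mean over the pre-onset `baseline` window, and averages
#' epochs.  Blocks whose epoch or baseline exceeds the record are dropped and
#' counted.  The default 40-s window deliberately extends past the 30-s block
#' into the following control block, as the late feature segments require.
#'
#' @param scan a `nirs_scan` with `data_kind = "hemoglobin"`.
#' @param layout a `probe_layout`.
#' @param window epoch window in seconds relative to onset.
#' @param condition which event condition to epoch.
#' @param baseline pre-onset baseline window `[a, b)` in seconds.
#' @return Named list (one per ROI, in [roi_order()] order where present) of
#'   `roi_timecourse` objects: `roi`, `time_s`, `hbo`, `hbr`, `fs`,
#'   `n_blocks_averaged`, `n_blocks_dropped`, `baseline_window`.
#' @export
epoch_and_block_average <- function(scan, layout = build_probe_layout(),
                                    window = c(0, 40), condition = "2-back",
                                    baseline = c(-2, 0)) {
  if (scan$data_kind != "hemoglobin")
    stop("scan must hold hemoglobin series; run the MBLL conversion first")
  fs <- scan$sampling_rate_hz
  n <- nrow(scan$series$hbo)
  ev <- scan$events[scan$events$condition == condition, , drop = FALSE]
  if (nrow(ev) == 0L)
    stop("scan ", scan_key(scan), " has no ", condition, " events")
  rel <- seq.int(as.integer(round(window[1] * fs)),
                 as.integer(round(window[2] * fs)))
  b_lo <- as.integer(ceiling(baseline[1] * fs))
  b_hi <- as.integer(ceiling(baseline[2] * fs)) - 1L
  if (b_hi < b_lo) stop("baseline window contains no samples")
  base_rel <- seq.int(b_lo, b_hi)
  usable <- ev$onset_sample + max(rel) <= n & ev$onset_sample + min(base_rel) >= 1L
  n_drop <- sum(!usable)
  ons <- ev$onset_sample[usable]
  if (length(ons) == 0L)
    stop("scan ", scan_key(scan), ": no ", condition,
         " block has a full epoch window")
  out <- list()
  rois <- intersect(roi_order(), names(layout$roi_map))
  rois <- c(rois, setdiff(names(layout$roi_map), rois))
  for (roi in rois) {
    chs <- layout$roi_map[[roi]]
    avg <- list()
    for (chrom in c("hbo", "hbr")) {
      series <- rowMeans(scan$series[[chrom]][, chs, drop = FALSE])
      ep <- vapply(ons, function(o) {
        e <- series[o + rel]
        e - mean(series[o + base_rel])
      }, numeric(length(rel)))
      avg[[chrom]] <- rowMeans(ep)
    }
    out[[roi]] <- structure(
      list(roi = roi, time_s = rel / fs - window[1], hbo = avg$hbo,
           hbr = avg$hbr, fs = fs, n_blocks_averaged = length(ons),
           n_blocks_dropped = n_drop, baseline_window = baseline),
      class = "roi_timecourse")
  }
  out
}

#' Full preprocessing of one scan to ROI timecourses
#'
#' Convenience wrapper: optional raw-to-hemoglobin conversion (if the scan
#' holds raw intensities), optional band-pass/detrend, then per-ROI epoching
#' and block averaging.
#'
#' @inheritParams epoch_and_block_average
#' @param params MBLL parameters (used only for raw-intensity scans).
#' @param band band edges in Hz, or `NULL` to skip filtering.
#' @return As [epoch_and_block_average()].
#' @export
preprocess_scan <- function(scan, layout = build_probe_layout(),
                            params = mbll_params(), band = NULL,
                            window = c(0, 40), baseline = c(-2, 0)) {
  if (scan$data_kind == "raw_intensity") {
    od <- lapply(scan$series, intensity_to_od)
    hb <- od_to_hemoglobin(od, params)
    scan <- new_scan(scan$participant_id, scan$visit_arm, scan$scan_index,
                     scan$sampling_rate_hz, "hemoglobin", hb, scan$events)
  }
  if (!is.null(band)) {
    scan$series$hbo <- bandpass_and_detrend(scan$series$hbo,
                                            scan$sampling_rate_hz,
                                            band[1], band[2])
    scan$series$hbr <- bandpass_and_detrend(scan$series$hbr,
                                            scan$sampling_rate_hz,
                                            band[1], band[2])
  }
  epoch_and_block_average(scan, layout, window = window, baseline = baseline)
}
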