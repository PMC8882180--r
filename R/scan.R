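#' Construct a scan object
#'
#' A `nirs_scan` holds one 6-minute recording: a time x channel matrix per
#' wavelength (raw intensities) or per chromophore (HbO/HbR, micromolar),
#' the block-design task events, and visit metadata.  Sample k (1-based row k)
#' is at time (k-1)/fs seconds from scan start; event intervals are half-open
#' `[onset, onset + duration)`.
#'
#' @param participant_id character scalar.
#' @param visit_arm `"THC"` or `"placebo"`.
#' @param scan_index 1 (pre-dose), 2 (~100 min) or 3 (~200 min post-dose).
#' @param sampling_rate_hz sampling frequency, default 7.81 Hz.
#' @param data_kind `"raw_intensity"` or `"hemoglobin"`.
#' @param series named list of numeric matrices (time x channel), e.g.
#'   `list(hbo = , hbr = )` or `list(wl760 = , wl850 = )`.
#' @param events data.frame with columns `onset_sample` (1-based row index),
#'   `condition` (`"0-back"`/`"2-back"`) and `duration_s`.
#' @return An object of class `nirs_scan`.
#' @export
new_scan <- function(participant_id, visit_arm, scan_index,
                     sampling_rate_hz = 7.81, data_kind, series, events) {
  visit_arm <- match.arg(visit_arm, c("THC", "placebo"))
  data_kind <- match.arg(data_kind, c("raw_intensity", "hemoglobin"))
  if (!is.numeric(sampling_rate_hz) || sampling_rate_hz <= 0)
    stop("sampling_rate_hz must be > 0")
  if (!scan_index %in% 1:3) stop("scan_index must be 1, 2 or 3")
  if (!is.list(series) || is.null(names(series)) || length(series) == 0L)
    stop("series must be a named list of matrices")
  nr <- vapply(series, nrow, integer(1))
  nc <- vapply(series, ncol, integer(1))
  if (length(unique(nr)) != 1L || length(unique(nc)) != 1L)
    stop("all series matrices must share dimensions")
  n <- nr[[1]]
  events <- as.data.frame(events)
  if (nrow(events) > 0L) {
    need <- c("onset_sample", "condition", "duration_s")
    if (!all(need %in% names(events)))
      stop("events must have columns ", paste(need, collapse = ", "))
    if (any(diff(events$onset_sample) <= 0))
      stop("event onsets must be strictly increasing")
    if (any(events$onset_sample < 1 | events$onset_sample > n))
      stop("event onset outside the record")
  }
  structure(list(participant_id = as.character(participant_id),
                 visit_arm = visit_arm, scan_index = as.integer(scan_index),
                 sampling_rate_hz = sampling_rate_hz, data_kind = data_kind,
                 series = lapply(series, as.matrix), events = events),
            class = "nirs_scan")
}

#' @export
print.nirs_scan <- function(x, ...) {
  d <- dim(x$series[[1]])
  cat("<nirs_scan> participant ", x$participant_id, ", ", x$visit_arm,
      " visit, scan ", x$scan_index, "\n  ", x$data_kind, ": ",
      d[1], " samples x ", d[2], " channels at ", x$sampling_rate_hz,
      " Hz (", paste(names(x$series), collapse = "/"), "), ",
      nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Unique key identifying a scan
#' @param scan a `nirs_scan` (or anything with the three id fields).
#' @return Character scalar `"participant/arm/scan_index"`.
#' @export
scan_key <- function(scan) {
  paste(scan$participant_id, scan$visit_arm, scan$scan_index, sep = "/")
}

#' Construct a vitals series
#'
#' Heart rate (bpm) and Drug Effects Questionnaire self-rated "high" (0-100)
#' sampled roughly every 20 minutes across a visit, minutes measured from
#' dosing (pre-dose samples have minutes <= 0).
#'
#' @param participant_id character scalar.
#' @param visit_arm `"THC"` or `"placebo"`.
#' @param samples data.frame with columns `minutes`, `heart_rate`, `deq_high`.
#' @return An object of class `vitals_series`.
#' @export
new_vitals <- function(participant_id, visit_arm, samples) {
  visit_arm <- match.arg(visit_arm, c("THC", "placebo"))
  samples <- as.data.frame(samples)
  need <- c("minutes", "heart_rate", "deq_high")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  if (any(samples$deq_high < 0 | samples$deq_high > 100))
    stop("deq_high must lie in [0, 100]")
  if (any(samples$heart_rate <= 0)) stop("heart_rate must be positive")
  if (!any(samples$minutes <= 0))
    stop("vitals need at least one pre-dose (minutes <= 0) sample")
  structure(list(participant_id = as.character(participant_id),
                 visit_arm = visit_arm,
                 samples = samples[order(samples$minutes), , drop = FALSE]),
            class = "vitals_series")
}

#' @export
print.vitals_series <- function(x, ...) {
  cat("<vitals_series> participant ", x$participant_id, ", ", x$visit_arm,
      " visit, ", nrow(x$samples), " samples over [",
      min(x$samples$minutes), ", ", max(x$samples$minutes), "] min\n", sep = "")
  invisible(x)
}

#' Flatten a list of vitals series to one table
#' @param vitals list of `vitals_series`.
#' @return data.frame with columns participant_id, visit_arm, minutes,
#'   heart_rate, deq_high.
#' @export
vitals_table <- function(vitals) {
  do.call(rbind, lapply(vitals, function(v) {
    cbind(data.frame(participant_id = v$participant_id,
                     visit_arm = v$visit_arm, stringsAsFactors = FALSE),
          v$samples)
  }))
}

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

#' Write a scan to wide CSV plus JSON sidecar
#'
#' The CSV holds a `time_s` column (seconds from scan start, sample k at
#' (k-1)/fs) followed by one column per channel and series, named
#' `<series>_ch<NN>`.  Metadata and events go to a JSON sidecar next to the
#' CSV (same name, `.json` extension).
#'
#' @param scan a `nirs_scan`.
#' @param path output CSV path (must end in `.csv`).
#' @return Invisibly, the CSV path.
#' @export
write_scan <- function(scan, path) {
  if (!grepl("\\.csv$", path)) stop("path must end in .csv")
  n <- nrow(scan$series[[1]])
  nc <- ncol(scan$series[[1]])
  cols <- list(time_s = (seq_len(n) - 1) / scan$sampling_rate_hz)
  for (nm in names(scan$series)) {
    m <- scan$series[[nm]]
    for (j in seq_len(nc))
      cols[[sprintf("%s_ch%02d", nm, j)]] <- m[, j]
  }
  dt <- data.table::as.data.table(cols)
  data.table::fwrite(dt, path)
  meta <- list(participant_id = scan$participant_id,
               visit_arm = scan$visit_arm, scan_index = scan$scan_index,
               sampling_rate_hz = scan$sampling_rate_hz,
               data_kind = scan$data_kind,
               series_names = names(scan$series), n_channels = nc,
               events = scan$events)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read a scan written by [write_scan()]
#'
#' @param path CSV path; the JSON sidecar must sit next to it.
#' @param layout optional `probe_layout`; if given, the channel count in the
#'   file must match the layout.
#' @return A `nirs_scan`.
#' @export
read_scan <- function(path, layout = NULL) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) stop("missing JSON sidecar for ", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  dt <- data.table::fread(path, data.table = FALSE)
  if (is.unsorted(dt$time_s, strictly = TRUE))
    stop("time column is not strictly increasing in ", path)
  series <- list()
  for (nm in meta$series_names) {
    cols <- grep(sprintf("^%s_ch[0-9]+$", nm), names(dt), value = TRUE)
    series[[nm]] <- as.matrix(dt[, cols, drop = FALSE])
    dimnames(series[[nm]]) <- NULL
  }
  ncol_found <- ncol(series[[1]])
  if (ncol_found != meta$n_channels)
    stop("file has ", ncol_found, " channel columns but sidecar declares ",
         meta$n_channels)
  if (!is.null(layout) && ncol_found != n_channels(layout))
    stop("file has ", ncol_found, " channel columns but layout has ",
         n_channels(layout))
  ev <- meta$events
  if (is.null(ev) || length(ev) == 0L)
    ev <- data.frame(onset_sample = integer(), condition = character(),
                     duration_s = numeric())
  new_scan(meta$participant_id, meta$visit_arm, meta$scan_index,
           meta$sampling_rate_hz, meta$data_kind, series, as.data.frame(ev))
}
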