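#' Default prefrontal probe configuration
#'
#' The study probe: 8 sources and 7 detectors over the forehead, mid-column on
#' Fpz with the lowest optodes along the F5-Fp1-Fpz-Fp2-F6 line, giving 20
#' source-detector channels grouped into five regions of interest.  Optode
#' positions are 10-20 labels only; geometry is metadata, the analysis uses it
#' solely for ROI grouping.
#'
#' @param sd_distance_cm source-detector separation assumed for every channel
#'   (cm).  The physical separations ranged 2.5-3 cm but are not published per
#'   channel; 3 cm is the default and is configurable.
#' @return A list with `sources`, `detectors`, `channels` (data.frame of
#'   channel_id, source_id, detector_id, position, distance_cm) and `roi_map`,
#'   suitable for [build_probe_layout()].
#' @export
default_probe_config <- function(sd_distance_cm = 3) {
  sources <- data.frame(
    source_id = paste0("S", 1:8),
    position  = c("F5", "AF7", "Fp1", "AFz", "Fp2", "AF8", "F6", "Fpz"),
    stringsAsFactors = FALSE
  )
  detectors <- data.frame(
    detector_id = paste0("D", 1:7),
    position    = c("AF5", "AF3", "F1", "F2", "AF4", "AF6", "FCz"),
    stringsAsFactors = FALSE
  )
  # Left lateral (1-6), middle (7-14), right lateral (15-20) columns.
  channels <- data.frame(
    channel_id  = 1:20,
    source_id   = c("S1", "S2", "S1", "S2", "S2", "S3", "S3", "S3", "S4", "S4",
                    "S8", "S8", "S5", "S4", "S6", "S5", "S6", "S7", "S6", "S7"),
    detector_id = c("D1", "D1", "D2", "D2", "D3", "D2", "D3", "D4", "D3", "D4",
                    "D3", "D4", "D4", "D7", "D5", "D5", "D4", "D5", "D6", "D6"),
    stringsAsFactors = FALSE
  )
  channels$position <- paste0("Ch", channels$channel_id)
  channels$distance_cm <- sd_distance_cm
  list(sources = sources, detectors = detectors, channels = channels,
       roi_map = default_roi_map())
}

#' Default ROI map
#'
#' The five prefrontal regions of interest and their channel memberships:
#' MPFC (7-14), right DLPFC (15, 17, 18), right VLPFC (16, 19, 20),
#' left DLPFC (1, 2, 5) and left VLPFC (3, 4, 6).  The sets partition
#' channels 1-20.
#'
#' @return Named list of integer channel-id vectors, in the fixed ROI order
#'   used throughout the package (MPFC, RDLPFC, RVLPFC, LDLPFC, LVLPFC).
#' @export
default_roi_map <- function() {
  list(
    MPFC   = 7:14,
    RDLPFC = c(15L, 17L, 18L),
    RVLPFC = c(16L, 19L, 20L),
    LDLPFC = c(1L, 2L, 5L),
    LVLPFC = c(3L, 4L, 6L)
  )
}

#' ROI order used for feature vectors
#' @return Character vector of the five ROI names in canonical order.
#' @export
roi_order <- function() c("MPFC", "RDLPFC", "RVLPFC", "LDLPFC", "LVLPFC")

#' Build and validate a probe layout
#'
#' Validates a probe configuration (optodes, source-detector pairings, ROI
#' map) and returns a `probe_layout` object.  Every channel must reference an
#' existing source and detector, channel ids must be unique, and every ROI may
#' only contain known channels.
#'
#' @param config probe configuration as returned by [default_probe_config()].
#' @return An object of class `probe_layout`.
#' @export
build_probe_layout <- function(config = default_probe_config()) {
  ch <- config$channels
  stopifnot(is.data.frame(ch))
  dup <- ch$channel_id[duplicated(ch$channel_id)]
  if (length(dup) > 0L)
    stop("duplicate channel id(s): ", paste(unique(dup), collapse = ", "))
  bad_src <- setdiff(ch$source_id, config$sources$source_id)
  if (length(bad_src) > 0L)
    stop("channel references unknown source(s): ",
         paste(bad_src, collapse = ", "))
  bad_det <- setdiff(ch$detector_id, config$detectors$detector_id)
  if (length(bad_det) > 0L)
    stop("channel references unknown detector(s): ",
         paste(bad_det, collapse = ", "))
  if (any(ch$distance_cm <= 0))
    stop("source-detector distances must be positive")
  roi_map <- config$roi_map
  for (roi in names(roi_map)) {
    unknown <- setdiff(roi_map[[roi]], ch$channel_id)
    if (length(unknown) > 0L)
      stop("ROI ", roi, " references unknown channel(s): ",
           paste(unknown, collapse = ", "))
  }
  all_roi <- unlist(roi_map, use.names = FALSE)
  if (anyDuplicated(all_roi))
    stop("ROI channel sets overlap: channel(s) ",
         paste(unique(all_roi[duplicated(all_roi)]), collapse = ", "),
         " appear in more than one ROI")
  layout <- structure(
    list(sources = config$sources, detectors = config$detectors,
         channels = ch, roi_map = roi_map),
    class = "probe_layout")
  layout
}

#' @export
print.probe_layout <- function(x, ...) {
  cat("<probe_layout> ", nrow(x$sources), " sources, ",
      nrow(x$detectors), " detectors, ", nrow(x$channels), " channels, ",
      length(x$roi_map), " ROIs\n", sep = "")
  for (roi in names(x$roi_map))
    cat("  ", roi, ": ", paste(x$roi_map[[roi]], collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of channels in a layout
#' @param layout a `probe_layout`.
#' @return Integer channel count.
#' @export
n_channels <- function(layout) nrow(layout$channels)
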