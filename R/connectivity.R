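#' Sliding-window dynamic connectivity
#'
#' Pearson correlations between all channel pairs in sliding windows of
#' `window` samples advanced by `skip` samples (defaults 300 and 100, i.e.
#' ~38 s windows stepped ~13 s at 7.81 Hz), computed on the continuous HbO
#' record.  Window starts are 0-indexed multiples of `skip`; the last partial
#' window is not used, giving `floor((T - window) / skip) + 1` windows.
#' Zero-variance channels yield correlation 0 for their pairs and raise a
#' degeneracy flag instead of aborting.
#'
#' @param hbo time x channel matrix (or a `nirs_scan`, whose HbO series is
#'   used).
#' @param window window length in samples.
#' @param skip hop between window starts in samples.
#' @return Object of class `connectivity_sequence`: list with `windows`
#'   (list of symmetric C x C correlation matrices, unit diagonal),
#'   `starts` (1-based start samples), `window`, `skip`, `degenerate`
#'   (logical per window), `scan_key` when a scan was given.
#' @export
sliding_window_correlations <- function(hbo, window = 300, skip = 100) {
  key <- NULL
  if (inherits(hbo, "nirs_scan")) {
    key <- scan_key(hbo)
    hbo <- hbo$series$hbo
  }
  hbo <- as.matrix(hbo)
  n <- nrow(hbo)
  if (n < window)
    stop("record has ", n, " samples but the window needs ", window,
         "; use a smaller window")
  starts <- seq.int(1L, n - window + 1L, by = skip)
  windows <- vector("list", length(starts))
  degenerate <- logical(length(starts))
  for (w in seq_along(starts)) {
    slice <- hbo[starts[w]:(starts[w] + window - 1L), , drop = FALSE]
    sds <- apply(slice, 2, stats::sd)
    if (any(sds == 0)) {
      degenerate[w] <- TRUE
      cm <- suppressWarnings(stats::cor(slice))
      cm[!is.finite(cm)] <- 0
      diag(cm) <- 1
    } else {
      cm <- stats::cor(slice)
    }
    windows[[w]] <- cm
  }
  structure(list(windows = windows, starts = starts, window = window,
                 skip = skip, degenerate = degenerate, scan_key = key),
            class = "connectivity_sequence")
}

#' @export
print.connectivity_sequence <- function(x, ...) {
  cat("<connectivity_sequence> ", length(x$windows), " windows of ",
      x$window, " samples (skip ", x$skip, "), ",
      nrow(x$windows[[1]]), " channels\n", sep = "")
  invisible(x)
}

#' Vectorize correlation windows
#'
#' Extracts the strict upper triangle of every window matrix in row-major
#' channel order — pair (1,2), (1,3), ..., (1,C), (2,3), ... — giving
#' `C*(C-1)/2` values per window (190 for 20 channels).
#'
#' @param seq a `connectivity_sequence`.
#' @return Matrix of dimension n_windows x C(C,2), one row per window.
#' @export
vectorize_windows <- function(seq) {
  mats <- seq$windows
  C <- nrow(mats[[1]])
  for (m in mats)
    if (max(abs(m - t(m))) > 1e-8)
      stop("asymmetric correlation matrix in connectivity sequence")
  ut <- upper.tri(matrix(0, C, C))
  out <- t(vapply(mats, function(m) t(m)[t(ut)], numeric(C * (C - 1) / 2)))
  colnames(out) <- pair_names(C)
  out
}

pair_names <- function(C) {
  idx <- which(upper.tri(matrix(0, C, C)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  sprintf("ch%02d_ch%02d", idx[, 1], idx[, 2])
}

#' Rebuild a correlation matrix from its upper-triangle vector
#'
#' Inverse of one row of [vectorize_windows()].
#'
#' @param v vector of `C*(C-1)/2` correlations in row-major pair order.
#' @return Symmetric C x C matrix with unit diagonal.
#' @export
unvectorize_window <- function(v) {
  C <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (C != round(C)) stop("length is not a triangular number")
  C <- as.integer(C)
  low <- matrix(0, C, C)
  low[lower.tri(low)] <- v     # column-major lower = row-major upper of t()
  m <- t(low) + low
  diag(m) <- 1
  m
}
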