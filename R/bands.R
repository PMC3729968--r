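#' Canonical frequency bands
#'
#' The six classical bands used throughout the pipeline: delta (0.5-4 Hz),
#' theta (4-8 Hz), alpha1 (8-10 Hz), alpha2 (10-13 Hz), beta (13-30 Hz) and
#' gamma (30-48 Hz).
#'
#' @return a data.frame with columns `name`, `lo`, `hi` (Hz).
#' @export
canonical_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha1", "alpha2", "beta", "gamma"),
    lo   = c(0.5, 4, 8, 10, 13, 30),
    hi   = c(4, 8, 10, 13, 30, 48),
    stringsAsFactors = FALSE
  )
}

#' Construct or look up a frequency band
#'
#' @param band either the name of a canonical band (see [canonical_bands()]),
#'   or a numeric vector `c(lo, hi)` in Hz.
#' @return a list with elements `name`, `lo`, `hi`.
#' @export
as_band <- function(band) {
  if (is.character(band)) {
    stopifnot(length(band) == 1L)
    tab <- canonical_bands()
    i <- match(band, tab$name)
    if (is.na(i)) {
      stop("unknown band '", band, "'; canonical bands are: ",
           paste(tab$name, collapse = ", "))
    }
    return(list(name = tab$name[i], lo = tab$lo[i], hi = tab$hi[i]))
  }
  if (is.list(band) && !is.null(band$lo) && !is.null(band$hi)) {
    band$name <- band$name %||% sprintf("%g-%gHz", band$lo, band$hi)
    stopifnot(band$lo > 0, band$hi > band$lo)
    return(band[c("name", "lo", "hi")])
  }
  stopifnot(is.numeric(band), length(band) == 2L, band[1] > 0, band[2] > band[1])
  list(name = sprintf("%g-%gHz", band[1], band[2]), lo = band[1], hi = band[2])
}

#' Epoch duration in seconds
#'
#' @param epoch_samples samples per epoch (default 4096).
#' @param fs sampling frequency in Hz (default 625).
#' @return duration in seconds (4096 samples at 625 Hz last 6.5536 s).
#' @export
epoch_duration <- function(epoch_samples = 4096, fs = 625) {
  stopifnot(epoch_samples > 0, fs > 0)
  epoch_samples / fs
}

#' Number of non-overlapping epochs in a recording
#'
#' @param recording_seconds total recording duration in seconds.
#' @param epoch_samples samples per epoch.
#' @param fs sampling frequency in Hz.
#' @return integer count of complete non-overlapping epochs (a 5-minute
#'   recording at 625 Hz holds 45 epochs of 4096 samples).
#' @export
n_epochs_available <- function(recording_seconds, epoch_samples = 4096, fs = 625) {
  stopifnot(recording_seconds > 0)
  as.integer(floor(recording_seconds * fs / epoch_samples))
}
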