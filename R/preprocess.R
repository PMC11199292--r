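#' Preprocessing: filtering, interpolation, epoching, artifact rejection
#'
#' Transforms a raw continuous recording into artifact-screened,
#' average-referenced, fixed-length epochs: zero-phase band-pass plus notch
#' filtering, neighbor-based interpolation of bad channels, segmentation of
#' the tagged condition into non-overlapping epochs, amplitude-threshold
#' rejection of whole epochs, and re-derivation to the average reference.
#'
#' @name preprocess
NULL

#' Construct an epoch set
#'
#' @param epochs List of channels x samples matrices, all the same shape.
#' @param sfreq Sampling frequency, Hz.
#' @param epoch_length Epoch length, seconds.
#' @param reference "original" or "average".
#' @param provenance List of processing counters.
#' @export
epoch_set <- function(epochs, sfreq, epoch_length,
                      reference = c("original", "average"),
                      provenance = list()) {
  reference <- match.arg(reference)
  stopifnot(is.list(epochs), length(epochs) > 0, sfreq > 0)
  dims <- vapply(epochs, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all epochs must have identical dimensions")
  structure(list(epochs = epochs, sfreq = sfreq, epoch_length = epoch_length,
                 reference = reference, provenance = provenance),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$epochs[[1]])
  cat(sprintf("<epoch_set> %d epochs of %d ch x %d samples @ %g Hz (%s reference)\n",
              length(x$epochs), d[1], d[2], x$sfreq, x$reference))
  invisible(x)
}

#' Zero-phase band-pass and notch filter
#'
#' Applies a 4th-order Butterworth band-pass and a 2 Hz-wide 4th-order
#' Butterworth band-stop (notch), both forward-backward (zero phase, no group
#' delay). The band-pass removes the DC component.
#'
#' @param rec An `eeg_recording`.
#' @param low,high Band-pass corner frequencies, Hz (0 < low < high < sfreq/2).
#' @param notch Notch center frequency, Hz, or NULL to skip.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_notch <- function(rec, low = 1.5, high = 20, notch = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$sfreq / 2
  if (!(low > 0 && low < high && high < nyq))
    stop("invalid band edges: need 0 < low < high < sfreq/2")
  bp <- signal::butter(2, c(low, high) / nyq, type = "pass")
  filts <- list(bp)
  if (!is.null(notch)) {
    if (notch <= 1 || notch >= nyq - 1) stop("notch frequency outside (1, sfreq/2 - 1)")
    filts <- c(filts, list(signal::butter(2, c(notch - 1, notch + 1) / nyq,
                                          type = "stop")))
  }
  x <- rec$data
  x <- x - rowMeans(x)   # remove DC before filtering for numerical stability
  for (f in filts) {
    x <- t(apply(x, 1, function(ch) signal::filtfilt(f, ch)))
  }
  rownames(x) <- rec$labels
  rec$data <- x
  rec
}

#' Interpolate bad channels from montage neighbors
#'
#' Each bad channel is replaced by the unweighted mean of its `k` nearest good
#' channels by geodesic (angular) distance on the montage sphere.
#'
#' @param rec An `eeg_recording`.
#' @param bad_labels Character vector of channel names to interpolate.
#' @param montage The `sensor_montage` matching the recording's channels.
#' @param k Number of neighbors (default 4).
#' @return The recording with bad channels replaced; attribute
#'   `interpolated_channels` records which.
#' @export
interpolate_channels <- function(rec, bad_labels, montage, k = 4) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "sensor_montage"))
  if (length(bad_labels) == 0) {
    attr(rec, "interpolated_channels") <- character(0)
    return(rec)
  }
  if (!all(bad_labels %in% rec$labels)) stop("bad_labels not all in recording")
  if (!all(rec$labels %in% montage$labels)) stop("recording channels missing from montage")
  good <- setdiff(rec$labels, bad_labels)
  if (length(good) < 2) stop("fewer than 2 good channels available for interpolation")
  d <- .montage_geodesic(montage)[rec$labels, rec$labels]
  for (b in bad_labels) {
    nb <- good[order(d[b, good])][seq_len(min(k, length(good)))]
    rec$data[b, ] <- colMeans(rec$data[nb, , drop = FALSE])
  }
  attr(rec, "interpolated_channels") <- bad_labels
  rec
}

#' Cut tagged spans into non-overlapping fixed-length epochs
#'
#' Contiguous epochs of exactly `epoch_length` seconds are cut from every
#' annotation span carrying `tag`; remainders shorter than one epoch are
#' discarded.
#'
#' @param rec An `eeg_recording`.
#' @param tag Annotation tag to select (default "eyes_closed").
#' @param epoch_length Epoch length, seconds.
#' @return An `epoch_set` with `original` reference.
#' @export
select_condition_and_epoch <- function(rec, tag = "eyes_closed",
                                       epoch_length = 2) {
  stopifnot(inherits(rec, "eeg_recording"), epoch_length > 0)
  ann <- rec$annotations[rec$annotations$tag == tag, , drop = FALSE]
  if (nrow(ann) == 0) stop(sprintf("no annotation with tag '%s'", tag))
  L <- as.integer(round(epoch_length * rec$sfreq))
  epochs <- list()
  for (i in seq_len(nrow(ann))) {
    start <- as.integer(floor(ann$onset[i] * rec$sfreq)) + 1L
    span <- as.integer(floor(ann$duration[i] * rec$sfreq))
    n_ep <- span %/% L
    for (j in seq_len(n_ep)) {
      i0 <- start + (j - 1L) * L
      epochs[[length(epochs) + 1L]] <- rec$data[, i0:(i0 + L - 1L), drop = FALSE]
    }
  }
  if (length(epochs) == 0)
    stop(sprintf("no span tagged '%s' is long enough for a %g s epoch", tag, epoch_length))
  epoch_set(epochs, rec$sfreq, epoch_length, reference = "original",
            provenance = list(n_epochs_cut = length(epochs)))
}

#' Reject epochs exceeding an amplitude threshold
#'
#' Any epoch containing a sample with |value| > threshold on any channel is
#' removed; the count is recorded in provenance.
#'
#' @param epochs An `epoch_set`.
#' @param threshold Amplitude threshold in microvolts (> 0).
#' @export
reject_artifacts <- function(epochs, threshold = 100) {
  stopifnot(inherits(epochs, "epoch_set"), threshold > 0)
  keep <- vapply(epochs$epochs, function(e) max(abs(e)) <= threshold, logical(1))
  if (!any(keep))
    stop(sprintf("all %d epochs exceed the %g uV artifact threshold",
                 length(keep), threshold))
  epochs$provenance$n_rejected <- sum(!keep)
  epochs$provenance$rejection_threshold_uV <- threshold
  epochs$epochs <- epochs$epochs[keep]
  epochs
}

#' Re-derive epochs to the average reference
#'
#' Subtracts the across-channel mean at every sample, so each sample's channel
#' mean is zero. Idempotent.
#'
#' @param epochs An `epoch_set` with at least 2 channels.
#' @export
average_reference <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  if (nrow(epochs$epochs[[1]]) < 2) stop("average reference requires >= 2 channels")
  epochs$epochs <- lapply(epochs$epochs, function(e) {
    sweep(e, 2, colMeans(e), "-")
  })
  epochs$reference <- "average"
  epochs
}

#' Full preprocessing chain
#'
#' filter -> interpolate bad channels -> cut tagged epochs -> reject
#' amplitude artifacts -> average reference. All steps are deterministic.
#'
#' @param rec An `eeg_recording`.
#' @param montage A `sensor_montage` (required if `bad_channels` given).
#' @param low,high,notch Filter settings; see [bandpass_notch()].
#' @param bad_channels Channels to interpolate (default none).
#' @param tag Condition tag to keep.
#' @param epoch_length Epoch length, seconds.
#' @param threshold Artifact rejection threshold, microvolts.
#' @return An average-referenced `epoch_set` with provenance counters.
#' @export
preprocess_recording <- function(rec, montage = NULL, low = 1.5, high = 20,
                                 notch = 60, bad_channels = character(0),
                                 tag = "eyes_closed", epoch_length = 2,
                                 threshold = 100) {
  rec <- bandpass_notch(rec, low, high, notch)
  if (length(bad_channels) > 0) {
    if (is.null(montage)) stop("montage required to interpolate channels")
    rec <- interpolate_channels(rec, bad_channels, montage)
  }
  eps <- select_condition_and_epoch(rec, tag, epoch_length)
  eps <- reject_artifacts(eps, threshold)
  eps <- average_reference(eps)
  eps$provenance$interpolated_channels <- bad_channels
  eps
}
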