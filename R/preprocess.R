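#' EEG recordings and the preprocessing chain
#'
#' A recording holds one subject's multichannel EEG in microvolts together
#' with channel names, sampling rate, subject id and group label (0 = healthy
#' control, 1 = patient).  The cleaning chain applies, in order: band-pass +
#' notch filtering, pluggable ICA artifact removal, non-overlapping
#' segmentation, amplitude rejection, average re-referencing and z-score
#' standardization.  Amplitude rejection therefore always sees microvolt
#' values, and z-scoring is the last numeric step before band decomposition.
#'
#' @name preprocessing
NULL

#' Construct an EEG recording
#'
#' @param data numeric matrix (n_channels x n_samples), microvolts.
#' @param channel_names character vector, one per row; defaults to existing
#'   rownames.
#' @param sampling_rate_hz sampling rate (Hz), > 0.
#' @param subject_id subject identifier string.
#' @param label group label: 0 (control) or 1 (patient); NA if unknown.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(data, channel_names = rownames(data),
                          sampling_rate_hz, subject_id = "s01", label = NA) {
  stopifnot(is.matrix(data), sampling_rate_hz > 0)
  if (is.null(channel_names))
    stop("channel names are required")
  if (length(channel_names) != nrow(data))
    stop("channel_names length does not match data rows")
  if (anyDuplicated(tolower(channel_names)))
    stop("duplicate channel names")
  if (!is.na(label) && !label %in% c(0, 1))
    stop("label must be 0, 1 or NA")
  rownames(data) <- channel_names
  structure(list(data = data, channel_names = channel_names,
                 sampling_rate_hz = sampling_rate_hz,
                 subject_id = subject_id, label = label),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %s (label %s): %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id, format(x$label), nrow(x$data), ncol(x$data),
              x$sampling_rate_hz, ncol(x$data) / x$sampling_rate_hz))
  invisible(x)
}

#' One fixed-length EEG segment
#'
#' @param data numeric matrix (n_channels x t_seg).
#' @param subject_id,label inherited from the parent recording.
#' @param segment_index 1-based position within the recording.
#' @param sampling_rate_hz sampling rate.
#' @export
new_segment <- function(data, subject_id, label, segment_index,
                        sampling_rate_hz) {
  structure(list(data = data, subject_id = subject_id, label = label,
                 segment_index = segment_index,
                 sampling_rate_hz = sampling_rate_hz),
            class = "eeg_segment")
}

#' Band-pass plus notch filtering of a recording
#'
#' Zero-phase Hamming-windowed FIR band-pass (default 0.5-70 Hz) followed by
#' a narrow band-stop notch of +/- `notch_halfwidth_hz` around `notch_hz`
#' (default 50 Hz mains).  The filter length defaults to a transition width
#' of 25% of the lower band edge, capped so the kernel fits the recording.
#'
#' @param rec an `eeg_recording`.
#' @param low_hz,high_hz pass-band edges (Hz); `high_hz` must be below
#'   Nyquist.
#' @param notch_hz notch center; `NULL` disables.  A notch outside the pass
#'   band is skipped with a warning.
#' @param notch_halfwidth_hz half-width of the band-stop (Hz).
#' @param numtaps optional odd FIR length override.
#' @return The filtered recording (same shape and metadata).
#' @export
bandpass_notch <- function(rec, low_hz = 0.5, high_hz = 70, notch_hz = 50,
                           notch_halfwidth_hz = 2, numtaps = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate_hz
  if (low_hz <= 0 || low_hz >= high_hz)
    stop("need 0 < low_hz < high_hz")
  if (high_hz >= fs / 2)
    stop("high_hz (", high_hz, " Hz) must be below Nyquist (", fs / 2, " Hz)")
  n <- ncol(rec$data)
  if (is.null(numtaps)) {
    # Hamming transition width ~ 3.3 / N (normalized); target 25% of low edge
    numtaps <- ceiling(3.3 * fs / (0.25 * low_hz))
    cap <- max(5L, floor((n - 1) / 2))
    if (numtaps > cap) numtaps <- cap
  }
  if (numtaps %% 2L == 0L) numtaps <- numtaps - 1L
  h <- fir_design(low_hz, high_hz, fs, numtaps, window = "hamming")
  out <- fir_apply(rec$data, h)
  if (!is.null(notch_hz)) {
    if (notch_hz <= low_hz || notch_hz >= high_hz) {
      warning("notch at ", notch_hz, " Hz is outside the pass band; skipped")
    } else {
      hn <- fir_design(notch_hz - notch_halfwidth_hz,
                       notch_hz + notch_halfwidth_hz, fs, numtaps,
                       window = "hamming", type = "stop")
      out <- fir_apply(out, hn)
    }
  }
  rec$data <- out
  rec
}

#' Split a recording into non-overlapping fixed windows
#'
#' Windows are contiguous and in original time order; a trailing remainder
#' shorter than one window is discarded.  `window_seconds * sampling_rate`
#' must be an integer.
#'
#' @param rec an `eeg_recording`.
#' @param window_seconds window length (default 5 s, i.e. 1280 samples at
#'   256 Hz).
#' @return List of `eeg_segment` objects (empty, with a warning, if the
#'   recording is shorter than one window).
#' @export
segment_recording <- function(rec, window_seconds = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  t_seg <- window_seconds * rec$sampling_rate_hz
  if (abs(t_seg - round(t_seg)) > 1e-9)
    stop("window_seconds x sampling rate must be an integer sample count")
  t_seg <- as.integer(round(t_seg))
  n <- ncol(rec$data)
  n_seg <- n %/% t_seg
  if (n_seg == 0L) {
    warning("recording ", rec$subject_id, " shorter than one window; ",
            "no segments produced")
    return(list())
  }
  lapply(seq_len(n_seg), function(i) {
    cols <- ((i - 1L) * t_seg + 1L):(i * t_seg)
    new_segment(rec$data[, cols, drop = FALSE], rec$subject_id, rec$label,
                i, rec$sampling_rate_hz)
  })
}

#' Drop segments with excessive amplitudes
#'
#' Retains exactly the segments whose every sample lies within
#' `[-threshold_uv, +threshold_uv]`; order is preserved and retained
#' segments are untouched.  Must be applied to microvolt values (before
#' z-scoring).
#'
#' @param segments list of `eeg_segment`.
#' @param threshold_uv rejection threshold in microvolts (default 100).
#' @return Filtered list.
#' @export
reject_amplitude <- function(segments, threshold_uv = 100) {
  keep <- vapply(segments, function(s) {
    max(abs(s$data)) <= threshold_uv
  }, logical(1))
  segments[keep]
}

#' Average re-referencing
#'
#' Subtracts, at every time point, the mean across channels, so the
#' channel-mean of the output is exactly zero.  Idempotent.
#'
#' @param x an `eeg_recording`, `eeg_segment`, or plain channel x time
#'   matrix.
#' @return Same type as the input.
#' @export
rereference_average <- function(x) {
  if (inherits(x, c("eeg_recording", "eeg_segment"))) {
    x$data <- rereference_average(x$data)
    return(x)
  }
  stopifnot(is.matrix(x), nrow(x) >= 2L)
  sweep(x, 2L, colMeans(x))
}

#' Per-channel z-score standardization
#'
#' Scales every channel to mean 0, standard deviation 1 (population
#' denominator).  Applied per segment so each model input is
#' self-normalized.
#'
#' @param x an `eeg_recording`, `eeg_segment`, or channel x time matrix.
#' @return Same type as the input.
#' @export
zscore_standardize <- function(x) {
  if (inherits(x, c("eeg_recording", "eeg_segment"))) {
    x$data <- zscore_standardize(x$data)
    return(x)
  }
  stopifnot(is.matrix(x))
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  bad <- sd_pop <= 1e-12
  if (any(bad)) {
    nm <- rownames(x)
    if (is.null(nm)) nm <- as.character(which(bad))
    stop("zero-variance channel(s): ", paste(nm[bad], collapse = ", "))
  }
  (x - mu) / sd_pop
}

#' Preprocessing configuration
#'
#' @param low_hz,high_hz,notch_hz cleaning filter settings.
#' @param window_seconds segmentation window.
#' @param threshold_uv amplitude-rejection threshold.
#' @param ica_selector component-rejection policy passed to
#'   [remove_artifacts()]; the default identity policy leaves the data
#'   untouched.
#' @export
preprocess_config <- function(low_hz = 0.5, high_hz = 70, notch_hz = 50,
                              window_seconds = 5, threshold_uv = 100,
                              ica_selector = selector_identity()) {
  list(low_hz = low_hz, high_hz = high_hz, notch_hz = notch_hz,
       window_seconds = window_seconds, threshold_uv = threshold_uv,
       ica_selector = ica_selector)
}

#' Run the full cleaning chain on one recording
#'
#' filter -> ICA -> segment -> amplitude rejection -> average re-reference ->
#' z-score, in that order.
#'
#' @param rec an `eeg_recording`.
#' @param config from [preprocess_config()].
#' @return List with `segments` (cleaned, standardized), `n_total` and
#'   `n_kept` segment counts.
#' @export
preprocess_recording <- function(rec, config = preprocess_config()) {
  rec <- bandpass_notch(rec, config$low_hz, config$high_hz, config$notch_hz)
  rec <- remove_artifacts(rec, config$ica_selector)
  segs <- segment_recording(rec, config$window_seconds)
  n_total <- length(segs)
  segs <- reject_amplitude(segs, config$threshold_uv)
  segs <- lapply(segs, rereference_average)
  segs <- lapply(segs, zscore_standardize)
  list(segments = segs, n_total = n_total, n_kept = length(segs))
}
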