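#' EDF (European Data Format) input and output
#'
#' Minimal 16-bit EDF support sufficient for clinical resting-state EEG:
#' ASCII headers, one-second data records, little-endian int16 samples with
#' per-signal physical/digital scaling.  The reader normalizes vendor label
#' decorations (e.g. "EEG Fp1-LE" -> "Fp1"), drops the earlobe references
#' A1/A2 and any non-montage channels, and checks that every montage
#' channel is present.
#'
#' @name edf
NULL

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width)                # left-justified, space-padded
}

#' Write recordings as EDF files
#'
#' One file per recording (`<subject_id>.edf`), 1-second records, all
#' channels sharing a symmetric physical range.  Values are quantized to
#' 16 bits; the round-trip error is bounded by `physical_max / 32767`.
#'
#' @param recordings an `eeg_recording` or list of them.
#' @param out_dir destination directory (created if needed).
#' @param physical_max symmetric physical range (uV); default: the smallest
#'   power-of-ten-ish bound covering the data.  Data exceeding a
#'   user-supplied range is an error.
#' @return Invisibly, the written file paths.
#' @export
write_edf <- function(recordings, out_dir, physical_max = NULL) {
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(recordings, function(rec) {
    fs <- rec$sampling_rate_hz
    if (abs(fs - round(fs)) > 1e-9)
      stop("EDF writer supports integer sampling rates only")
    fs <- as.integer(round(fs))
    ns <- nrow(rec$data)
    n_rec <- ncol(rec$data) %/% fs
    if (n_rec < 1L) stop("recording shorter than one EDF record (1 s)")
    dmax <- max(abs(rec$data))
    pmax_file <- physical_max
    if (is.null(pmax_file)) {
      pmax_file <- max(100, ceiling(dmax * 1.05))
    } else if (dmax > pmax_file) {
      stop("data amplitude ", round(dmax, 1),
           " uV exceeds physical range +/-", pmax_file,
           " uV; widen physical_max")
    }
    path <- file.path(out_dir, paste0(rec$subject_id, ".edf"))
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    hdr <- paste0(
      pad_ascii("0", 8),
      pad_ascii(rec$subject_id, 80),
      pad_ascii(paste("Startdate 01-JAN-2000", rec$subject_id), 80),
      pad_ascii("01.01.00", 8), pad_ascii("00.00.00", 8),
      pad_ascii(256 * (ns + 1), 8), pad_ascii("", 44),
      pad_ascii(n_rec, 8), pad_ascii(1, 8), pad_ascii(ns, 4))
    sig <- function(field, width)
      paste(vapply(field, pad_ascii, "", width = width), collapse = "")
    labels <- paste("EEG", rec$channel_names)
    hdr <- paste0(hdr,
                  sig(labels, 16),
                  sig(rep("AgAgCl electrode", ns), 80),
                  sig(rep("uV", ns), 8),
                  sig(rep(-pmax_file, ns), 8),
                  sig(rep(pmax_file, ns), 8),
                  sig(rep(-32768L, ns), 8),
                  sig(rep(32767L, ns), 8),
                  sig(rep("", ns), 80),
                  sig(rep(fs, ns), 8),
                  sig(rep("", ns), 32))
    writeChar(hdr, con, eos = NULL, useBytes = TRUE)
    scale <- 65535 / (2 * pmax_file)
    for (r in seq_len(n_rec)) {
      cols <- ((r - 1L) * fs + 1L):(r * fs)
      block <- round((rec$data[, cols, drop = FALSE] + pmax_file) * scale) -
        32768
      block[block > 32767] <- 32767L
      block[block < -32768] <- -32768L
      writeBin(as.integer(t(block)), con, size = 2L, endian = "little")
    }
    path
  }, character(1))
  invisible(paths)
}

normalize_edf_label <- function(label) {
  x <- trimws(label)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](LE|REF|AVG|AV|A1|A2|M1|M2)$", "", x, ignore.case = TRUE)
  trimws(x)
}

#' Read one EDF file into a recording
#'
#' @param path EDF file.
#' @param montage an `eeg_montage`; all montage channels must resolve
#'   (after label normalization) or an error lists the missing ones.
#'   Reference (A1/A2) and non-montage channels are dropped.
#' @param subject_id,label metadata; default subject id is the file stem,
#'   default label is looked up with [mumtaz_label_from_filename()] (NA if
#'   the pattern does not match).
#' @param expected_rate_hz sampling rate the pipeline requires (error on
#'   mismatch; resampling is out of scope).  `NULL` accepts any rate.
#' @return An `eeg_recording` in microvolts.
#' @export
read_edf <- function(path, montage = default_montage(), subject_id = NULL,
                     label = NULL, expected_rate_hz = NULL) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  rdv <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- rdv(16); rdv(80); rdv(8)
  pmin <- as.numeric(rdv(8)); pmax_v <- as.numeric(rdv(8))
  dmin <- as.numeric(rdv(8)); dmax_v <- as.numeric(rdv(8))
  rdv(80)
  spr <- as.integer(rdv(8))                 # samples per record
  rdv(32)
  raw <- readBin(con, integer(), n = n_rec * sum(spr), size = 2L,
                 endian = "little")
  data_by_sig <- lapply(seq_len(ns), function(i) numeric(n_rec * spr[i]))
  offs <- c(0L, cumsum(spr))
  per_rec <- sum(spr)
  for (r in seq_len(n_rec)) {
    base <- (r - 1L) * per_rec
    for (i in seq_len(ns)) {
      seg <- raw[(base + offs[i] + 1L):(base + offs[i + 1L])]
      data_by_sig[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- seg
    }
  }
  clean <- normalize_edf_label(labels)
  want <- tolower(montage$entries$channel)
  sel <- match(want, tolower(clean))
  if (anyNA(sel))
    stop("EDF is missing montage channel(s): ",
         paste(montage$entries$channel[is.na(sel)], collapse = ", "))
  fs <- spr[sel[1]] / rec_dur
  if (!is.null(expected_rate_hz) && abs(fs - expected_rate_hz) > 1e-6)
    stop("sampling rate ", fs, " Hz differs from required ",
         expected_rate_hz, " Hz; resampling is not supported")
  data <- matrix(0, length(sel), n_rec * spr[sel[1]],
                 dimnames = list(montage$entries$channel, NULL))
  for (k in seq_along(sel)) {
    i <- sel[k]
    gain <- (pmax_v[i] - pmin[i]) / (dmax_v[i] - dmin[i])
    data[k, ] <- (data_by_sig[[i]] - dmin[i]) * gain + pmin[i]
  }
  if (is.null(subject_id))
    subject_id <- sub("\\.edf$", "", basename(path), ignore.case = TRUE)
  if (is.null(label)) label <- mumtaz_label_from_filename(basename(path))
  new_recording(data, montage$entries$channel, fs, subject_id, label)
}

#' Infer the group label from a Mumtaz-style file name
#'
#' `"MDD S<k> ..."` gives 1, `"H S<k> ..."` gives 0, anything else NA.
#' Provided as a convenience; a sidecar manifest (subject_id, label, path)
#' is the recommended label source.
#'
#' @param filename file name (not path).
#' @return 0, 1 or NA.
#' @export
mumtaz_label_from_filename <- function(filename) {
  if (grepl("^MDD[ _]?S", filename, ignore.case = TRUE)) return(1)
  if (grepl("^H[ _]?S", filename, ignore.case = TRUE)) return(0)
  NA_real_
}
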