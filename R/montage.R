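#' Electrode montages: mapping 10-20 channels onto a 2D grid
#'
#' The 19 active electrodes of the international 10-20 system are placed on a
#' fixed H x W grid (5 x 5 by default) so that a multichannel sample becomes a
#' small image per time point, with the 6 cells that carry no electrode filled
#' with zeros.  Row 0 is frontal, column 0 is the left hemisphere; indices in
#' the serialized table are 0-based.
#'
#' @name montage
NULL

MONTAGE_CHANNELS <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                      "T3", "C3", "Cz", "C4", "T4",
                      "T5", "P3", "Pz", "P4", "T6", "O1", "O2")

#' Construct an electrode montage
#'
#' @param entries data.frame with columns `channel` (character), `row`, `col`
#'   (0-based integer grid indices).
#' @param height,width grid extent.
#' @return An object of class `eeg_montage`.
#' @export
new_montage <- function(entries, height, width) {
  stopifnot(is.data.frame(entries),
            all(c("channel", "row", "col") %in% names(entries)))
  entries$channel <- as.character(entries$channel)
  entries$row <- as.integer(entries$row)
  entries$col <- as.integer(entries$col)
  if (anyDuplicated(entries$channel))
    stop("duplicate channel names in montage")
  if (anyDuplicated(entries[, c("row", "col")]))
    stop("two electrodes mapped to the same grid cell")
  if (any(entries$row < 0L) || any(entries$row >= height) ||
      any(entries$col < 0L) || any(entries$col >= width))
    stop("montage coordinates outside the grid")
  structure(list(entries = entries,
                 height = as.integer(height),
                 width = as.integer(width)),
            class = "eeg_montage")
}

#' Default 5 x 5 montage for the 19 active 10-20 electrodes
#'
#' Layout (row 0 = frontal, col 0 = left):
#' \preformatted{
#'   .   Fp1  .   Fp2  .
#'   F7  F3   Fz  F4   F8
#'   T3  C3   Cz  C4   T4
#'   T5  P3   Pz  P4   T6
#'   .   O1   .   O2   .
#' }
#' Reference electrodes A1/A2 are not part of the montage.  The table is
#' shipped as a plain-text package resource
#' (`system.file("extdata", "montage_1020_5x5.tsv", package = "eegcaps")`)
#' and can be replaced via [read_montage()].
#'
#' @return An `eeg_montage` with 19 entries on a 5 x 5 grid.
#' @export
default_montage <- function() {
  path <- system.file("extdata", "montage_1020_5x5.tsv", package = "eegcaps")
  read_montage(path)
}

#' Read a montage from a plain-text table
#'
#' One line per electrode: `channel<TAB>row<TAB>col`, 0-based indices,
#' with a header line.  Grid extent is taken as max(index) + 1 unless given.
#'
#' @param path file path.
#' @param height,width optional grid extent overrides.
#' @export
read_montage <- function(path, height = NULL, width = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (is.null(height)) height <- max(tab$row) + 1L
  if (is.null(width)) width <- max(tab$col) + 1L
  new_montage(tab, height, width)
}

#' Write a montage to its plain-text serialization
#' @param montage an `eeg_montage`.
#' @param path destination file.
#' @export
write_montage <- function(montage, path) {
  utils::write.table(montage$entries, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes on a %d x %d grid\n",
              nrow(x$entries), x$height, x$width))
  grid <- matrix(".", x$height, x$width)
  grid[cbind(x$entries$row + 1L, x$entries$col + 1L)] <- x$entries$channel
  apply(grid, 1L, function(r) cat(" ", formatC(r, width = 4), "\n"))
  invisible(x)
}

#' Project multichannel samples onto the montage grid
#'
#' Each time point of a (channels x time) matrix becomes one H x W frame;
#' grid cells without an electrode are exactly zero.  Channels are matched by
#' name (case-insensitively), never by position, so permuting the input rows
#' does not change the output.
#'
#' @param data numeric matrix (n_channels x n_samples) with rownames, or an
#'   `eeg_recording` (see [new_recording()]).
#' @param montage an `eeg_montage`; defaults to [default_montage()].
#' @return Array of dim (T, H, W) (a `grid_frames` object carrying the
#'   montage and, for recordings, subject metadata).
#' @export
project_to_grid <- function(data, montage = default_montage()) {
  meta <- NULL
  if (inherits(data, "eeg_recording")) {
    meta <- data[c("subject_id", "label", "sampling_rate_hz")]
    data <- data$data
  }
  stopifnot(is.matrix(data))
  ch <- rownames(data)
  if (is.null(ch)) stop("input matrix must carry channel names as rownames")
  if (anyDuplicated(tolower(ch)))
    stop("duplicate channel names: ",
         paste(ch[duplicated(tolower(ch))], collapse = ", "))
  idx <- match(tolower(montage$entries$channel), tolower(ch))
  if (anyNA(idx))
    stop("recording is missing montage channel(s): ",
         paste(montage$entries$channel[is.na(idx)], collapse = ", "))
  n_t <- ncol(data)
  frames <- array(0, dim = c(n_t, montage$height, montage$width))
  for (k in seq_along(idx)) {
    frames[, montage$entries$row[k] + 1L, montage$entries$col[k] + 1L] <-
      data[idx[k], ]
  }
  structure(frames, class = "grid_frames", montage = montage, meta = meta)
}

#' Recover the channel series from projected frames
#'
#' Exact inverse of [project_to_grid()] on the 19 occupied cells.
#'
#' @param frames a `grid_frames` array (T, H, W).
#' @param montage montage used for the projection; defaults to the one stored
#'   on `frames`.
#' @return Numeric matrix (n_channels x n_samples) with channel rownames.
#' @export
unproject_grid <- function(frames, montage = attr(frames, "montage")) {
  if (is.null(montage)) montage <- default_montage()
  n_t <- dim(frames)[1]
  out <- matrix(0, nrow(montage$entries), n_t,
                dimnames = list(montage$entries$channel, NULL))
  for (k in seq_len(nrow(montage$entries))) {
    out[k, ] <- frames[, montage$entries$row[k] + 1L,
                       montage$entries$col[k] + 1L]
  }
  out
}
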