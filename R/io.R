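# Plain-text and TIFF readers/writers for the pipeline's interchange
# formats: two-column CSV signals, hypnogram/event/density TSVs, gene x
# sample matrices, and multi-page TIFF section stacks.

#' Write a recording to CSV
#'
#' The signal file holds `time_s, eeg_uV, emg_uV`; the auxiliary file holds
#' the 1 Hz `time_s, activity, temperature_c` channels.
#'
#' @param rec a `fad_recording`.
#' @param signal_path,aux_path output CSV paths.
#' @return Invisibly, the paths.
#' @export
write_recording_csv <- function(rec, signal_path, aux_path) {
  t <- (seq_along(rec$eeg) - 1) / rec$sample_rate_hz
  write.csv(data.frame(time_s = t, eeg_uV = rec$eeg, emg_uV = rec$emg),
            signal_path, row.names = FALSE)
  write.csv(data.frame(time_s = seq_along(rec$activity) - 1,
                       activity = rec$activity,
                       temperature_c = rec$temperature),
            aux_path, row.names = FALSE)
  invisible(c(signal = signal_path, aux = aux_path))
}

#' Read a recording from CSV
#'
#' @param signal_path,aux_path paths written by
#'   \code{\link{write_recording_csv}}.
#' @param ... further arguments to \code{\link{recording}} (clock times,
#'   light schedule).
#' @return A `fad_recording`; the sample rate is inferred from the time
#'   column.
#' @export
read_recording_csv <- function(signal_path, aux_path = NULL, ...) {
  sig <- read.csv(signal_path)
  fs <- round(1 / median(diff(sig$time_s)))
  activity <- temperature <- NULL
  if (!is.null(aux_path)) {
    aux <- read.csv(aux_path)
    activity <- aux$activity
    temperature <- aux$temperature_c
  }
  recording(sig$eeg_uV, sig$emg_uV, activity = activity,
            temperature = temperature, sample_rate_hz = fs, ...)
}

#' Write/read simple TSV tables
#'
#' Thin wrappers fixing the conventions used throughout (tab separation,
#' no quoting, header row, no row names).
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `read_tsv_table` returns a data.frame.
#' @export
write_tsv_table <- function(x, path) {
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write/read a gene x sample matrix as TSV
#'
#' Header row of sample ids; first column `gene`.
#'
#' @param mat numeric matrix with row and column names.
#' @param path file path.
#' @return `read_matrix_tsv` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(mat, path) {
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write/read a section stack as multi-page 16-bit TIFF
#'
#' Intensities are rescaled into the 16-bit range by `scale` (default:
#' 2^16 - 1, i.e. values are assumed to lie in [0, 65535]).
#'
#' @param imgs list of numeric matrices (one per section) or one matrix.
#' @param path file path.
#' @param scale full-scale intensity mapped to the top of the 16-bit range.
#' @return `read_tiff_stack` returns a list of matrices on the original
#'   scale.
#' @export
write_tiff_stack <- function(imgs, path, scale = 65535) {
  if (is.matrix(imgs)) imgs <- list(imgs)
  imgs <- lapply(imgs, function(m) pmin(pmax(m / scale, 0), 1))
  tiff::writeTIFF(imgs, path, bits.per.sample = 16)
  invisible(path)
}

#' @rdname write_tiff_stack
#' @export
read_tiff_stack <- function(path, scale = 65535) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  lapply(imgs, function(m) m * scale)
}

#' Write an integer label image as TIFF
#'
#' Labels are stored losslessly in the 16-bit range (max label 65535).
#'
#' @param labels integer matrix.
#' @param path file path.
#' @return `read_labels_tiff` returns an integer matrix.
#' @export
write_labels_tiff <- function(labels, path) {
  if (max(labels) > 65535) stop_invalid("labels exceed the 16-bit range")
  write_tiff_stack(list(labels), path, scale = 65535)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  m <- read_tiff_stack(path, scale = 65535)[[1]]
  matrix(as.integer(round(m)), nrow(m), ncol(m))
}
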