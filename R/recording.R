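#' EEG recording container
#'
#' A minimal container for one multichannel EEG session: a channel-by-sample
#' matrix of microvolt values, the sampling rate, the ordered electrode
#' montage, the eye state of the recording, and the current reference scheme.
#'
#' @param data numeric matrix, channels in rows, samples in columns.
#' @param rate_hz sampling rate in Hz (positive).
#' @param montage character vector of electrode names, one per row of `data`.
#'   Defaults to the 19-electrode 10-20 set (see [montage_1020()]).
#' @param eye_state `"closed"` or `"open"`.
#' @param reference `"linked-ears"` (acquisition reference) or
#'   `"common-average"`.
#' @return An object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(19 * 500), nrow = 19), rate_hz = 250)
#' rec
#' @export
eeg_recording <- function(data, rate_hz = 250,
                          montage = montage_1020()$names,
                          eye_state = c("closed", "open"),
                          reference = c("linked-ears", "common-average")) {
  if (!is.matrix(data) || !is.numeric(data) || nrow(data) < 1L || ncol(data) < 1L)
    stop_input("'data' must be a non-empty numeric channel-by-sample matrix")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop_invalid("'rate_hz' must be a positive scalar")
  eye_state <- match.arg(eye_state)
  reference <- match.arg(reference)
  if (length(montage) != nrow(data))
    stop_input(sprintf("montage length (%d) does not match channel count (%d)",
                       length(montage), nrow(data)))
  rownames(data) <- montage
  structure(list(data = data, rate_hz = rate_hz, montage = as.character(montage),
                 eye_state = eye_state, reference = reference),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s eyes, %s reference)\n",
              nrow(x$data), ncol(x$data), x$rate_hz, x$eye_state, x$reference))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$data)
n_samples <- function(rec) ncol(rec$data)

#' Standard 19-channel 10-20 montage
#'
#' Electrode names in acquisition order and a symmetric neighbourhood graph on
#' the 10-20 scalp layout, used for bad-channel interpolation. Neighbour sets
#' are the immediately adjacent electrodes in the standard planar layout;
#' every electrode has at least two neighbours.
#'
#' @return A list with elements `names` (character vector of 19 labels,
#'   Fp1 ... O2) and `adjacency` (named list of neighbour name vectors).
#' @examples
#' m <- montage_1020()
#' m$adjacency$Cz
#' @export
montage_1020 <- function() {
  names <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
             "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  adjacency <- list(
    Fp1 = c("Fp2", "F7", "F3", "Fz"),
    Fp2 = c("Fp1", "Fz", "F4", "F8"),
    F7  = c("Fp1", "F3", "T3"),
    F3  = c("Fp1", "F7", "Fz", "C3"),
    Fz  = c("Fp1", "Fp2", "F3", "F4", "Cz"),
    F4  = c("Fp2", "Fz", "F8", "C4"),
    F8  = c("Fp2", "F4", "T4"),
    T3  = c("F7", "C3", "T5"),
    C3  = c("F3", "T3", "Cz", "P3"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "Cz", "T4", "P4"),
    T4  = c("F8", "C4", "T6"),
    T5  = c("T3", "P3", "O1"),
    P3  = c("C3", "T5", "Pz", "O1"),
    Pz  = c("Cz", "P3", "P4", "O1", "O2"),
    P4  = c("C4", "Pz", "T6", "O2"),
    T6  = c("T4", "P4", "O2"),
    O1  = c("T5", "P3", "Pz", "O2"),
    O2  = c("O1", "Pz", "P4", "T6")
  )
  list(names = names, adjacency = adjacency)
}

#' Read/write a recording as a plain matrix CSV
#'
#' The on-disk dialect is a headered CSV with one column per electrode and one
#' row per sample (microvolts), the transpose of the in-memory layout.
#'
#' @param rec an [eeg_recording()].
#' @param path file path.
#' @param rate_hz,eye_state,reference metadata to attach on read (the CSV
#'   itself carries only electrode names).
#' @return `write_recording_csv` returns `path` invisibly;
#'   `read_recording_csv` returns an [eeg_recording()].
#' @export
write_recording_csv <- function(rec, path) {
  m <- t(rec$data)
  colnames(m) <- rec$montage
  utils::write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_csv
#' @export
read_recording_csv <- function(path, rate_hz = 250, eye_state = "closed",
                               reference = "linked-ears") {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  eeg_recording(t(m), rate_hz = rate_hz, montage = colnames(m),
                eye_state = eye_state, reference = reference)
}
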