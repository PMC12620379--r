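# Deterministic EEG cleaning: baseline removal, FIR band-pass, 50 Hz notch,
# common average reference, bad-channel interpolation, amplitude-based
# segment rejection. ICA-based component removal is deliberately not part of
# this chain (it is delegated to external tools upstream); everything here is
# reproducible arithmetic.

#' Remove per-channel baseline
#'
#' Subtracts the sample mean from every channel, the continuous-data baseline
#' convention. Idempotent.
#'
#' @param rec an [eeg_recording()].
#' @return the recording with zero-mean channels.
#' @export
remove_baseline <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_samples(rec) < 1L) stop_input("empty recording")
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

# Hamming windowed-sinc band-pass design. Cutoffs are placed mid-transition
# (0.75*low, high+5) so the nominal band edges [low, high] sit at ~unity gain
# while 0.5*low and high+10 fall deep in the stopband; the order follows the
# Hamming transition-width rule for the narrow low edge.
design_bandpass <- function(low_hz, high_hz, rate_hz) {
  trans <- low_hz / 2                       # 0.5*low .. low must bracket the edge
  ord <- ceiling(3.3 * rate_hz / trans)
  if (ord %% 2 == 1) ord <- ord + 1         # even order -> integer group delay
  edges <- c(0.75 * low_hz, high_hz + 5) / (rate_hz / 2)
  if (edges[2] >= 1) edges[2] <- (high_hz + (rate_hz / 2 - high_hz) / 2) / (rate_hz / 2)
  list(b = signal::fir1(ord, edges, type = "pass"), order = ord)
}

# Odd-symmetric (whole-point) reflection about both endpoints: the padded
# signal continues smoothly, so filter edge transients see plausible data
# instead of an artificial step to zero.
reflect_pad <- function(x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  c(2 * x[1] - x[(pad + 1L):2L], x, 2 * x[n] - x[(n - 1L):(n - pad)])
}

# Exact linear-phase FIR application: FFT convolution on the
# reflection-padded signal, group delay removed.
apply_fir <- function(x, b) {
  ord <- length(b) - 1L
  pad <- min(length(x) - 1L, ord)
  xp <- reflect_pad(x, pad)
  y <- signal::fftfilt(b, c(xp, numeric(ord)))
  y[(pad + ord / 2 + 1):(pad + ord / 2 + length(x))]
}

#' FIR band-pass filter (1-70 Hz by default)
#'
#' Applies a linear-phase Hamming windowed-sinc band-pass with delay
#' compensation (zero net phase). The design guarantees passband ripple below
#' 1 dB on `[low_hz, high_hz]` and at least 30 dB attenuation at `0.5*low_hz`
#' and at `high_hz + 10` Hz.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges in Hz, `0 < low_hz < high_hz < rate/2`.
#' @return the filtered recording.
#' @export
fir_bandpass <- function(rec, low_hz = 1, high_hz = 70) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz))
    stop_invalid("need 0 < low_hz < high_hz")
  if (high_hz >= rec$rate_hz / 2)
    stop_invalid("'high_hz' must be below the Nyquist frequency")
  des <- design_bandpass(low_hz, high_hz, rec$rate_hz)
  rec$data <- t(apply(rec$data, 1, apply_fir, b = des$b))
  rec
}

# Second-order IIR notch: unit-circle zero at f0, pole radius r sets width.
design_notch <- function(freq_hz, rate_hz, r = 0.975) {
  w <- 2 * pi * freq_hz / rate_hz
  b <- c(1, -2 * cos(w), 1)
  a <- c(1, -2 * r * cos(w), r^2)
  b <- b * sum(a) / sum(b)   # unity DC gain
  list(b = b, a = a)
}

#' Notch filter for mains interference
#'
#' Two complementary steps. First the coherent line component is removed
#' exactly by least-squares regression of each channel on the in-phase and
#' quadrature sinusoids at `freq_hz` (the CleanLine-style projection, free of
#' filter edge transients — essential on short records where an IIR startup
#' transient would otherwise smear line energy across the record). Then a
#' zero-phase (forward-backward) second-order IIR notch suppresses any
#' residual narrowband energy: its zero sits on the unit circle, so
#' attenuation at `freq_hz` far exceeds 30 dB, while the narrow pole radius
#' keeps attenuation at `freq_hz +/- 5` Hz under 3 dB.
#'
#' @param rec an [eeg_recording()].
#' @param freq_hz notch frequency in Hz (default 50, the mains frequency of
#'   the recordings this pipeline targets).
#' @return the filtered recording.
#' @export
notch <- function(rec, freq_hz = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (freq_hz <= 0 || freq_hz >= rec$rate_hz / 2)
    stop_invalid("'freq_hz' must lie in (0, rate/2)")
  tt <- (seq_len(n_samples(rec)) - 1) / rec$rate_hz
  basis <- cbind(sin(2 * pi * freq_hz * tt), cos(2 * pi * freq_hz * tt))
  gram <- solve(crossprod(basis))
  des <- design_notch(freq_hz, rec$rate_hz)
  flt <- signal::Arma(b = des$b, a = des$a)
  pad <- min(n_samples(rec) - 1L, 250L)  # long past the biquad's ring-down
  rec$data <- t(apply(rec$data, 1, function(x) {
    x <- x - as.numeric(basis %*% (gram %*% crossprod(basis, x)))
    y <- signal::filtfilt(flt, reflect_pad(x, pad))
    y[(pad + 1):(pad + length(x))]
  }))
  rec
}

#' Common average reference
#'
#' Subtracts the instantaneous across-channel mean from every channel, so the
#' across-channel mean of the output is exactly zero at each sample.
#' Idempotent.
#'
#' @param rec an [eeg_recording()] with at least two channels.
#' @return the re-referenced recording (`reference = "common-average"`).
#' @export
common_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (n_channels(rec) < 2L)
    stop_input("common average reference needs at least 2 channels")
  rec$data <- sweep(rec$data, 2, colMeans(rec$data))
  rec$reference <- "common-average"
  rec
}

#' Detect and interpolate bad channels
#'
#' A channel is bad if its peak-to-peak range is below `flat_tol` (flat or
#' disconnected) or any sample exceeds `amp_tol` in absolute value. Bad
#' channels are replaced sample-wise by the unweighted mean of their non-bad
#' neighbours on the montage graph.
#'
#' @param rec an [eeg_recording()].
#' @param montage a montage list as from [montage_1020()] (names + adjacency).
#' @param flat_tol peak-to-peak floor in uV (default 0.1).
#' @param amp_tol absolute amplitude ceiling in uV (default 500).
#' @return a list: `recording` (repaired) and `repaired` (character vector of
#'   repaired channel names).
#' @export
detect_and_interpolate_bad <- function(rec, montage = montage_1020(),
                                       flat_tol = 0.1, amp_tol = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!all(rec$montage %in% names(montage$adjacency)))
    stop_input("montage adjacency does not cover all recording channels")
  ptp <- apply(rec$data, 1, function(x) diff(range(x)))
  amax <- apply(rec$data, 1, function(x) max(abs(x)))
  bad <- ptp < flat_tol | amax > amp_tol
  if (sum(bad) > n_channels(rec) / 2)
    stop_unrecoverable(sprintf("%d of %d channels bad", sum(bad), n_channels(rec)))
  if (any(bad)) {
    for (ch in which(bad)) {
      nb <- montage$adjacency[[rec$montage[ch]]]
      nb_idx <- match(nb, rec$montage)
      nb_idx <- nb_idx[!is.na(nb_idx)]
      nb_idx <- nb_idx[!bad[nb_idx]]
      if (length(nb_idx) == 0L)
        stop_unrecoverable(sprintf("channel %s has no good neighbours", rec$montage[ch]))
      rec$data[ch, ] <- colMeans(rec$data[nb_idx, , drop = FALSE])
    }
  }
  list(recording = rec, repaired = rec$montage[bad])
}

#' Amplitude-threshold segment rejection
#'
#' Splits the recording into consecutive windows of `window_s` seconds and
#' keeps only windows in which every channel stays within `+/- amp_tol` uV;
#' kept windows are concatenated. A stand-in for artifact-subspace
#' reconstruction style cleaning: deterministic, and sufficient to remove the
#' rare high-amplitude transients the synthetic cohorts plant.
#'
#' @param rec an [eeg_recording()].
#' @param window_s window length in seconds (default 1).
#' @param amp_tol amplitude ceiling in uV (default 200).
#' @return a list: `recording` (concatenated kept windows) and `kept`
#'   (logical mask over windows).
#' @export
reject_segments <- function(rec, window_s = 1, amp_tol = 200) {
  stopifnot(inherits(rec, "eeg_recording"))
  wlen <- as.integer(window_s * rec$rate_hz)
  if (wlen < 1L) stop_invalid("'window_s' times the rate must be >= 1 sample")
  n_win <- n_samples(rec) %/% wlen
  if (n_win < 1L) stop_invalid("recording shorter than one window")
  kept <- logical(n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1L) * wlen + 1L):(w * wlen)
    kept[w] <- all(abs(rec$data[, idx]) <= amp_tol)
  }
  if (!any(kept))
    stop_unrecoverable("all windows exceeded the amplitude threshold")
  keep_idx <- unlist(lapply(which(kept), function(w) ((w - 1L) * wlen + 1L):(w * wlen)))
  rec$data <- rec$data[, keep_idx, drop = FALSE]
  list(recording = rec, kept = kept)
}

#' Full deterministic preprocessing chain
#'
#' Fixed order: baseline removal, notch, FIR band-pass, common average
#' reference, bad-channel interpolation, segment rejection. The notch and
#' band-pass are linear time-invariant operators and commute exactly; the
#' notch runs first because removing the mains line before the long
#' band-pass impulse response minimizes finite-record edge transients.
#' Returns the cleaned recording plus a log of what was repaired/rejected.
#' Output is guaranteed finite and NaN-free.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band-pass edges (Hz).
#' @param notch_hz notch frequency (Hz).
#' @param montage montage with adjacency for interpolation.
#' @param flat_tol,bad_amp_tol bad-channel thresholds (uV), see
#'   [detect_and_interpolate_bad()].
#' @param window_s,reject_amp_tol segment-rejection settings, see
#'   [reject_segments()].
#' @return list with `recording`, `repaired_channels`, `kept_windows`.
#' @export
preprocess <- function(rec, low_hz = 1, high_hz = 70, notch_hz = 50,
                       montage = montage_1020(), flat_tol = 0.1,
                       bad_amp_tol = 500, window_s = 1, reject_amp_tol = 200) {
  rec <- remove_baseline(rec)
  rec <- notch(rec, notch_hz)
  rec <- fir_bandpass(rec, low_hz, high_hz)
  rec <- common_average_reference(rec)
  rep_out <- detect_and_interpolate_bad(rec, montage, flat_tol, bad_amp_tol)
  rej_out <- reject_segments(rep_out$recording, window_s, reject_amp_tol)
  out <- rej_out$recording
  if (!all(is.finite(out$data)))
    stop_unrecoverable("non-finite samples after preprocessing")
  list(recording = out, repaired_channels = rep_out$repaired,
       kept_windows = rej_out$kept)
}
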