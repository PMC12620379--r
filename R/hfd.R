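# Higuchi Fractal Dimension estimation and the 38-element per-subject
# feature vectors (2 eyes-closed recordings x 19 channels).

#' HFD estimator configuration
#'
#' @param k_max maximum delay (default 8, a common choice for 250 Hz EEG
#'   segments; stable for series of 1000+ samples).
#' @param fit_range subset of `1:k_max` used in the log-log regression
#'   (default all; at least two values).
#' @return list of class `hfd_config`.
#' @export
hfd_config <- function(k_max = 8, fit_range = seq_len(k_max)) {
  if (!is_count(k_max) || k_max < 2) stop_invalid("'k_max' must be an integer >= 2")
  if (!all(fit_range %in% seq_len(k_max)) || length(fit_range) < 2)
    stop_invalid("'fit_range' must be >= 2 values within 1..k_max")
  structure(list(k_max = as.integer(k_max), fit_range = as.integer(fit_range)),
            class = "hfd_config")
}

#' Normalized Higuchi curve length
#'
#' For a series `x` of length N, start offset `m` and delay `k`, returns
#' `L_m(k) = [sum_i |x(m+ik) - x(m+(i-1)k)|] * (N-1) / (floor((N-m)/k) * k) / k`.
#'
#' @param x numeric series.
#' @param m start offset, `1 <= m <= k`.
#' @param k delay.
#' @return non-negative scalar.
#' @examples
#' higuchi_curve_length(0:5, m = 1, k = 1)  # 5
#' higuchi_curve_length(0:5, m = 1, k = 2)  # 2.5
#' @export
higuchi_curve_length <- function(x, m, k) {
  n <- length(x)
  if (!is_count(k) || !is_count(m) || m > k)
    stop_invalid("need integer 1 <= m <= k")
  if (k > n - m) stop_invalid("'k' too large for the series length")
  idx <- seq.int(m, n, by = k)
  nm <- length(idx) - 1L
  sum(abs(diff(x[idx]))) * (n - 1) / (nm * k) / k
}

#' Higuchi Fractal Dimension of a series
#'
#' Computes the mean normalized curve length `<L(k)>` over start offsets
#' `m = 1..k` for each delay `k` in the fit range, then returns the slope of
#' the ordinary least-squares fit of `ln <L(k)>` against `ln(1/k)`. Smooth
#' curves give ~1, white noise ~2, and discrete fractional Brownian motion
#' with Hurst exponent H gives `2 - H`. The estimate is invariant under
#' affine transforms of the series.
#'
#' @param x numeric series, length at least `4 * k_max`, not all-constant.
#' @param cfg an [hfd_config()].
#' @return scalar dimension estimate.
#' @examples
#' higuchi_fd(seq_len(1000))          # ~1 (smooth ramp)
#' higuchi_fd(generate_fbm(2500, hurst = 0.8, seed = 1))  # ~1.2
#' @export
higuchi_fd <- function(x, cfg = hfd_config()) {
  stopifnot(inherits(cfg, "hfd_config"))
  n <- length(x)
  if (n < 4 * cfg$k_max)
    stop_invalid("series too short: need length >= 4 * k_max")
  if (!all(is.finite(x))) stop_input("series contains non-finite values")
  lk <- vapply(cfg$fit_range, function(k) {
    mean(vapply(seq_len(k), function(m) higuchi_curve_length(x, m, k),
                numeric(1)))
  }, numeric(1))
  if (any(lk <= 0))
    stop_degenerate("zero curve length (constant or near-constant series)")
  xk <- log(1 / cfg$fit_range)
  yk <- log(lk)
  # OLS slope, closed form
  sum((xk - mean(xk)) * (yk - mean(yk))) / sum((xk - mean(xk))^2)
}

#' Map a feature index to its EEG channel
#'
#' Features come in per-channel pairs (recording 1, recording 2), so feature
#' `j` originates from channel `ceiling(j/2)`: higu_7 -> channel 4 (F3),
#' higu_29 -> channel 15 (Pz).
#'
#' @param j feature index (1-based, vectorized), `1..2*n_channels`.
#' @param montage electrode names in channel order.
#' @return data.frame with columns `feature`, `channel`, `electrode`.
#' @export
feature_to_channel <- function(j, montage = montage_1020()$names) {
  if (any(j < 1 | j > 2 * length(montage)) || any(j != floor(j)))
    stop_invalid(sprintf("feature index out of range 1..%d", 2 * length(montage)))
  ch <- ceiling(j / 2)
  data.frame(feature = paste0("higu_", j), channel = ch,
             electrode = montage[ch], stringsAsFactors = FALSE)
}

#' Higuchi feature vector for one subject
#'
#' Two eyes-closed recordings on a shared montage yield `2 * n_channels`
#' ordered features: `higu_{2c-1}` is the HFD of channel `c` in recording 1
#' and `higu_{2c}` the HFD of channel `c` in recording 2.
#'
#' @param recordings list of exactly 2 [eeg_recording()]s with identical
#'   montages.
#' @param cfg an [hfd_config()].
#' @return named numeric vector `higu_1 ... higu_{2*n_channels}`.
#' @export
features_from_subject <- function(recordings, cfg = hfd_config()) {
  if (length(recordings) != 2L)
    stop_input("exactly two recordings per subject are required")
  if (!identical(recordings[[1]]$montage, recordings[[2]]$montage))
    stop_input("recordings do not share a montage")
  nc <- n_channels(recordings[[1]])
  vals <- numeric(2L * nc)
  for (c in seq_len(nc)) {
    vals[2 * c - 1] <- higuchi_fd(recordings[[1]]$data[c, ], cfg)
    vals[2 * c]     <- higuchi_fd(recordings[[2]]$data[c, ], cfg)
  }
  stats::setNames(vals, paste0("higu_", seq_along(vals)))
}

#' Higuchi feature table for a whole cohort
#'
#' Runs [features_from_subject()] for every subject. Subjects with more than
#' two usable recordings contribute their first two in manifest order; those
#' with fewer than two are excluded with a warning.
#'
#' @param cohort an `eeg_cohort`, or any list of subject records each holding
#'   `subject_id`, `group` and a list `recordings`.
#' @param cfg an [hfd_config()].
#' @return data.frame: `subject_id`, `group`, `higu_1 ... higu_{2C}`.
#' @export
features_from_cohort <- function(cohort, cfg = hfd_config()) {
  subjects <- if (inherits(cohort, "eeg_cohort")) cohort$subjects else cohort
  rows <- list()
  for (s in subjects) {
    if (length(s$recordings) < 2L) {
      warning(sprintf("subject %s has %d usable recordings; excluded",
                      s$subject_id, length(s$recordings)))
      next
    }
    v <- features_from_subject(s$recordings[1:2], cfg)
    rows[[length(rows) + 1L]] <- c(list(subject_id = s$subject_id,
                                        group = s$group), as.list(v))
  }
  do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

# Split a feature table into the numeric matrix and the label column.
feature_matrix <- function(features) {
  num <- features[, grepl("^higu_|^cell_", names(features)), drop = FALSE]
  as.matrix(num)
}
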