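# Synthetic EEG cohorts with analytically known fractal dimension.
#
# Channel signals are discrete fractional Brownian motion (the cumulative sum
# of fractional Gaussian noise with Hurst exponent H), whose graph has fractal
# dimension 2 - H. That gives every downstream stage -- preprocessing, Higuchi
# estimation, ranking, classification, ANOVA -- a ground-truth channel.

# Exact fGn autocovariance at integer lag k (unit variance).
fgn_autocov <- function(k, hurst) {
  0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) + abs(k - 1)^(2 * hurst))
}

#' Fractional Gaussian noise by circulant embedding
#'
#' Generates a stationary, unit-variance fractional Gaussian noise series with
#' Hurst exponent `hurst` using the Davies-Harte circulant-embedding method:
#' the exact autocovariance sequence is embedded in a circulant matrix whose
#' eigenvalues (computed by FFT) are provably non-negative for fGn, so the
#' simulation is exact up to floating point. `H = 0.5` reduces to white noise.
#'
#' The graph of the *cumulative sum* of this series (discrete fractional
#' Brownian motion, see [generate_fbm()]) has fractal dimension `2 - hurst`,
#' which is the truth channel used throughout the synthetic cohorts.
#'
#' @param n_samples series length (>= 16).
#' @param hurst Hurst exponent, strictly inside (0, 1).
#' @param seed integer seed; the draw is reproducible under it. `NULL` uses
#'   the current RNG stream.
#' @return numeric vector of length `n_samples`.
#' @examples
#' x <- generate_fgn(1024, hurst = 0.5, seed = 1)
#' cor(x[-1], x[-length(x)])  # ~0: H = 0.5 fGn is white
#' @export
generate_fgn <- function(n_samples, hurst, seed = NULL) {
  if (!is_count(n_samples) || n_samples < 16)
    stop_invalid("'n_samples' must be an integer >= 16")
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_invalid("'hurst' must lie strictly inside (0, 1)")
  draw <- function() fgn_draw(as.integer(n_samples), hurst)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

fgn_draw <- function(n, hurst) {
  m <- 2L * n
  cv <- fgn_autocov(c(0:n, (n - 1):1), hurst)
  lam <- Re(stats::fft(cv))
  # Non-negativity is a theorem for fGn; tolerate tiny FFT round-off.
  if (min(lam) < -1e-8 * max(lam))
    stop_degenerate("circulant embedding produced negative eigenvalues")
  lam[lam < 0] <- 0
  w <- complex(length.out = m)
  w[1] <- sqrt(lam[1]) * stats::rnorm(1)
  w[n + 1] <- sqrt(lam[n + 1]) * stats::rnorm(1)
  k <- 2:n
  u <- stats::rnorm(n - 1)
  v <- stats::rnorm(n - 1)
  w[k] <- sqrt(lam[k] / 2) * complex(real = u, imaginary = v)
  w[m + 2 - k] <- Conj(w[k])
  Re(stats::fft(w))[1:n] / sqrt(m)
}

#' @rdname generate_fgn
#' @details `generate_fbm()` returns the cumulative sum of the fGn draw
#'   (discrete fractional Brownian motion); its Higuchi fractal dimension is
#'   `2 - hurst`.
#' @export
generate_fbm <- function(n_samples, hurst, seed = NULL) {
  cumsum(generate_fgn(n_samples, hurst, seed))
}

#' Artifact parameters for synthetic recordings
#'
#' Amplitudes are in microvolts on the scale of the simulated EEG (channel SD
#' `signal_sd_uv` in [cohort_config()], default 20 uV). Defaults contaminate
#' the signal with mains interference, slow drift well below the 1 Hz
#' high-pass edge, and rare Poisson-timed high-amplitude transients of the
#' kind amplitude-based segment rejection must catch.
#'
#' @param line_amp_uv 50 Hz line-noise amplitude (uV), >= 0.
#' @param line_freq_hz mains frequency (Hz).
#' @param drift_amp_uv slow-drift amplitude (uV), >= 0.
#' @param drift_freq_hz drift frequency (Hz), below 0.5.
#' @param transient_rate_hz expected transients per second (Poisson), >= 0.
#' @param transient_amp_uv transient peak amplitude (uV), >= 0.
#' @return list of class `artifact_params`.
#' @export
artifact_params <- function(line_amp_uv = 20, line_freq_hz = 50,
                            drift_amp_uv = 50, drift_freq_hz = 0.2,
                            transient_rate_hz = 0.05, transient_amp_uv = 400) {
  amps <- c(line_amp_uv, drift_amp_uv, transient_rate_hz, transient_amp_uv)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop_invalid("artifact amplitudes and rates must be non-negative")
  if (drift_freq_hz <= 0 || drift_freq_hz >= 0.5)
    stop_invalid("'drift_freq_hz' must lie in (0, 0.5) Hz")
  structure(list(line_amp_uv = line_amp_uv, line_freq_hz = line_freq_hz,
                 drift_amp_uv = drift_amp_uv, drift_freq_hz = drift_freq_hz,
                 transient_rate_hz = transient_rate_hz,
                 transient_amp_uv = transient_amp_uv),
            class = "artifact_params")
}

#' Inject line noise, drift and transients into a recording
#'
#' Adds, per channel, a sinusoid at the mains frequency (random phase) and a
#' slow sinusoidal drift (< 0.5 Hz, random phase). High-amplitude biphasic
#' transients (~40 ms, movement-artifact-like) occur as a Poisson process in
#' time over the whole recording (`transient_rate_hz` events per second),
#' each hitting one randomly chosen channel. The input is not modified.
#'
#' @param rec an [eeg_recording()].
#' @param params an [artifact_params()].
#' @param seed integer seed for phases and transient times.
#' @return a new [eeg_recording()] with artifacts added.
#' @export
inject_artifacts <- function(rec, params = artifact_params(), seed = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!inherits(params, "artifact_params"))
    params <- do.call(artifact_params, params)
  run <- function() {
    n <- n_samples(rec)
    fs <- rec$rate_hz
    t <- (seq_len(n) - 1) / fs
    out <- rec$data
    for (ch in seq_len(n_channels(rec))) {
      x <- out[ch, ]
      if (params$line_amp_uv > 0)
        x <- x + params$line_amp_uv *
          sin(2 * pi * params$line_freq_hz * t + stats::runif(1, 0, 2 * pi))
      if (params$drift_amp_uv > 0)
        x <- x + params$drift_amp_uv *
          sin(2 * pi * params$drift_freq_hz * t + stats::runif(1, 0, 2 * pi))
      out[ch, ] <- x
    }
    if (params$transient_rate_hz > 0) {
      n_tr <- stats::rpois(1, params$transient_rate_hz * n / fs)
      if (n_tr > 0) {
        centers <- sample.int(n, n_tr, replace = TRUE)
        chans <- sample.int(n_channels(rec), n_tr, replace = TRUE)
        half <- max(1L, round(0.02 * fs))  # ~40 ms biphasic spike
        shape <- params$transient_amp_uv *
          sin(pi * seq(-half, half) / half) * exp(-abs(seq(-half, half)) / half)
        for (j in seq_len(n_tr)) {
          idx <- (centers[j] - half):(centers[j] + half)
          ok <- idx >= 1 & idx <= n
          out[chans[j], idx[ok]] <- out[chans[j], idx[ok]] + shape[ok]
        }
      }
    }
    rec$data <- out
    rec
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Synthetic cohort configuration
#'
#' Defines the study conditions the generator emulates: four groups with the
#' study's eyes-closed sample sizes, 19 channels at 250 Hz, two recordings per
#' subject, and a planted complexity effect: on `affected_channels` each group
#' has its own Hurst exponent (default 0.55/0.65/0.75/0.85 for
#' addict/first/second/normal, i.e. a fractal-dimension separation of 0.10
#' between adjacent groups); all other channels share `baseline_hurst` across
#' groups. Subject-level Hurst values are jittered around the group profile by
#' `hurst_sd` so that within-group variance exceeds estimator noise and
#' classification is non-trivial.
#'
#' @param n_per_group named integer vector of subject counts for groups
#'   addict, first, second, normal.
#' @param n_channels,rate_hz,duration_s,recordings_per_subject recording
#'   geometry; both recordings are eyes-closed.
#' @param group_hurst named per-group Hurst exponent on affected channels.
#' @param baseline_hurst shared Hurst exponent for unaffected channels.
#' @param hurst_sd between-subject SD of the Hurst exponent (truncated so all
#'   values stay inside (0.05, 0.95)).
#' @param affected_channels 1-based channel indices carrying the group effect.
#' @param signal_sd_uv amplitude scale (uV) each channel is standardized to.
#' @param artifact_params an [artifact_params()] (amplitude 0 disables).
#' @param seed integer RNG seed.
#' @return list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(addict = 19, first = 24,
                                          second = 23, normal = 20),
                          n_channels = 19, rate_hz = 250, duration_s = 10,
                          recordings_per_subject = 2,
                          group_hurst = c(addict = 0.55, first = 0.65,
                                          second = 0.75, normal = 0.85),
                          baseline_hurst = 0.70, hurst_sd = 0.05,
                          affected_channels = c(4, 5, 6, 15),
                          signal_sd_uv = 20,
                          artifact_params = eegfd::artifact_params(),
                          seed = 1) {
  groups <- c("addict", "first", "second", "normal")
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (!setequal(names(n_per_group), groups))
    stop_invalid("'n_per_group' must be named addict, first, second, normal")
  if (any(n_per_group < 1))
    stop_invalid("every group needs at least one subject")
  if (is.null(names(group_hurst))) names(group_hurst) <- groups
  hh <- c(group_hurst, baseline_hurst)
  if (any(hh <= 0) || any(hh >= 1))
    stop_invalid("all Hurst exponents must lie strictly inside (0, 1)")
  if (!all(affected_channels %in% seq_len(n_channels)))
    stop_invalid("'affected_channels' must be a subset of 1..n_channels")
  if (duration_s * rate_hz < 64)
    stop_invalid("recordings must be long enough for downstream HFD (>= 64 samples)")
  structure(list(n_per_group = n_per_group[groups], n_channels = n_channels,
                 rate_hz = rate_hz, duration_s = duration_s,
                 recordings_per_subject = recordings_per_subject,
                 group_hurst = group_hurst[groups],
                 baseline_hurst = baseline_hurst, hurst_sd = hurst_sd,
                 affected_channels = sort(unique(affected_channels)),
                 signal_sd_uv = signal_sd_uv,
                 artifact_params = artifact_params, seed = seed),
            class = "cohort_config")
}

# Per-channel Hurst profile for one group (before subject jitter).
group_profile <- function(cfg, group) {
  h <- rep(cfg$baseline_hurst, cfg$n_channels)
  h[cfg$affected_channels] <- cfg$group_hurst[[group]]
  h
}

#' Generate a synthetic EEG cohort
#'
#' Draws one subject record per subject: a per-channel Hurst profile (group
#' profile plus truncated Gaussian subject jitter), then
#' `recordings_per_subject` independent eyes-closed recordings whose channels
#' are discrete fractional Brownian motion standardized to `signal_sd_uv`,
#' contaminated by [inject_artifacts()]. Deterministic under `cfg$seed`.
#'
#' @param cfg a [cohort_config()].
#' @return A list of class `eeg_cohort`: elements `subjects` (list of subject
#'   records, each with `subject_id`, `group`, `recordings`, `truth`),
#'   `truth` (data.frame subject_id, group, hurst_1..hurst_C), and `config`.
#' @export
generate_cohort <- function(cfg = cohort_config()) {
  stopifnot(inherits(cfg, "cohort_config"))
  montage <- if (cfg$n_channels == 19) montage_1020()$names else
    paste0("ch", seq_len(cfg$n_channels))
  n <- as.integer(cfg$duration_s * cfg$rate_hz)
  with_seed(cfg$seed, {
    subjects <- list()
    sid <- 0L
    for (g in names(cfg$n_per_group)) {
      prof <- group_profile(cfg, g)
      for (i in seq_len(cfg$n_per_group[[g]])) {
        sid <- sid + 1L
        h <- prof + stats::rnorm(cfg$n_channels, 0, cfg$hurst_sd)
        h <- pmin(pmax(h, 0.05), 0.95)
        recs <- lapply(seq_len(cfg$recordings_per_subject), function(r) {
          dat <- t(vapply(seq_len(cfg$n_channels), function(ch) {
            x <- cumsum(fgn_draw(n, h[ch]))
            s <- stats::sd(x)
            if (s == 0) s <- 1
            (x - mean(x)) / s * cfg$signal_sd_uv
          }, numeric(n)))
          rec <- eeg_recording(dat, rate_hz = cfg$rate_hz, montage = montage,
                               eye_state = "closed", reference = "linked-ears")
          inject_artifacts(rec, cfg$artifact_params, seed = NULL)
        })
        subjects[[sid]] <- list(subject_id = sprintf("S%03d", sid), group = g,
                                recordings = recs, truth = h)
      }
    }
    truth <- data.frame(
      subject_id = vapply(subjects, `[[`, "", "subject_id"),
      group = vapply(subjects, `[[`, "", "group"),
      stringsAsFactors = FALSE
    )
    hmat <- t(vapply(subjects, `[[`, numeric(cfg$n_channels), "truth"))
    colnames(hmat) <- paste0("hurst_", seq_len(cfg$n_channels))
    truth <- cbind(truth, as.data.frame(hmat))
    structure(list(subjects = subjects, truth = truth, config = cfg),
              class = "eeg_cohort")
  })
}

#' @export
print.eeg_cohort <- function(x, ...) {
  tab <- table(factor(vapply(x$subjects, `[[`, "", "group"),
                      levels = names(x$config$n_per_group)))
  cat(sprintf("<eeg_cohort> %d subjects (%s), %d x %g s recordings @ %g Hz\n",
              length(x$subjects),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
              x$config$recordings_per_subject, x$config$duration_s,
              x$config$rate_hz))
  invisible(x)
}

#' Write a cohort to disk as matrix CSVs plus a manifest
#'
#' One CSV per recording (rows = samples, columns = electrode names) and a
#' `manifest.csv` listing subject_id, group, recording paths, and the true
#' per-channel Hurst exponents.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort$subjects, function(s) {
    paths <- vapply(seq_along(s$recordings), function(r) {
      p <- file.path(dir, sprintf("%s_rec%d.csv", s$subject_id, r))
      write_recording_csv(s$recordings[[r]], p)
      basename(p)
    }, "")
    c(subject_id = s$subject_id, group = s$group,
      stats::setNames(paths, paste0("recording_", seq_along(paths))),
      stats::setNames(sprintf("%.6f", s$truth),
                      paste0("hurst_", seq_along(s$truth))))
  })
  manifest <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
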