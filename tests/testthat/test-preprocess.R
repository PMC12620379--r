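test_that("baseline removal centers every channel and is idempotent", {
  rec <- make_rec(c(5, 5, 5, 5), c(1, 2, 3, 4))
  out <- remove_baseline(rec)
  expect_equal(out$data[1, ], c(0, 0, 0, 0))
  expect_equal(out$data[2, ], c(-1.5, -0.5, 0.5, 1.5))
  expect_equal(remove_baseline(out)$data, out$data, tolerance = 1e-12)
  expect_lt(max(abs(rowMeans(out$data))), 1e-9)
})

test_that("band-pass meets its passband and stopband contract", {
  fs <- 250
  t <- (0:(20 * fs - 1)) / fs
  tone <- function(f) sin(2 * pi * f * t)
  rms <- function(x) sqrt(mean(x^2))
  mid <- (5 * fs):(15 * fs)     # avoid edge transition in the measurement
  run <- function(f) {
    rec <- make_rec(tone(f), tone(f))
    fir_bandpass(rec)$data[1, mid]
  }
  expect_lt(abs(mean(run(0)[1])), 0.05)               # DC rejected
  expect_lt(abs(rms(run(10)) / rms(tone(10)[mid]) - 1), 0.12)
  expect_lt(rms(run(0.1)) / rms(tone(0.1)[mid]), 0.1)
  expect_lt(rms(run(0.5)) / rms(tone(0.5)[mid]), 10^(-30 / 20))
  expect_lt(rms(run(80)) / rms(tone(80)[mid]), 10^(-30 / 20))
  expect_lt(abs(rms(run(70)) / rms(tone(70)[mid]) - 1), 0.12)
  rec <- make_rec(tone(10), tone(10))
  expect_error(fir_bandpass(rec, 1, 130), class = "eegfd_invalid_parameter")
})

test_that("band-pass frequency response meets design specs (oracle)", {
  # direct DFT of the designed taps, independent of the application path
  des <- eegfd:::design_bandpass(1, 70, 250)
  gain <- function(f) {
    k <- seq_along(des$b) - 1
    Mod(sum(des$b * exp(-2i * pi * f * k / 250)))
  }
  expect_lt(20 * log10(gain(0.5)), -30)
  expect_lt(20 * log10(gain(80)), -30)
  expect_gt(20 * log10(gain(1)), -1)
  expect_gt(20 * log10(gain(70)), -1)
  expect_lt(abs(20 * log10(gain(10))), 1)
})

test_that("notch suppresses 50 Hz by 30 dB or more and spares neighbours", {
  fs <- 250
  t <- (0:(10 * fs - 1)) / fs
  rms <- function(x) sqrt(mean(x^2))
  run <- function(f) {
    rec <- make_rec(sin(2 * pi * f * t), cos(2 * pi * f * t))
    notch(rec)$data[1, ]
  }
  expect_lt(rms(run(50)) / rms(sin(2 * pi * 50 * t)), 0.032)
  expect_lt(abs(rms(run(10)) / rms(sin(2 * pi * 10 * t)) - 1), 0.10)
  mid <- (2 * fs):(8 * fs)
  for (f in c(45, 55))
    expect_gt(rms(run(f)[mid]) / rms(sin(2 * pi * f * t)[mid]), 10^(-3 / 20))
  zero <- make_rec(numeric(1000), numeric(1000))
  expect_equal(notch(zero)$data, zero$data, tolerance = 1e-12)
})

test_that("IIR notch transfer function meets the attenuation contract", {
  des <- eegfd:::design_notch(50, 250)
  gain <- function(f) {
    z <- exp(2i * pi * f / 250)
    Mod(sum(des$b * z^-(0:2)) / sum(des$a * z^-(0:2)))^2  # zero-phase = 2 passes
  }
  expect_lt(20 * log10(gain(50)), -30)
  expect_gt(20 * log10(gain(45)), -3)
  expect_gt(20 * log10(gain(55)), -3)
})

test_that("common average reference zeroes the channel mean exactly", {
  rec <- make_rec(c(1, 1), c(3, 3))
  out <- common_average_reference(rec)
  expect_equal(out$data, rbind(c(-1, -1), c(1, 1)), ignore_attr = TRUE)
  rec3 <- make_rec(0, 3, 6)
  expect_equal(common_average_reference(rec3)$data[, 1], c(-3, 0, 3),
               ignore_attr = TRUE)
  # idempotent, and zero-sum to floating tolerance at every sample
  big <- make_rec(rnorm(500) * 100, rnorm(500) * 100, rnorm(500) * 100)
  out1 <- common_average_reference(big)
  expect_lt(max(abs(colSums(out1$data))), 1e-9 * max(abs(big$data)))
  expect_equal(common_average_reference(out1)$data, out1$data,
               tolerance = 1e-12)
  expect_identical(out1$reference, "common-average")
  single <- eeg_recording(matrix(1:4, 1), montage = "Cz")
  expect_error(common_average_reference(single), class = "eegfd_invalid_input")
})

test_that("filters are amplitude-linear", {
  set.seed(8)
  x <- rnorm(2000)
  rec1 <- make_rec(x, x)
  rec2 <- make_rec(3.7 * x, 3.7 * x)
  for (f in list(fir_bandpass, notch)) {
    y1 <- f(rec1)$data[1, ]
    y2 <- f(rec2)$data[1, ]
    expect_lt(max(abs(y2 - 3.7 * y1)) / max(abs(y1)), 1e-9)
  }
})

test_that("bad channels are detected and repaired from their neighbours", {
  n <- 500
  good <- function() rnorm(n, sd = 10)
  m <- montage_1020()
  data <- t(vapply(seq_len(19), function(i) good(), numeric(n)))
  rec <- eeg_recording(data, montage = m$names)
  out0 <- detect_and_interpolate_bad(rec)
  expect_identical(out0$repaired, character(0))
  expect_equal(out0$recording$data, rec$data)
  # flat channel F3 (idx 4): replaced by mean of its good neighbours
  rec$data[4, ] <- 0.001
  out <- detect_and_interpolate_bad(rec)
  expect_identical(out$repaired, "F3")
  nb <- match(m$adjacency$F3, m$names)
  expect_equal(out$recording$data[4, ],
               colMeans(rec$data[nb, ]), ignore_attr = TRUE)
  expect_gt(cor(out$recording$data[4, ], colMeans(rec$data[nb, ])), 0.5)
  # constant-neighbour worked example (flat detection off so constants pass):
  # a bad channel between constant neighbours becomes their mean
  rec2 <- rec
  rec2$data[] <- 5
  rec2$data[4, ] <- 1000  # amplitude violation
  rec2$data[nb[1], ] <- 2
  rec2$data[nb[-1], ] <- 4
  out2 <- detect_and_interpolate_bad(rec2, flat_tol = 0)
  expect_equal(unique(out2$recording$data[4, ]),
               mean(c(2, rep(4, length(nb) - 1))))
  # unrecoverable: majority bad
  rec3 <- rec
  rec3$data[1:12, ] <- 0.0001
  expect_error(detect_and_interpolate_bad(rec3),
               class = "eegfd_unrecoverable_recording")
})

test_that("segment rejection removes exactly the contaminated windows", {
  set.seed(5)
  n <- 60 * 250
  rec <- make_rec(rnorm(n, sd = 20), rnorm(n, sd = 20))
  ok <- reject_segments(rec, window_s = 1, amp_tol = 500)
  expect_true(all(ok$kept))
  expect_equal(ok$recording$data, rec$data)
  # a 500 uV transient in second 13
  rec$data[1, 12 * 250 + 100] <- 500.5
  out <- reject_segments(rec, window_s = 1, amp_tol = 200)
  brute <- vapply(seq_len(60), function(w)
    all(abs(rec$data[, ((w - 1) * 250 + 1):(w * 250)]) <= 200), logical(1))
  expect_identical(out$kept, brute)
  expect_false(out$kept[13])
  expect_equal(ncol(out$recording$data), sum(out$kept) * 250)
  expect_error(reject_segments(rec, window_s = 1, amp_tol = 0.001),
               class = "eegfd_unrecoverable_recording")
})

test_that("the composite chain returns finite data in fixed order", {
  set.seed(6)
  cfg <- cohort_config(n_per_group = c(addict = 1, first = 1, second = 1,
                                       normal = 1), duration_s = 6, seed = 3)
  co <- generate_cohort(cfg)
  pp <- preprocess(co$subjects[[1]]$recordings[[1]])
  expect_true(all(is.finite(pp$recording$data)))
  expect_identical(pp$recording$reference, "common-average")
  expect_lt(max(abs(colSums(pp$recording$data))),
            1e-9 * max(abs(pp$recording$data)))
})

test_that("montage adjacency is symmetric with at least two neighbours each", {
  m <- montage_1020()
  expect_setequal(names(m$adjacency), m$names)
  for (e in m$names) {
    expect_gte(length(m$adjacency[[e]]), 2)
    for (nb in m$adjacency[[e]]) expect_true(e %in% m$adjacency[[nb]])
  }
})
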