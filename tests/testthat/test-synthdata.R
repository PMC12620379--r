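test_that("fGn with H = 0.5 is white and draws are reproducible", {
  x <- generate_fgn(4096, hurst = 0.5, seed = 1)
  r1 <- cor(x[-1], x[-length(x)])
  expect_lt(abs(r1), 0.05)
  expect_identical(x, generate_fgn(4096, hurst = 0.5, seed = 1))
  expect_false(identical(x, generate_fgn(4096, hurst = 0.5, seed = 2)))
})

test_that("fGn sample autocovariance matches theory at long memory", {
  x <- generate_fgn(65536, hurst = 0.8, seed = 3)
  emp <- cor(x[-1], x[-length(x)])
  theory <- 0.5 * (2^1.6 - 2)  # lag-1 autocorrelation of H = 0.8 fGn
  expect_lt(abs(emp - theory), 0.03)
  expect_lt(abs(var(x) - 1), 0.25)
})

test_that("integrated fGn recovers the theoretical fractal dimension 2 - H", {
  for (h in c(0.2, 0.8)) {
    d <- vapply(1:20, function(i)
      higuchi_fd(generate_fbm(2500, hurst = h, seed = 100 + i)), numeric(1))
    expect_lt(abs(mean(d) - (2 - h)), 0.1)
  }
})

test_that("circulant-embedding draws agree with a Cholesky oracle in law", {
  # compare mean HFD of the two generators, same H, independent draws
  set.seed(42)
  d_ref <- replicate(12, ref_hfd(cumsum(ref_fgn_chol(1200, 0.7))))
  d_pkg <- vapply(1:12, function(i)
    higuchi_fd(generate_fbm(1200, hurst = 0.7, seed = 500 + i)), numeric(1))
  expect_lt(abs(mean(d_ref) - mean(d_pkg)), 0.05)
})

test_that("invalid fGn parameters are rejected", {
  expect_error(generate_fgn(100, hurst = 0), class = "eegfd_invalid_parameter")
  expect_error(generate_fgn(100, hurst = 1), class = "eegfd_invalid_parameter")
  expect_error(generate_fgn(8, hurst = 0.5), class = "eegfd_invalid_parameter")
})

test_that("artifact injection is additive, seeded, and identity at zero", {
  rec <- make_rec(rnorm(2500), rnorm(2500))
  none <- artifact_params(line_amp_uv = 0, drift_amp_uv = 0,
                          transient_rate_hz = 0)
  expect_identical(inject_artifacts(rec, none, seed = 1)$data, rec$data)
  out <- inject_artifacts(rec, artifact_params(), seed = 9)
  expect_identical(out$data, inject_artifacts(rec, artifact_params(), seed = 9)$data)
  expect_false(identical(out$data, rec$data))
  expect_error(artifact_params(line_amp_uv = -1),
               class = "eegfd_invalid_parameter")
})

test_that("injected line noise dominates the added spectrum at 50 Hz", {
  rec <- make_rec(rnorm(2500), rnorm(2500))
  out <- inject_artifacts(rec, artifact_params(line_amp_uv = 30,
                                               drift_amp_uv = 0,
                                               transient_rate_hz = 0), seed = 2)
  added <- out$data[1, ] - rec$data[1, ]
  spec <- Mod(fft(added))[1:1250]
  freqs <- (0:1249) * 250 / 2500
  expect_equal(freqs[which.max(spec)], 50)
})

test_that("transient count replays the Poisson stream", {
  rec <- make_rec(numeric(15000), numeric(15000))
  p <- artifact_params(line_amp_uv = 0, drift_amp_uv = 0,
                       transient_rate_hz = 0.1, transient_amp_uv = 400)
  out <- inject_artifacts(rec, p, seed = 7)
  # brute-force replay of the RNG stream: the Poisson count, the transient
  # centres and the channel picks follow the same seed path
  replay <- local({
    set.seed(7)
    n_tr <- rpois(1, 0.1 * 60)
    list(n = n_tr, centers = sample.int(15000, n_tr, replace = TRUE),
         chans = sample.int(2, n_tr, replace = TRUE))
  })
  expect_gt(replay$n, 0)
  added <- abs(out$data - rec$data)
  changed <- which(added > 1e-9, arr.ind = TRUE)
  half <- round(0.02 * 250)
  # every altered sample lies inside the support of a replayed transient
  ok <- vapply(seq_len(nrow(changed)), function(i) {
    any(replay$chans == changed[i, 1] &
          abs(replay$centers - changed[i, 2]) <= half)
  }, logical(1))
  expect_true(all(ok))
  # and every replayed transient altered its channel near its centre
  hit <- vapply(seq_len(replay$n), function(j)
    any(added[replay$chans[j],
              pmax(1, replay$centers[j] - half):
              pmin(15000, replay$centers[j] + half)] > 100), logical(1))
  expect_true(all(hit))
})

test_that("cohort bookkeeping matches the study group sizes and is reproducible", {
  cfg <- cohort_config(duration_s = 1, seed = 11)
  co <- generate_cohort(cfg)
  grp <- vapply(co$subjects, `[[`, "", "group")
  expect_length(co$subjects, 86)
  expect_equal(unname(table(grp)[c("addict", "first", "second", "normal")]),
               array(c(19L, 24L, 23L, 20L)), ignore_attr = TRUE)
  co2 <- generate_cohort(cfg)
  expect_identical(co$subjects[[5]]$recordings[[2]]$data,
                   co2$subjects[[5]]$recordings[[2]]$data)
  expect_error(
    cohort_config(n_per_group = c(addict = 0, first = 1, second = 1, normal = 1)),
    class = "eegfd_invalid_parameter")
})

test_that("group-mean fractal dimension decreases across groups on an affected channel", {
  cfg <- cohort_config(n_per_group = c(addict = 5, first = 5, second = 5,
                                       normal = 5),
                       duration_s = 10, hurst_sd = 0, seed = 21,
                       artifact_params = artifact_params(
                         line_amp_uv = 0, drift_amp_uv = 0,
                         transient_rate_hz = 0))
  ds <- replicate(4, {
    cfg$seed <- cfg$seed + 1
    co <- generate_cohort(cfg)
    hf <- vapply(co$subjects, function(s)
      ref_hfd(s$recordings[[1]]$data[4, ]), numeric(1))
    tapply(hf, vapply(co$subjects, `[[`, "", "group"), mean)[
      c("addict", "first", "second", "normal")]
  })
  means <- rowMeans(ds)
  expect_true(all(diff(means) < 0))
})

test_that("only affected channels carry a group effect in the generated data", {
  cfg <- cohort_config(n_per_group = c(addict = 12, first = 12, second = 12,
                                       normal = 12),
                       duration_s = 10, seed = 33,
                       artifact_params = artifact_params(
                         line_amp_uv = 0, drift_amp_uv = 0,
                         transient_rate_hz = 0))
  co <- generate_cohort(cfg)
  grp <- vapply(co$subjects, `[[`, "", "group")
  pvals <- vapply(c(4, 9), function(ch) {   # one affected, one null channel
    hf <- vapply(co$subjects, function(s)
      higuchi_fd(s$recordings[[1]]$data[ch, ]), numeric(1))
    ref_anova_f(hf, grp)$p
  }, numeric(1))
  expect_lt(pvals[1], 0.05)
  expect_gt(pvals[2], 0.01)  # single-draw null: no strong spurious effect
})

test_that("cohorts round-trip through CSV plus manifest", {
  cfg <- cohort_config(n_per_group = c(addict = 1, first = 1, second = 1,
                                       normal = 1), duration_s = 1, seed = 2)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rec <- read_recording_csv(file.path(dir, "S001_rec1.csv"))
  expect_equal(rec$data, co$subjects[[1]]$recordings[[1]]$data,
               tolerance = 1e-12)
  expect_identical(rec$montage, montage_1020()$names)
})
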