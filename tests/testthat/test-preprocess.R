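# Frozen oracle values for the periodized db6 DWT were computed with an
# independent reference implementation of the same transform
# (periodization mode) on x[t] = sin(0.7 t) + 0.1 t, t = 0..63, 2 levels.
pdwt_a2_head <- c(10.8929481854321, 12.1943245297707, 10.3924955542591,
                  3.37316049352959)
pdwt_d2_head <- c(-1.22700826386086, 0.555884324530893, -0.509624437528489,
                  0.761908763522217)
pdwt_d1_head <- c(0.418126504051425, -0.0162187458277473, -0.0366495723245047,
                  -0.0290974544307566)

test_that("periodized DWT matches the independent reference and reconstructs exactly", {
  x <- sin((0:63) * 0.7) + 0.1 * (0:63)
  w <- ecgmff:::dwt_periodic(x, "db6", 2)
  expect_equal(w$approx[1:4], pdwt_a2_head, tolerance = 1e-12)
  expect_equal(w$details[[2]][1:4], pdwt_d2_head, tolerance = 1e-12)
  expect_equal(w$details[[1]][1:4], pdwt_d1_head, tolerance = 1e-12)
  expect_equal(ecgmff:::idwt_periodic(w), x, tolerance = 1e-12)
  # perfect reconstruction at an awkward (non-power-of-two) length
  set.seed(1)
  y <- rnorm(651)
  expect_equal(ecgmff:::idwt_periodic(ecgmff:::dwt_periodic(y, "db6", 5)), y,
               tolerance = 1e-10)
})

test_that("baseline removal zero-centres and suppresses low-frequency drift", {
  # constant offset -> all-zero output
  flat <- vec_record(rep(0.5, 3000))
  expect_equal(max(abs(remove_baseline(flat)$signal)), 0)

  # 0.3 Hz wander: 0-0.5 Hz band power reduced at least 10x
  rec <- generate_record(clean_config(duration = 10, seed = 4))
  wander <- 0.4 * sin(2 * pi * 0.3 * (0:9999) / 1000)
  noisy <- rec
  noisy$signal <- sweep(rec$signal, 2, -wander)
  out <- remove_baseline(noisy)
  band_power <- function(x) {
    mag <- Mod(stats::fft(x))
    sum(mag[2:6]^2)                     # 0.1-0.5 Hz bins at n=10000, fs=1000
  }
  expect_lt(band_power(out$signal["II", ]),
            band_power(noisy$signal["II", ]) / 10)

  # near-idempotence on an already-clean record
  clean <- remove_baseline(rec)
  twice <- remove_baseline(clean)
  expect_lt(max(abs(twice$signal - clean$signal)), 0.05)

  expect_error(remove_baseline(vec_record(rnorm(100))), "shorter")
})

test_that("improved-threshold shrinkage matches direct elementwise evaluation", {
  set.seed(2)
  for (i in 1:20) {
    d <- rnorm(64, sd = runif(1, 0.1, 3))
    te <- runif(1, 0, 2)
    direct <- vapply(d, function(v) if (abs(v) > te) sign(v) * (abs(v) - te) else 0,
                     numeric(1))
    expect_equal(threshold_shrink(d, te), direct)
  }
  # first-branch example: a coefficient at twice the threshold shrinks to it
  te <- 0.7
  expect_equal(threshold_shrink(2 * te, te), te)
  expect_equal(threshold_shrink(-2 * te, te), -te)
})

test_that("wavelet denoising preserves zeros, sign and improves SNR", {
  zero <- vec_record(rep(0, 2048))
  expect_equal(max(abs(denoise_wavelet(zero)$signal)), 0)

  rec <- generate_record(clean_config(duration = 4, seed = 9))
  clean <- rec$signal["II", ]
  set.seed(10)
  noisy <- clean + rnorm(length(clean), sd = 0.08)
  den_pos <- denoise_wavelet(vec_record(noisy))$signal[1, ]
  den_neg <- denoise_wavelet(vec_record(-noisy))$signal[1, ]
  expect_equal(den_neg, -den_pos, tolerance = 1e-10)   # odd shrinkage rule
  snr <- function(est) 10 * log10(sum(clean^2) / sum((est - clean)^2))
  expect_gt(snr(den_pos), snr(noisy))

  expect_error(denoise_wavelet(vec_record(rnorm(16))), "shorter")
  expect_error(wavelet_denoise_config(n_levels = 10), "1..9")
  expect_error(denoise_wavelet(vec_record(rnorm(2048)),
                               wavelet_denoise_config("nosuch")), "unsupported")
})

test_that("Pan-Tompkins recovers clean and noisy synthetic peaks", {
  rec <- generate_record(clean_config(duration = 10, heart_rate = 60, seed = 5))
  det <- detect_r_peaks(remove_baseline(rec))
  expect_s3_class(det, "r_peak_list")
  expect_lte(abs(length(det$indices) - length(rec$r_peaks)), 1)
  expect_equal(peak_match_rate(det$indices, rec$r_peaks, tol = 50), 1)
  # refractory invariant
  expect_true(all(diff(det$indices) >= 200))

  flat <- vec_record(rep(0, 5000))
  expect_length(detect_r_peaks(flat)$indices, 0)

  cfg <- clean_config(duration = 10, heart_rate = 75, seed = 21)
  cfg$noise$broadband_sd <- 0.05
  noisy <- generate_record(cfg)
  detn <- detect_r_peaks(denoise_wavelet(remove_baseline(noisy)))
  expect_gte(peak_match_rate(detn$indices, noisy$r_peaks, tol = 50), 0.95)

  expect_error(detect_r_peaks(vec_record(rnorm(500))), "2 s")
  expect_error(detect_r_peaks(rec, lead = "V9"), "not present")
})

test_that("beat segmentation windows, boundary rule and bookkeeping", {
  rec <- generate_record(clean_config(duration = 10, heart_rate = 60, seed = 6))
  peaks <- rec$r_peaks
  ds <- segment_beats(rec, peaks)
  expect_equal(dim(ds$x)[1:2], c(12, 651))
  expect_equal(length(ds) + attr(ds, "dropped"), length(peaks))
  expect_true(all(ds$label == "HC"))
  # the beat is centred on the R peak: sample 251 is the R sample
  j <- 1
  expect_equal(ds$x[2, 251, j], unname(rec$signal["II", ds$r_index[j]]))

  # a peak too close to the record start is excluded
  ds2 <- segment_beats(rec, c(100L, peaks))
  expect_equal(attr(ds2, "dropped"), attr(ds, "dropped") + 1)
  expect_equal(length(ds2), length(ds))

  # degenerate window
  ds3 <- segment_beats(rec, peaks, pre = 0, post = 0)
  expect_equal(dim(ds3$x)[2], 1)
  expect_equal(ds3$x[2, 1, 1], unname(rec$signal["II", peaks[1]]))

  # empty peak list is not an error
  expect_length(segment_beats(rec, integer(0)), 0)
})

test_that("resampling preserves length ratio, spectral content and identity", {
  x <- sin(2 * pi * 10 * (0:4999) / 500)            # 10 Hz at 500 Hz
  rec <- ecg_record(matrix(x, 1, dimnames = list("II", NULL)), 500, "II")
  up <- resample_record(rec, 1000)
  expect_equal(ncol(up$signal), 10000)
  expect_equal(up$sampling_rate, 1000)
  mag <- Mod(stats::fft(up$signal[1, ]))[2:5001]
  expect_equal(which.max(mag) * 1000 / 10000, 10)   # dominant bin still 10 Hz

  same <- resample_record(rec, 500)
  expect_identical(same$signal, rec$signal)
  expect_error(resample_record(rec, -1), "positive")
})

test_that("record preprocessing is deterministic end to end", {
  cfg <- synth_config(duration = 6, heart_rate = 72, seed = 31)
  rec <- generate_record(cfg)
  b1 <- preprocess_record(rec)
  b2 <- preprocess_record(rec)
  expect_identical(b1$x, b2$x)
  expect_identical(b1$r_index, b2$r_index)
  expect_equal(dim(b1$x)[1:2], c(12, 651))
})
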