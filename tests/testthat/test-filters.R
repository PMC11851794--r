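test_that("cleaning band-pass and notch meet their spectral contract", {
  fs <- 256
  # 100 Hz tone is outside 0.5-70 Hz: residual power <= 1%
  rec <- sine_recording(100)
  out <- bandpass_notch(rec, 0.5, 70, notch_hz = NULL)
  p_in <- periodogram_band_power(rec$data[1, ], fs, 95, 105)
  p_out <- periodogram_band_power(out$data[1, ], fs, 95, 105)
  expect_lt(p_out / p_in, 0.01)

  # 10 Hz tone is inside the band: >= 90% power retained
  rec <- sine_recording(10)
  out <- bandpass_notch(rec, 0.5, 70, notch_hz = NULL)
  expect_gt(sum(out$data[1, ]^2) / sum(rec$data[1, ]^2), 0.9)

  # 50 Hz tone with the notch enabled: <= 1% power survives
  rec <- sine_recording(50)
  out <- bandpass_notch(rec, 0.5, 70, notch_hz = 50)
  expect_lt(sum(out$data[1, ]^2) / sum(rec$data[1, ]^2), 0.01)
})

test_that("band-pass rejects impossible settings, warns on odd notches", {
  rec <- sine_recording(10, n_seconds = 4)
  expect_error(bandpass_notch(rec, 0.5, 128), "Nyquist")
  expect_error(bandpass_notch(rec, 0.5, 130), "Nyquist")
  expect_error(bandpass_notch(rec, 0, 70), "low_hz")
  expect_warning(bandpass_notch(rec, 0.5, 40, notch_hz = 50), "outside")
})

test_that("band filter design meets gain and symmetry contracts", {
  h <- design_band_filter(4, 8, 256, 513L)
  g6 <- fir_response(h, 6, 256)
  expect_lt(abs(20 * log10(g6)), 1)          # within +/- 1 dB at center
  g20 <- fir_response(h, 20, 256)
  expect_lt(20 * log10(g20), -20)            # stop band
  expect_equal(h[seq_len(256)], rev(h[258:513]),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(design_band_filter(4, 8, 256, 512L), "odd")
  expect_error(design_band_filter(140, 150, 256), "Nyquist")
  # gamma's printed 100 Hz upper edge is clamped below Nyquist, not an error
  hg <- design_band_filter(30, 100, 256, 513L)
  expect_lt(attr(hg, "high_hz"), 128)
})

test_that("pure tones land in the right band slice of the decomposition", {
  fs <- 256
  ch <- eegcaps:::MONTAGE_CHANNELS
  t <- seq_len(5 * fs) / fs
  bands <- default_bands()
  probes <- c(delta = 2, theta = 6, alpha = 10, beta = 20, gamma = 45)
  for (bi in seq_along(probes)) {
    x <- matrix(rep(sin(2 * pi * probes[bi] * t), 19), 19, length(t),
                byrow = TRUE, dimnames = list(ch, NULL))
    seg <- new_segment(x, "s", 0, 1, fs)
    stack <- decompose_bands(seg, bands)
    pow <- sapply(seq_len(5), function(b) sum(stack$data[b, 1, ]^2))
    expect_gt(pow[bi] / sum(pow), 0.9)
    for (adj in c(bi - 1, bi + 1))
      if (adj >= 1 && adj <= 5) expect_lt(pow[adj] / sum(pow), 0.05)
  }
})

test_that("decomposition is linear, deterministic, and zero on zero", {
  seg <- tiny_segment(seed = 3)
  s1 <- decompose_bands(seg)
  s2 <- decompose_bands(seg)
  expect_identical(s1$data, s2$data)
  zseg <- seg
  zseg$data[] <- 0
  expect_true(all(decompose_bands(zseg)$data == 0))
  expect_equal(dim(s1$data), c(5L, 19L, 1280L))
  expect_equal(s1$subject_id, seg$subject_id)
  expect_equal(s1$label, seg$label)
})

test_that("five band slices jointly conserve broadband power (Parseval)", {
  seg <- tiny_segment(seed = 7)
  stack <- decompose_bands(seg)
  p_in <- sum(seg$data^2)
  p_bands <- sum(stack$data^2)
  expect_gt(p_bands / p_in, 0.7)
  expect_lt(p_bands / p_in, 1.1)
})

test_that("band filtering commutes with grid projection on occupied cells", {
  seg <- tiny_segment(seed = 9)
  m <- default_montage()
  # decompose then project
  sample1 <- build_tsf_sample(decompose_bands(seg), m)
  # project each band slice of the segment and compare on occupied cells
  stack <- decompose_bands(seg)
  for (b in c(2L, 4L)) {
    fr <- project_to_grid(stack$data[b, , ], m)
    expect_equal(unclass(fr), sample1$tensor[b, , , ],
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})
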