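frontal <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")

test_that("subject generation is a pure function of spec, group and seed", {
  spec <- cohort_spec(duration_s = 6, seed = 1)
  r1 <- generate_subject(spec, "mdd", subject_seed = 42)
  r2 <- generate_subject(spec, "mdd", subject_seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- generate_subject(spec, "mdd", subject_seed = 43)
  expect_false(identical(r1$data, r3$data))
  expect_equal(r1$label, 1)
  expect_equal(generate_subject(spec, "hc", 1)$label, 0)
  expect_equal(dim(r1$data), c(19L, 6L * 256L))
  expect_setequal(r1$channel_names, eegcaps:::MONTAGE_CHANNELS)
})

test_that("cohort generation produces distinct, labelled recordings", {
  spec <- cohort_spec(n_mdd = 3, n_hc = 2, duration_s = 5, seed = 9)
  co <- generate_cohort(spec)
  expect_length(co$recordings, 5L)
  expect_equal(sum(co$manifest$label == 1), 3L)
  expect_equal(sum(co$manifest$label == 0), 2L)
  expect_equal(anyDuplicated(co$manifest$subject_id), 0L)
  # all recordings have the expected sample count and are mutually distinct
  for (r in co$recordings) expect_equal(ncol(r$data), 5L * 256L)
  expect_false(identical(co$recordings[[1]]$data, co$recordings[[2]]$data))
  # reproducible from the master seed
  co2 <- generate_cohort(spec)
  expect_identical(co$recordings[[4]]$data, co2$recordings[[4]]$data)
})

test_that("band oscillations keep >= 80% of their power in the nominal band", {
  set.seed(11)
  fs <- 256
  bands <- default_bands()
  for (b in seq_len(nrow(bands))) {
    x <- eegcaps:::band_oscillation(30 * fs, fs, bands$low_hz[b],
                                    bands$high_hz[b], amplitude = 10)
    inband <- periodogram_band_power(x, fs, bands$low_hz[b],
                                     bands$high_hz[b])
    total <- periodogram_band_power(x, fs, 0, fs / 2)
    expect_gt(inband / total, 0.8)
  }
})

test_that("a theta amplitude effect doubles frontal theta power", {
  spec <- cohort_spec(n_mdd = 8, n_hc = 8, duration_s = 20,
                      effects = list(group_effect("theta", frontal, 2.0)),
                      subject_sd = 0.1, seed = 5)
  co <- generate_cohort(spec)
  theta_front <- vapply(co$recordings, function(r) {
    mean(vapply(frontal, function(ch)
      band_power(r$data[ch, ], 256, 4, 8), 0))
  }, 0)
  labs <- co$manifest$label
  ratio <- mean(theta_front[labs == 1]) / mean(theta_front[labs == 0])
  expect_gt(ratio, 1.5)
})

test_that("a null cohort carries no group signal in band power", {
  spec <- cohort_spec(n_mdd = 20, n_hc = 20, duration_s = 8,
                      effects = list(), seed = 42)
  co <- generate_cohort(spec)
  theta_front <- vapply(co$recordings, function(r) {
    mean(vapply(frontal, function(ch)
      band_power(r$data[ch, ], 256, 4, 8), 0))
  }, 0)
  labs <- co$manifest$label
  p <- stats::t.test(theta_front[labs == 1], theta_front[labs == 0])$p.value
  expect_gt(p, 0.01)
})

test_that("spike artifacts exercise the amplitude-rejection path", {
  spec <- cohort_spec(duration_s = 30, artifact_rate_per_min = 12, seed = 3)
  rec <- generate_subject(spec, "hc", subject_seed = 8)
  expect_gt(max(abs(rec$data)), 100)      # spikes exceed the threshold
  segs <- segment_recording(rec)
  kept <- reject_amplitude(segs)
  expect_lt(length(kept), length(segs))
  clean_spec <- cohort_spec(duration_s = 30, artifact_rate_per_min = 0,
                            seed = 3)
  rec2 <- generate_subject(clean_spec, "hc", subject_seed = 8)
  expect_length(reject_amplitude(segment_recording(rec2)), 6L)
})

test_that("spec validation rejects nonsense", {
  expect_error(cohort_spec(duration_s = 2), "not TRUE")
  expect_error(cohort_spec(effects = list(group_effect("theta", "Fz", 0))))
  expect_error(group_effect("theta", "Fz", -1))
})
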