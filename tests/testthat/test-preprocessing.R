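test_that("segmentation arithmetic follows the window contract", {
  rec <- toy_recording(300)
  segs <- segment_recording(rec, 5)
  expect_length(segs, 60L)
  expect_true(all(vapply(segs, function(s) ncol(s$data), 0L) == 1280L))
  # contiguous, ordered, and concatenation reconstructs the series
  recon <- do.call(cbind, lapply(segs, function(s) s$data))
  expect_identical(recon, rec$data[, seq_len(60L * 1280L)])

  expect_length(segment_recording(toy_recording(5)), 1L)
  expect_equal(ncol(segment_recording(toy_recording(5))[[1]]$data), 1280L)
  expect_warning(short <- segment_recording(toy_recording(4.9)), "shorter")
  expect_length(short, 0L)
  expect_error(segment_recording(toy_recording(6), window_seconds = 1 / 3),
               "integer")
  # metadata travels with every segment
  rec2 <- toy_recording(10, subject_id = "subjX", label = 1)
  segs <- segment_recording(rec2)
  expect_true(all(vapply(segs, function(s) s$subject_id, "") == "subjX"))
  expect_true(all(vapply(segs, function(s) s$label, 0) == 1))
  expect_equal(vapply(segs, function(s) s$segment_index, 0L), 1:2)
})

test_that("amplitude rejection keeps exactly the in-range segments", {
  rec <- toy_recording(50, seed = 5)
  segs <- segment_recording(rec)
  # corrupt segments 2, 5, 9 with +/-200 uV spikes
  for (i in c(2, 5, 9)) segs[[i]]$data[3, 100] <- 200 * (-1)^i
  kept <- reject_amplitude(segs, 100)
  expect_length(kept, 7L)
  expect_equal(vapply(kept, function(s) s$segment_index, 0L),
               setdiff(1:10, c(2, 5, 9)))
  # retained segments are bit-identical (membership only, no mutation)
  expect_identical(kept[[1]], segs[[1]])

  seg_hi <- segs[[1]]
  seg_hi$data[1, 1] <- 150
  expect_length(reject_amplitude(list(seg_hi)), 0L)
  seg_ok <- segs[[1]]
  seg_ok$data[] <- pmin(pmax(seg_ok$data, -99.9), 99.9)
  expect_length(reject_amplitude(list(seg_ok)), 1L)
})

test_that("average re-referencing zeroes the channel mean and is idempotent", {
  x <- matrix(rnorm(19 * 100), 19, 100)
  y <- rereference_average(x)
  expect_lt(max(abs(colMeans(y))), 1e-10)
  expect_equal(rereference_average(y), y, tolerance = 1e-12)
  # constant common-mode offset vanishes entirely
  expect_true(all(abs(rereference_average(matrix(5, 19, 10))) < 1e-12))
  # single-channel deflection: closed form d(1 - 1/n) / -d/n
  n <- 19
  x0 <- matrix(0, n, 1)
  x0[4, 1] <- 2.5
  y0 <- rereference_average(x0)
  expect_equal(y0[4, 1], 2.5 * (1 - 1 / n))
  expect_equal(y0[1, 1], -2.5 / n)
})

test_that("z-scoring standardizes, is idempotent, and flags flat channels", {
  set.seed(2)
  x <- matrix(rnorm(3 * 2000, mean = 3, sd = 4), 3, 2000,
              dimnames = list(c("Fp1", "Fp2", "Cz"), NULL))
  z <- zscore_standardize(x)
  expect_lt(max(abs(rowMeans(z))), 1e-8)
  sds <- sqrt(rowMeans(z^2))
  expect_lt(max(abs(sds - 1)), 1e-6)
  expect_equal(zscore_standardize(z), z, tolerance = 1e-6)
  x["Fp2", ] <- 7
  expect_error(zscore_standardize(x), "Fp2")
})

test_that("the full cleaning chain preserves metadata and logs retention", {
  rec <- toy_recording(15, seed = 11, subject_id = "subj7", label = 1)
  pp <- preprocess_recording(rec)
  expect_equal(pp$n_total, 3L)
  expect_equal(pp$n_kept, length(pp$segments))
  for (s in pp$segments) {
    expect_equal(s$subject_id, "subj7")
    expect_equal(s$label, 1)
    expect_lt(max(abs(sqrt(rowMeans(s$data^2)) - 1)), 1e-6)
  }
})
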