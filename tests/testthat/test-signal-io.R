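test_that("montage validates its inputs", {
  expect_s3_class(default_montage(), "montage")
  expect_equal(default_montage()$nc, 14L)
  expect_error(montage(c("A", "B"), c("FL")), "equal length")
  expect_error(montage(c("A", "B"), c("FL", "XX")), "unknown lobe symbol")
  expect_error(montage(c("A", "A"), c("FL", "FR")), "duplicated")
})

test_that("segmentation cuts non-overlapping full windows and drops the remainder", {
  m <- default_montage()
  rec <- eeg_record(matrix(seq_len(14 * 4000) / 1000, nrow = 14), fs = 128,
                    label = 1, record_id = "r1", montage = m)
  segs <- segment_record(rec, 15)
  expect_length(segs, 2L)                        # floor(4000 / 1920)
  expect_true(all(vapply(segs, function(s) ncol(s$signal), 0L) == 1920L))
  ## concatenating segments reproduces a prefix of the record exactly
  expect_identical(cbind(segs[[1]]$signal, segs[[2]]$signal),
                   rec$signal[, 1:3840])
  ## exact division leaves nothing behind
  rec2 <- eeg_record(rec$signal[, 1:3840], fs = 128, label = 1,
                     record_id = "r2", montage = m)
  expect_length(segment_record(rec2, 15), 2L)
  ## shorter than one window: empty with a warning
  rec3 <- eeg_record(rec$signal[, 1:100], fs = 128, label = 1,
                     record_id = "r3", montage = m)
  expect_warning(out <- segment_record(rec3, 15), "shorter")
  expect_length(out, 0L)
})

test_that("dataset segment count follows floor arithmetic over records", {
  m <- default_montage()
  set.seed(42)
  lens <- sample(1920:8000, 5)
  recs <- lapply(seq_along(lens), function(i) {
    eeg_record(matrix(rnorm(14 * lens[i]), 14), fs = 128, label = 1 + i %% 2,
               record_id = paste0("r", i), montage = m)
  })
  ds <- segment_dataset(recs, 15)
  expect_length(ds$segments, sum(lens %/% 1920))
  expect_equal(ds$record_ids,
               rep(paste0("r", seq_along(lens)), lens %/% 1920))
})

test_that("delimited matrices load, validate channel count and honour orientation", {
  m <- default_montage()
  sig <- matrix(rnorm(14 * 2560), nrow = 14)
  path <- withr::local_tempfile(fileext = ".csv")
  write.table(sig, path, sep = ",", row.names = FALSE, col.names = FALSE)
  rec <- load_record(path, m, label = 1, record_id = "a", fs = 128)
  expect_equal(unname(rec$signal), sig, tolerance = 1e-12)
  expect_equal(ncol(rec$signal), 2560L)

  ## channels in columns
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.table(t(sig), path2, sep = ",", row.names = FALSE, col.names = FALSE)
  rec2 <- load_record(path2, m, label = 1, record_id = "b", fs = 128,
                      orientation = "channels_in_columns")
  expect_equal(unname(rec2$signal), sig, tolerance = 1e-12)

  ## 13 channels against a 14-channel montage
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.table(sig[1:13, ], path3, sep = ",", row.names = FALSE,
              col.names = FALSE)
  expect_error(load_record(path3, m, label = 1, fs = 128), "montage error")
  expect_error(load_record("no/such/file.csv", m, label = 1, fs = 128),
               "not found")
})

test_that("EDF files round-trip and channels are reordered to montage order", {
  m <- default_montage()
  set.seed(7)
  sig <- matrix(rnorm(14 * 256, sd = 20), nrow = 14)
  path <- withr::local_tempfile(fileext = ".edf")
  ## write with permuted channel order; the reader must restore montage order
  perm <- c(3, 1, 2, 5, 4, 7, 6, 9, 8, 11, 10, 13, 12, 14)
  soxfe:::write_edf(sig[perm, ], m$channel_names[perm], fs = 128, path)
  rec <- load_record(path, m, label = 2, record_id = "edf1")
  expect_equal(rec$fs, 128)
  ## int16 quantization: tolerance from the stored amplitude range
  expect_equal(unname(rec$signal), sig,
               tolerance = diff(range(sig)) / 65000)
  expect_equal(rownames(rec$signal), m$channel_names)
})

test_that("MATLAB v7.3 containers are read with MATLAB dimension order restored", {
  m <- default_montage()
  sig <- matrix(rnorm(14 * 1920), nrow = 14)
  path <- withr::local_tempfile(fileext = ".mat")
  ## v7.3 files are HDF5 with array dims reversed relative to MATLAB shape
  rhdf5::h5createFile(path)
  rhdf5::h5write(t(sig), path, "data")
  rhdf5::h5closeAll()
  rec <- load_record(path, m, label = 1, record_id = "mat1", fs = 128)
  expect_equal(unname(rec$signal), sig, tolerance = 1e-9)
})

test_that("manifest-driven loading reconstructs the dataset", {
  dir <- withr::local_tempdir()
  recs <- small_dataset(seed = 3, records_per_class = 2,
                        segments_per_record = 1)
  man <- write_dataset(recs, dir)
  loaded <- load_dataset(man, default_montage(), fs = 128)
  expect_length(loaded, 4L)
  expect_equal(vapply(loaded, function(r) r$record_id, ""),
               vapply(recs, function(r) r$record_id, ""))
  expect_equal(loaded[[1]]$signal, recs[[1]]$signal, tolerance = 1e-10)
  expect_equal(vapply(loaded, function(r) r$label, 0),
               vapply(recs, function(r) r$label, 0))
})
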