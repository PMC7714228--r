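# Container round-trips and label-preference rules for the NinaPro-style
# .mat reader/writer.

make_rec <- function(n_samples = 2000, n_channels = 12, seed = 42) {
  set.seed(seed)
  emg_recording(
    signal = matrix(rnorm(n_samples * n_channels), n_samples, n_channels),
    sampling_rate = 2000,
    movement_label = rep(c(0, 1, 1, 0, 2), length.out = n_samples),
    repetition_label = rep(c(0, 1, 2, 0, 1), length.out = n_samples),
    subject_id = "S7"
  )
}

test_that("write_fixture / read_recording round-trips signal bitwise and labels exactly", {
  rec <- make_rec()
  f <- withr::local_tempfile(fileext = ".mat")
  write_fixture(rec, f)
  back <- read_recording(f, subject_id = "S7")
  expect_identical(back$signal, rec$signal)
  expect_identical(back$movement_label, rec$movement_label)
  expect_identical(back$repetition_label, rec$repetition_label)
  expect_identical(back$channel_roles, rec$channel_roles)
  expect_equal(back$sampling_rate, rec$sampling_rate)
  expect_equal(ncol(back$signal), 12)
  expect_equal(nrow(back$signal), 2000)
})

test_that("reader preserves channel and sample order", {
  rec <- make_rec(n_samples = 50, n_channels = 4)
  f <- withr::local_tempfile(fileext = ".mat")
  write_fixture(rec, f)
  back <- read_recording(f)
  # a distinctive value planted at a known position survives in place
  expect_identical(back$signal[17, 3], rec$signal[17, 3])
  expect_identical(back$signal, rec$signal)
})

test_that("refined label vectors win over raw ones when they disagree", {
  rec <- make_rec(n_samples = 100, n_channels = 4)
  f <- withr::local_tempfile(fileext = ".mat")
  raw_labels <- rec$movement_label
  refined <- raw_labels
  refined[1:5] <- 9L
  write_mat5(list(
    emg = rec$signal,
    stimulus = matrix(as.double(raw_labels), ncol = 1),
    restimulus = matrix(as.double(refined), ncol = 1),
    repetition = matrix(as.double(rec$repetition_label), ncol = 1),
    frequency = matrix(2000)
  ), f)
  back <- read_recording(f)
  expect_identical(back$movement_label, refined)
  back_raw <- read_recording(f, prefer_refined = FALSE)
  expect_identical(back_raw$movement_label, raw_labels)
})

test_that("label vectors are flattened regardless of stored orientation", {
  rec <- make_rec(n_samples = 60, n_channels = 3)
  f <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(
    emg = rec$signal,
    stimulus = matrix(as.double(rec$movement_label), nrow = 1)  # row vector
  ), f)
  back <- read_recording(f)
  expect_identical(back$movement_label, rec$movement_label)
})

test_that("missing and mismatched arrays raise the stated errors", {
  rec <- make_rec(n_samples = 40, n_channels = 3)
  f <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(stimulus = matrix(as.double(rec$movement_label), ncol = 1)), f)
  expect_error(read_recording(f), "emg")
  write_mat5(list(emg = rec$signal), f)
  expect_error(read_recording(f), "stimulus")
  write_mat5(list(
    emg = rec$signal,
    stimulus = matrix(as.double(rec$movement_label[-1]), ncol = 1)  # 1 short
  ), f)
  expect_error(read_recording(f), "integrity")
})

test_that("degenerate recordings are refused", {
  expect_error(emg_recording(matrix(numeric(0), 0, 3), 2000, integer(0)),
               "0 samples")
  expect_error(emg_recording(matrix(1, 4, 2), 2000, c(0, 1, -1, 0)),
               "nonnegative")
  expect_error(emg_recording(matrix(1, 4, 2), 2000, c(0, 1, 1)), "length")
})

test_that("all-rest recordings round-trip with all-zero movement labels", {
  rec <- emg_recording(matrix(runif(100 * 2), 100, 2), 1000, rep(0L, 100))
  f <- withr::local_tempfile(fileext = ".mat")
  write_fixture(rec, f)
  back <- read_recording(f)
  expect_true(all(back$movement_label == 0L))
  expect_identical(back$signal, rec$signal)
})

test_that("channel-map config files parse and order by column index", {
  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# montage", "2=EDS", "1=FDS", "", "3=RING1"), f)
  expect_identical(read_channel_map(f), c("FDS", "EDS", "RING1"))
  writeLines(c("1=FDS", "1=EDS"), f)
  expect_error(read_channel_map(f), "unique")
})

test_that("mat5 reader handles compressed elements and rejects v7.3", {
  # compressed element: compress one matrix element by hand
  x <- matrix(as.double(1:6), 2, 3)
  f <- withr::local_tempfile(fileext = ".mat")
  write_mat5(list(a = x), f)
  r <- readBin(f, "raw", file.size(f))
  body <- r[129:length(r)]                      # the full miMATRIX element
  comp <- memCompress(body, "gzip")
  f2 <- withr::local_tempfile(fileext = ".mat")
  con <- file(f2, "wb")
  writeBin(r[1:128], con)
  writeBin(c(15L, length(comp)), con, size = 4L, endian = "little")
  writeBin(comp, con)
  close(con)
  expect_equal(read_mat5(f2)$a, x)
  f3 <- withr::local_tempfile(fileext = ".mat")
  writeBin(c(charToRaw("MATLAB 7.3 MAT-file"), raw(200)), f3)
  expect_error(read_mat5(f3), "7.3")
})
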