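test_that("eeg_recording validates its invariants", {
  expect_s3_class(eeg_recording(matrix(0, 2, 10), 100, c("A", "B")),
                  "eeg_recording")
  expect_error(eeg_recording(matrix(0, 2, 10), -1, c("A", "B")), "fs")
  expect_error(eeg_recording(matrix(0, 1, 10), 100, "A"), "2 channels")
  expect_error(eeg_recording(matrix(0, 2, 10), 100, c("A", "A")), "duplicate")
  expect_error(eeg_recording(matrix(c(NA, 0), 2, 10), 100, c("A", "B")),
               "non-finite")
  expect_error(eeg_recording(matrix(0, 2, 10), 100, "A"), "length")
})

test_that("hdf5 round trip is bit-identical, csv good to 9 significant digits", {
  rec <- noise_recording(3, fs = 200, duration_s = 2, seed = 42,
                         channel_names = c("F3", "F4", "CZ"))
  fh <- tempfile(fileext = ".h5")
  write_recording(rec, fh)
  r2 <- read_recording(fh)
  expect_identical(r2$data, rec$data)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$fs, rec$fs)

  fc <- tempfile(fileext = ".csv")
  write_recording(rec, fc)
  r3 <- read_recording(fc)
  expect_equal(r3$data, rec$data, tolerance = 1e-8, ignore_attr = TRUE)
  expect_identical(r3$channel_names, rec$channel_names)
})

test_that("edf round trip is exact to one quantization step", {
  rec <- sine_recording(5, amplitude = 100, duration_s = 2)
  rec$subject_id <- "subj01"
  fe <- tempfile(fileext = ".edf")
  write_recording(rec, fe)
  r2 <- read_recording(fe)
  step <- (500 - (-500)) / (32767 - (-32768))
  expect_lte(max(abs(r2$data - rec$data)), step)
  expect_equal(r2$fs, rec$fs)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_identical(r2$subject_id, "subj01")
  # out-of-range data widens the physical range instead of clipping
  big <- eeg_recording(matrix(c(-900, 900), 2, 100), 100, c("A", "B"))
  fb <- tempfile(fileext = ".edf")
  write_recording(big, fb)
  rb <- read_recording(fb)
  expect_lt(max(abs(rb$data - big$data)), 0.1)
})

test_that("csv loader rejects duplicate channel names and bad headers", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("# fs=100", "A,A", "1,2", "3,4"), f)
  expect_error(read_recording(f), "duplicate")
  writeLines(c("no fs line", "A,B", "1,2"), f)
  expect_error(read_recording(f), "fs")
})

test_that("packaged montages have the documented pair structure", {
  m62 <- default_montage("seed62")
  expect_length(m62$channel_order, 62)
  expect_equal(nrow(m62$hemispheric_pairs), 27)
  expect_equal(nrow(m62$frontal_posterior_pairs), 23)
  m32 <- default_montage("deap32")
  expect_length(m32$channel_order, 32)
  for (m in list(m62, m32)) {
    expect_true(all(m$hemispheric_pairs %in% m$channel_order))
    expect_true(all(m$frontal_posterior_pairs %in% m$channel_order))
  }
})

test_that("montage validation catches self-pairs and unknown channels", {
  expect_error(montage(c("F3", "F4"), rbind(c("F3", "F3")),
                       matrix(character(0), ncol = 2)),
               "itself")
  expect_error(montage(c("F3", "F4"), rbind(c("F3", "F8")),
                       matrix(character(0), ncol = 2)),
               "F8")
  expect_error(montage(c("F3", "F4"),
                       rbind(c("F3", "F4"), c("F3", "F4")),
                       matrix(character(0), ncol = 2)),
               "duplicate pair")
})

test_that("load_montage parses the config dialect and reports bad pairs", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("name: mini", "channel_order: A B C D",
               "hemispheric_pairs: A-B C-D",
               "frontal_posterior_pairs: A-C"), f)
  m <- load_montage(f)
  expect_equal(m$name, "mini")
  expect_equal(nrow(m$hemispheric_pairs), 2)
  writeLines(c("channel_order: A B", "hemispheric_pairs: A-Z"), f)
  expect_error(load_montage(f), "Z")
})

test_that("reorder_channels makes montage order authoritative", {
  m <- toy_montage()
  rec <- noise_recording(4, duration_s = 1,
                         channel_names = c("R2", "L1", "R1", "L2"))
  r2 <- reorder_channels(rec, m)
  expect_identical(r2$channel_names, m$channel_order)
  expect_identical(r2$data[1, ], rec$data[2, ])  # L1 was stored second
  rec_missing <- noise_recording(2, duration_s = 1,
                                 channel_names = c("L1", "R1"))
  expect_error(reorder_channels(rec_missing, m), "L2")
})

test_that("band_set enforces edge ordering; default is the five canonical bands", {
  b <- default_bands()
  expect_equal(b$name, c("delta", "theta", "alpha", "beta", "gamma"))
  expect_equal(b$low_hz, c(1, 4, 8, 14, 31))
  expect_equal(b$high_hz, c(3, 7, 13, 30, 50))
  expect_error(band_set("x", 5, 4), "low_hz")
  expect_error(band_set("x", 0, 4), "low_hz")
})
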