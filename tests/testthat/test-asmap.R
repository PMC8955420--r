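test_that("window_average groups epochs with the floor rule", {
  v <- array(rnorm(2 * 1 * 60), c(2, 1, 60))
  de <- structure(list(values = v, band_set = band_set("b", 1, 2),
                       channel_names = c("A", "B"), epoch_len_s = 1,
                       smoothed = FALSE, span = NA_integer_),
                  class = "de_features")
  expect_equal(dim(window_average(de, 3)$values)[3], 20)
  expect_equal(dim(window_average(de, 7)$values)[3], 8)   # floor(60/7)
  expect_error(window_average(de, 2.5), "multiple")
  expect_error(window_average(de, 120), "no complete window")
  # averaging: epochs 1,2,3 valued 1,2,3 -> 2
  v[1, 1, 1:3] <- c(1, 2, 3)
  de$values <- v
  expect_equal(window_average(de, 3)$values[1, 1, 1], 2)
})

test_that("raw AsMap equals the brute-force all-pairs difference table", {
  set.seed(21)
  de_vals <- array(rnorm(4 * 2 * 3), c(4, 2, 3),
                   dimnames = list(NULL, c("alpha", "gamma"), NULL))
  wd <- toy_windowed(de_vals, c("L1", "R1", "L2", "R2"))
  a <- build_asmap(wd, 2, "all")
  av <- unname(a$values)
  dv <- unname(de_vals)
  for (k in 1:2) for (i in 1:4) for (j in 1:4)
    expect_identical(av[i, j, k], dv[i, k, 2] - dv[j, k, 2])
  # antisymmetry and zero diagonal, exact
  for (k in 1:2) {
    expect_identical(av[, , k] + t(av[, , k]), matrix(0, 4, 4))
    expect_identical(diag(av[, , k]), rep(0, 4))
  }
})

test_that("AsMap on a known DE column matches hand arithmetic", {
  wd <- toy_windowed(array(c(2, 1, 0), c(3, 1, 1)), c("A", "B", "C"),
                     band_names = "gamma")
  a <- build_asmap(wd, 1)
  expect_equal(a$values[, , 1],
               rbind(c(0, 1, 2), c(-1, 0, 1), c(-2, -1, 0)),
               ignore_attr = TRUE)
  # constant DE -> all-zero map; adding a constant changes nothing
  wd0 <- toy_windowed(array(5, c(3, 1, 1)), c("A", "B", "C"))
  expect_true(all(build_asmap(wd0, 1)$values == 0))
  wd_c <- toy_windowed(array(c(2, 1, 0) + 11.3, c(3, 1, 1)), c("A", "B", "C"))
  expect_equal(build_asmap(wd_c, 1)$values, a$values, ignore_attr = TRUE)
})

test_that("build_asmap validates window index and band names", {
  wd <- toy_windowed(array(0, c(2, 1, 2)), c("A", "B"), band_names = "gamma")
  expect_error(build_asmap(wd, 3), "out of range")
  expect_error(build_asmap(wd, 1, "sigma"), "unknown band")
})

test_that("normalization maps to [0,1] with the documented conventions", {
  wd <- toy_windowed(array(c(2, 1, 0), c(3, 1, 1)), c("A", "B", "C"))
  n <- normalize_asmap(build_asmap(wd, 1))
  expect_equal(n$values[, , 1],
               rbind(c(0.5, 0.75, 1), c(0.25, 0.5, 0.75), c(0, 0.25, 0.5)),
               ignore_attr = TRUE)
  expect_true(n$normalized)
  # constant slice -> 0.5 everywhere
  wd0 <- toy_windowed(array(1, c(3, 1, 1)), c("A", "B", "C"))
  expect_true(all(normalize_asmap(build_asmap(wd0, 1))$values == 0.5))
  # scale invariance of min-max
  wd_s <- toy_windowed(array(c(2, 1, 0) * 7, c(3, 1, 1)), c("A", "B", "C"))
  expect_equal(normalize_asmap(build_asmap(wd_s, 1))$values, n$values,
               ignore_attr = TRUE)
})

test_that("normalized AsMap satisfies v[i,j] + v[j,i] = 1 (property)", {
  set.seed(31)
  for (rep in 1:5) {
    vals <- array(rnorm(5 * 3 * 2), c(5, 3, 2),
                  dimnames = list(NULL, c("b1", "b2", "b3"), NULL))
    wd <- toy_windowed(vals, paste0("C", 1:5))
    n <- normalize_asmap(build_asmap(wd, 1))
    expect_true(all(n$values >= 0 & n$values <= 1))
    for (k in 1:3) {
      s <- unname(n$values[, , k])
      expect_equal(s + t(s), matrix(1, 5, 5), tolerance = 1e-12)
      expect_equal(range(s), c(0, 1))
    }
  }
})

test_that("baseline definitions: DASM difference, RASM ratio, DCAU caudality", {
  de_vals <- array(0, c(4, 1, 1), dimnames = list(NULL, "gamma", NULL))
  de_vals[, 1, 1] <- c(2, 0.5, 3, 3)  # L1=2 R1=0.5 L2=3 R2=3
  wd <- toy_windowed(de_vals, c("L1", "R1", "L2", "R2"))
  m <- toy_montage()
  dasm <- baseline_features(wd, 1, "DASM", m)
  expect_equal(unname(dasm$values), c(1.5, 0))
  rasm <- baseline_features(wd, 1, "RASM", m)
  expect_equal(unname(rasm$values), c(4, 1))
  expect_false(rasm$capped)
  dcau <- baseline_features(wd, 1, "DCAU", m)
  expect_equal(unname(dcau$values), 2 - 3)
  de <- baseline_features(wd, 1, "DE", m)
  expect_equal(unname(de$values), c(2, 0.5, 3, 3))
})

test_that("RASM guards a near-zero divisor with a sign-preserving cap", {
  de_vals <- array(c(1, 1e-12, -2, -1e-12), c(4, 1, 1),
                   dimnames = list(NULL, "gamma", NULL))
  wd <- toy_windowed(de_vals, c("L1", "R1", "L2", "R2"))
  r <- baseline_features(wd, 1, "RASM", toy_montage())
  expect_true(r$capped)
  expect_equal(unname(r$values), c(1e9, -1e9 * -2 / 2))
  expect_true(all(is.finite(r$values)))
})

test_that("62-channel baselines have the canonical dimensions", {
  set.seed(41)
  m <- default_montage("seed62")
  vals <- array(rnorm(62 * 5 * 2), c(62, 5, 2),
                dimnames = list(NULL, default_bands()$name, NULL))
  wd <- toy_windowed(vals, m$channel_order)
  lens <- vapply(c("DE", "DASM", "RASM", "DCAU"), function(meth)
    baseline_features(wd, 1, meth, m)$length, 0L)
  expect_equal(unname(lens), c(310L, 135L, 135L, 115L))
})

test_that("DASM and DCAU are exact sub-samples of the raw AsMap", {
  set.seed(43)
  m <- default_montage("seed62")
  vals <- array(rnorm(62 * 5 * 1), c(62, 5, 1),
                dimnames = list(NULL, default_bands()$name, NULL))
  wd <- toy_windowed(vals, m$channel_order)
  a <- build_asmap(wd, 1, "all")
  ih_l <- match(m$hemispheric_pairs[, 1], m$channel_order)
  ih_r <- match(m$hemispheric_pairs[, 2], m$channel_order)
  dasm <- baseline_features(wd, 1, "DASM", m)$values
  for (k in 1:5) {
    idx <- seq(k, by = 5, length.out = 27)  # pair-major, band-minor
    expect_identical(unname(dasm[idx]), unname(a$values[cbind(ih_l, ih_r, k)]))
  }
  if_f <- match(m$frontal_posterior_pairs[, 1], m$channel_order)
  if_p <- match(m$frontal_posterior_pairs[, 2], m$channel_order)
  dcau <- baseline_features(wd, 1, "DCAU", m)$values
  for (k in 1:5) {
    idx <- seq(k, by = 5, length.out = 23)
    expect_identical(unname(dcau[idx]), unname(a$values[cbind(if_f, if_p, k)]))
  }
})

test_that("raw AsMap is invariant under a common input gain", {
  rec <- noise_recording(4, fs = 128, duration_s = 6, seed = 17,
                         channel_names = c("L1", "R1", "L2", "R2"))
  rec2 <- eeg_recording(5 * rec$data, rec$fs, rec$channel_names)
  a1 <- build_asmap(window_average(compute_de_features(rec), 3), 1)
  a2 <- build_asmap(window_average(compute_de_features(rec2), 3), 1)
  expect_equal(a1$values, a2$values, tolerance = 1e-9)
})

test_that("asmap serialization and PGM export round-trip", {
  wd <- toy_windowed(array(rnorm(8), c(4, 2, 1),
                           dimnames = list(NULL, c("alpha", "gamma"), NULL)),
                     c("L1", "R1", "L2", "R2"))
  a <- normalize_asmap(build_asmap(wd, 1))
  f <- tempfile(fileext = ".h5")
  write_asmap(a, f)
  a2 <- read_asmap(f)
  expect_equal(a2$values, a$values)
  expect_identical(a2$band_names, a$band_names)
  expect_true(a2$normalized)
  pgm <- tempfile(fileext = ".pgm")
  export_asmap_pgm(a, pgm, band = "gamma")
  lines <- readLines(pgm)
  expect_identical(lines[1], "P2")
  expect_identical(lines[2], "4 4")
  vals <- scan(pgm, skip = 3, quiet = TRUE)
  expect_true(all(vals >= 0 & vals <= 255))
})

test_that("build_asmap_stack stacks normalized per-window maps", {
  set.seed(51)
  vals <- array(rnorm(4 * 2 * 6), c(4, 2, 6),
                dimnames = list(NULL, c("alpha", "gamma"), NULL))
  wd <- toy_windowed(vals, c("L1", "R1", "L2", "R2"))
  st <- build_asmap_stack(wd, "gamma")
  expect_equal(dim(st), c(4, 4, 1, 6))
  expect_true(all(st >= 0 & st <= 1))
  expect_equal(st[, , 1, 3],
               unname(normalize_asmap(build_asmap(wd, 3, "gamma"))$values[, , 1]))
})
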