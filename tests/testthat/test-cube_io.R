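test_that("ENVI write/read round-trips identically for every interleave", {
  cube <- tiny_cube(3L, 4L, 5L, wl = c(450, 500, 625, 700, 800))
  for (il in c("bsq", "bil", "bip")) {
    path <- tempfile(fileext = ".dat")
    write_cube(cube, path, format = "envi", interleave = il)
    back <- read_cube(path)
    expect_identical(back$data, cube$data, info = il)
    expect_equal(back$wavelengths, cube$wavelengths, info = il)
    unlink(c(path, paste0(path, ".hdr")))
  }
})

test_that("rds container round-trips data, axis and meta", {
  cube <- tiny_cube(2L, 2L, 3L)
  cube$meta$note <- "fixture"
  path <- tempfile(fileext = ".rds")
  write_cube(cube, path, format = "rds")
  back <- read_cube(path)
  expect_identical(back$data, cube$data)
  expect_identical(back$meta$note, "fixture")
})

test_that("malformed ENVI inputs are hard errors", {
  cube <- tiny_cube(2L, 2L, 3L)
  path <- tempfile(fileext = ".dat")
  write_cube(cube, path, format = "envi")

  # band count in header inconsistent with wavelength list
  hdr <- readLines(paste0(path, ".hdr"))
  writeLines(sub("^bands = 3", "bands = 4", hdr), paste0(path, ".hdr"))
  expect_error(read_cube(path), "wavelengths")

  # truncated binary
  writeLines(hdr, paste0(path, ".hdr"))
  bin <- readBin(path, "raw", n = file.info(path)$size)
  writeBin(bin[-seq_len(8)], path)
  expect_error(read_cube(path), "inconsistent")

  # header without a wavelength array
  path2 <- tempfile(fileext = ".dat")
  write_cube(cube, path2, format = "envi")
  hdr2 <- readLines(paste0(path2, ".hdr"))
  writeLines(hdr2[!grepl("^wavelength =", hdr2)], paste0(path2, ".hdr"))
  expect_error(read_cube(path2), "wavelength")
})

test_that("hypercube constructor enforces axis/band consistency", {
  expect_error(hypercube(array(0, c(2, 2, 3)), c(450, 500)), "band count")
  expect_error(hypercube(array(0, c(2, 2, 2)), c(500, 450)), "increasing")
  expect_error(hypercube(matrix(0, 2, 2), c(450, 500)), "3-D")
})

test_that("reflectance calibration hits reference points and flags invalid pixels", {
  wl <- c(500, 600, 700)
  dark <- hypercube(array(0.1, c(2, 2, 3)), wl)
  white <- hypercube(array(0.9, c(2, 2, 3)), wl)

  r1 <- reflectance_calibrate(white, white, dark)
  expect_true(all(r1$data == 1))
  r0 <- reflectance_calibrate(dark, white, dark)
  expect_true(all(r0$data == 0))
  mid <- hypercube((white$data + dark$data) / 2, wl)
  rm_ <- reflectance_calibrate(mid, white, dark)
  expect_true(all(abs(rm_$data - 0.5) < 1e-12))

  # gain invariance: common positive gain leaves R unchanged
  gain <- 3.7
  raw <- hypercube(array(runif(12, 0.2, 0.8), c(2, 2, 3)), wl)
  a <- reflectance_calibrate(raw, white, dark)
  b <- reflectance_calibrate(hypercube(raw$data * gain, wl),
                             hypercube(white$data * gain, wl),
                             hypercube(dark$data * gain, wl))
  expect_equal(a$data, b$data, tolerance = 1e-12)

  # white <= dark pixels become NaN and are counted
  badwhite <- white
  badwhite$data[1, 1, 1] <- 0.05
  rb <- reflectance_calibrate(raw, badwhite, dark)
  expect_true(is.nan(rb$data[1, 1, 1]))
  expect_identical(rb$meta$n_invalid, 1L)

  # negative reflectance clamped to zero
  below <- hypercube(array(0.05, c(2, 2, 3)), wl)
  rc <- reflectance_calibrate(below, white, dark)
  expect_true(all(rc$data[!is.nan(rc$data)] >= 0))
})

test_that("mean_spectrum matches a brute-force pixel loop and is additive over regions", {
  set.seed(42)
  nr <- 6L; nc <- 7L; nb <- 4L
  a <- array(runif(nr * nc * nb), c(nr, nc, nb))
  cube <- hypercube(a, seq(450, 800, length.out = nb))
  labels <- matrix(0L, nr, nc)
  labels[2:4, 2:3] <- 1L
  labels[5:6, 5:7] <- 2L
  mask <- leaf_mask(labels > 0L, labels)

  sp1 <- mean_spectrum(cube, mask, 1L)
  for (b in seq_len(nb)) {
    vals <- c()
    for (r in 2:4) for (cc in 2:3) vals <- c(vals, a[r, cc, b])
    expect_equal(sp1$mean_reflectance[b], mean(vals), tolerance = 1e-12)
    expect_equal(sp1$sd_reflectance[b], sd(vals), tolerance = 1e-12)
  }

  # union mean equals the pixel-count-weighted mean of region means
  sp2 <- mean_spectrum(cube, mask, 2L)
  spu <- mean_spectrum(cube, mask, NULL)
  n1 <- 6; n2 <- 6
  expect_equal(spu$mean_reflectance,
               (n1 * sp1$mean_reflectance + n2 * sp2$mean_reflectance) /
                 (n1 + n2),
               tolerance = 1e-10)

  # constant field: mean = value, sd = 0
  const <- hypercube(array(0.3, c(nr, nc, nb)), cube$wavelengths)
  spc <- mean_spectrum(const, mask, 1L)
  expect_true(all(spc$mean_reflectance == 0.3))
  expect_true(all(spc$sd_reflectance == 0))
})

test_that("non-finite pixels are excluded from means", {
  a <- array(0.5, c(2, 2, 2))
  a[1, 1, 1] <- NaN
  cube <- hypercube(a, c(500, 600))
  mask <- leaf_mask(matrix(TRUE, 2, 2))
  sp <- mean_spectrum(cube, mask, 1L)
  expect_equal(sp$mean_reflectance, c(0.5, 0.5))
  expect_equal(sp$n_pixels, c(3L, 4L))
})
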