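test_that("PNG round trip is exact for raw8 images", {
  m <- matrix(c(0, 85, 170, 255), 2, 2)
  p <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(m, "raw8"), p)
  back <- read_image(p)
  expect_identical(as.matrix(back), m)
  expect_equal(range_tag(back), "raw8")

  r <- rand_raw8(37, 53, seed = 11)
  write_image(gray_image(r, "raw8"), p)
  expect_identical(as.matrix(read_image(p)), r)
})

test_that("TIFF round trip is exact for raw8 images", {
  r <- rand_raw8(21, 34, seed = 12)
  p <- withr::local_tempfile(fileext = ".tiff")
  write_image(gray_image(r, "raw8"), p)
  expect_identical(as.matrix(read_image(p)), r)
})

test_that("unit images are quantized round-half-up on write", {
  p <- withr::local_tempfile(fileext = ".png")
  img <- gray_image(matrix(0.5, 4, 4), "unit")  # 127.5 -> 128
  write_image(img, p)
  expect_true(all(as.matrix(read_image(p)) == 128))
})

test_that("I/O error paths are reported as I/O errors", {
  expect_error(read_image(file.path(tempdir(), "nope.png")),
               class = "ncfuse_io_error")
  # truncated file
  p <- withr::local_tempfile(fileext = ".png")
  write_image(gray_image(rand_raw8(8, 8, 1), "raw8"), p)
  bytes <- readBin(p, "raw", file.size(p))
  writeBin(bytes[1:20], p)
  expect_error(read_image(p), class = "ncfuse_io_error")
  # not an image at all
  writeLines("hello", p)
  expect_error(read_image(p), class = "ncfuse_io_error")
  # unwritable destination
  expect_error(
    write_image(gray_image(matrix(0, 2, 2), "raw8"),
                file.path(tempdir(), "no_such_dir", "x.png")),
    class = "ncfuse_io_error")
})

test_that("gray_image validates range and shape", {
  expect_error(gray_image(matrix(-1, 2, 2), "raw8"),
               class = "ncfuse_validation_error")
  expect_error(gray_image(matrix(2, 2, 2), "unit"),
               class = "ncfuse_validation_error")
  expect_error(gray_image(matrix(1, 1, 5), "unit"),
               class = "ncfuse_validation_error")
  expect_error(gray_image(matrix(NA_real_, 2, 2), "unit"),
               class = "ncfuse_validation_error")
})

test_that("phantom generation is a pure function of its spec", {
  s <- phantom_spec(size = c(48, 48), seed = 33, noise_sigma = 0)
  p1 <- generate_phantom_pair(s)
  p2 <- generate_phantom_pair(s)
  expect_identical(as.matrix(p1$ct), as.matrix(p2$ct))
  expect_identical(as.matrix(p1$mri), as.matrix(p2$mri))
  # with noise too
  sn <- phantom_spec(size = c(48, 48), seed = 33, noise_sigma = 0.05)
  expect_identical(as.matrix(generate_phantom_pair(sn)$ct),
                   as.matrix(generate_phantom_pair(sn)$ct))
})

test_that("phantom CT ring is brighter than its interior and differs from MRI", {
  pair <- fixture_pair_default()
  msk <- ncfuse:::phantom_masks(256L, 256L)
  ct <- as.matrix(pair$ct)
  expect_gt(mean(ct[msk$ring]), mean(ct[msk$interior]))
  # frozen regression: mean absolute CT/MRI difference of the default spec
  mad_ab <- mean(abs(ct - as.matrix(pair$mri)))
  expect_gt(mad_ab, 0)
  expect_equal(mad_ab, 42.28291, tolerance = 1e-6)
})

test_that("phantom spec validation rejects bad fields", {
  expect_error(phantom_spec(size = c(16, 64)), class = "ncfuse_validation_error")
  expect_error(phantom_spec(noise_sigma = -1), class = "ncfuse_validation_error")
  expect_error(phantom_spec(bone_intensity = 0), class = "ncfuse_validation_error")
  expect_error(phantom_spec(tissue_contrast = 1.5), class = "ncfuse_validation_error")
})

test_that("add_noise is seeded, sized correctly, and clipped", {
  img <- gray_image(matrix(128, 256, 256), "raw8")
  expect_identical(add_noise(img, 0, 5), img)
  n1 <- add_noise(img, 10, seed = 5)
  n2 <- add_noise(img, 10, seed = 5)
  expect_identical(as.matrix(n1), as.matrix(n2))
  # mid-gray is far from clipping: empirical std within 5% of sigma
  resid <- as.matrix(n1) - 128
  expect_equal(stats::sd(resid), 10, tolerance = 0.05)
  expect_error(add_noise(img, -1), class = "ncfuse_validation_error")
  # clipping keeps the declared range even at extreme sigma
  extreme <- add_noise(gray_image(matrix(0.5, 16, 16), "unit"), 50, seed = 1)
  expect_true(all(as.matrix(extreme) >= 0 & as.matrix(extreme) <= 1))
})

test_that("add_noise leaves the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(add_noise(gray_image(matrix(0.5, 8, 8), "unit"), 0.1, seed = 2))
  expect_identical(.Random.seed, before)
})
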