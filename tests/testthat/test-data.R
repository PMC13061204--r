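# Phantom generation, pairing, splitting, and I/O.

test_that("phantom generation is a pure function of its config", {
  a <- generate_phantom(phantom_config(size = 64, seed = 42))
  b <- generate_phantom(phantom_config(size = 64, seed = 42))
  expect_identical(a, b)
  expect_false(identical(a, generate_phantom(phantom_config(size = 64, seed = 43))))
  expect_true(all(a >= 0 & a <= 1))
  expect_identical(dim(a), c(64L, 64L))
  # generation must not disturb the caller's RNG stream
  set.seed(7); r1 <- runif(3)
  set.seed(7); invisible(generate_phantom(phantom_config(size = 32, seed = 1)))
  expect_identical(runif(3), r1)
})

test_that("degenerate phantom config yields the uniform background", {
  ph <- generate_phantom(phantom_config(size = 32, n_ellipses = 0,
                                        texture_amp = 0, bias_amp = 0,
                                        noise_sd = 0, seed = 1))
  expect_true(all(ph == ph[1, 1]))
})

test_that("phantoms with >= 3 separated tissue classes have >= 3 intensity modes", {
  ph <- generate_phantom(phantom_config(size = 128, n_ellipses = 4,
                                        texture_amp = 0.005, bias_amp = 0,
                                        noise_sd = 0.005, seed = 8))
  d <- density(ph, bw = 0.02)
  peaks <- sum(diff(sign(diff(d$y))) == -2)
  expect_gte(peaks, 3)
})

test_that("pair construction enforces the published degradation geometry", {
  pairs <- make_phantom_pairs(10, size = 64, scale = 2)
  expect_length(pairs, 10)
  for (p in pairs) {
    expect_identical(dim(p$lr), c(32L, 32L))
    expect_identical(dim(p$hr), c(64L, 64L))
    expect_true(all(p$lr >= 0 & p$lr <= 1))
  }
  # reproducible bit-for-bit
  again <- make_phantom_pairs(10, size = 64, scale = 2)
  expect_identical(lapply(pairs, `[[`, "lr"), lapply(again, `[[`, "lr"))
  expect_error(build_pairs(list(matrix(0.5, 63, 64)), scale = 2), "divisible")
  expect_error(slice_pair(matrix(0.5, 8, 8), matrix(2, 4, 4)), "\\[0, 1\\]")
})

test_that("volume-level split is exhaustive, disjoint, seeded, and sized 70/10/20", {
  ids <- sprintf("v%02d", 1:10)
  sp <- split_dataset(ids, seed = 3)
  expect_length(sp$train, 7); expect_length(sp$val, 1); expect_length(sp$test, 2)
  expect_setequal(c(sp$train, sp$val, sp$test), ids)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_identical(sp, split_dataset(ids, seed = 3))
  expect_false(identical(sp, split_dataset(ids, seed = 4)))
  expect_error(split_dataset(c("a", "b"), c(0.7, 0.1, 0.2)), "fewer volumes")
  expect_error(split_dataset(ids, c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(split_dataset(c("a", "a", "b"), seed = 1), "distinct")
})

test_that("NIfTI volumes round-trip and slice along the last axis", {
  tmp <- tempfile(fileext = ".nii.gz")
  vol <- array(runif(8 * 8 * 4), c(8, 8, 4))
  write_image(vol, tmp)
  rv <- read_volume(tmp, modality = "T2")
  expect_identical(rv$record$shape, c(8L, 8L, 4L))
  expect_identical(rv$record$modality, "T2")
  expect_equal(rv$data, vol, tolerance = 1e-6)
  sl <- volume_slices(rv)
  expect_length(sl, 4)
  expect_equal(sl[[2]], vol[, , 2], tolerance = 1e-6)
  expect_error(read_volume(tempfile(fileext = ".nii")), "exist")
  # non-3D volume is a dimensionality error
  tmp4 <- tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 2, 2))), tmp4)
  expect_error(read_volume(tmp4), "3D")
})

test_that("an IXI-shaped volume yields 96 slices of 256x256", {
  tmp <- tempfile(fileext = ".nii.gz")
  vol <- array(runif(256 * 256 * 96), c(256, 256, 96))
  write_image(vol, tmp)
  rv <- read_volume(tmp)
  expect_identical(rv$record$shape, c(256L, 256L, 96L))
  expect_length(volume_slices(rv), 96)
  unlink(tmp)
})

test_that("PNG slices round-trip within quantization tolerance", {
  tmp <- tempfile(fileext = ".png")
  img <- matrix(runif(32 * 32), 32, 32)
  write_image(img, tmp)
  back <- read_image(tmp)
  expect_identical(dim(back), dim(img))
  expect_lt(max(abs(back - img)), 1 / 255)
  # a directory of PNGs reads as a volume
  dir <- file.path(tempdir(), "slices"); dir.create(dir, showWarnings = FALSE)
  for (i in 1:3) write_image(matrix(i / 10, 16, 16), file.path(dir, sprintf("s%02d.png", i)))
  rv <- read_volume(dir)
  expect_identical(rv$record$shape, c(16L, 16L, 3L))
  unlink(dir, recursive = TRUE)
})

test_that("split manifests record every volume with its assignment", {
  tmp <- tempfile(fileext = ".csv")
  sp <- split_dataset(sprintf("v%02d", 1:10), seed = 2, manifest = tmp)
  tab <- read.csv(tmp)
  expect_setequal(tab$volume_id, sprintf("v%02d", 1:10))
  expect_identical(sort(tab$volume_id[tab$split == "train"]), sort(sp$train))
  unlink(tmp)
})
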