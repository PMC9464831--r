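test_that("generation is seed-reproducible and mask-registered", {
  sp <- synth_spec(size = 64, seed = 9)
  d1 <- generate_dataset(sp, 4)
  d2 <- generate_dataset(sp, 4)
  expect_identical(d1, d2)
  for (p in d1) {
    expect_equal(dim(p$image), c(64L, 64L, 3L))
    expect_equal(dim(p$mask), c(64L, 64L))
    expect_true(all(p$mask %in% c(0L, 1L)))
    expect_true(all(p$image >= 0 & p$image <= 1))
  }
  # different seed changes the stream
  expect_false(identical(generate_dataset(synth_spec(size = 64, seed = 10), 1),
                         d1[1]))
})

test_that("a zero lesion count produces all-background masks", {
  sp <- synth_spec(size = 64, lesion_count = c(0L, 0L), seed = 3)
  ds <- generate_dataset(sp, 3)
  expect_true(all(vapply(ds, function(p) sum(p$mask), numeric(1)) == 0))
})

test_that("the empirical foreground fraction tracks the requested lesion sizes", {
  # a specification aimed at roughly a fifth of the image being lesion
  sp <- synth_spec(size = 64, lesion_count = c(1L, 3L),
                   lesion_radius = c(0.12, 0.28), seed = 1)
  fr <- mean(vapply(generate_dataset(sp, 40), function(p) mean(p$mask), numeric(1)))
  expect_gt(fr, 0.1)
  expect_lt(fr, 0.3)
})

test_that("infeasible lesion specifications are rejected", {
  expect_error(synth_spec(size = 64, lesion_radius = c(0.6, 0.7)), "lesion_radius")
  expect_error(synth_spec(size = 60), "divisible by 32")
})

test_that("flips are involutions applied jointly to image and mask", {
  p <- tiny_dataset(1, size = 64)[[1]]
  expect_equal(augment(augment(p, "hflip"), "hflip"), p)
  expect_equal(augment(augment(p, "vflip"), "vflip"), p)
  # a foreground pixel at (r, c) lands at (r, width - 1 - c) 0-based
  h <- augment(p, "hflip")
  idx <- which(p$mask == 1L, arr.ind = TRUE)[1, ]
  expect_equal(h$mask[idx["row"], ncol(p$mask) + 1 - idx["col"]], 1L)
  expect_equal(h$image[idx["row"], ncol(p$mask) + 1 - idx["col"], ],
               p$image[idx["row"], idx["col"], ])
  expect_error(augment(p, "rot90"), "unknown augmentation")
})

test_that("sample centering zeroes the image mean and leaves the mask alone", {
  p <- tiny_dataset(1, size = 64)[[1]]
  cen <- augment(p, "center")
  expect_equal(mean(cen$image), 0, tolerance = 1e-6)
  expect_identical(cen$mask, p$mask)
})

test_that("splitting is disjoint, exhaustive and seed-stable", {
  ds <- tiny_dataset(10, size = 32)
  sp <- split_dataset(ds, 0.8, seed = 2)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  ids <- function(x) vapply(x, `[[`, character(1), "id")
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0L)
  expect_setequal(c(ids(sp$train), ids(sp$test)), ids(ds))
  sp2 <- split_dataset(ds, 0.8, seed = 2)
  expect_identical(ids(sp2$train), ids(sp$train))
  expect_error(split_dataset(ds[1], 0.8), "too small")
  expect_error(split_dataset(ds, 1.2), "ratio")
})

test_that("resizing keeps masks binary and approximately preserves area", {
  p <- tiny_dataset(1, size = 64)[[1]]
  expect_identical(resize_pair(p, 64), p)
  down <- resize_pair(p, 32)
  expect_true(all(down$mask %in% c(0L, 1L)))
  expect_equal(dim(down$image), c(32L, 32L, 3L))
  # a centred square lesion keeps its area fraction through resizing
  sq <- p
  sq$mask <- matrix(0L, 64, 64); sq$mask[17:48, 17:48] <- 1L
  expect_equal(mean(resize_pair(sq, 32)$mask), 0.25, tolerance = 0.02)
  expect_equal(mean(resize_pair(sq, 128)$mask), 0.25, tolerance = 0.02)
})

test_that("datasets survive a PNG round-trip", {
  dir <- withr::local_tempdir()
  ds <- tiny_dataset(3, size = 32)
  write_dataset(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_dataset(dir)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, ds[[i]]$mask)
    expect_lt(max(abs(back[[i]]$image - ds[[i]]$image)), 1 / 255)
    expect_equal(back[[i]]$id, ds[[i]]$id)
  }
})
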