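test_that("normalize_and_clip standardizes then clips to the asymmetric range", {
  # hand oracle on 1..27: mean 14, sample SD from the definition
  x <- array(1:27, c(3, 3, 3))
  m <- mean(1:27)
  s <- sqrt(sum((1:27 - m)^2) / 26)
  z_expect <- pmin(pmax((x - m) / s, -1), 2.5)
  out <- normalize_and_clip(as_volume(x))
  expect_equal(out$data, z_expect, tolerance = 1e-12)

  # an extreme outlier ends up exactly at the clip bounds
  y <- array(rnorm(1000), c(10, 10, 10))
  y[1] <- -1e6; y[2] <- 1e6
  out <- normalize_and_clip(as_volume(y), -1, 2.5)
  expect_gte(min(out$data), -1)
  expect_lte(max(out$data), 2.5)
  expect_equal(out$data[1], -1)
  expect_equal(out$data[2], 2.5)

  # near-identity on standard-normal data with infinite clip range
  set.seed(1)
  z <- array(rnorm(4000), c(20, 20, 10))
  out <- normalize_and_clip(as_volume(z), -Inf, Inf)
  expect_equal(out$data, (z - mean(z)) / sd(z), tolerance = 1e-12)

  expect_error(normalize_and_clip(as_volume(array(3, c(2, 2, 2)))),
               "constant")
  expect_error(normalize_and_clip(as_volume(array(rnorm(8), c(2, 2, 2))),
                                  2, -1), "clip_lo")
})

test_that("normalize_and_clip is idempotent on standardized data inside the clip range", {
  # skewed two-point mixture: after standardization all values sit in
  # [-1, 2.5], so a second pass must reproduce the input exactly
  set.seed(2)
  x0 <- c(rnorm(750, -0.5, 0.02), rnorm(250, 1.5, 0.02))
  x <- (x0 - mean(x0)) / sd(x0)
  stopifnot(min(x) >= -1, max(x) <= 2.5)
  v <- as_volume(array(x, c(10, 10, 10)))
  v2 <- normalize_and_clip(v)
  expect_equal(v2$data, v$data, tolerance = 1e-6)
})

test_that("crop_patch extracts the exact half-open box and records origin", {
  set.seed(3)
  vol <- as_volume(array(rnorm(24 * 30 * 20), c(24, 30, 20)))

  whole <- crop_patch(vol, c(0, 0, 0), c(24, 30, 20))
  expect_identical(whole$data, vol$data)
  expect_identical(whole$origin, c(0L, 0L, 0L))

  # marked voxel: 0-based source (6, 7, 6), corner (2, 3, 2) -> patch (4, 4, 4)
  vol$data[7, 8, 7] <- 1e6
  p <- crop_patch(vol, c(2, 3, 2), c(10, 10, 10))
  expect_equal(dim(p$data), c(10, 10, 10))
  expect_equal(p$data[5, 5, 5], 1e6)
  expect_equal(which(p$data == 1e6), which(array(seq_len(1000),
               c(10, 10, 10)) == ((5 - 1) + (5 - 1) * 10 + (5 - 1) * 100 + 1)))

  # voxel-for-voxel equality with direct slicing
  expect_equal(p$data, vol$data[3:12, 4:13, 3:12])

  err <- expect_error(crop_patch(vol, c(20, 0, 0), c(10, 5, 5)), "axis 1")
  expect_error(crop_patch(vol, c(0, 28, 0), c(5, 5, 5)), "axis 2")
})

test_that("NIfTI round-trip preserves phantom voxels bitwise", {
  s <- tiny_cohort(n_per_class = 1)[[1]]
  path <- tempfile(fileext = ".nii.gz")
  write_volume(s$patch$data, path)
  back <- read_volume(path)
  p <- crop_patch(back, c(0, 0, 0), back$shape)
  expect_identical(p$data, s$patch$data)
  unlink(path)
})

test_that("load_cohort reads rows in order and reports rejects", {
  dir <- tempfile(); dir.create(dir)
  co <- tiny_cohort(n_per_class = 2)
  write_cohort(co, dir)

  out <- load_cohort(dir, file.path(dir, "cohort.csv"), clip = NULL)
  expect_length(out$samples, 4)
  expect_equal(nrow(out$rejects), 0)
  expect_equal(vapply(out$samples, function(s) s$subject_id, ""),
               vapply(co, function(s) s$subject_id, ""))
  # metric vector round-trips in column order
  expect_equal(out$samples[[1]]$morph, co[[1]]$morph, tolerance = 1e-12)
  expect_equal(out$metric_cols, c("m1", "m2", "m3"))

  # a missing image becomes a reject, not a failure
  tab <- read.csv(file.path(dir, "cohort.csv"))
  tab <- rbind(tab, data.frame(subject_id = "GHOST", label = 1,
                               m1 = 0, m2 = 0, m3 = 0))
  write.csv(tab, file.path(dir, "cohort2.csv"), row.names = FALSE)
  out2 <- load_cohort(dir, file.path(dir, "cohort2.csv"), clip = NULL)
  expect_length(out2$samples, 4)
  expect_equal(out2$rejects$subject_id, "GHOST")

  # malformed labels are rejected too
  tab$label[1] <- 7
  write.csv(tab, file.path(dir, "cohort3.csv"), row.names = FALSE)
  out3 <- load_cohort(dir, file.path(dir, "cohort3.csv"), clip = NULL)
  expect_length(out3$samples, 3)
  expect_true("malformed label" %in% out3$rejects$reason)

  # duplicate ids and empty tables fail loudly
  tab2 <- read.csv(file.path(dir, "cohort.csv"))
  write.csv(rbind(tab2, tab2[1, ]), file.path(dir, "dup.csv"),
            row.names = FALSE)
  expect_error(load_cohort(dir, file.path(dir, "dup.csv")), "duplicate")
  unlink(dir, recursive = TRUE)
})

test_that("sample_record validates labels", {
  p <- array(rnorm(8), c(2, 2, 2))
  expect_error(sample_record(p, numeric(0), 2, "x"), "label")
  r <- sample_record(p, c(1, 2), 1, "x")
  expect_s3_class(r, "recnn_sample")
  expect_equal(r$morph, c(1, 2))
})
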