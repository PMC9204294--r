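test_that("phantom generation is deterministic and order-independent", {
  cfg <- phantom_config(shape = c(10, 12, 10), n_per_class = 3, seed = 5)
  a <- phantom_sample(cfg, 1, 2)
  b <- phantom_sample(cfg, 1, 2)
  expect_identical(a$patch$data, b$patch$data)
  expect_identical(a$morph, b$morph)

  # generating other samples in between must not perturb the stream
  phantom_sample(cfg, 0, 0); phantom_sample(cfg, 1, 0)
  c <- phantom_sample(cfg, 1, 2)
  expect_identical(a$patch$data, c$patch$data)

  # different seeds give different cohorts
  cfg2 <- phantom_config(shape = c(10, 12, 10), n_per_class = 3, seed = 6)
  expect_false(identical(phantom_sample(cfg2, 1, 2)$patch$data,
                         a$patch$data))
  expect_error(phantom_sample(cfg, 1, 3), "index")
})

test_that("cohorts are balanced and label frequency is exactly one half", {
  co <- tiny_cohort(n_per_class = 5)
  expect_length(co, 10)
  labels <- vapply(co, function(s) s$label, integer(1))
  expect_equal(mean(labels), 0.5)
  expect_equal(sum(labels == 0), 5)
  ids <- vapply(co, function(s) s$subject_id, "")
  expect_false(anyDuplicated(ids) > 0)
})

test_that("atrophy shrinks the hippocampal blob volume by about the cubed factor", {
  # geometry probe: negligible noise, no redundant blobs, so the bright
  # voxels are exactly the two planted ellipsoids
  shape <- c(40L, 50L, 40L)
  count_signal <- function(label, atrophy) {
    cfg <- phantom_config(shape = shape, n_per_class = 1,
                          signal_radius_nc = 8, atrophy_fraction = atrophy,
                          noise_sd = 1e-3, n_redundant_blobs = 0, seed = 1)
    s <- phantom_sample(cfg, label, 0)
    sum(s$patch$data > max(s$patch$data) / 2)
  }
  # lattice-count oracle at the generator's centres (radius scales with
  # the grid: 8 * 40/80 = 4 voxels for NC)
  centers <- list(c(0.35, 0.5, 0.5) * shape, c(0.65, 0.5, 0.5) * shape)
  oracle <- function(r) sum(vapply(centers, sphere_voxels, 0, r = r,
                                   shape = shape))
  n_nc <- count_signal(0, 0.3)
  n_ad <- count_signal(1, 0.3)
  expect_equal(n_nc, oracle(4))
  expect_equal(n_ad, oracle(4 * 0.7))
  expect_lt(n_ad, n_nc)
  expect_equal(n_ad / n_nc, 0.7^3, tolerance = 0.15)

  # null atrophy: both classes carry the same signal volume
  expect_equal(count_signal(0, 0), count_signal(1, 0))
})

test_that("morphological metrics carry the configured class mean shift", {
  co <- phantom_cohort(phantom_config(shape = c(6, 6, 6), n_per_class = 100,
                                      morph_dim = 1, morph_effect = 1.5,
                                      seed = 3))
  m <- vapply(co, function(s) s$morph[1], 0)
  lab <- vapply(co, function(s) s$label, integer(1))
  diff <- mean(m[lab == 1]) - mean(m[lab == 0])
  se <- sqrt(1 / 100 + 1 / 100)
  expect_lt(abs(diff - 1.5), 3 * se)
})

test_that("phantom config validates its invariants", {
  expect_error(phantom_config(signal_radius_nc = 1, atrophy_fraction = 0.5),
               "below 1 voxel")
  expect_error(phantom_config(noise_sd = 0))
  cfg <- phantom_config(morph_dim = 2, morph_effect = c(1, 2))
  expect_equal(cfg$morph_effect, c(1, 2))
  # scalar effect is recycled across metrics
  expect_equal(phantom_config(morph_dim = 3, morph_effect = 1.5)$morph_effect,
               rep(1.5, 3))
})
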