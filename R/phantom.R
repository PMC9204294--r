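#' Configuration for the 3D phantom simulator
#'
#' The phantom cohort emulates the statistical structure the classifier
#' assumes in registered hippocampal patches: a localized class-dependent
#' volumetric signal (two bright "hippocampus" ellipsoids whose radius
#' shrinks by `atrophy_fraction` in the AD class), class-independent
#' redundant bright blobs at random positions, additive Gaussian
#' background noise, and a morphological metric vector drawn from
#' N(label * `morph_effect`, 1).
#'
#' @param shape Integer triple, patch grid; reduced shapes such as
#'   `c(32, 40, 32)` keep simulations fast.
#' @param n_per_class Samples per class.
#' @param signal_radius_nc Hippocampal blob radius (voxels) in the NC
#'   class.
#' @param atrophy_fraction Fractional radius reduction in the AD class,
#'   in \[0, 1).
#' @param noise_sd SD of the additive background noise.
#' @param n_redundant_blobs Number of class-independent bright blobs.
#' @param morph_dim Length of the metric vector (default 3: GM, WM, CSF).
#' @param morph_effect Class mean shift of each metric, in SD units;
#'   recycled to `morph_dim`.
#' @param seed Master seed; every sample derives its own substream from
#'   `(seed, label, index)`, so cohorts are order-independent.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(shape = c(80L, 100L, 80L), n_per_class = 100L,
                           signal_radius_nc = 8, atrophy_fraction = 0.3,
                           noise_sd = 1, n_redundant_blobs = 4L,
                           morph_dim = 3L, morph_effect = 1.5, seed = 0L) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape > 0L), n_per_class >= 1L,
            noise_sd > 0, n_redundant_blobs >= 0L, morph_dim >= 0L,
            atrophy_fraction >= 0, atrophy_fraction < 1)
  morph_effect <- rep_len(as.numeric(morph_effect), morph_dim)
  if (signal_radius_nc * (1 - atrophy_fraction) < 1)
    stop("atrophied blob radius would fall below 1 voxel")
  structure(list(shape = shape, n_per_class = as.integer(n_per_class),
                 signal_radius_nc = signal_radius_nc,
                 atrophy_fraction = atrophy_fraction, noise_sd = noise_sd,
                 n_redundant_blobs = as.integer(n_redundant_blobs),
                 morph_dim = as.integer(morph_dim),
                 morph_effect = morph_effect, seed = as.integer(seed)),
            class = "phantom_config")
}

# Additive ellipsoidal bump of given amplitude; semi-axes in voxels.
.add_ellipsoid <- function(arr, center, semi, amplitude) {
  d <- dim(arr)
  lo <- pmax(1L, floor(center - semi)); hi <- pmin(d, ceiling(center + semi))
  if (any(lo > hi)) return(arr)
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
  gx <- ((ix - center[1]) / semi[1])^2
  gy <- ((iy - center[2]) / semi[2])^2
  gz <- ((iz - center[3]) / semi[3])^2
  inside <- outer(outer(gx, gy, `+`), gz, `+`) <= 1
  arr[ix, iy, iz][inside] <- arr[ix, iy, iz][inside] + amplitude
  arr
}

# Analytic voxel membership of the two hippocampal blobs for a label,
# used both by the generator and by geometry tests.
.hippo_centers <- function(shape) {
  list(left  = c(0.35, 0.5, 0.5) * shape,
       right = c(0.65, 0.5, 0.5) * shape)
}

#' Generate one phantom sample
#'
#' Deterministic given `(cfg$seed, label, index)`: the same triple always
#' yields a bitwise-identical record, independent of call order.  The
#' volume is standardized and clipped to \[-1, 2.5\] like a preprocessed
#' clinical patch.
#'
#' @param cfg A [phantom_config()].
#' @param label 0 (NC) or 1 (AD).
#' @param index Sample index within the class, `0 <= index < n_per_class`.
#' @return A [sample_record()].
#' @export
phantom_sample <- function(cfg, label, index) {
  stopifnot(inherits(cfg, "phantom_config"))
  label <- as.integer(label); index <- as.integer(index)
  if (index < 0L || index >= cfg$n_per_class)
    stop("index out of range [0, n_per_class)")
  st <- .rng_stream(.sub_seed(cfg$seed, label + 1L, index))
  .with_stream(st, {
    d <- cfg$shape
    arr <- array(rnorm(prod(d), 0, cfg$noise_sd), dim = d)
    # class-independent redundant structure
    if (cfg$n_redundant_blobs > 0L) {
      for (b in seq_len(cfg$n_redundant_blobs)) {
        center <- runif(3, 0.1, 0.9) * d
        semi <- runif(3, 0.04, 0.1) * min(d)
        arr <- .add_ellipsoid(arr, center, semi, 2)
      }
    }
    # class-dependent hippocampal signal, left and right
    r <- cfg$signal_radius_nc * min(d) / 80 * # scale with grid
      (if (label == 1L) 1 - cfg$atrophy_fraction else 1)
    for (ctr in .hippo_centers(d))
      arr <- .add_ellipsoid(arr, ctr, rep(r, 3), 2)
    vol <- normalize_and_clip(as_volume(arr), -1, 2.5)
    patch <- crop_patch(vol, c(0L, 0L, 0L), d)
    morph <- if (cfg$morph_dim > 0L)
      rnorm(cfg$morph_dim, mean = label * cfg$morph_effect, sd = 1)
    else numeric(0)
    sample_record(patch, morph,
                  label, sprintf("P%04d_%s", index, if (label == 1L) "AD" else "NC"))
  })
}

#' Generate a balanced phantom cohort
#'
#' @param cfg A [phantom_config()].
#' @return List of `2 * n_per_class` [sample_record()]s, NC then AD,
#'   each reproducible from the per-sample substream.
#' @export
phantom_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  recs <- vector("list", 2L * cfg$n_per_class)
  i <- 0L
  for (label in c(0L, 1L)) {
    for (index in seq_len(cfg$n_per_class) - 1L) {
      i <- i + 1L
      recs[[i]] <- phantom_sample(cfg, label, index)
    }
  }
  recs
}

#' Write a cohort to disk as NIfTI volumes plus a metric/label table
#'
#' Emits one `<subject_id>.nii.gz` per sample and a `cohort.csv` in the
#' exact dialect [load_cohort()] consumes.
#'
#' @param samples List of [sample_record()]s.
#' @param dir Output directory (created if absent).
#' @return Path of the written CSV, invisibly.
#' @export
write_cohort <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- length(samples[[1]]$morph)
  mcols <- if (m > 0) paste0("m", seq_len(m)) else character()
  rows <- lapply(samples, function(s) {
    write_volume(s$patch$data, file.path(dir, paste0(s$subject_id, ".nii.gz")))
    c(list(subject_id = s$subject_id, label = s$label),
      stats::setNames(as.list(s$morph), mcols))
  })
  tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  csv <- file.path(dir, "cohort.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  invisible(csv)
}
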