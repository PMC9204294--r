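# Shared fixtures and independent oracles for the test suite.

# --- naive reference implementations (kept deliberately dumb) ---------

# 3D "same" convolution, kernel 3 / stride 1 / zero padding, by direct
# summation over kernel offsets.
naive_conv3d <- function(x, w, b) {
  d <- dim(x)[1:3]; Cin <- dim(x)[4]; Cout <- dim(w)[5]
  y <- array(0, c(d, Cout))
  for (co in seq_len(Cout)) {
    acc <- array(b[co], d)
    for (ci in seq_len(Cin)) for (dz in 1:3) for (dy in 1:3) for (dx in 1:3) {
      oi <- dx - 2; oj <- dy - 2; ok <- dz - 2
      for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
        ii <- i + oi; jj <- j + oj; kk <- k + ok
        if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
            kk >= 1 && kk <= d[3])
          acc[i, j, k] <- acc[i, j, k] + x[ii, jj, kk, ci] * w[dx, dy, dz, ci, co]
      }
    }
    y[, , , co] <- acc
  }
  y
}

# ceil-mode 2x2x2 / stride-2 max pooling on one channel volume
naive_maxpool3d <- function(x) {
  d <- dim(x); o <- (d + 1L) %/% 2L
  y <- array(NA_real_, o)
  for (i in seq_len(o[1])) for (j in seq_len(o[2])) for (k in seq_len(o[3]))
    y[i, j, k] <- max(x[(2 * i - 1):min(2 * i, d[1]),
                        (2 * j - 1):min(2 * j, d[2]),
                        (2 * k - 1):min(2 * k, d[3])])
  y
}

# AUC by brute force over all positive/negative pairs, ties count 1/2.
pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg)
    wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}

# Monte-Carlo estimate of KL(N(mu, sd^2) || N(0,1)) by sampling from q.
mc_kl <- function(mu, sd, n) {
  x <- rnorm(n, mu, sd)
  mean(dnorm(x, mu, sd, log = TRUE) - dnorm(x, log = TRUE))
}

# Lattice-point count inside a sphere of radius r centred at c (3-vector),
# on a given grid; the analytic-ellipsoid oracle for the phantom blobs.
sphere_voxels <- function(center, r, shape) {
  ix <- seq_len(shape[1]); iy <- seq_len(shape[2]); iz <- seq_len(shape[3])
  gx <- ((ix - center[1]) / r)^2
  gy <- ((iy - center[2]) / r)^2
  gz <- ((iz - center[3]) / r)^2
  sum(outer(outer(gx, gy, `+`), gz, `+`) <= 1)
}

# --- small cohorts ----------------------------------------------------

tiny_cohort <- function(n_per_class = 10, shape = c(8L, 10L, 8L), seed = 7L,
                        ...) {
  phantom_cohort(phantom_config(shape = shape, n_per_class = n_per_class,
                                seed = seed, ...))
}

# --- memoised training runs shared by the acceptance suite -----------

.run_cache <- new.env(parent = emptyenv())

acceptance_fit <- function(scale = c("mid", "small"), J, alpha, seed,
                           epochs, atrophy = 0.3, morph_effect = 1.5) {
  scale <- match.arg(scale)
  key <- paste(scale, J, alpha, seed, epochs, atrophy, morph_effect,
               sep = "|")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  if (scale == "mid") {
    shape <- c(32L, 40L, 32L); channels <- c(4L, 8L, 16L, 32L, 32L)
  } else {
    shape <- c(16L, 20L, 16L); channels <- c(4L, 8L, 16L, 16L, 16L)
  }
  ckey <- paste("cohort", scale, atrophy, morph_effect, sep = "|")
  if (is.null(.run_cache[[ckey]]))
    .run_cache[[ckey]] <- phantom_cohort(phantom_config(
      shape = shape, n_per_class = 100L, atrophy_fraction = atrophy,
      morph_effect = morph_effect, seed = 0L))
  fit <- recnn(.run_cache[[ckey]], latent_dim = J, alpha = alpha,
               arch = recnn_arch(input_shape = shape, channels = channels),
               control = recnn_control(epochs = epochs), seed = seed)
  .run_cache[[key]] <- fit
  fit
}
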