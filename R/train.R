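#' Stratified train/validation split
#'
#' Shuffles each class independently with the given seed and assigns
#' `floor(fraction * n_class)` samples per class to training, the rest
#' to validation.  Identical seeds give identical splits; changing the
#' seed realizes repeated random cross-validation.
#'
#' @param samples List of [sample_record()]s containing both classes.
#' @param fraction Training fraction in (0, 1), default 0.8.
#' @param seed Integer split seed.
#' @return List with `train` and `validation` sample lists; the chosen
#'   indices are attached as attributes `train_idx` / `val_idx`.
#' @export
split_cohort <- function(samples, fraction = 0.8, seed = 0L) {
  if (length(samples) < 2L) stop("need at least 2 samples")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  labels <- vapply(samples, function(s) s$label, integer(1))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for a stratified split")
  st <- .rng_stream(.sub_seed(seed, 11L, 0L))
  train_idx <- integer(0)
  .with_stream(st, {
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      n_tr <- floor(fraction * length(idx))
      train_idx <- c(train_idx, idx[seq_len(n_tr)])
    }
  })
  train_idx <- sort(train_idx)
  val_idx <- setdiff(seq_along(samples), train_idx)
  out <- list(train = samples[train_idx], validation = samples[val_idx])
  attr(out, "train_idx") <- train_idx
  attr(out, "val_idx") <- val_idx
  out
}

#' Inverse-frequency oversampling weights
#'
#' Per-sample sampling weights proportional to the inverse class
#' frequency, so drawing with replacement yields an expected 1:1 class
#' ratio — the oversampling that compensates the AD/NC imbalance.
#'
#' @param labels Binary label vector with both classes present.
#' @return Numeric weights (mean 1) aligned with `labels`.
#' @export
oversample_weights <- function(labels) {
  labels <- as.integer(labels)
  n <- length(labels)
  n1 <- sum(labels == 1L); n0 <- n - n1
  if (n0 == 0L || n1 == 0L) stop("both classes must be present")
  w <- ifelse(labels == 1L, n / (2 * n1), n / (2 * n0))
  as.numeric(w)
}

#' Training protocol configuration
#'
#' Defaults follow the published protocol: Adam with base learning rate
#' 5e-4 and batch size 32, 120 epochs, a per-step linear warm-up over
#' the first 2 epochs starting from 0, the rate divided by 5 every 40
#' epochs thereafter, an 80/20 stratified split, and class-balancing
#' oversampling.
#'
#' @param lr_base Plateau learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param warmup_epochs Epochs of linear warm-up from 0.
#' @param decay_every Epoch period of the step decay.
#' @param decay_factor Division factor per decay step.
#' @param train_fraction Training fraction of the cohort.
#' @param oversample Draw each epoch with inverse-frequency weights
#'   (with replacement) instead of a plain shuffle.
#' @param sampled_inference Sample Z (instead of using the mean) at
#'   prediction time.
#' @param verbose Print a line per epoch.
#' @return A `recnn_control` list.
#' @export
recnn_control <- function(lr_base = 5e-4, batch_size = 32L, epochs = 120L,
                          warmup_epochs = 2L, decay_every = 40L,
                          decay_factor = 5, train_fraction = 0.8,
                          oversample = TRUE, sampled_inference = FALSE,
                          verbose = FALSE) {
  stopifnot(lr_base > 0, batch_size >= 1L, epochs >= 1L, warmup_epochs >= 0L,
            decay_every >= 1L, decay_factor >= 1,
            train_fraction > 0, train_fraction < 1)
  structure(list(lr_base = lr_base, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 decay_every = as.integer(decay_every),
                 decay_factor = decay_factor, train_fraction = train_fraction,
                 oversample = oversample,
                 sampled_inference = sampled_inference, verbose = verbose),
            class = "recnn_control")
}

#' Learning-rate schedule
#'
#' Per-optimizer-step rate: linear ramp from 0 to `lr_base` across the
#' warm-up epochs, then a plateau at `lr_base`, divided by
#' `decay_factor` once per `decay_every` epochs (at epochs 40 and 80
#' under the defaults).
#'
#' @param step 0-based optimizer step.
#' @param steps_per_epoch Optimizer steps per epoch.
#' @param control A [recnn_control()].
#' @return The learning rate at that step.
#' @export
learning_rate <- function(step, steps_per_epoch, control = recnn_control()) {
  stopifnot(step >= 0, steps_per_epoch >= 1)
  epoch <- step %/% steps_per_epoch
  warm_steps <- control$warmup_epochs * steps_per_epoch
  if (step < warm_steps) return(control$lr_base * step / warm_steps)
  control$lr_base / control$decay_factor^(epoch %/% control$decay_every)
}

# ---- internal: Adam over nested parameter/gradient trees -------------

.adam_rec <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    for (i in seq_along(p)) {
      if (is.null(g[[i]])) next
      r <- .adam_rec(p[[i]], g[[i]], m[[i]], v[[i]], lr, t, b1, b2, eps)
      p[[i]] <- r$p; m[[i]] <- r$m; v[[i]] <- r$v
    }
  } else {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  }
  list(p = p, m = m, v = v)
}

.zero_tree <- function(p) rapply(p, function(x) x * 0, how = "replace")

# ---- internal: cohort plumbing ---------------------------------------

.cohort_matrix <- function(samples) {
  V <- prod(samples[[1]]$patch$shape)
  vapply(samples, function(s) as.numeric(s$patch$data), numeric(V))
}

.cohort_morph <- function(samples) {
  m <- length(samples[[1]]$morph)
  if (m == 0L) return(matrix(0, length(samples), 0))
  t(vapply(samples, function(s) s$morph, numeric(m)))
}

.cohort_labels <- function(samples)
  vapply(samples, function(s) s$label, integer(1))

# Forward a sample set through a fitted model in chunks.
# Returns probs (n x 2), scores P(AD), latent params (or NULL).
.model_forward <- function(model, samples, training = FALSE, chunk = 32L) {
  labels <- .cohort_labels(samples)
  morph <- .cohort_morph(samples)
  if (ncol(morph) != model$morph_dim)
    stop("morph length ", ncol(morph), " does not match model (",
         model$morph_dim, ")")
  morph <- sweep(sweep(morph, 2, model$morph_center), 2, model$morph_scale, `/`)
  n <- length(samples)
  probs <- matrix(NA_real_, n, 2)
  mu_all <- NULL; lv_all <- NULL
  if (model$latent_dim > 0L) {
    shape <- model$arch$input_shape
    mu_all <- matrix(NA_real_, n, model$latent_dim)
    lv_all <- matrix(NA_real_, n, model$latent_dim)
    for (start in seq(1L, n, by = chunk)) {
      idx <- start:min(start + chunk - 1L, n)
      X <- array(vapply(samples[idx],
                        function(s) as.numeric(s$patch$data),
                        numeric(prod(shape))),
                 dim = c(shape, 1L, length(idx)))
      bb <- .backbone_fwd(model$params$backbone, model$arch, X,
                          training = FALSE)
      H <- flatten_features(bb$y)
      lat <- reparam_encode(H, model$params$fm, model$params$fs)
      Z <- if (model$control$sampled_inference)
        reparam_sample(lat, training = TRUE)
      else lat$mu
      out <- .mlp_forward(model$params$mlp,
                          cbind(Z, morph[idx, , drop = FALSE]))
      probs[idx, ] <- out$probs
      mu_all[idx, ] <- lat$mu
      lv_all[idx, ] <- lat$log_var
    }
  } else {
    out <- .mlp_forward(model$params$mlp, morph)
    probs[] <- out$probs
  }
  list(probs = probs, scores = probs[, 2], labels = labels,
       latent = if (!is.null(mu_all)) latent_params(mu_all, lv_all))
}

# ---- the fitting function --------------------------------------------

#' Fit a reparameterized CNN classifier
#'
#' Trains the full pipeline end to end on a cohort of sample records:
#' 3D convolutional backbone -> flattened deep features -> variational
#' bottleneck (latent mean / log-variance, reparameterized sampling) ->
#' concatenation with z-scored morphological metrics -> MLP -> softmax,
#' under the objective \eqn{l = l_{ce} + \alpha l_{kl}}.  The cohort is
#' split 80/20 (stratified) with the given seed; training draws
#' mini-batches with inverse-frequency oversampling; optimization is
#' Adam under the warm-up/step-decay schedule of [learning_rate()].
#' All randomness (weight init, shuffling, reparameterization noise)
#' derives from `seed` through independent substreams, so a fit is
#' bit-reproducible.
#'
#' With `latent_dim = 0` the model degenerates to the metrics-only MLP
#' (no image branch); with `alpha = 0` the KL constraint is off and the
#' model is the conventional CNN arm.
#'
#' @param samples List of [sample_record()]s (e.g. from
#'   [phantom_cohort()] or [load_cohort()]).
#' @param latent_dim Latent bottleneck width J ("semantic features
#'   dimension").
#' @param alpha Nonnegative KL weight.
#' @param arch A [recnn_arch()]; default infers the input shape from
#'   the first patch and uses the standard channel progression.
#' @param hidden MLP hidden layer sizes.
#' @param control A [recnn_control()].
#' @param seed Master seed.
#' @return An object of class `recnn` with components `params`
#'   (trained weights), `history` (per-epoch data frame: losses,
#'   learning rate, validation metrics), `validation` (final-epoch
#'   [evaluate_scores()] report), `split` and configuration fields.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`.
#' @export
recnn <- function(samples, latent_dim = 100L, alpha = 10, arch = NULL,
                  hidden = c(64L, 32L), control = recnn_control(),
                  seed = 0L) {
  stopifnot(length(samples) >= 2L, inherits(control, "recnn_control"))
  latent_dim <- as.integer(latent_dim)
  if (latent_dim < 0L) stop("latent_dim must be >= 0")
  if (alpha < 0) stop("alpha must be >= 0")
  morph_dim <- length(samples[[1]]$morph)
  if (latent_dim + morph_dim < 1L)
    stop("model needs at least one input feature (latent_dim + morph_dim >= 1)")

  split <- split_cohort(samples, control$train_fraction, seed)
  train <- split$train; val <- split$validation
  labels_tr <- .cohort_labels(train)

  morph_tr <- .cohort_morph(train)
  morph_center <- if (morph_dim) colMeans(morph_tr) else numeric(0)
  morph_scale <- if (morph_dim) {
    s <- apply(morph_tr, 2, stats::sd); ifelse(s > 0, s, 1)
  } else numeric(0)
  morph_tr <- sweep(sweep(morph_tr, 2, morph_center), 2, morph_scale, `/`)

  use_image <- latent_dim > 0L
  if (use_image) {
    shape <- train[[1]]$patch$shape
    if (is.null(arch)) arch <- recnn_arch(input_shape = shape)
    if (!all(arch$input_shape == shape))
      stop("arch input shape ", paste(arch$input_shape, collapse = "x"),
           " does not match patches ", paste(shape, collapse = "x"))
    Xtr <- .cohort_matrix(train)
  }

  init_st <- .rng_stream(.sub_seed(seed, 1L, 0L))
  shuffle_st <- .rng_stream(.sub_seed(seed, 2L, 0L))
  eps_st <- .rng_stream(.sub_seed(seed, 3L, 0L))

  params <- .with_stream(init_st, {
    p <- list()
    if (use_image) {
      p$backbone <- .backbone_init(arch)
      p$fm <- .linear_init(arch$feature_dim, latent_dim, init = "small")
      p$fs <- .linear_init(arch$feature_dim, latent_dim, init = "small")
    }
    p$mlp <- .mlp_init(latent_dim + morph_dim, hidden, 2L)
    p
  })

  adam_m <- .zero_tree(params); adam_v <- .zero_tree(params)
  w <- if (control$oversample) oversample_weights(labels_tr)
       else rep(1, length(labels_tr))
  n_tr <- length(train)
  steps_per_epoch <- max(1L, ceiling(n_tr / control$batch_size))

  model <- structure(list(arch = if (use_image) arch, params = params,
                          latent_dim = latent_dim, morph_dim = morph_dim,
                          alpha = alpha, hidden = hidden, control = control,
                          seed = seed, morph_center = morph_center,
                          morph_scale = morph_scale), class = "recnn")

  hist_rows <- vector("list", control$epochs)
  step <- 0L; adam_t <- 0L
  for (epoch in seq_len(control$epochs) - 1L) {
    order_idx <- .with_stream(shuffle_st, {
      if (control$oversample)
        sample.int(n_tr, n_tr, replace = TRUE, prob = w)
      else sample.int(n_tr)
    })
    ep_ce <- ep_kl <- ep_tot <- 0; nb_count <- 0L
    for (start in seq(1L, n_tr, by = control$batch_size)) {
      idx <- order_idx[start:min(start + control$batch_size - 1L, n_tr)]
      nb <- length(idx)
      y <- labels_tr[idx]
      Y <- cbind(1 - y, y)                       # one-hot
      grads <- list()
      if (use_image) {
        X <- array(Xtr[, idx], dim = c(arch$input_shape, 1L, nb))
        bb <- .backbone_fwd(params$backbone, arch, X, training = TRUE,
                            with_cache = TRUE)
        params$backbone <- bb$blocks             # running stats advance
        H <- flatten_features(bb$y)
        mu <- .linear_forward(params$fm, H)
        lv <- .linear_forward(params$fs, H)
        eps <- .with_stream(eps_st, matrix(rnorm(nb * latent_dim), nb))
        sigma <- exp(lv / 2)
        Z <- mu + eps * sigma
        Xc <- cbind(Z, morph_tr[idx, , drop = FALSE])
      } else {
        Xc <- morph_tr[idx, , drop = FALSE]
      }
      fw <- .mlp_forward(params$mlp, Xc, with_cache = TRUE)
      ce <- cross_entropy(fw$probs, y)
      kl <- if (use_image) kl_divergence(latent_params(mu, lv)) else 0
      tot <- ce + alpha * kl
      if (!is.finite(tot))
        stop("training diverged at epoch ", epoch, " (loss = ", tot,
             "); lower the learning rate or alpha")
      ep_ce <- ep_ce + ce; ep_kl <- ep_kl + kl; ep_tot <- ep_tot + tot
      nb_count <- nb_count + 1L

      glogits <- (fw$probs - Y) / nb
      mg <- .mlp_backward(params$mlp, fw$caches, glogits)
      grads$mlp <- lapply(mg, function(g) list(W = g$dW, b = g$db))
      if (use_image) {
        dXc <- .mlp_input_grad(params$mlp, fw$caches, glogits)
        dZ <- dXc[, seq_len(latent_dim), drop = FALSE]
        dmu <- dZ + alpha * mu / nb
        dlv <- dZ * eps * sigma / 2 + alpha * (sigma^2 - 1) / (2 * nb)
        gfm <- .linear_backward(params$fm, H, dmu)
        gfs <- .linear_backward(params$fs, H, dlv)
        grads$fm <- list(W = gfm$dW, b = gfm$db)
        grads$fs <- list(W = gfs$dW, b = gfs$db)
        dH <- gfm$dX + gfs$dX
        gy <- bb$y; gy[] <- t(dH)
        gb <- .backbone_bwd(params$backbone, bb$caches, gy)
        grads$backbone <- lapply(gb, function(g)
          list(conv = list(w = g$dw, b = g$db),
               bn = list(gamma = g$dgamma, beta = g$dbeta,
                         run_mean = NULL, run_var = NULL)))
      }
      lr <- learning_rate(step, steps_per_epoch, control)
      adam_t <- adam_t + 1L
      upd <- .adam_rec(params, grads[names(params)], adam_m, adam_v, lr, adam_t)
      # keep bn running stats (not touched: grads NULL) and adopt updates
      params <- upd$p; adam_m <- upd$m; adam_v <- upd$v
      step <- step + 1L
    }

    model$params <- params
    vf <- .model_forward(model, val, training = FALSE)
    vrep <- evaluate_scores(vf$scores, vf$labels)
    val_kl <- if (use_image) kl_divergence(vf$latent) else NA_real_
    hist_rows[[epoch + 1L]] <- data.frame(
      epoch = epoch, lr = learning_rate(step - 1L, steps_per_epoch, control),
      ce = ep_ce / nb_count, kl = ep_kl / nb_count, total = ep_tot / nb_count,
      val_acc = vrep$acc, val_se = vrep$se, val_sp = vrep$sp,
      val_auc = vrep$auc, val_kl = val_kl)
    if (control$verbose)
      message(sprintf(
        "epoch %3d  loss %.4f (ce %.4f, kl %.4f)  val AUC %.4f",
        epoch, ep_tot / nb_count, ep_ce / nb_count, ep_kl / nb_count,
        vrep$auc))
  }

  model$params <- params
  model$history <- do.call(rbind, hist_rows)
  vf <- .model_forward(model, val, training = FALSE)
  model$validation <- evaluate_scores(vf$scores, vf$labels)
  model$val_kl <- if (use_image) kl_divergence(vf$latent) else NA_real_
  model$split <- list(train_id = vapply(train, function(s) s$subject_id, ""),
                      val_id = vapply(val, function(s) s$subject_id, ""))
  model$call <- match.call()
  model
}

# Gradient of the MLP loss w.r.t. its input matrix.
.mlp_input_grad <- function(layers, caches, glogits) {
  g <- glogits
  for (i in rev(seq_along(layers))) {
    g <- tcrossprod(g, layers[[i]]$W)
    if (i > 1L) g[!caches[[i - 1L]]$mask] <- 0
  }
  g
}

#' Repeated seeded cross-validation
#'
#' Runs one independent [recnn()] fit per seed (each seed draws its own
#' 80/20 split, initialization and noise) and summarizes the final
#' validation metrics as mean and SD across seeds.
#'
#' @param samples Cohort of [sample_record()]s.
#' @param seeds Integer vector of seeds (default `0:4`, i.e. validated
#'   five times).
#' @param ... Passed on to [recnn()].
#' @return An object of class `recnn_cv`: list with `reports` (one
#'   data-frame row per seed), `summary` (mean/SD per metric) and
#'   `models` (the fitted objects).
#' @export
cross_validate <- function(samples, seeds = 0:4, ...) {
  stopifnot(length(seeds) >= 1L)
  models <- lapply(seeds, function(s) recnn(samples, seed = s, ...))
  reports <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    cbind(data.frame(seed = seeds[i]), as.data.frame(models[[i]]$validation))
  }))
  metrics <- c("acc", "se", "sp", "auc")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(reports[[m]]), numeric(1)),
    sd = vapply(metrics, function(m)
      if (nrow(reports) > 1L) stats::sd(reports[[m]]) else 0, numeric(1)))
  rownames(summary) <- NULL
  structure(list(reports = reports, summary = summary, seeds = seeds,
                 models = models), class = "recnn_cv")
}

#' @export
print.recnn_cv <- function(x, digits = 4, ...) {
  cat("Repeated cross-validation over", length(x$seeds), "seeds\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %.*f +/- %.*f\n", toupper(s$metric[i]),
                digits, s$mean[i], digits, s$sd[i]))
  invisible(x)
}
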