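#' @export
print.recnn <- function(x, ...) {
  cat("Reparameterized CNN classifier (AD vs NC)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("  latent dim J = %d, morph dim = %d, alpha = %.3g, seed = %d\n",
              x$latent_dim, x$morph_dim, x$alpha, x$seed))
  if (!is.null(x$arch))
    cat("  backbone:", paste(x$arch$channels, collapse = "->"), "channels on",
        paste(x$arch$input_shape, collapse = "x"), "patches\n")
  if (!is.null(x$validation)) {
    cat("  validation (final epoch):\n  ")
    print(x$validation)
  }
  invisible(x)
}

#' @export
summary.recnn <- function(object, ...) {
  h <- object$history
  out <- list(
    config = list(latent_dim = object$latent_dim, alpha = object$alpha,
                  morph_dim = object$morph_dim,
                  epochs = object$control$epochs, seed = object$seed),
    final = h[nrow(h), ],
    best_auc = h[which.max(h$val_auc), ],
    validation = object$validation,
    val_kl = object$val_kl,
    n_parameters = sum(unlist(rapply(object$params, length, how = "list"))))
  class(out) <- "summary.recnn"
  out
}

#' @export
print.summary.recnn <- function(x, ...) {
  cat(sprintf(
    "Re-CNN fit: J = %d, alpha = %.3g, %d epochs, seed %d (%d parameters)\n",
    x$config$latent_dim, x$config$alpha, x$config$epochs, x$config$seed,
    x$n_parameters))
  cat(sprintf("final epoch: loss %.4f (ce %.4f, kl %.4f)\n",
              x$final$total, x$final$ce, x$final$kl))
  cat(sprintf("validation KL %.4f\nfinal validation: ",
              if (is.na(x$val_kl)) NA else x$val_kl))
  print(x$validation)
  cat(sprintf("best-epoch AUC %.4f at epoch %d\n",
              x$best_auc$val_auc, x$best_auc$epoch))
  invisible(x)
}

#' @export
coef.recnn <- function(object, ...) object$params

#' Predict AD probabilities for new samples
#'
#' Runs the fitted pipeline in inference mode (latent Z equals the mean
#' unless the model was configured for sampled inference); morphological
#' metrics are z-scored with the training-split statistics stored in the
#' model.
#'
#' @param object A fitted [recnn()] model.
#' @param newdata List of [sample_record()]s (or a single record).
#' @param type `"prob"` for the n x 2 probability matrix, `"score"` for
#'   P(AD), `"class"` for 0/1 predictions at threshold 0.5, `"latent"`
#'   for the [latent_params()] of the bottleneck.
#' @param ... Unused.
#' @return Per `type`.
#' @export
predict.recnn <- function(object, newdata,
                          type = c("prob", "score", "class", "latent"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "recnn_sample")) newdata <- list(newdata)
  fw <- .model_forward(object, newdata, training = FALSE)
  switch(type,
         prob = { colnames(fw$probs) <- c("NC", "AD"); fw$probs },
         score = fw$scores,
         class = as.integer(fw$scores >= 0.5),
         latent = {
           if (is.null(fw$latent)) stop("model has no latent bottleneck")
           fw$latent
         })
}

#' Plot training history
#'
#' Two panels: losses (total, cross-entropy, alpha-weighted KL) and
#' validation AUC/accuracy per epoch.
#'
#' @param x A fitted [recnn()] model.
#' @param ... Unused.
#' @export
plot.recnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$total, type = "l", xlab = "epoch",
                 ylab = "training loss", main = "objective")
  graphics::lines(h$epoch, h$ce, lty = 2)
  graphics::lines(h$epoch, x$alpha * h$kl, lty = 3)
  graphics::legend("topright", c("total", "ce", "alpha*kl"), lty = 1:3,
                   bty = "n", cex = 0.8)
  graphics::plot(h$epoch, h$val_auc, type = "l", ylim = c(0, 1),
                 xlab = "epoch", ylab = "validation", main = "metrics")
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::legend("bottomright", c("AUC", "ACC"), lty = 1:2, bty = "n",
                   cex = 0.8)
  invisible(x)
}
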