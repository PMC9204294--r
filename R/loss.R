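#' Cross-entropy loss
#'
#' Mean negative log-probability of the true class,
#' \eqn{-\frac{1}{N}\sum_i \log p_{i,y_i}}, computed from softmax
#' probabilities.  Probabilities are floored at `floor` before the log
#' so a confidently wrong prediction yields a large finite value, never
#' NaN.
#'
#' @param probs N x M matrix of class probabilities (rows sum to 1).
#' @param labels Length-N integer class indices in `0:(M-1)`.
#' @param floor Numerical floor inside the log.
#' @return Scalar loss.
#' @export
cross_entropy <- function(probs, labels, floor = 1e-12) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (nrow(probs) != length(labels)) stop("probs rows must match labels")
  if (any(labels < 0L | labels >= ncol(probs))) stop("label out of range")
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6)) stop("probability rows must sum to 1")
  p <- probs[cbind(seq_along(labels), labels + 1L)]
  -mean(log(pmax(p, floor)))
}

#' KL divergence of latent distributions from the standard normal
#'
#' Closed form of \eqn{KL(N(\mu, \sigma^2) \,\|\, N(0, 1))} summed over
#' latent coordinates:
#' \deqn{l_{kl} = \frac{1}{2}\sum_{j=1}^{J}(\mu_j^2 + \sigma_j^2 - 1 - \log\sigma_j^2).}
#' Nonnegative, and zero exactly when every coordinate is standard
#' normal.  For a batch (matrix `mu`) the per-sample sums are reduced by
#' their mean by default, keeping the weight \eqn{\alpha} comparable
#' across batch sizes.
#'
#' @param params A [latent_params()] object.
#' @param reduce `"mean"`, `"sum"` or `"none"` over batch samples.
#' @return Scalar (or per-sample vector for `reduce = "none"`).
#' @export
kl_divergence <- function(params, reduce = c("mean", "sum", "none")) {
  stopifnot(inherits(params, "latent_params"))
  reduce <- match.arg(reduce)
  term <- params$mu^2 + exp(params$log_var) - 1 - params$log_var
  if (is.matrix(term)) {
    per <- rowSums(term) / 2
    switch(reduce, mean = mean(per), sum = sum(per), none = per)
  } else {
    sum(term) / 2
  }
}

#' Combine cross-entropy and KL into the training objective
#'
#' \eqn{l = l_{ce} + \alpha \, l_{kl}}: \eqn{\alpha} trades class
#' separation against the similarity constraint that pulls latent
#' distributions toward N(0, 1).  `alpha = 0` recovers the conventional
#' CNN objective.
#'
#' @param ce Cross-entropy value.
#' @param kl KL divergence value.
#' @param alpha Nonnegative weight.
#' @return An object of class `recnn_loss`: list with `total`, `ce`,
#'   `kl`, `alpha`.
#' @export
total_loss <- function(ce, kl, alpha) {
  if (alpha < 0) stop("alpha must be nonnegative")
  structure(list(total = ce + alpha * kl, ce = ce, kl = kl, alpha = alpha),
            class = "recnn_loss")
}

#' @export
print.recnn_loss <- function(x, ...) {
  cat(sprintf("loss: total %.6f = ce %.6f + %.3g * kl %.6f\n",
              x$total, x$ce, x$alpha, x$kl))
  invisible(x)
}
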