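#' Latent distribution parameters
#'
#' Container for the per-sample latent mean \eqn{\mu} and log-variance
#' (so \eqn{\sigma = e^{\log\sigma^2 / 2}} is positive by construction).
#'
#' @param mu Numeric vector of length J, or N x J matrix for a batch.
#' @param log_var Same shape as `mu`.
#' @return An object of class `latent_params` with fields `mu`,
#'   `log_var` and `J`.
#' @export
latent_params <- function(mu, log_var) {
  if (is.matrix(mu) != is.matrix(log_var) ||
      !identical(dim(mu), dim(log_var)) || length(mu) != length(log_var))
    stop("mu and log_var must have identical shape")
  J <- if (is.matrix(mu)) ncol(mu) else length(mu)
  structure(list(mu = mu, log_var = log_var, J = as.integer(J)),
            class = "latent_params")
}

#' Encode deep features into latent distribution parameters
#'
#' Applies the two affine maps of the bottleneck: \eqn{\mu = f_m(h)} and
#' \eqn{\log\sigma^2 = f_s(h)}.  The latent dimension J ("semantic
#' features dimension") is the output width of both maps.
#'
#' @param h Deep feature vector (length F) or N x F matrix.
#' @param fm,fs Affine maps as lists `list(W, b)` with `W` an F x J
#'   matrix and `b` length J.
#' @return A [latent_params()] object.
#' @export
reparam_encode <- function(h, fm, fs) {
  single <- !is.matrix(h)
  H <- if (single) matrix(h, 1) else h
  if (ncol(H) != nrow(fm$W) || ncol(H) != nrow(fs$W))
    stop("feature length ", ncol(H), " does not match encoder input dim")
  mu <- .linear_forward(fm, H)
  lv <- .linear_forward(fs, H)
  if (single) latent_params(drop(mu), drop(lv)) else latent_params(mu, lv)
}

#' Sample latent features with the reparameterization trick
#'
#' Training mode draws \eqn{Z = \mu + \epsilon \odot \sigma} with
#' \eqn{\epsilon \sim N(0, 1)} i.i.d.; inference mode returns
#' \eqn{Z = \mu} exactly so that evaluation is deterministic (sampled
#' inference can be requested by passing `training = TRUE` with an
#' explicit `eps`).
#'
#' @param params A [latent_params()] object.
#' @param eps Optional noise of the same shape as `params$mu`; drawn
#'   from the current RNG stream if `NULL` and `training` is `TRUE`.
#' @param training Logical; `FALSE` short-circuits to the mean.
#' @return Numeric vector / matrix Z shaped like `params$mu`, with the
#'   noise used attached as attribute `"eps"` in training mode.
#' @export
reparam_sample <- function(params, eps = NULL, training = TRUE) {
  stopifnot(inherits(params, "latent_params"))
  if (!training) return(params$mu)
  if (is.null(eps)) {
    eps <- if (is.matrix(params$mu))
      matrix(rnorm(length(params$mu)), nrow(params$mu))
    else rnorm(length(params$mu))
  }
  if (length(eps) != length(params$mu))
    stop("eps must match the latent dimension")
  sigma <- exp(params$log_var / 2)
  z <- params$mu + eps * sigma
  attr(z, "eps") <- eps
  z
}
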