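# Internal layer primitives.  Activations are R arrays with
# dim = c(d1, d2, d3, C, N); linear layers operate on N x F matrices.
# Convolution / pooling kernels live in src/tensor_ops.cpp.

.he_init <- function(fan_in, n) rnorm(n, 0, sqrt(2 / fan_in))

# init = "uniform": the standard U(+/- 1/sqrt(fan_in)) for MLP layers;
# "small": near-zero normal for the variational heads so the latent
# distributions start near N(0, 1) (log-variance near 0).
.linear_init <- function(in_dim, out_dim, init = "uniform") {
  if (init == "small") {
    W <- matrix(rnorm(in_dim * out_dim, 0, 0.01), in_dim, out_dim)
    b <- numeric(out_dim)
  } else {
    bound <- 1 / sqrt(in_dim)
    W <- matrix(runif(in_dim * out_dim, -bound, bound), in_dim, out_dim)
    b <- runif(out_dim, -bound, bound)
  }
  list(W = W, b = b)
}

.linear_forward <- function(p, X) {
  # X: N x in_dim
  sweep(X %*% p$W, 2, p$b, `+`)
}

.linear_backward <- function(p, X, gY) {
  list(dW = crossprod(X, gY), db = colSums(gY), dX = tcrossprod(gY, p$W))
}

.bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C),
       run_mean = numeric(C), run_var = rep(1, C))
}

.relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(y = x, mask = mask)
}

.softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}
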