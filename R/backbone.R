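# Backbone: init / forward / backward over the conv-bn-relu-pool blocks,
# plus the user-facing forward and flatten operations.

.backbone_init <- function(arch) {
  cin <- 1L
  blocks <- vector("list", arch$n_blocks)
  for (b in seq_len(arch$n_blocks)) {
    cout <- arch$channels[b]
    fan_in <- 27L * cin
    blocks[[b]] <- list(
      conv = list(w = array(.he_init(fan_in, fan_in * cout),
                            dim = c(3L, 3L, 3L, cin, cout)),
                  b = numeric(cout)),
      bn = .bn_init(cout))
    cin <- cout
  }
  blocks
}

# x: array dim (d1,d2,d3,1,N).  Returns y (4D+N feature array) and, when
# with_cache, everything backward needs.
.backbone_fwd <- function(blocks, arch, x, training, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", arch$n_blocks)
  for (b in seq_len(arch$n_blocks)) {
    p <- blocks[[b]]
    dims <- as.integer(dim(x))
    y <- .conv3d_forward(x, dims, p$conv$w, p$conv$b)
    ydims <- as.integer(dim(y))
    bn <- .bn_relu_forward(y, ydims, p$bn$gamma, p$bn$beta,
                           p$bn$run_mean, p$bn$run_var, training, 0.1, 1e-5)
    blocks[[b]]$bn$run_mean <- bn$run_mean
    blocks[[b]]$bn$run_var <- bn$run_var
    pl <- .maxpool3d_forward(bn$y, ydims)
    if (with_cache)
      caches[[b]] <- list(x = x, in_dims = dims, relu = bn$y,
                          xhat = bn$xhat, sd = bn$sd,
                          argmax = pl$argmax, relu_dims = ydims)
    x <- pl$y
  }
  list(y = x, blocks = blocks, caches = caches)
}

.backbone_bwd <- function(blocks, caches, gy) {
  grads <- vector("list", length(blocks))
  for (b in rev(seq_along(blocks))) {
    cc <- caches[[b]]
    g <- .maxpool3d_backward(gy, cc$argmax, cc$relu_dims)
    bg <- .bn_relu_backward(g, cc$relu, cc$xhat, cc$sd,
                            blocks[[b]]$bn$gamma, cc$relu_dims)
    cv <- .conv3d_backward(cc$x, cc$in_dims, blocks[[b]]$conv$w,
                           dim(blocks[[b]]$conv$w)[5], bg$dx)
    grads[[b]] <- list(dw = cv$dw, db = cv$db,
                       dgamma = bg$dgamma, dbeta = bg$dbeta)
    gy <- cv$dx
  }
  grads
}

#' Forward a patch (or batch of patches) through a backbone
#'
#' Convenience inference-mode forward pass with freshly initialized (or
#' supplied) weights, returning the feature volume and asserting the
#' shape contract: with the default five-block architecture an
#' \[80, 100, 80\] patch yields 128 feature maps of spatial size
#' \[3, 4, 3\].
#'
#' @param arch A [recnn_arch()].
#' @param patch A `recnn_patch`, a 3D array, or a 5D array
#'   `(d1, d2, d3, 1, N)` for a batch.
#' @param weights Optional backbone weights (as stored in a fitted
#'   model); if `NULL`, weights are drawn from the He-normal initializer
#'   using `seed`.
#' @param seed Seed for the random initialization.
#' @return An object of class `recnn_features`: list with `data`
#'   (array `(d1', d2', d3', C)` for one sample, 5D for a batch),
#'   `channels` and `spatial`.
#' @export
backbone_forward <- function(arch, patch, weights = NULL, seed = 0L) {
  stopifnot(inherits(arch, "recnn_arch"))
  x <- if (inherits(patch, "recnn_patch")) patch$data else as.array(patch)
  single <- length(dim(x)) == 3L
  if (single) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) != 5L)
    stop("patch must be a 3D array or a (d1,d2,d3,1,N) batch")
  if (!all(dim(x)[1:3] == arch$input_shape))
    stop("input shape mismatch: expected ",
         paste(arch$input_shape, collapse = "x"), ", got ",
         paste(dim(x)[1:3], collapse = "x"))
  if (is.null(weights)) {
    st <- .rng_stream(.sub_seed(seed, 1L, 0L))
    weights <- .with_stream(st, .backbone_init(arch))
  }
  out <- .backbone_fwd(weights, arch, x, training = FALSE)
  y <- out$y
  d <- dim(y)
  data <- if (single) array(y, dim = d[1:4]) else y
  structure(list(data = data, channels = d[4], spatial = d[1:3],
                 source_shape = arch$input_shape),
            class = "recnn_features")
}

#' Flatten a feature volume to the deep feature vector h
#'
#' Column-major flattening of the `(d1, d2, d3, C)` feature array: the
#' first spatial axis varies fastest and the channel axis slowest, so
#' the element at 0-based position `(i, j, k, c)` lands at flat index
#' `i + d1 * (j + d2 * (k + d3 * c))`.  For the default backbone this
#' maps \[3, 4, 3\] x 128 maps to a vector of length 4608.
#'
#' @param fv A `recnn_features` object or a 4D/5D array.
#' @return Numeric vector (one sample) or N x F matrix (batch).
#' @export
flatten_features <- function(fv) {
  x <- if (inherits(fv, "recnn_features")) fv$data else as.array(fv)
  d <- dim(x)
  if (length(d) == 4L) return(as.numeric(x))
  if (length(d) == 5L) {
    F <- prod(d[1:4])
    return(t(matrix(x, F, d[5])))
  }
  stop("expected a 4D (single) or 5D (batch) feature array")
}
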