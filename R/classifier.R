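# MLP classifier over [Z || morph].

.mlp_init <- function(in_dim, hidden, n_classes = 2L) {
  dims <- c(in_dim, hidden, n_classes)
  lapply(seq_len(length(dims) - 1L),
         function(i) .linear_init(dims[i], dims[i + 1L]))
}

.mlp_forward <- function(layers, X, with_cache = FALSE) {
  caches <- if (with_cache) vector("list", length(layers))
  n <- length(layers)
  for (i in seq_len(n)) {
    Y <- .linear_forward(layers[[i]], X)
    if (i < n) {
      r <- .relu_forward(Y)
      if (with_cache) caches[[i]] <- list(x = X, mask = r$mask)
      X <- r$y
    } else {
      if (with_cache) caches[[i]] <- list(x = X)
      X <- Y
    }
  }
  list(logits = X, probs = .softmax(X), caches = caches)
}

.mlp_backward <- function(layers, caches, glogits) {
  grads <- vector("list", length(layers))
  g <- glogits
  for (i in rev(seq_along(layers))) {
    bk <- .linear_backward(layers[[i]], caches[[i]]$x, g)
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    g <- bk$dX
    if (i > 1L) g[!caches[[i - 1L]]$mask] <- 0
  }
  grads
}

#' Classify a latent/morphological feature pair with an MLP
#'
#' Concatenates the latent features and the morphological metric vector
#' (in that fixed order) and forwards the result through the perceptron
#' layers, returning softmax class probabilities `(P(NC), P(AD))`.
#' With `J = 0` latent features the model degenerates to the
#' metrics-only MLP.
#'
#' @param layers MLP weights: list of `list(W, b)` layers, ReLU between
#'   hidden layers and softmax on the output — as stored in a fitted
#'   [recnn()] model under `$params$mlp`, or hand-built.
#' @param z Latent feature vector (length J, possibly 0) or N x J
#'   matrix.
#' @param morph Morphological metric vector (length M, possibly 0) or
#'   N x M matrix.
#' @return Probability vector of length 2 (or N x 2 matrix), rows
#'   summing to 1.
#' @export
mlp_classify <- function(layers, z, morph) {
  zm <- if (is.matrix(z)) z else matrix(z, 1)
  mm <- if (is.matrix(morph)) morph else matrix(morph, 1)
  if (length(z) == 0L) zm <- matrix(0, nrow(mm), 0)
  if (length(morph) == 0L) mm <- matrix(0, nrow(zm), 0)
  if (nrow(zm) != nrow(mm)) stop("z and morph batch sizes differ")
  X <- cbind(zm, mm)
  if (ncol(X) != nrow(layers[[1]]$W))
    stop("input length ", ncol(X), " does not match first-layer width ",
         nrow(layers[[1]]$W))
  p <- .mlp_forward(layers, X)$probs
  if (is.matrix(z) || is.matrix(morph)) p else drop(p)
}

#' First-layer weight profile of the classifier
#'
#' For each input feature of the MLP, the aggregate magnitude of its
#' first-layer connections, fixed here as the maximum absolute incoming
#' weight.  After training with a strong KL constraint, profiles of
#' redundant latent features collapse toward zero while the
#' discriminative few stay large — the sparsification signature of the
#' reparameterized bottleneck.
#'
#' @param model A fitted [recnn()] object, or a raw MLP layer list.
#' @return Data frame with columns `feature` (`z1..zJ`, `m1..mM`),
#'   `type` (`"latent"` / `"morph"`) and `weight` (max |w|).
#' @export
first_layer_weight_profile <- function(model) {
  if (inherits(model, "recnn")) {
    layers <- model$params$mlp
    J <- model$latent_dim
    M <- model$morph_dim
  } else if (is.list(model) && length(model) && is.list(model[[1]]) &&
             !is.null(model[[1]]$W)) {
    layers <- model
    J <- nrow(layers[[1]]$W)
    M <- 0L
  } else stop("need a fitted model or an MLP layer list")
  if (is.null(layers)) stop("model has no trained classifier weights")
  W <- layers[[1]]$W
  prof <- apply(abs(W), 1, max)
  n_in <- length(prof)
  type <- c(rep("latent", J), rep("morph", M))[seq_len(n_in)]
  feature <- c(if (J > 0) paste0("z", seq_len(J)),
               if (M > 0) paste0("m", seq_len(M)))[seq_len(n_in)]
  data.frame(feature = feature, type = type, weight = as.numeric(prof),
             stringsAsFactors = FALSE)
}
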