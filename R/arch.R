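#' Backbone architecture specification
#'
#' Describes the convolutional feature extractor: five blocks of
#' Conv3D (kernel 3, stride 1, "same" padding) + BatchNorm3D + ReLU +
#' padded (ceil-mode) max pooling (kernel 2, stride 2).  Five
#' ceil-halvings are what map an \[80, 100, 80\] patch to spatial
#' \[3, 4, 3\]; the default channel progression 8-16-32-64-128 ends at
#' the advertised 128 feature maps.
#'
#' @param input_shape Integer triple, expected patch shape.
#' @param channels Output channels per block; its length sets the number
#'   of blocks.
#' @param conv_kernel,conv_stride Convolution kernel size and stride
#'   (currently fixed at 3 and 1; recorded for receptive-field
#'   arithmetic).
#' @param pool_kernel,pool_stride Pooling kernel size and stride.
#' @return An object of class `recnn_arch`.
#' @export
recnn_arch <- function(input_shape = c(80L, 100L, 80L),
                       channels = c(8L, 16L, 32L, 64L, 128L),
                       conv_kernel = 3L, conv_stride = 1L,
                       pool_kernel = 2L, pool_stride = 2L) {
  input_shape <- as.integer(input_shape)
  channels <- as.integer(channels)
  stopifnot(length(input_shape) == 3L, all(input_shape > 0L),
            length(channels) >= 1L, all(channels > 0L),
            conv_kernel >= 1L, conv_stride >= 1L,
            pool_kernel >= 1L, pool_stride >= 1L)
  if (conv_kernel != 3L || conv_stride != 1L)
    stop("this engine implements kernel-3, stride-1 'same' convolutions")
  if (pool_kernel != 2L || pool_stride != 2L)
    stop("this engine implements kernel-2, stride-2 ceil-mode pooling")
  out <- output_shape(input_shape, length(channels))
  structure(list(input_shape = input_shape, channels = channels,
                 n_blocks = length(channels),
                 conv_kernel = as.integer(conv_kernel),
                 conv_stride = as.integer(conv_stride),
                 pool_kernel = as.integer(pool_kernel),
                 pool_stride = as.integer(pool_stride),
                 output_spatial = out,
                 feature_dim = as.integer(prod(out) * channels[length(channels)])),
            class = "recnn_arch")
}

#' Spatial output shape after repeated ceil-mode halvings
#'
#' @param input_shape Integer triple.
#' @param n_blocks Number of pooling stages.
#' @return Integer triple after `n_blocks` ceil-halvings.
#' @export
output_shape <- function(input_shape, n_blocks) {
  s <- as.integer(input_shape)
  for (b in seq_len(n_blocks)) {
    s <- (s + 1L) %/% 2L
    if (any(s < 1L)) stop("input too small for ", n_blocks, " pooling stages")
  }
  s
}

#' Receptive-field recursion
#'
#' Computes the per-layer receptive field
#' \deqn{l_k = l_{k-1} + (f_k - 1) \prod_{i=1}^{k-1} s_i}
#' over a flattened layer sequence with kernel sizes `kernels` and
#' strides `strides`, starting from \eqn{l_0 = 1}.  For the backbone's
#' five-stage stride-2 downsampling stack (five kernel-2, stride-2
#' layers) the final value is 32: each output voxel summarizes a
#' 32x32x32 region of the input patch.  Passing the full conv+pool layer
#' list of a `recnn_arch` (see [arch_layers()]) gives the larger field
#' including the 3x3x3 convolutions.
#'
#' @param kernels Integer vector of kernel sizes \eqn{f_k}.
#' @param strides Integer vector of strides \eqn{s_k}, same length.
#' @return Integer vector of \eqn{l_k}, one per layer (nondecreasing).
#' @export
receptive_field <- function(kernels, strides) {
  kernels <- as.integer(kernels); strides <- as.integer(strides)
  stopifnot(length(kernels) >= 1L, length(kernels) == length(strides),
            all(kernels >= 1L), all(strides >= 1L))
  l <- 1L
  jump <- 1L   # product of strides of preceding layers
  out <- integer(length(kernels))
  for (k in seq_along(kernels)) {
    l <- l + (kernels[k] - 1L) * jump
    out[k] <- l
    jump <- jump * strides[k]
  }
  out
}

#' Flattened layer list of an architecture
#'
#' @param arch A [recnn_arch()].
#' @param pooling_only If `TRUE`, return only the downsampling (pooling)
#'   stack — the reading under which the backbone's receptive field is
#'   32 per axis; if `FALSE`, interleave the convolutions too.
#' @return Data frame with columns `layer`, `kernel`, `stride`.
#' @export
arch_layers <- function(arch, pooling_only = FALSE) {
  stopifnot(inherits(arch, "recnn_arch"))
  if (pooling_only) {
    data.frame(layer = paste0("pool", seq_len(arch$n_blocks)),
               kernel = rep(arch$pool_kernel, arch$n_blocks),
               stride = rep(arch$pool_stride, arch$n_blocks))
  } else {
    data.frame(
      layer = as.vector(rbind(paste0("conv", seq_len(arch$n_blocks)),
                              paste0("pool", seq_len(arch$n_blocks)))),
      kernel = rep(c(arch$conv_kernel, arch$pool_kernel), arch$n_blocks),
      stride = rep(c(arch$conv_stride, arch$pool_stride), arch$n_blocks))
  }
}

#' @export
print.recnn_arch <- function(x, ...) {
  cat("3D convolutional backbone:", x$n_blocks, "blocks",
      "(conv3 'same' + batch norm + ReLU + ceil-mode maxpool2)\n")
  cat("  input :", paste(x$input_shape, collapse = " x "), "\n")
  cat("  channels:", paste(x$channels, collapse = " -> "), "\n")
  cat("  output:", x$channels[x$n_blocks], "maps of",
      paste(x$output_spatial, collapse = " x "),
      sprintf("(flattened dim %d)\n", x$feature_dim))
  rf <- receptive_field(rep(x$pool_kernel, x$n_blocks),
                        rep(x$pool_stride, x$n_blocks))
  cat("  receptive field (downsampling stack):",
      rf[length(rf)], "per axis\n")
  invisible(x)
}
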