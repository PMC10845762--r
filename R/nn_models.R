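#' Network architecture configuration
#'
#' @param kind `"modified_unet"` (sinogram completion network) or
#'   `"modified_resunet"` (image denoising network).
#' @param depth number of down-sampling stages (default 3). Down-sampling
#'   always uses strided convolution (stride 2), never max-pooling.
#' @param base_channels feature channels at the first stage, doubled at
#'   each deeper stage (default 16).
#' @param patch_size training/inference patch side in pixels: 64 for the
#'   sinogram network, 48 for the image network. Must be divisible by
#'   `2^depth`.
#' @return An object of class `net_config`.
#' @export
net_config <- function(kind = c("modified_unet", "modified_resunet"),
                       depth = 3L, base_channels = 16L,
                       patch_size = NULL) {
  kind <- match.arg(kind)
  depth <- as.integer(depth)
  base_channels <- as.integer(base_channels)
  stopifnot(depth >= 1, base_channels >= 1)
  if (is.null(patch_size)) {
    patch_size <- if (kind == "modified_unet") 64L else 48L
  }
  patch_size <- as.integer(patch_size)
  if (patch_size %% 2^depth != 0) {
    stop("patch_size (", patch_size, ") must be divisible by 2^depth (",
         2^depth, ")", call. = FALSE)
  }
  structure(list(kind = kind, depth = depth, base_channels = base_channels,
                 patch_size = patch_size),
            class = "net_config")
}

finish_net <- function(gr, config, seed_used) {
  structure(list(kind = config$kind, config = config,
                 nodes = gr$nodes, params = gr$params,
                 norm = list(lo = 0, hi = 1),
                 trained = FALSE, init_seed = seed_used),
            class = "sinomar_net")
}

#' Build the modified U-Net (sinogram synthesis network)
#'
#' Encoder-decoder with two structural modifications relative to a plain
#' U-Net: pooling is replaced by 3x3 convolutions with stride 2 (the
#' down-sampling itself is learned, preserving input detail), and the
#' input is connected to the final layer by an additive skip, so the
#' network learns a residual correction on top of its input and a freshly
#' initialized network is exactly the identity map. Encoder features are
#' concatenated into the decoder at matching resolutions, and channels
#' double at each stage. All convolutions are 3x3 with ReLU activations
#' and no normalization layers; the final 3x3 projection to one channel is
#' linear and zero-initialized.
#'
#' @param config a [net_config()] with `kind = "modified_unet"`.
#' @param seed optional integer seed for the weight initialization.
#' @return An untrained `sinomar_net`; input and output shapes are equal
#'   for any input whose sides are divisible by `2^depth`.
#' @export
build_modified_unet <- function(config = net_config("modified_unet"),
                                seed = NULL) {
  stopifnot(inherits(config, "net_config"))
  if (config$kind != "modified_unet") {
    stop("config$kind must be 'modified_unet', got ", config$kind,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  ch <- config$base_channels * 2^(seq_len(d + 1) - 1)  # stage channels
  gr <- ng_new()
  x <- ng_input(gr)
  enc <- integer(d)
  cur <- x
  c_cur <- 1L
  for (i in seq_len(d)) {
    h <- ng_conv(gr, cur, c_cur, ch[i])             # stage features
    enc[i] <- h
    cur <- ng_conv(gr, h, ch[i], ch[i + 1], stride = 2)  # strided-conv pool
    c_cur <- ch[i + 1]
  }
  cur <- ng_conv(gr, cur, c_cur, c_cur)             # bottleneck
  for (i in rev(seq_len(d))) {
    cur <- ng_up2(gr, cur)
    cur <- ng_conv(gr, cur, c_cur, ch[i])
    cur <- ng_concat(gr, cur, enc[i])               # encoder->decoder skip
    cur <- ng_conv(gr, cur, 2L * ch[i], ch[i])
    c_cur <- ch[i]
  }
  y <- ng_conv(gr, cur, ch[1], 1L, relu = FALSE, zero = TRUE)
  ng_add(gr, y, x)                                  # global input residual
  finish_net(gr, config, seed)
}

#' Build the modified ResU-Net (image denoising network)
#'
#' U-Net backbone sharing the strided-convolution down-sampling and the
#' global input-to-output residual of [build_modified_unet()], with two
#' differences: cross-stage connections from encoder to decoder are
#' additive rather than concatenative, and every stage contains a residual
#' block (`relu(h + conv(relu(conv(h))))`), so detail flows across and
#' within stages by summation. The final projection is zero-initialized,
#' making the fresh network an identity map.
#'
#' @param config a [net_config()] with `kind = "modified_resunet"`.
#' @param seed optional integer seed for the weight initialization.
#' @return An untrained `sinomar_net`.
#' @export
build_modified_resunet <- function(config = net_config("modified_resunet"),
                                   seed = NULL) {
  stopifnot(inherits(config, "net_config"))
  if (config$kind != "modified_resunet") {
    stop("config$kind must be 'modified_resunet', got ", config$kind,
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- config$depth
  ch <- config$base_channels * 2^(seq_len(d + 1) - 1)
  gr <- ng_new()
  res_block <- function(h, c) {
    n1 <- ng_conv(gr, h, c, c)                      # conv + relu
    n2 <- ng_conv(gr, n1, c, c, relu = FALSE)
    ng_relu(gr, ng_add(gr, n2, h))                  # within-stage residual
  }
  x <- ng_input(gr)
  cur <- ng_conv(gr, x, 1L, ch[1])                  # stem
  enc <- integer(d)
  for (i in seq_len(d)) {
    h <- res_block(cur, ch[i])
    enc[i] <- h
    cur <- ng_conv(gr, h, ch[i], ch[i + 1], stride = 2)
  }
  cur <- res_block(cur, ch[d + 1])
  for (i in rev(seq_len(d))) {
    cur <- ng_up2(gr, cur)
    cur <- ng_conv(gr, cur, ch[i + 1], ch[i])
    cur <- ng_add(gr, cur, enc[i])                  # additive cross-stage
    cur <- res_block(cur, ch[i])
  }
  y <- ng_conv(gr, cur, ch[1], 1L, relu = FALSE, zero = TRUE)
  ng_add(gr, y, x)
  finish_net(gr, config, seed)
}

#' @export
print.sinomar_net <- function(x, ...) {
  cat(sprintf("sinomar_net (%s): depth %d, base %d channels, %d parameters%s\n",
              x$kind, x$config$depth, x$config$base_channels,
              count_params(x),
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}
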