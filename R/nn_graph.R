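# Small static computation-graph engine backing the two network
# architectures. A model is a list of nodes evaluated in order; each node
# is one of: input, conv (3x3 or 1x1, stride 1 or 2, zero padding), relu,
# up2 (nearest-neighbour 2x up-sampling), add, concat (channels).
# Activations are arrays with dims (H, W, C, N). Backpropagation walks the
# node list in reverse; convolution kernels run in C++ (im2col + BLAS).

ng_new <- function() {
  env <- new.env(parent = emptyenv())
  env$nodes <- list()
  env$params <- list()
  env
}

ng_add_node <- function(gr, node) {
  gr$nodes[[length(gr$nodes) + 1L]] <- node
  length(gr$nodes)
}

ng_input <- function(gr) ng_add_node(gr, list(op = "input"))

# He-normal initialization; `zero = TRUE` for the final projection so the
# freshly built network is exactly the identity through its global
# residual connection.
ng_conv <- function(gr, input, c_in, c_out, k = 3L, stride = 1L,
                    relu = TRUE, zero = FALSE) {
  w <- array(if (zero) 0 else rnorm(k * k * c_in * c_out,
                                    sd = sqrt(2 / (k * k * c_in))),
             dim = c(k, k, c_in, c_out))
  b <- numeric(c_out)
  gr$params[[length(gr$params) + 1L]] <- list(w = w, b = b)
  i <- ng_add_node(gr, list(op = "conv", in1 = input,
                            param = length(gr$params),
                            stride = as.integer(stride),
                            pad = as.integer((k - 1) / 2)))
  if (relu) i <- ng_add_node(gr, list(op = "relu", in1 = i))
  i
}

ng_relu <- function(gr, input) ng_add_node(gr, list(op = "relu", in1 = input))
ng_up2 <- function(gr, input) ng_add_node(gr, list(op = "up2", in1 = input))
ng_add <- function(gr, a, b) ng_add_node(gr, list(op = "add", in1 = a, in2 = b))
ng_concat <- function(gr, a, b) {
  ng_add_node(gr, list(op = "concat", in1 = a, in2 = b))
}

concat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

nn_forward <- function(model, x, keep_acts = FALSE) {
  nodes <- model$nodes
  params <- model$params
  acts <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    nd <- nodes[[i]]
    acts[[i]] <- switch(nd$op,
      input = x,
      conv = {
        p <- params[[nd$param]]
        cpp_conv_fwd(acts[[nd$in1]], p$w, p$b, nd$stride, nd$pad)
      },
      relu = pmax(acts[[nd$in1]], 0),
      up2 = cpp_upsample2_fwd(acts[[nd$in1]]),
      add = acts[[nd$in1]] + acts[[nd$in2]],
      concat = concat_channels(acts[[nd$in1]], acts[[nd$in2]]),
      stop("unknown op ", nd$op))
  }
  if (keep_acts) acts else acts[[length(acts)]]
}

# Returns gradients with respect to every conv parameter (same structure
# as model$params). `gout` is dLoss/dOutput for the final node.
nn_backward <- function(model, acts, gout) {
  nodes <- model$nodes
  params <- model$params
  n <- length(nodes)
  g <- vector("list", n)
  g[[n]] <- gout
  grads <- lapply(params, function(p) {
    list(w = array(0, dim(p$w)), b = numeric(length(p$b)))
  })
  acc <- function(i, val) {
    if (is.null(g[[i]])) g[[i]] <<- val else g[[i]] <<- g[[i]] + val
  }
  for (i in rev(seq_len(n))) {
    gi <- g[[i]]
    if (is.null(gi)) next
    nd <- nodes[[i]]
    switch(nd$op,
      input = NULL,
      conv = {
        p <- params[[nd$param]]
        res <- cpp_conv_bwd(acts[[nd$in1]], p$w, gi, nd$stride, nd$pad)
        grads[[nd$param]]$w <- grads[[nd$param]]$w + res$gw
        grads[[nd$param]]$b <- grads[[nd$param]]$b + res$gb
        acc(nd$in1, res$gx)
      },
      relu = acc(nd$in1, gi * (acts[[nd$in1]] > 0)),
      up2 = acc(nd$in1, cpp_upsample2_bwd(gi)),
      add = {
        acc(nd$in1, gi)
        acc(nd$in2, gi)
      },
      concat = {
        c1 <- dim(acts[[nd$in1]])[3]
        c2 <- dim(acts[[nd$in2]])[3]
        acc(nd$in1, gi[, , seq_len(c1), , drop = FALSE])
        acc(nd$in2, gi[, , c1 + seq_len(c2), , drop = FALSE])
      })
    g[[i]] <- NULL   # free as we go
  }
  grads
}

#' Number of trainable parameters of a network
#'
#' @param model a `sinomar_net`.
#' @return integer count of weights plus biases over all convolutions.
#' @export
count_params <- function(model) {
  stopifnot(inherits(model, "sinomar_net"))
  sum(vapply(model$params,
             function(p) length(p$w) + length(p$b), numeric(1)))
}

#' Run a network on a batch of patches
#'
#' Applies the model's stored intensity normalization (linear map of the
#' training data range onto `[0, 1]`), evaluates the network, and maps the
#' result back. The forward pass has no stochastic layers: two evaluations
#' of the same input are bit-identical.
#'
#' @param model a `sinomar_net`.
#' @param x array `(H, W, 1, N)` or a single `H x W` matrix.
#' @return array (or matrix, matching the input form) of predictions.
#' @export
nn_predict <- function(model, x) {
  stopifnot(inherits(model, "sinomar_net"))
  was_mat <- is.matrix(x)
  if (was_mat) x <- array(x, c(nrow(x), ncol(x), 1, 1))
  stopifnot(length(dim(x)) == 4)
  d <- dim(x)
  if (d[1] %% 2^model$config$depth != 0 || d[2] %% 2^model$config$depth != 0) {
    stop("input size ", d[1], "x", d[2], " is not divisible by 2^depth = ",
         2^model$config$depth, call. = FALSE)
  }
  lo <- model$norm$lo
  hi <- model$norm$hi
  scale <- if (hi > lo) hi - lo else 1
  y <- nn_forward(model, (x - lo) / scale) * scale + lo
  if (was_mat) matrix(y, d[1], d[2]) else y
}
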