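#' Iterative reconstruction configuration
#'
#' Parameters of the penalized weighted-least-squares (PWLS) comparison
#' baseline: the regularization weight (smoothness control), the
#' edge-preservation threshold of the Huber potential, and the iteration
#' count. The preset `ir_config(150, 1e-5, 100)` mirrors the
#' penalized-likelihood comparison setting used alongside FBP.
#'
#' @param smoothness regularization weight `beta >= 0` (default 150).
#' @param edge_preservation Huber threshold `delta > 0`: neighbour
#'   differences below it are penalized quadratically, above it linearly,
#'   so edges larger than `delta` are preserved (default 1e-5).
#' @param n_iterations iteration count, >= 1 (default 100).
#' @return An object of class `ir_config`.
#' @export
ir_config <- function(smoothness = 150, edge_preservation = 1e-5,
                      n_iterations = 100) {
  stopifnot(smoothness >= 0, edge_preservation > 0, n_iterations >= 1)
  structure(list(smoothness = smoothness,
                 edge_preservation = edge_preservation,
                 n_iterations = as.integer(n_iterations)),
            class = "ir_config")
}

#' Penalized weighted-least-squares reconstruction
#'
#' Minimizes `0.5 * ||A x - y||^2 + beta * sum_j sum_{k in N(j)}
#' psi_delta(x_j - x_k)` over images `x`, where `A` is the line-integral
#' projector, `N(j)` are the 4-connected neighbours and `psi_delta` is the
#' Huber edge-preserving potential (`t^2 / 2` for `|t| <= delta`, else
#' `delta * |t| - delta^2 / 2`). Optimized by gradient descent with a
#' backtracking line search that guarantees a monotone non-increasing
#' objective; `A^T` is the exact adjoint of the projector, so the descent
#' direction is a true gradient. The noise weighting `W` is the identity.
#'
#' This reconstructor is a comparison baseline, not part of the proposed
#' pipeline.
#'
#' @param sino a fully valid [sinogram()].
#' @param config an [ir_config()].
#' @param x0 optional starting image matrix (default all zeros).
#' @param track_objective if `TRUE`, attach the per-iteration objective as
#'   attribute `"objective"` of the result.
#' @return An [image_slice()]; with `track_objective = TRUE` the attribute
#'   `"objective"` holds the objective value after each iteration
#'   (non-increasing).
#' @export
pwls_reconstruct <- function(sino, config = ir_config(), x0 = NULL,
                             track_objective = FALSE) {
  stopifnot(inherits(sino, "sinogram"), inherits(config, "ir_config"))
  if (!all(sino$valid)) {
    stop("sinogram has invalid entries; complete it before reconstruction",
         call. = FALSE)
  }
  g <- sino$geometry
  y <- sino$values
  n <- g$image_size
  angles <- view_angles(g)
  beta <- config$smoothness
  delta <- config$edge_preservation

  A <- function(x) cpp_forward_project(x, angles, g$n_bins, g$bin_spacing,
                                       g$pixel_size)
  At <- function(r) cpp_forward_adjoint(r, angles, n, g$bin_spacing,
                                        g$pixel_size)
  x <- if (is.null(x0)) matrix(0, n, n) else x0
  stopifnot(all(dim(x) == c(n, n)))

  huber <- function(t) ifelse(abs(t) <= delta, t^2 / 2,
                              delta * abs(t) - delta^2 / 2)
  huber_d <- function(t) ifelse(abs(t) <= delta, t, delta * sign(t))
  neigh_diffs <- function(x) {
    list(h = x[, -1, drop = FALSE] - x[, -ncol(x), drop = FALSE],
         v = x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE])
  }
  objective <- function(x, Ax) {
    d <- neigh_diffs(x)
    0.5 * sum((Ax - y)^2) + beta * (sum(huber(d$h)) + sum(huber(d$v)))
  }
  penalty_grad <- function(x) {
    d <- neigh_diffs(x)
    gh <- huber_d(d$h)
    gv <- huber_d(d$v)
    gr <- matrix(0, n, n)
    gr[, -1] <- gr[, -1] + gh
    gr[, -n] <- gr[, -n] - gh
    gr[-1, ] <- gr[-1, ] + gv
    gr[-n, ] <- gr[-n, ] - gv
    gr
  }

  Ax <- A(x)
  obj <- objective(x, Ax)
  obj_trace <- numeric(config$n_iterations)
  step <- 1 / max(sum(abs(At(A(matrix(1, n, n))))) / n^2, 1e-12)  # crude 1/L
  for (it in seq_len(config$n_iterations)) {
    grad <- At(Ax - y) + beta * penalty_grad(x)
    accepted <- FALSE
    for (ls in 1:40) {
      x_new <- x - step * grad
      Ax_new <- A(x_new)
      obj_new <- objective(x_new, Ax_new)
      if (obj_new <= obj + 1e-12 * max(1, abs(obj))) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) {
      stop(sprintf(paste0(
        "PWLS line search failed to decrease the objective at iteration %d ",
        "(objective %.6g, step %.3g): divergence"), it, obj, step),
        call. = FALSE)
    }
    x <- x_new
    Ax <- Ax_new
    obj <- obj_new
    obj_trace[it] <- obj
    step <- step * 1.3
  }
  out <- image_slice(x, g)
  if (track_objective) attr(out, "objective") <- obj_trace
  out
}
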