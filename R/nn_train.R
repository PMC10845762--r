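#' Training configuration
#'
#' Optimization hyperparameters for [train_model()]. The per-stage
#' defaults mirror the reference training setup: the sinogram network
#' (`stage = "sino"`) uses 180,000 training and 18,000 validation patches,
#' 100 epochs and learning rate 1e-5; the image network (`stage = "image"`)
#' uses 458,640 / 80,000 patches, 1300 epochs and learning rate 1e-3. Both
#' optimize the RMSE loss with Adam. These cluster-scale presets are
#' configurable downward; [desk_train_config()] provides the scaled-down
#' preset used throughout the tests and examples.
#'
#' @param stage `"sino"` or `"image"`, selecting the per-stage defaults.
#' @param n_train_patches,n_val_patches patch budget; the validation count
#'   must be smaller than the training count.
#' @param epochs number of passes over the training patches.
#' @param learning_rate Adam step size (> 0).
#' @param batch_size minibatch size (default 16).
#' @param seed integer seed controlling shuffling (and any patch sampling
#'   done with the same seed).
#' @return An object of class `train_config` with fields including
#'   `optimizer = "adam"` and `loss = "rmse"`.
#' @export
train_config <- function(stage = c("sino", "image"),
                         n_train_patches = NULL, n_val_patches = NULL,
                         epochs = NULL, learning_rate = NULL,
                         batch_size = 16L, seed = 1L) {
  stage <- match.arg(stage)
  defaults <- if (stage == "sino") {
    list(n_train_patches = 180000L, n_val_patches = 18000L,
         epochs = 100L, learning_rate = 0.00001)
  } else {
    list(n_train_patches = 458640L, n_val_patches = 80000L,
         epochs = 1300L, learning_rate = 0.001)
  }
  cfg <- list(
    stage = stage,
    n_train_patches = as.integer(n_train_patches %||%
                                   defaults$n_train_patches),
    n_val_patches = as.integer(n_val_patches %||% defaults$n_val_patches),
    epochs = as.integer(epochs %||% defaults$epochs),
    learning_rate = learning_rate %||% defaults$learning_rate,
    batch_size = as.integer(batch_size),
    optimizer = "adam", loss = "rmse", seed = as.integer(seed))
  stopifnot(cfg$learning_rate > 0, cfg$epochs >= 1,
            cfg$n_val_patches < cfg$n_train_patches, cfg$batch_size >= 1)
  structure(cfg, class = "train_config")
}

#' Scaled-down training preset
#'
#' A small-budget [train_config()] for single-CPU runs: 512 training and
#' 64 validation patches, 20 epochs, learning rate 1e-3. The learning rate
#' is raised relative to the sinogram stage's cluster-scale preset because
#' with 350x fewer patches per epoch the parameter update count shrinks
#' accordingly.
#'
#' @inheritParams train_config
#' @param ... overrides passed to [train_config()].
#' @export
desk_train_config <- function(stage = c("sino", "image"), ...) {
  stage <- match.arg(stage)
  defaults <- list(stage = stage, n_train_patches = 512L,
                   n_val_patches = 64L, epochs = 20L, learning_rate = 1e-3)
  do.call(train_config, modifyList(defaults, list(...)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract aligned training patch pairs
#'
#' Draws `n_patches` aligned `(input, target)` patch pairs from one or
#' more image pairs. The sampling probability of a patch position is
#' proportional to `sampling_weights`; by default this is the local
#' artifact energy — the mean absolute input-target difference over the
#' patch — which emphasizes regions destroyed by artifacts, emulating the
#' hand-selection of informative patches. Reproducible under a fixed seed.
#'
#' @param inputs,targets matrices, or lists of matrices of equal shapes,
#'   each at least `patch_size` in both dimensions.
#' @param patch_size patch side in pixels.
#' @param n_patches number of pairs to draw (> 0).
#' @param sampling_weights `"artifact"` (default), `"uniform"`, or a list
#'   of user weight matrices of dimension
#'   `(nrow - patch_size + 1) x (ncol - patch_size + 1)` per image.
#' @param seed integer seed.
#' @return An object of class `patch_set`: arrays `input` and `target` of
#'   dims `(patch_size, patch_size, 1, n_patches)` plus the drawn
#'   positions.
#' @export
extract_patches <- function(inputs, targets, patch_size, n_patches,
                            sampling_weights = "artifact", seed = 1L) {
  if (is.matrix(inputs)) inputs <- list(inputs)
  if (is.matrix(targets)) targets <- list(targets)
  stopifnot(length(inputs) == length(targets), length(inputs) >= 1)
  n_patches <- as.integer(n_patches)
  if (n_patches <= 0) stop("n_patches must be positive", call. = FALSE)
  p <- as.integer(patch_size)
  for (i in seq_along(inputs)) {
    stopifnot(all(dim(inputs[[i]]) == dim(targets[[i]])))
    if (nrow(inputs[[i]]) < p || ncol(inputs[[i]]) < p) {
      stop("image ", i, " (", nrow(inputs[[i]]), "x", ncol(inputs[[i]]),
           ") is smaller than the patch size ", p, call. = FALSE)
    }
  }
  # per-image position weight maps
  wmaps <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    nr <- nrow(inputs[[i]]) - p + 1
    nc <- ncol(inputs[[i]]) - p + 1
    if (is.list(sampling_weights)) {
      w <- sampling_weights[[i]]
      stopifnot(all(dim(w) == c(nr, nc)), all(w >= 0))
    } else if (identical(sampling_weights, "uniform")) {
      w <- matrix(1, nr, nc)
    } else if (identical(sampling_weights, "artifact")) {
      w <- patch_mean_abs_diff(inputs[[i]], targets[[i]], p) + 1e-12
    } else {
      stop("sampling_weights must be 'artifact', 'uniform' or a list of ",
           "weight matrices", call. = FALSE)
    }
    wmaps[[i]] <- w
  }
  img_w <- vapply(wmaps, sum, numeric(1))
  withr_seed(seed, {
    img_idx <- sample.int(length(inputs), n_patches, replace = TRUE,
                          prob = img_w)
    rows <- integer(n_patches)
    cols <- integer(n_patches)
    for (i in unique(img_idx)) {
      sel <- which(img_idx == i)
      w <- wmaps[[i]]
      pos <- sample.int(length(w), length(sel), replace = TRUE, prob = w)
      rows[sel] <- (pos - 1) %% nrow(w) + 1
      cols[sel] <- (pos - 1) %/% nrow(w) + 1
    }
  })
  xin <- array(0, c(p, p, 1, n_patches))
  xtg <- array(0, c(p, p, 1, n_patches))
  for (k in seq_len(n_patches)) {
    r <- rows[k]:(rows[k] + p - 1)
    cc <- cols[k]:(cols[k] + p - 1)
    xin[, , 1, k] <- inputs[[img_idx[k]]][r, cc]
    xtg[, , 1, k] <- targets[[img_idx[k]]][r, cc]
  }
  structure(list(input = xin, target = xtg, patch_size = p,
                 positions = data.frame(image = img_idx, row = rows,
                                        col = cols)),
            class = "patch_set")
}

# Mean |input - target| over every patch-size window, via integral image.
patch_mean_abs_diff <- function(input, target, p) {
  d <- abs(input - target)
  ii <- matrix(0, nrow(d) + 1, ncol(d) + 1)
  ii[-1, -1] <- t(apply(apply(d, 2, cumsum), 1, cumsum))
  nr <- nrow(d) - p + 1
  nc <- ncol(d) - p + 1
  r1 <- seq_len(nr)
  c1 <- seq_len(nc)
  (ii[r1 + p, c1 + p, drop = FALSE] - ii[r1, c1 + p, drop = FALSE] -
      ii[r1 + p, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]) / p^2
}

# run code under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  eval.parent(substitute(code))
}

#' Train a network on a patch set
#'
#' Minimizes the RMSE loss `sqrt(mean((model(input) - target)^2))` with
#' Adam for `config$epochs` epochs. The patch set is split into training
#' and validation subsets (a seeded random split of sizes taken from the
#' configuration, capped at the available patches); intensities are
#' normalized to `[0, 1]` using the joint min/max of the training data,
#' which is stored with the model and re-applied at inference. The
#' validation loss is evaluated before training (epoch 0) and after every
#' epoch, and the returned model carries the weights of the best
#' validation epoch — for these residual architectures the initial network
#' is the identity, so the returned model is never worse on validation
#' than its input initialization. Training is reproducible under a fixed
#' seed in single-threaded execution.
#'
#' @param model an untrained (or previously trained) `sinomar_net`.
#' @param patches a [extract_patches()] result.
#' @param config a [train_config()] / [desk_train_config()].
#' @return An object of class `train_state`: `model` (with best weights),
#'   `train_loss` and `val_loss` (per completed epoch), `val_loss0`
#'   (epoch-0 validation loss), `best_epoch` (0 means the initial
#'   weights), and the configuration.
#' @export
train_model <- function(model, patches, config) {
  stopifnot(inherits(model, "sinomar_net"), inherits(patches, "patch_set"),
            inherits(config, "train_config"))
  n_all <- dim(patches$input)[4]
  n_val <- min(config$n_val_patches, max(1, floor(n_all / 5)))
  n_train <- min(config$n_train_patches, n_all - n_val)
  if (n_train < 1) stop("not enough patches to train", call. = FALSE)

  withr_seed(config$seed + 1L, {
    perm <- sample.int(n_all)
  })
  idx_val <- perm[seq_len(n_val)]
  idx_train <- perm[n_val + seq_len(n_train)]

  lo <- min(patches$input[, , , idx_train], patches$target[, , , idx_train])
  hi <- max(patches$input[, , , idx_train], patches$target[, , , idx_train])
  scale <- if (hi > lo) hi - lo else 1
  model$norm <- list(lo = lo, hi = hi)
  norm <- function(a) (a - lo) / scale

  xin <- norm(patches$input)
  xtg <- norm(patches$target)
  take <- function(a, idx) a[, , , idx, drop = FALSE]

  batch_loss <- function(params, idx, want_grad = FALSE) {
    model$params <- params
    x <- take(xin, idx)
    t <- take(xtg, idx)
    acts <- nn_forward(model, x, keep_acts = want_grad)
    pred <- if (want_grad) acts[[length(acts)]] else acts
    resid <- pred - t
    rmse <- sqrt(mean(resid^2))
    if (!want_grad) return(rmse)
    gout <- if (rmse > 1e-12) resid / (length(resid) * rmse) else resid * 0
    list(loss = rmse, grads = nn_backward(model, acts, gout))
  }
  eval_set <- function(params, idx) {
    # batched forward pass; RMSE over the whole set
    sq <- 0
    nel <- 0
    for (chunk in split(idx, ceiling(seq_along(idx) / 64))) {
      model$params <- params
      pred <- nn_forward(model, take(xin, chunk))
      sq <- sq + sum((pred - take(xtg, chunk))^2)
      nel <- nel + length(pred)
    }
    sqrt(sq / nel)
  }

  params <- model$params
  mstate <- lapply(params, function(p) {
    list(w = array(0, dim(p$w)), b = numeric(length(p$b)))
  })
  vstate <- mstate
  b1 <- 0.9
  b2 <- 0.999
  eps <- 1e-8
  lr <- config$learning_rate
  tstep <- 0

  val0 <- eval_set(params, idx_val)
  best_val <- val0
  best_params <- params
  best_epoch <- 0L
  train_hist <- numeric(config$epochs)
  val_hist <- numeric(config$epochs)

  for (ep in seq_len(config$epochs)) {
    withr_seed(config$seed + 1000L + ep, {
      ord <- sample(idx_train)
    })
    ep_losses <- c()
    for (batch in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      res <- batch_loss(params, batch, want_grad = TRUE)
      if (!is.finite(res$loss)) {
        stop(sprintf(
          "non-finite training loss at epoch %d (lr %.3g): training failure",
          ep, lr), call. = FALSE)
      }
      ep_losses <- c(ep_losses, res$loss)
      tstep <- tstep + 1
      corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
      for (j in seq_along(params)) {
        for (fld in c("w", "b")) {
          gvec <- res$grads[[j]][[fld]]
          mstate[[j]][[fld]] <- b1 * mstate[[j]][[fld]] + (1 - b1) * gvec
          vstate[[j]][[fld]] <- b2 * vstate[[j]][[fld]] + (1 - b2) * gvec^2
          params[[j]][[fld]] <- params[[j]][[fld]] -
            lr * corr * mstate[[j]][[fld]] /
              (sqrt(vstate[[j]][[fld]]) + eps)
        }
      }
    }
    train_hist[ep] <- mean(ep_losses)
    val_hist[ep] <- eval_set(params, idx_val)
    if (val_hist[ep] < best_val) {
      best_val <- val_hist[ep]
      best_params <- params
      best_epoch <- ep
    }
  }
  model$params <- best_params
  model$trained <- TRUE
  structure(list(model = model, train_loss = train_hist,
                 val_loss = val_hist, val_loss0 = val0,
                 best_epoch = best_epoch, best_val = best_val,
                 config = config,
                 n_train = n_train, n_val = n_val),
            class = "train_state")
}

#' @export
print.train_state <- function(x, ...) {
  cat(sprintf(paste0(
    "train_state: %d epochs on %d patches (%d validation)\n",
    "  validation loss %.5g (epoch 0) -> %.5g (best, epoch %d)\n"),
    length(x$train_loss), x$n_train, x$n_val,
    x$val_loss0, x$best_val, x$best_epoch))
  invisible(x)
}

#' Write training curves to CSV
#'
#' @param state a [train_model()] result.
#' @param path output CSV path; columns `epoch`, `train_loss`, `val_loss`.
#' @return the path, invisibly.
#' @export
write_training_curves <- function(state, path) {
  stopifnot(inherits(state, "train_state"))
  df <- data.frame(epoch = seq_along(state$train_loss),
                   train_loss = state$train_loss,
                   val_loss = state$val_loss)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
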