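# Overlapping-patch inference: tile a 2-D array, run the network on every
# patch (batched), and blend overlaps by uniform averaging. Tile origins
# step by `stride`; the final tile in each direction is clamped so the
# whole array is covered even when the size is not a multiple of the
# stride.

tile_positions <- function(n, patch, stride) {
  if (n < patch) {
    stop("array side ", n, " is smaller than the patch size ", patch,
         call. = FALSE)
  }
  unique(c(seq(1, n - patch + 1, by = stride), n - patch + 1))
}

apply_model_tiled <- function(mat, model, patch_size = NULL, stride = NULL,
                              batch = 32L) {
  stopifnot(inherits(model, "sinomar_net"), is.matrix(mat))
  p <- as.integer(patch_size %||% model$config$patch_size)
  if (p %% 2^model$config$depth != 0) {
    stop("patch_size ", p, " is not divisible by 2^depth", call. = FALSE)
  }
  stride <- as.integer(stride %||% max(p %/% 2, 1))
  rows <- tile_positions(nrow(mat), p, stride)
  cols <- tile_positions(ncol(mat), p, stride)
  pos <- expand.grid(r = rows, c = cols)
  acc <- matrix(0, nrow(mat), ncol(mat))
  cnt <- matrix(0, nrow(mat), ncol(mat))
  for (chunk in split(seq_len(nrow(pos)), ceiling(seq_len(nrow(pos)) / batch))) {
    x <- array(0, c(p, p, 1, length(chunk)))
    for (k in seq_along(chunk)) {
      i <- pos$r[chunk[k]]
      j <- pos$c[chunk[k]]
      x[, , 1, k] <- mat[i:(i + p - 1), j:(j + p - 1)]
    }
    y <- nn_predict(model, x)
    for (k in seq_along(chunk)) {
      i <- pos$r[chunk[k]]
      j <- pos$c[chunk[k]]
      acc[i:(i + p - 1), j:(j + p - 1)] <-
        acc[i:(i + p - 1), j:(j + p - 1)] + y[, , 1, k]
      cnt[i:(i + p - 1), j:(j + p - 1)] <-
        cnt[i:(i + p - 1), j:(j + p - 1)] + 1
    }
  }
  acc / cnt
}
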