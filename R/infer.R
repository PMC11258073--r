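#' Sliding-window inference over a whole volume
#'
#' Tiles the volume with patch-sized windows (configurable overlap),
#' averages logits where windows overlap, and takes the argmax. Volumes
#' smaller than the patch in any axis are reflect-padded and the result is
#' cropped back, so inference never fails on size. Class ties at the
#' argmax go to the lowest class code. Deterministic (no dropout at
#' inference).
#'
#' @param model a `trained_unet`.
#' @param volume `ct_volume` on the model's working grid.
#' @param overlap fraction of patch overlap between neighbouring windows
#'   (0 = abutting tiles, 0.5 = half-patch steps).
#' @return A `label_mask` with exactly the input's shape.
#' @export
sliding_window_infer <- function(model, volume, overlap = 0.5) {
  stopifnot(inherits(model, "trained_unet"), inherits(volume, "ct_volume"))
  logits <- sw_logits(model$net, normalize_hu(volume$values),
                      model$config$patch_size, overlap)
  label_mask(argmax_labels(logits), volume$spacing, volume$origin)
}

argmax_labels <- function(logits) {
  C <- dim(logits)[4]
  m <- matrix(logits, ncol = C)
  # ties.method = "first": the lowest class code wins a logit tie
  array(max.col(m, ties.method = "first") - 1L, dim = dim(logits)[1:3])
}

sw_logits <- function(net, values, patch, overlap = 0.5) {
  d0 <- dim(values)
  pad <- pmax(patch - d0, 0L)
  if (any(pad > 0L)) values <- reflect_pad3(values, pad)
  d <- dim(values)
  starts <- lapply(1:3, function(ax) window_starts(d[ax], patch[ax], overlap))
  acc <- array(0, dim = c(d, 4L))
  cnt <- array(0, dim = d)
  for (sz in starts[[1]]) for (sy in starts[[2]]) for (sx in starts[[3]]) {
    iz <- sz:(sz + patch[1] - 1L)
    iy <- sy:(sy + patch[2] - 1L)
    ix <- sx:(sx + patch[3] - 1L)
    x <- array(values[iz, iy, ix], dim = c(patch, 1L))
    lg <- unet_forward(net, x, train = FALSE)$logits
    acc[iz, iy, ix, ] <- acc[iz, iy, ix, , drop = FALSE] + lg
    cnt[iz, iy, ix] <- cnt[iz, iy, ix] + 1
  }
  acc <- acc / as.vector(cnt)      # recycles over the class axis
  acc[seq_len(d0[1]), seq_len(d0[2]), seq_len(d0[3]), , drop = FALSE]
}

window_starts <- function(n, p, overlap) {
  if (p >= n) return(1L)
  stride <- max(1L, as.integer(round(p * (1 - overlap))))
  s <- seq.int(1L, n - p + 1L, by = stride)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  s
}

reflect_pad3 <- function(arr, pad) {
  for (ax in 1:3) {
    p1 <- pad[1]
    if (p1 > 0L) {
      n <- dim(arr)[1]
      # mirror indices without repeating the edge; degenerate n = 1 repeats
      idx <- c(seq_len(n),
               if (n > 1L) pmax(1L, n - seq_len(p1)) else rep(1L, p1))
      arr <- arr[idx, , , drop = FALSE]
    }
    arr <- aperm(arr, c(2, 3, 1))
    pad <- pad[c(2, 3, 1)]
  }
  arr
}
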