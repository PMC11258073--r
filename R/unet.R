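#' Compact 3D U-Net for aortic root segmentation
#'
#' A standard encoder-decoder with skip connections: each resolution level
#' applies two 3x3x3 same-padded convolutions with instance normalization
#' and ReLU; levels are linked by 2x2x2 max pooling and nearest-neighbour
#' upsampling. Dropout (training only) precedes the last and second-to-last
#' convolution layers. The final 1x1x1 convolution emits one logit per
#' class (background, aorta, LM, RCA). Implemented in-package: im2col-based
#' convolutions in C++ with BLAS matrix products, exact hand-derived
#' backward passes, so training is fully reproducible from an R seed.
#'
#' @param levels number of resolution levels (>= 2).
#' @param width channels of the first level; doubled per level.
#' @param n_classes number of output classes.
#' @param seed RNG seed for He-initialized weights.
#' @return A `unet_params` list: `meta` (architecture) and `params`
#'   (named numeric arrays).
#' @export
unet_init <- function(levels = 3L, width = 8L, n_classes = 4L, seed = 1L) {
  stopifnot(levels >= 2L, width >= 1L)
  set.seed(seed)
  params <- list()
  he <- function(cout, cin, k) {
    matrix(rnorm(cout * cin * k^3, 0, sqrt(2 / (cin * k^3))),
           nrow = cout)
  }
  add_unit <- function(name, cin, cout) {
    params[[paste0(name, "_W")]] <<- he(cout, cin, 3)
    params[[paste0(name, "_b")]] <<- numeric(cout)
    params[[paste0(name, "_g")]] <<- rep(1, cout)
    params[[paste0(name, "_be")]] <<- numeric(cout)
  }
  chan <- width * 2^(seq_len(levels) - 1)
  cin <- 1L
  for (i in seq_len(levels)) {
    add_unit(sprintf("enc%d_c1", i), cin, chan[i])
    add_unit(sprintf("enc%d_c2", i), chan[i], chan[i])
    cin <- chan[i]
  }
  for (i in rev(seq_len(levels - 1L))) {
    add_unit(sprintf("dec%d_c1", i), chan[i + 1L] + chan[i], chan[i])
    add_unit(sprintf("dec%d_c2", i), chan[i], chan[i])
  }
  params[["final_W"]] <- he(n_classes, chan[1], 1)
  params[["final_b"]] <- numeric(n_classes)
  structure(list(meta = list(levels = levels, width = width,
                             n_classes = n_classes, channels = chan),
                 params = params),
            class = "unet_params")
}

IN_EPS <- 1e-5

conv_unit_fwd <- function(params, name, x, train) {
  W <- params[[paste0(name, "_W")]]
  b <- params[[paste0(name, "_b")]]
  g <- params[[paste0(name, "_g")]]
  be <- params[[paste0(name, "_be")]]
  dims <- dim(x)
  col <- cpp_im2col3(x, dims, 3L)
  z <- W %*% col + b
  C <- nrow(z); N <- ncol(z)
  zm <- t(z)                                     # N x C
  mu <- colMeans(zm)
  va <- colMeans(zm * zm) - mu^2
  istd <- 1 / sqrt(va + IN_EPS)
  xhat <- (zm - matrix(mu, N, C, byrow = TRUE)) *
    matrix(istd, N, C, byrow = TRUE)
  ynorm <- xhat * matrix(g, N, C, byrow = TRUE) +
    matrix(be, N, C, byrow = TRUE)
  act <- ynorm > 0
  y <- array(ynorm * act, dim = c(dims[1:3], C))
  cache <- if (train) list(col = col, x_dims = dims, xhat = xhat,
                           istd = istd, act = act, name = name) else NULL
  list(y = y, cache = cache)
}

conv_unit_bwd <- function(params, grads, cache, dy) {
  name <- cache$name
  W <- params[[paste0(name, "_W")]]
  g <- params[[paste0(name, "_g")]]
  C <- ncol(cache$xhat); N <- nrow(cache$xhat)
  dym <- matrix(dy, ncol = C) * cache$act        # through ReLU
  grads[[paste0(name, "_g")]] <- grads[[paste0(name, "_g")]] +
    colSums(dym * cache$xhat)
  grads[[paste0(name, "_be")]] <- grads[[paste0(name, "_be")]] +
    colSums(dym)
  dxhat <- dym * matrix(g, N, C, byrow = TRUE)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dz <- matrix(cache$istd / N, N, C, byrow = TRUE) *
    (N * dxhat - matrix(s1, N, C, byrow = TRUE) -
       cache$xhat * matrix(s2, N, C, byrow = TRUE))
  dzm <- t(dz)                                   # C x N
  grads[[paste0(name, "_W")]] <- grads[[paste0(name, "_W")]] +
    dzm %*% t(cache$col)
  grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] +
    rowSums(dzm)
  dcol <- crossprod(W, dzm)
  dx <- cpp_col2im3(dcol, cache$x_dims, 3L)
  list(grads = grads, dx = dx)
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

upsample2_bwd <- function(dy) {
  d <- dim(dy)
  out <- 0
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1)
    out <- out + dy[seq(1L + oz, d[1], 2L), seq(1L + oy, d[2], 2L),
                    seq(1L + ox, d[3], 2L), , drop = FALSE]
  out
}

#' Forward pass of the U-Net on one patch
#'
#' @param net `unet_params`.
#' @param x array (D, H, W, 1); extents must be divisible by
#'   `2^(levels - 1)`.
#' @param train keep caches for the backward pass and apply dropout.
#' @param dropout_rate dropout probability before the last two conv layers
#'   (training only; inverted dropout, so inference needs no rescaling).
#' @return list with `logits` (D, H, W, n_classes) and, when `train`,
#'   `cache`.
#' @export
unet_forward <- function(net, x, train = FALSE, dropout_rate = 0.5) {
  L <- net$meta$levels
  p <- net$params
  div <- 2^(L - 1L)
  if (any(dim(x)[1:3] %% div != 0))
    stop("patch extents must be divisible by ", div)
  cache <- list(enc = vector("list", L), dec = vector("list", L - 1L),
                pool = vector("list", L - 1L), drop = list())
  h <- x
  enc_out <- vector("list", L)
  for (i in seq_len(L)) {
    if (i > 1L) {
      pl <- cpp_maxpool3(h, dim(h))
      cache$pool[[i - 1L]] <- list(argmax = pl$argmax, in_dims = dim(h))
      h <- pl$y
    }
    u1 <- conv_unit_fwd(p, sprintf("enc%d_c1", i), h, train)
    u2 <- conv_unit_fwd(p, sprintf("enc%d_c2", i), u1$y, train)
    cache$enc[[i]] <- list(c1 = u1$cache, c2 = u2$cache)
    h <- u2$y
    enc_out[[i]] <- h
  }
  for (i in rev(seq_len(L - 1L))) {
    up <- upsample2(h)
    skip <- enc_out[[i]]
    d <- dim(up)
    h <- array(c(up, skip), dim = c(d[1:3], d[4] + dim(skip)[4]))
    dropmask <- NULL
    u1 <- conv_unit_fwd(p, sprintf("dec%d_c1", i), h, train)
    h1 <- u1$y
    if (i == 1L && train && dropout_rate > 0) {
      # dropout before the second-to-last convolution layer
      dropmask <- array(runif(length(h1)) >= dropout_rate, dim = dim(h1))
      h1 <- h1 * dropmask / (1 - dropout_rate)
    }
    u2 <- conv_unit_fwd(p, sprintf("dec%d_c2", i), h1, train)
    cache$dec[[i]] <- list(c1 = u1$cache, c2 = u2$cache,
                           n_up = d[4], dropmask = dropmask)
    h <- u2$y
  }
  if (train && dropout_rate > 0) {
    # dropout before the last (classifier) convolution layer
    m <- array(runif(length(h)) >= dropout_rate, dim = dim(h))
    cache$drop$final <- m
    h <- h * m / (1 - dropout_rate)
  }
  dims <- dim(h)
  col <- matrix(h, ncol = dims[4])               # 1x1x1 conv = matmul
  logits_m <- col %*% t(p$final_W) +
    matrix(p$final_b, nrow(col), length(p$final_b), byrow = TRUE)
  logits <- array(logits_m, dim = c(dims[1:3], ncol(logits_m)))
  if (train) cache$final_in <- h
  list(logits = logits,
       cache = if (train) c(cache, list(dropout_rate = dropout_rate))
               else NULL)
}

#' Backward pass: gradients of the loss w.r.t. all parameters
#'
#' @param net `unet_params`.
#' @param cache forward cache from `unet_forward(..., train = TRUE)`.
#' @param dlogits gradient at the logits, same shape as the logits.
#' @return named list of gradients matching `net$params`.
#' @export
unet_backward <- function(net, cache, dlogits) {
  L <- net$meta$levels
  p <- net$params
  grads <- lapply(p, function(q) q * 0)
  dims <- dim(cache$final_in)
  dl <- matrix(dlogits, ncol = dim(dlogits)[4])  # N x n_classes
  fin <- matrix(cache$final_in, ncol = dims[4])
  grads$final_W <- t(dl) %*% fin
  grads$final_b <- colSums(dl)
  dh <- array(dl %*% p$final_W, dim = dims)
  if (cache$dropout_rate > 0)
    dh <- dh * cache$drop$final / (1 - cache$dropout_rate)
  for (i in seq_len(L - 1L)) {
    dc <- cache$dec[[i]]
    r2 <- conv_unit_bwd(p, grads, dc$c2, dh)
    grads <- r2$grads; dh1 <- r2$dx
    if (!is.null(dc$dropmask))
      dh1 <- dh1 * dc$dropmask / (1 - cache$dropout_rate)
    r1 <- conv_unit_bwd(p, grads, dc$c1, dh1)
    grads <- r1$grads
    dcat <- r1$dx
    d <- dim(dcat)
    dup <- dcat[, , , seq_len(dc$n_up), drop = FALSE]
    dskip <- dcat[, , , dc$n_up + seq_len(d[4] - dc$n_up), drop = FALSE]
    ddeep <- upsample2_bwd(dup)
    # skip-path gradient through enc_c2 now; the pool-path contribution is
    # added in the encoder sweep below (backward of a conv unit is linear
    # in the upstream gradient, so the two passes through enc_c2 sum to
    # the gradient of the combined flow)
    r2e <- conv_unit_bwd(p, grads, cache$enc[[i]]$c2, dskip)
    grads <- r2e$grads
    dh <- ddeep
    cache$enc[[i]]$pending_dx <- r2e$dx
  }
  # encoder sweep: dh arrives at the bottleneck from the decoder
  for (i in rev(seq_len(L))) {
    if (i < L) {
      pool <- cache$pool[[i]]
      dpool <- cpp_maxpool3_bwd(dh, pool$argmax, pool$in_dims)
      r2 <- conv_unit_bwd(p, grads, cache$enc[[i]]$c2, dpool)
      grads <- r2$grads
      dxi <- r2$dx + cache$enc[[i]]$pending_dx
      r1 <- conv_unit_bwd(p, grads, cache$enc[[i]]$c1, dxi)
      grads <- r1$grads
      dh <- r1$dx
    } else {
      r2 <- conv_unit_bwd(p, grads, cache$enc[[i]]$c2, dh)
      grads <- r2$grads
      r1 <- conv_unit_bwd(p, grads, cache$enc[[i]]$c1, r2$dx)
      grads <- r1$grads
      dh <- r1$dx
    }
  }
  grads
}

#' Cross-entropy loss with an ignore label
#'
#' Softmax cross-entropy averaged over non-ignored voxels. Voxels labelled
#' `255` contribute neither to the loss nor to any gradient.
#'
#' @param logits array (D, H, W, n_classes).
#' @param labels integer array (D, H, W) with codes 0..n_classes-1 or 255.
#' @param want_grad also return `dlogits`.
#' @return list: `loss`, `n_valid`, and optionally `dlogits`.
#' @export
softmax_ce_ignore <- function(logits, labels, want_grad = FALSE) {
  C <- dim(logits)[4]
  m <- matrix(logits, ncol = C)
  lab <- as.vector(labels)
  valid <- lab != 255L
  n_valid <- sum(valid)
  if (n_valid == 0L)
    return(list(loss = 0, n_valid = 0L,
                dlogits = if (want_grad) array(0, dim(logits))))
  mx <- do.call(pmax, lapply(seq_len(C), function(j) m[, j]))
  e <- exp(m - mx)
  Z <- rowSums(e)
  p <- e / Z
  idx <- cbind(which(valid), lab[valid] + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  out <- list(loss = loss, n_valid = n_valid)
  if (want_grad) {
    g <- p
    g[!valid, ] <- 0
    g[idx] <- g[idx] - 1
    out$dlogits <- array(g / n_valid, dim = dim(logits))
  }
  out
}
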