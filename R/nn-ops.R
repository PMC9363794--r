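# Differentiable primitives for the CPU training engine.
#
# Activations are 4-D arrays (H, W, C, N). Dense convolution is im2col +
# BLAS gemm; depthwise convolution, bilinear resizing and the scatter-add
# backward passes are C++ kernels. Each *_fwd returns list(y, cache) and the
# matching *_bwd consumes the cache and the upstream gradient.

same_pad <- function(k, dil) as.integer(((k - 1) * dil) %/% 2)

conv_fwd <- function(x, w, b = NULL, stride = 1L, dil = 1L) {
  d <- dim(x); wd <- dim(w)
  kh <- wd[1]; kw <- wd[2]; cin <- wd[3]; cout <- wd[4]
  stopifnot(d[3] == cin)
  ph <- same_pad(kh, dil); pw <- same_pad(kw, dil)
  cols <- nn_im2col(x, d, kh, kw, as.integer(stride), as.integer(dil), ph, pw)
  wm <- matrix(w, nrow = kh * kw * cin, ncol = cout)
  ym <- crossprod(wm, cols)                     # cout x (Ho*Wo*N)
  if (!is.null(b)) ym <- ym + b
  Ho <- (d[1] + 2 * ph - dil * (kh - 1) - 1) %/% stride + 1
  Wo <- (d[2] + 2 * pw - dil * (kw - 1) - 1) %/% stride + 1
  y <- aperm(array(t(ym), c(Ho, Wo, d[4], cout)), c(1, 2, 4, 3))
  list(y = y, cache = list(cols = cols, w = w, xdim = d, stride = stride,
                           dil = dil, ph = ph, pw = pw, has_b = !is.null(b)))
}

conv_bwd <- function(cache, dy) {
  wd <- dim(cache$w)
  kh <- wd[1]; kw <- wd[2]; cin <- wd[3]; cout <- wd[4]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = cout)  # (Ho*Wo*N) x cout
  dw <- array(cache$cols %*% dym, wd)
  db <- if (cache$has_b) colSums(dym) else NULL
  wm <- matrix(cache$w, nrow = kh * kw * cin, ncol = cout)
  dcols <- wm %*% t(dym)
  dx <- nn_col2im(dcols, cache$xdim, kh, kw, as.integer(cache$stride),
                  as.integer(cache$dil), cache$ph, cache$pw)
  list(dx = dx, dw = dw, db = db)
}

dw_fwd <- function(x, w, stride = 1L, dil = 1L) {
  d <- dim(x); wd <- dim(w)
  stopifnot(d[3] == wd[3])
  ph <- same_pad(wd[1], dil); pw <- same_pad(wd[2], dil)
  y <- nn_dwconv_fwd(x, d, w, wd[1], wd[2], as.integer(stride),
                     as.integer(dil), ph, pw)
  list(y = y, cache = list(x = x, w = w, stride = stride, dil = dil,
                           ph = ph, pw = pw))
}

dw_bwd <- function(cache, dy) {
  wd <- dim(cache$w)
  g <- nn_dwconv_bwd(cache$x, dim(cache$x), cache$w, dy, wd[1], wd[2],
                     as.integer(cache$stride), as.integer(cache$dil),
                     cache$ph, cache$pw)
  list(dx = g$dx, dw = g$dw)
}

# Group normalization: per-sample, per-group mean/variance over (H, W, Cg).
# Batch-size independent, so training and inference behave identically.
gn_groups <- function(C) {
  for (g in c(8L, 4L, 2L)) if (C %% g == 0L) return(g)
  1L
}

gn_fwd <- function(x, gamma, beta, groups, eps = 1e-5) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  cg <- C %/% groups
  m <- matrix(x, H * W * cg, groups * N)
  mu <- colMeans(m)
  v <- colMeans(m * m) - mu^2
  invstd <- 1 / sqrt(v + eps)
  xhat <- (m - rep(mu, each = nrow(m))) * rep(invstd, each = nrow(m))
  gfull <- rep(gamma, each = H * W)   # length H*W*C, recycles over N
  bfull <- rep(beta, each = H * W)
  y <- array(as.numeric(xhat) * gfull + bfull, d)
  list(y = y, cache = list(xhat = xhat, invstd = invstd, gamma = gamma,
                           d = d, groups = groups))
}

gn_bwd <- function(cache, dy) {
  d <- cache$d
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  groups <- cache$groups; cg <- C %/% groups
  xhat_arr <- as.numeric(cache$xhat)
  dy_v <- as.numeric(dy)
  # per-channel parameter grads
  chan <- function(v) {
    m <- matrix(v, H * W, C * N)
    rowSums(matrix(colSums(m), C, N))
  }
  dgamma <- chan(dy_v * xhat_arr)
  dbeta <- chan(dy_v)
  gfull <- rep(cache$gamma, each = H * W)
  dxhat <- matrix(dy_v * gfull, H * W * cg, groups * N)
  mh <- nrow(dxhat)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * cache$xhat)
  dxm <- (dxhat - rep(m1, each = mh) - cache$xhat * rep(m2, each = mh)) *
    rep(cache$invstd, each = mh)
  list(dx = array(dxm, d), dgamma = dgamma, dbeta = dbeta)
}

relu6_fwd <- function(x) {
  y <- pmin(pmax(x, 0), 6)
  dim(y) <- dim(x)
  list(y = y, cache = (x > 0 & x < 6))
}

relu6_bwd <- function(cache, dy) {
  dx <- dy * cache
  dim(dx) <- dim(dy)
  dx
}

upsample_fwd <- function(x, Ho, Wo) {
  list(y = nn_resize_bilinear(x, dim(x), as.integer(Ho), as.integer(Wo)),
       cache = dim(x))
}

upsample_bwd <- function(cache, dy) {
  nn_resize_bilinear_bwd(dy, dim(dy), cache[1], cache[2])
}

# Global average pooling to 1 x 1 spatial extent.
gap_fwd <- function(x) {
  d <- dim(x)
  m <- matrix(x, d[1] * d[2], d[3] * d[4])
  list(y = array(colMeans(m), c(1L, 1L, d[3], d[4])), cache = d)
}

gap_bwd <- function(cache, dy) {
  d <- cache
  array(rep(as.numeric(dy), each = d[1] * d[2]) / (d[1] * d[2]), d)
}

# Adaptive average pooling to a b x b grid (pyramid pooling). Bin i covers
# rows floor((i-1)H/b)+1 .. ceil(iH/b), so grids coarser than b still give
# valid (possibly overlapping) one-pixel regions.
adapool_range <- function(i, H, bins) {
  (floor((i - 1) * H / bins) + 1):max(floor((i - 1) * H / bins) + 1,
                                      ceiling(i * H / bins))
}

adapool_fwd <- function(x, bins) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  y <- array(0, c(bins, bins, C, N))
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    r <- adapool_range(i, H, bins)
    cc <- adapool_range(j, W, bins)
    blk <- x[r, cc, , , drop = FALSE]
    y[i, j, , ] <- colMeans(matrix(blk, length(r) * length(cc), C * N))
  }
  list(y = y, cache = list(d = d, bins = bins))
}

adapool_bwd <- function(cache, dy) {
  d <- cache$d; bins <- cache$bins
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  dx <- array(0, d)
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    r <- adapool_range(i, H, bins)
    cc <- adapool_range(j, W, bins)
    g <- dy[i, j, , , drop = FALSE] / (length(r) * length(cc))
    dx[r, cc, , ] <- dx[r, cc, , , drop = FALSE] +
      array(rep(as.numeric(g), each = length(r) * length(cc)),
            c(length(r), length(cc), C, N))
  }
  dx
}

concat_fwd <- function(a, b) {
  da <- dim(a); db <- dim(b)
  stopifnot(da[c(1, 2, 4)] == db[c(1, 2, 4)])
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  list(y = y, cache = c(da[3], db[3]))
}

concat_bwd <- function(cache, dy) {
  ca <- cache[1]; cb <- cache[2]
  list(da = dy[, , seq_len(ca), , drop = FALSE],
       db = dy[, , ca + seq_len(cb), , drop = FALSE])
}

# Mean per-pixel softmax cross-entropy over K classes.
# logits: (H, W, K, N); labels: (H, W, N) integers in 0..K-1.
softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  K <- d[3]
  lm <- matrix(aperm(logits, c(1, 2, 4, 3)), ncol = K)  # rows = (h, w, n)
  lm <- lm - apply(lm, 1, max)
  el <- exp(lm)
  p <- el / rowSums(el)
  idx <- cbind(seq_len(nrow(p)), as.integer(labels) + 1L)
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  dp <- dp / nrow(p)
  dlogits <- aperm(array(dp, c(d[1], d[2], d[4], K)), c(1, 2, 4, 3))
  list(loss = loss, dlogits = dlogits, prob = p)
}

# ---- parameter-tree utilities ----
# Leaves named "meta" hold block hyperparameters (stride, dilation, ...),
# not trainable weights: they pass through every tree operation unchanged.

is_leaf <- function(x) is.numeric(x)

tree_map <- function(f, a) {
  if (is_leaf(a)) return(f(a))
  nm <- names(a)
  out <- lapply(seq_along(a), function(i) {
    if (identical(nm[i], "meta")) a[[i]] else tree_map(f, a[[i]])
  })
  names(out) <- nm
  out
}

tree_map2 <- function(f, a, b) {
  if (is_leaf(a)) return(f(a, b))
  nm <- names(a)
  out <- lapply(seq_along(a), function(i) {
    if (identical(nm[i], "meta")) a[[i]] else tree_map2(f, a[[i]], b[[i]])
  })
  names(out) <- nm
  out
}

tree_count <- function(a) {
  if (is_leaf(a)) return(length(a))
  nm <- names(a)
  sum(vapply(seq_along(a), function(i)
    if (identical(nm[i], "meta")) 0 else tree_count(a[[i]]), 0))
}

# He-style initialization for conv weights.
init_conv_w <- function(kh, kw, cin, cout, scale = 1) {
  array(rnorm(kh * kw * cin * cout, 0, scale * sqrt(2 / (kh * kw * cin))),
        c(kh, kw, cin, cout))
}
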