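# Composite blocks: conv + groupnorm (+ ReLU6), and the inverted-residual
# bottleneck (expand 1x1 -> depthwise 3x3 -> project 1x1, with a residual
# addition exactly when stride is 1 and input/output channel counts match).

cgr_init <- function(k, cin, cout, stride = 1L, dil = 1L, act = TRUE) {
  list(w = init_conv_w(k, k, cin, cout),
       gamma = rep(1, cout), beta = rep(0, cout),
       meta = c(stride = stride, dil = dil, act = as.integer(act)))
}

cgr_fwd <- function(p, x) {
  m <- p$meta
  cv <- conv_fwd(x, p$w, stride = m[["stride"]], dil = m[["dil"]])
  gn <- gn_fwd(cv$y, p$gamma, p$beta, gn_groups(length(p$gamma)))
  if (m[["act"]] == 1L) {
    ac <- relu6_fwd(gn$y)
    list(y = ac$y, cache = list(cv = cv$cache, gn = gn$cache, ac = ac$cache))
  } else {
    list(y = gn$y, cache = list(cv = cv$cache, gn = gn$cache, ac = NULL))
  }
}

cgr_bwd <- function(p, cache, dy) {
  if (!is.null(cache$ac)) dy <- relu6_bwd(cache$ac, dy)
  g <- gn_bwd(cache$gn, dy)
  c2 <- conv_bwd(cache$cv, g$dx)
  list(dx = c2$dx,
       grads = list(w = c2$dw, gamma = g$dgamma, beta = g$dbeta,
                    meta = p$meta * 0))
}

dgr_init <- function(k, C, stride = 1L, dil = 1L) {
  list(w = array(rnorm(k * k * C, 0, sqrt(2 / (k * k))), c(k, k, C)),
       gamma = rep(1, C), beta = rep(0, C),
       meta = c(stride = stride, dil = dil))
}

dgr_fwd <- function(p, x) {
  m <- p$meta
  dv <- dw_fwd(x, p$w, stride = m[["stride"]], dil = m[["dil"]])
  gn <- gn_fwd(dv$y, p$gamma, p$beta, gn_groups(length(p$gamma)))
  ac <- relu6_fwd(gn$y)
  list(y = ac$y, cache = list(dv = dv$cache, gn = gn$cache, ac = ac$cache))
}

dgr_bwd <- function(p, cache, dy) {
  dy <- relu6_bwd(cache$ac, dy)
  g <- gn_bwd(cache$gn, dy)
  d2 <- dw_bwd(cache$dv, g$dx)
  list(dx = d2$dx,
       grads = list(w = d2$dw, gamma = g$dgamma, beta = g$dbeta,
                    meta = p$meta * 0))
}

bottleneck_init <- function(cin, cout, expansion, stride = 1L, dil = 1L) {
  hidden <- cin * expansion
  p <- list()
  if (expansion != 1) p$expand <- cgr_init(1L, cin, hidden)
  p$dw <- dgr_init(3L, hidden, stride = stride, dil = dil)
  p$proj <- cgr_init(1L, hidden, cout, act = FALSE)
  p$meta <- c(cin = cin, cout = cout, expansion = expansion,
              stride = stride, dil = dil,
              residual = as.integer(stride == 1L && cin == cout))
  p
}

bottleneck_fwd <- function(p, x) {
  h <- x
  cache <- list()
  if (!is.null(p$expand)) {
    e <- cgr_fwd(p$expand, h)
    h <- e$y; cache$expand <- e$cache
  }
  d <- dgr_fwd(p$dw, h)
  cache$dw <- d$cache
  pr <- cgr_fwd(p$proj, d$y)
  cache$proj <- pr$cache
  y <- pr$y
  if (p$meta[["residual"]] == 1L) y <- y + x
  list(y = y, cache = cache)
}

bottleneck_bwd <- function(p, cache, dy) {
  gpr <- cgr_bwd(p$proj, cache$proj, dy)
  gdw <- dgr_bwd(p$dw, cache$dw, gpr$dx)
  grads <- list()
  dx <- gdw$dx
  if (!is.null(p$expand)) {
    ge <- cgr_bwd(p$expand, cache$expand, dx)
    grads$expand <- ge$grads
    dx <- ge$dx
  }
  grads$dw <- gdw$grads
  grads$proj <- gpr$grads
  grads$meta <- p$meta * 0
  if (p$meta[["residual"]] == 1L) dx <- dx + dy
  list(dx = dx, grads = grads)
}
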