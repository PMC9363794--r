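# The three segmentation architectures. Each is a triple of functions
# (init, forward, backward) over the primitives in nn-ops.R / nn-blocks.R,
# with parameters stored as nested lists so the optimizer can walk them
# generically.

round_channels <- function(c, width) max(4L, as.integer(round(c * width)))

#' MobileNetV2 encoder block plan
#'
#' The encoder stacks 17 inverted-residual bottlenecks in the canonical
#' stage layout (expansion, channels, repeats, stride) =
#' (1,16,1,1), (6,24,2,2), (6,32,3,2), (6,64,4,2), (6,96,3,1), (6,160,3,2),
#' (6,320,1,1), scaled by `width_multiplier`. The low-level feature tap sits
#' after the first three bottlenecks (1 + 2); the remaining 14 produce the
#' high-level features. Once the cumulative stride reaches `output_stride`,
#' further stride-2 blocks become stride-1 dilated blocks.
#'
#' @param width_multiplier Channel width scale factor.
#' @param output_stride Encoder output stride, 8 or 16.
#' @return A data frame with one row per bottleneck: `block`, `expansion`,
#'   `cin`, `cout`, `stride`, `dilation`, `residual`, `low_level_tap`, plus
#'   attribute `stem_channels`.
#' @export
mobilenetv2_plan <- function(width_multiplier = 1, output_stride = 16) {
  stopifnot(output_stride %in% c(8, 16))
  stages <- data.frame(t = c(1, 6, 6, 6, 6, 6, 6),
                       c = c(16, 24, 32, 64, 96, 160, 320),
                       n = c(1, 2, 3, 4, 3, 3, 1),
                       s = c(1, 2, 2, 2, 1, 2, 1))
  stem <- round_channels(32, width_multiplier)
  cur_stride <- 2L
  dil <- 1L
  cin <- stem
  rows <- list()
  k <- 0L
  for (i in seq_len(nrow(stages))) {
    cout <- round_channels(stages$c[i], width_multiplier)
    for (j in seq_len(stages$n[i])) {
      s <- if (j == 1) stages$s[i] else 1L
      if (s > 1L && cur_stride >= output_stride) {
        dil <- dil * s
        s <- 1L
      }
      k <- k + 1L
      rows[[k]] <- data.frame(block = k, expansion = stages$t[i],
                              cin = cin, cout = cout, stride = s,
                              dilation = dil,
                              residual = s == 1L && cin == cout,
                              low_level_tap = k == 3L)
      cur_stride <- cur_stride * s
      cin <- cout
    }
  }
  plan <- do.call(rbind, rows)
  attr(plan, "stem_channels") <- stem
  plan
}

# ---------------------------------------------------------------- DeepLabv3+

# Low-level feature tap: after bottleneck 1 plus the two following
# bottlenecks, i.e. encoder block 3.
DEEPLAB_TAP <- 3L

deeplab_init <- function(config) {
  w <- config$width_multiplier
  plan <- mobilenetv2_plan(w, config$output_stride)
  stem_ch <- attr(plan, "stem_channels")
  aspp_ch <- max(8L, as.integer(round(256 * w)))
  low_ch <- max(4L, as.integer(round(48 * w)))
  hi_ch <- plan$cout[nrow(plan)]
  ll_ch <- plan$cout[which(plan$low_level_tap)]

  blocks <- lapply(seq_len(nrow(plan)), function(i)
    bottleneck_init(plan$cin[i], plan$cout[i], plan$expansion[i],
                    plan$stride[i], plan$dilation[i]))
  rates <- config$atrous_rates
  params <- list(
    stem = cgr_init(3L, 3L, stem_ch, stride = 2L),
    blocks = blocks,
    aspp = list(
      b1x1 = cgr_init(1L, hi_ch, aspp_ch),
      br1 = cgr_init(3L, hi_ch, aspp_ch, dil = rates[1]),
      br2 = cgr_init(3L, hi_ch, aspp_ch, dil = rates[2]),
      br3 = cgr_init(3L, hi_ch, aspp_ch, dil = rates[3]),
      pool = cgr_init(1L, hi_ch, aspp_ch),
      proj = cgr_init(1L, 5L * aspp_ch, aspp_ch)
    ),
    low_proj = cgr_init(1L, ll_ch, low_ch),
    dec1 = cgr_init(3L, aspp_ch + low_ch, aspp_ch),
    dec2 = cgr_init(3L, aspp_ch, aspp_ch),
    logits = list(w = init_conv_w(1L, 1L, aspp_ch, config$num_classes, scale = 0.1),
                  b = rep(0, config$num_classes))
  )
  attr(params, "plan") <- plan
  params
}

deeplab_fwd <- function(params, x, config) {
  cache <- list()
  st <- cgr_fwd(params$stem, x)
  cache$stem <- st$cache
  h <- st$y
  cache$blocks <- vector("list", length(params$blocks))
  low <- NULL
  for (i in seq_along(params$blocks)) {
    bo <- bottleneck_fwd(params$blocks[[i]], h)
    cache$blocks[[i]] <- bo$cache
    h <- bo$y
    if (i == DEEPLAB_TAP) low <- h
  }
  hd <- dim(h)
  a1 <- cgr_fwd(params$aspp$b1x1, h)
  a2 <- cgr_fwd(params$aspp$br1, h)
  a3 <- cgr_fwd(params$aspp$br2, h)
  a4 <- cgr_fwd(params$aspp$br3, h)
  gp <- gap_fwd(h)
  pc <- cgr_fwd(params$aspp$pool, gp$y)
  pu <- upsample_fwd(pc$y, hd[1], hd[2])
  cache$aspp <- list(a1 = a1$cache, a2 = a2$cache, a3 = a3$cache,
                     a4 = a4$cache, gp = gp$cache, pc = pc$cache,
                     pu = pu$cache)
  cat12 <- concat_fwd(a1$y, a2$y)
  cat123 <- concat_fwd(cat12$y, a3$y)
  cat1234 <- concat_fwd(cat123$y, a4$y)
  catall <- concat_fwd(cat1234$y, pu$y)
  cache$cats <- list(cat12$cache, cat123$cache, cat1234$cache, catall$cache)
  pr <- cgr_fwd(params$aspp$proj, catall$y)
  cache$aspp_proj <- pr$cache

  ld <- dim(low)
  lo <- cgr_fwd(params$low_proj, low)
  cache$low_proj <- lo$cache
  up1 <- upsample_fwd(pr$y, ld[1], ld[2])
  cache$up1 <- up1$cache
  dcat <- concat_fwd(up1$y, lo$y)
  cache$dcat <- dcat$cache
  d1 <- cgr_fwd(params$dec1, dcat$y)
  cache$dec1 <- d1$cache
  d2 <- cgr_fwd(params$dec2, d1$y)
  cache$dec2 <- d2$cache
  lg <- conv_fwd(d2$y, params$logits$w, b = params$logits$b)
  cache$logits <- lg$cache
  out <- upsample_fwd(lg$y, config$input_size, config$input_size)
  cache$out <- out$cache
  list(logits = out$y, cache = cache)
}

deeplab_bwd <- function(params, cache, dlogits, config) {
  dy <- upsample_bwd(cache$out, dlogits)
  glg <- conv_bwd(cache$logits, dy)
  g <- list()
  gd2 <- cgr_bwd(params$dec2, cache$dec2, glg$dx)
  gd1 <- cgr_bwd(params$dec1, cache$dec1, gd2$dx)
  sp <- concat_bwd(cache$dcat, gd1$dx)
  glo <- cgr_bwd(params$low_proj, cache$low_proj, sp$db)
  dpr <- upsample_bwd(cache$up1, sp$da)
  gpr <- cgr_bwd(params$aspp$proj, cache$aspp_proj, dpr)

  s4 <- concat_bwd(cache$cats[[4]], gpr$dx)
  s3 <- concat_bwd(cache$cats[[3]], s4$da)
  s2 <- concat_bwd(cache$cats[[2]], s3$da)
  s1 <- concat_bwd(cache$cats[[1]], s2$da)
  dpu <- upsample_bwd(cache$aspp$pu, s4$db)
  gpc <- cgr_bwd(params$aspp$pool, cache$aspp$pc, dpu)
  dgp <- gap_bwd(cache$aspp$gp, gpc$dx)
  ga4 <- cgr_bwd(params$aspp$br3, cache$aspp$a4, s3$db)
  ga3 <- cgr_bwd(params$aspp$br2, cache$aspp$a3, s2$db)
  ga2 <- cgr_bwd(params$aspp$br1, cache$aspp$a2, s1$db)
  ga1 <- cgr_bwd(params$aspp$b1x1, cache$aspp$a1, s1$da)
  dh <- ga1$dx + ga2$dx + ga3$dx + ga4$dx + dgp

  gblocks <- vector("list", length(params$blocks))
  dlow <- glo$dx
  for (i in rev(seq_along(params$blocks))) {
    if (i == DEEPLAB_TAP) dh <- dh + dlow
    gb <- bottleneck_bwd(params$blocks[[i]], cache$blocks[[i]], dh)
    gblocks[[i]] <- gb$grads
    dh <- gb$dx
  }
  gst <- cgr_bwd(params$stem, cache$stem, dh)

  g <- list(
    stem = gst$grads,
    blocks = gblocks,
    aspp = list(b1x1 = ga1$grads, br1 = ga2$grads, br2 = ga3$grads,
                br3 = ga4$grads, pool = gpc$grads, proj = gpr$grads),
    low_proj = glo$grads,
    dec1 = gd1$grads,
    dec2 = gd2$grads,
    logits = list(w = glg$dw, b = glg$db)
  )
  g
}

# --------------------------------------------------------------------- U-Net

unet_init <- function(config) {
  b <- round_channels(64, config$width_multiplier)
  ch <- c(b, 2L * b, 4L * b, 8L * b, 16L * b)
  enc <- list()
  cin <- 3L
  for (i in 1:4) {
    enc[[i]] <- list(c1 = cgr_init(3L, cin, ch[i]),
                     c2 = cgr_init(3L, ch[i], ch[i]),
                     down = cgr_init(3L, ch[i], ch[i + 1L], stride = 2L))
    cin <- ch[i + 1L]
  }
  bottom <- list(c1 = cgr_init(3L, ch[5], ch[5]), c2 = cgr_init(3L, ch[5], ch[5]))
  dec <- list()
  for (i in 4:1) {
    dec[[5L - i]] <- list(up = cgr_init(1L, ch[i + 1L], ch[i]),
                          c1 = cgr_init(3L, 2L * ch[i], ch[i]),
                          c2 = cgr_init(3L, ch[i], ch[i]))
  }
  list(enc = enc, bottom = bottom, dec = dec,
       logits = list(w = init_conv_w(1L, 1L, ch[1], config$num_classes, scale = 0.1),
                     b = rep(0, config$num_classes)))
}

unet_fwd <- function(params, x, config) {
  cache <- list(enc = vector("list", 4), dec = vector("list", 4))
  skips <- vector("list", 4)
  h <- x
  for (i in 1:4) {
    e <- params$enc[[i]]
    o1 <- cgr_fwd(e$c1, h)
    o2 <- cgr_fwd(e$c2, o1$y)
    skips[[i]] <- o2$y
    od <- cgr_fwd(e$down, o2$y)
    cache$enc[[i]] <- list(c1 = o1$cache, c2 = o2$cache, down = od$cache)
    h <- od$y
  }
  b1 <- cgr_fwd(params$bottom$c1, h)
  b2 <- cgr_fwd(params$bottom$c2, b1$y)
  cache$bottom <- list(c1 = b1$cache, c2 = b2$cache)
  h <- b2$y
  for (k in 1:4) {
    i <- 5L - k            # matching encoder level
    d <- params$dec[[k]]
    sd <- dim(skips[[i]])
    uu <- upsample_fwd(h, sd[1], sd[2])
    pc <- cgr_fwd(d$up, uu$y)
    ct <- concat_fwd(pc$y, skips[[i]])
    o1 <- cgr_fwd(d$c1, ct$y)
    o2 <- cgr_fwd(d$c2, o1$y)
    cache$dec[[k]] <- list(uu = uu$cache, up = pc$cache, ct = ct$cache,
                           c1 = o1$cache, c2 = o2$cache)
    h <- o2$y
  }
  lg <- conv_fwd(h, params$logits$w, b = params$logits$b)
  cache$logits <- lg$cache
  list(logits = lg$y, cache = cache)
}

unet_bwd <- function(params, cache, dlogits, config) {
  glg <- conv_bwd(cache$logits, dlogits)
  dh <- glg$dx
  gdec <- vector("list", 4)
  dskips <- vector("list", 4)
  for (k in 4:1) {
    i <- 5L - k
    d <- params$dec[[k]]
    cc <- cache$dec[[k]]
    g2 <- cgr_bwd(d$c2, cc$c2, dh)
    g1 <- cgr_bwd(d$c1, cc$c1, g2$dx)
    sp <- concat_bwd(cc$ct, g1$dx)
    dskips[[i]] <- sp$db
    gu <- cgr_bwd(d$up, cc$up, sp$da)
    dh <- upsample_bwd(cc$uu, gu$dx)
    gdec[[k]] <- list(up = gu$grads, c1 = g1$grads, c2 = g2$grads)
  }
  gb2 <- cgr_bwd(params$bottom$c2, cache$bottom$c2, dh)
  gb1 <- cgr_bwd(params$bottom$c1, cache$bottom$c1, gb2$dx)
  dh <- gb1$dx
  genc <- vector("list", 4)
  for (i in 4:1) {
    e <- params$enc[[i]]
    cc <- cache$enc[[i]]
    gd <- cgr_bwd(e$down, cc$down, dh)
    d2 <- gd$dx + dskips[[i]]
    g2 <- cgr_bwd(e$c2, cc$c2, d2)
    g1 <- cgr_bwd(e$c1, cc$c1, g2$dx)
    genc[[i]] <- list(c1 = g1$grads, c2 = g2$grads, down = gd$grads)
    dh <- g1$dx
  }
  list(enc = genc, bottom = list(c1 = gb1$grads, c2 = gb2$grads),
       dec = gdec, logits = list(w = glg$dw, b = glg$db))
}

# -------------------------------------------------------------------- PSPNet

PSP_BINS <- c(1L, 2L, 3L, 6L)

pspnet_init <- function(config) {
  w <- config$width_multiplier
  c1 <- round_channels(64, w)
  c2 <- round_channels(128, w)
  c3 <- round_channels(256, w)
  pb <- max(4L, c3 %/% 4L)
  list(
    stem = cgr_init(3L, 3L, c1, stride = 2L),
    down2 = cgr_init(3L, c1, c2, stride = 2L),
    body1 = cgr_init(3L, c2, c2),
    down3 = cgr_init(3L, c2, c3, stride = 2L),
    body2 = cgr_init(3L, c3, c3),
    ppm = lapply(PSP_BINS, function(b) cgr_init(1L, c3, pb)),
    fuse = cgr_init(3L, c3 + 4L * pb, c2),
    logits = list(w = init_conv_w(1L, 1L, c2, config$num_classes, scale = 0.1),
                  b = rep(0, config$num_classes))
  )
}

pspnet_fwd <- function(params, x, config) {
  cache <- list()
  s <- cgr_fwd(params$stem, x); cache$stem <- s$cache
  d2 <- cgr_fwd(params$down2, s$y); cache$down2 <- d2$cache
  b1 <- cgr_fwd(params$body1, d2$y); cache$body1 <- b1$cache
  d3 <- cgr_fwd(params$down3, b1$y); cache$down3 <- d3$cache
  b2 <- cgr_fwd(params$body2, d3$y); cache$body2 <- b2$cache
  h <- b2$y
  hd <- dim(h)
  cat <- h
  cache$ppm <- vector("list", length(PSP_BINS))
  cache$cats <- vector("list", length(PSP_BINS))
  for (i in seq_along(PSP_BINS)) {
    ap <- adapool_fwd(h, PSP_BINS[i])
    cv <- cgr_fwd(params$ppm[[i]], ap$y)
    uu <- upsample_fwd(cv$y, hd[1], hd[2])
    ct <- concat_fwd(cat, uu$y)
    cache$ppm[[i]] <- list(ap = ap$cache, cv = cv$cache, uu = uu$cache)
    cache$cats[[i]] <- ct$cache
    cat <- ct$y
  }
  fu <- cgr_fwd(params$fuse, cat); cache$fuse <- fu$cache
  lg <- conv_fwd(fu$y, params$logits$w, b = params$logits$b)
  cache$logits <- lg$cache
  out <- upsample_fwd(lg$y, config$input_size, config$input_size)
  cache$out <- out$cache
  list(logits = out$y, cache = cache)
}

pspnet_bwd <- function(params, cache, dlogits, config) {
  dy <- upsample_bwd(cache$out, dlogits)
  glg <- conv_bwd(cache$logits, dy)
  gfu <- cgr_bwd(params$fuse, cache$fuse, glg$dx)
  dcat <- gfu$dx
  gppm <- vector("list", length(PSP_BINS))
  dh_extra <- 0
  for (i in rev(seq_along(PSP_BINS))) {
    sp <- concat_bwd(cache$cats[[i]], dcat)
    dcat <- sp$da
    du <- upsample_bwd(cache$ppm[[i]]$uu, sp$db)
    gc <- cgr_bwd(params$ppm[[i]], cache$ppm[[i]]$cv, du)
    dh_extra <- dh_extra + adapool_bwd(cache$ppm[[i]]$ap, gc$dx)
    gppm[[i]] <- gc$grads
  }
  dh <- dcat + dh_extra
  gb2 <- cgr_bwd(params$body2, cache$body2, dh)
  gd3 <- cgr_bwd(params$down3, cache$down3, gb2$dx)
  gb1 <- cgr_bwd(params$body1, cache$body1, gd3$dx)
  gd2 <- cgr_bwd(params$down2, cache$down2, gb1$dx)
  gst <- cgr_bwd(params$stem, cache$stem, gd2$dx)
  list(stem = gst$grads, down2 = gd2$grads, body1 = gb1$grads,
       down3 = gd3$grads, body2 = gb2$grads, ppm = gppm,
       fuse = gfu$grads, logits = list(w = glg$dw, b = glg$db))
}

arch_registry <- function(architecture) {
  switch(architecture,
         deeplabv3plus = list(init = deeplab_init, fwd = deeplab_fwd,
                              bwd = deeplab_bwd),
         unet = list(init = unet_init, fwd = unet_fwd, bwd = unet_bwd),
         pspnet = list(init = pspnet_init, fwd = pspnet_fwd, bwd = pspnet_bwd),
         stop_dfameter("bad_config", sprintf("unknown architecture '%s'",
                                             architecture)))
}
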