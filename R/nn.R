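# Minimal convolutional-network machinery (forward + hand-derived backward)
# used by both the segmentation U-net and the deformable-registration flow
# network. Activations are (H, W, C) arrays; weights (kh, kw, Cin, Cout).
# Heavy inner loops live in compiled code (cpp_conv2d_fwd / cpp_conv2d_bwd).

conv_init <- function(kh, kw, cin, cout, sd = NULL) {
  sd <- sd %||% sqrt(2 / (kh * kw * cin))
  list(w = array(rnorm(kh * kw * cin * cout, 0, sd), c(kh, kw, cin, cout)),
       b = rep(0, cout))
}

lrelu <- function(x) pmax(x, 0) + 0.1 * pmin(x, 0)
lrelu_grad <- function(x) ifelse(x > 0, 1, 0.1)

maxpool2 <- function(x) {
  d <- dim(x)
  a <- x[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  b <- x[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  cc <- x[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  dd <- x[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  # remember which corner won (first winner on ties)
  arg <- 1L * (a == m)
  arg[arg == 0 & b == m] <- 2L
  arg[arg == 0 & cc == m] <- 3L
  arg[arg == 0] <- 4L
  list(out = m, arg = arg, in_dim = d)
}

maxpool2_bwd <- function(pool, gout) {
  g <- array(0, pool$in_dim)
  d <- pool$in_dim
  ri <- list(seq(1, d[1], 2), seq(2, d[1], 2))
  ci <- list(seq(1, d[2], 2), seq(2, d[2], 2))
  sel <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    mask <- pool$arg == k
    sub <- g[ri[[sel[[k]][1]]], ci[[sel[[k]][2]]], , drop = FALSE]
    sub[mask] <- gout[mask]
    g[ri[[sel[[k]][1]]], ci[[sel[[k]][2]]], ] <- sub
  }
  g
}

upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), ,
    drop = FALSE]
}

upsample2_bwd <- function(gout) {
  d <- dim(gout)
  a <- gout[seq(1, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  b <- gout[seq(2, d[1], 2), seq(1, d[2], 2), , drop = FALSE]
  cc <- gout[seq(1, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  dd <- gout[seq(2, d[1], 2), seq(2, d[2], 2), , drop = FALSE]
  a + b + cc + dd
}

concat_ch <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1], d[2], d[3] + dim(b)[3]))
  out[, , seq_len(d[3])] <- a
  out[, , d[3] + seq_len(dim(b)[3])] <- b
  out
}

# ---- U-net-style encoder-decoder ---------------------------------------
# Two pooling levels, one 3x3 conv per block, skip connections by channel
# concatenation, leaky-ReLU activations, linear 1x1 output head.

unet_init <- function(in_channels, out_channels, base = 8,
                      head_sd = NULL) {
  F1 <- base
  list(
    c1 = conv_init(3, 3, in_channels, F1),
    c2 = conv_init(3, 3, F1, 2 * F1),
    c3 = conv_init(3, 3, 2 * F1, 4 * F1),
    d2 = conv_init(3, 3, 4 * F1 + 2 * F1, 2 * F1),
    d1 = conv_init(3, 3, 2 * F1 + F1, F1),
    out = conv_init(1, 1, F1, out_channels, sd = head_sd)
  )
}

unet_forward <- function(params, x) {
  z1 <- cpp_conv2d_fwd(x, params$c1$w, params$c1$b); e1 <- lrelu(z1)
  p1 <- maxpool2(e1)
  z2 <- cpp_conv2d_fwd(p1$out, params$c2$w, params$c2$b); e2 <- lrelu(z2)
  p2 <- maxpool2(e2)
  z3 <- cpp_conv2d_fwd(p2$out, params$c3$w, params$c3$b); e3 <- lrelu(z3)
  u2 <- concat_ch(upsample2(e3), e2)
  z4 <- cpp_conv2d_fwd(u2, params$d2$w, params$d2$b); e4 <- lrelu(z4)
  u1 <- concat_ch(upsample2(e4), e1)
  z5 <- cpp_conv2d_fwd(u1, params$d1$w, params$d1$b); e5 <- lrelu(z5)
  out <- cpp_conv2d_fwd(e5, params$out$w, params$out$b)
  list(out = out,
       cache = list(x = x, z1 = z1, p1 = p1, z2 = z2, p2 = p2, z3 = z3,
                    u2 = u2, z4 = z4, u1 = u1, z5 = z5, e5 = e5))
}

unet_backward <- function(params, cache, gout) {
  gr <- list()
  bo <- cpp_conv2d_bwd(cache$e5, params$out$w, gout)
  gr$out <- list(w = bo$gw, b = bo$gb)
  g5 <- bo$gx * lrelu_grad(cache$z5)
  b5 <- cpp_conv2d_bwd(cache$u1, params$d1$w, g5)
  gr$d1 <- list(w = b5$gw, b = b5$gb)
  n4 <- dim(cache$z4)[3]
  g_up1 <- b5$gx[, , seq_len(n4), drop = FALSE]
  g_e1 <- b5$gx[, , n4 + seq_len(dim(b5$gx)[3] - n4), drop = FALSE]
  g4 <- upsample2_bwd(g_up1) * lrelu_grad(cache$z4)
  b4 <- cpp_conv2d_bwd(cache$u2, params$d2$w, g4)
  gr$d2 <- list(w = b4$gw, b = b4$gb)
  n3 <- dim(cache$z3)[3]
  g_up2 <- b4$gx[, , seq_len(n3), drop = FALSE]
  g_e2a <- b4$gx[, , n3 + seq_len(dim(b4$gx)[3] - n3), drop = FALSE]
  g3 <- upsample2_bwd(g_up2) * lrelu_grad(cache$z3)
  b3 <- cpp_conv2d_bwd(cache$p2$out, params$c3$w, g3)
  gr$c3 <- list(w = b3$gw, b = b3$gb)
  g_e2 <- maxpool2_bwd(cache$p2, b3$gx) + g_e2a
  g2 <- g_e2 * lrelu_grad(cache$z2)
  b2 <- cpp_conv2d_bwd(cache$p1$out, params$c2$w, g2)
  gr$c2 <- list(w = b2$gw, b = b2$gb)
  g_e1full <- maxpool2_bwd(cache$p1, b2$gx) + g_e1
  g1 <- g_e1full * lrelu_grad(cache$z1)
  b1 <- cpp_conv2d_bwd(cache$x, params$c1$w, g1)
  gr$c1 <- list(w = b1$gw, b = b1$gb)
  gr
}

# ---- optimiser + schedule ----------------------------------------------

adamw_init <- function(params) {
  st <- rapply(params, function(p) list(m = p * 0, v = p * 0),
               how = "replace", classes = "ANY")
  list(state = st, t = 0)
}

# params and grads share one nesting structure: list(layer = list(w, b)).
adamw_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, weight_decay = 1e-4) {
  opt$t <- opt$t + 1
  for (ly in names(params)) {
    for (pn in names(params[[ly]])) {
      g <- grads[[ly]][[pn]]
      st <- opt$state[[ly]][[pn]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^opt$t)
      vh <- st$v / (1 - beta2^opt$t)
      params[[ly]][[pn]] <- params[[ly]][[pn]] -
        lr * (mh / (sqrt(vh) + eps) + weight_decay * params[[ly]][[pn]])
      opt$state[[ly]][[pn]] <- st
    }
  }
  list(params = params, opt = opt)
}

# One-cycle schedule: linear warmup to max_lr over the first `pct` of steps,
# cosine decay to max_lr/final_div afterwards.
onecycle_lr <- function(step, total_steps, max_lr, pct = 0.3,
                        final_div = 100) {
  warm <- max(1, round(pct * total_steps))
  if (step <= warm) return(max_lr * (0.1 + 0.9 * step / warm))
  t <- (step - warm) / max(1, total_steps - warm)
  lo <- max_lr / final_div
  lo + (max_lr - lo) * (1 + cos(pi * t)) / 2
}

# Softmax cross-entropy over the channel axis; target is a binary matrix
# (class 1 = vessel). Returns loss and gradient w.r.t. the logits.
softmax_ce <- function(logits, target) {
  d <- dim(logits)
  m <- pmax(logits[, , 1], logits[, , 2])
  e0 <- exp(logits[, , 1] - m); e1 <- exp(logits[, , 2] - m)
  z <- e0 + e1
  p1 <- e1 / z
  eps <- 1e-12
  loss <- -mean(target * log(p1 + eps) + (1 - target) * log(1 - p1 + eps))
  g <- array(0, d)
  n <- length(target)
  g[, , 1] <- ((1 - p1) - (1 - target)) / n
  g[, , 2] <- (p1 - target) / n
  list(loss = loss, grad = g, prob_vessel = p1)
}
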