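# Desk-scale multi-scale detector backbone.
#
# The topology mirrors the three-stride feature pyramid of the full-size
# architecture: five stride-2 stages produce feature maps at 1/8, 1/16 and
# 1/32 of the input, the deepest map is upsampled 2x and concatenated with
# the next-shallower one before each finer head, and each head is a 1x1
# convolution emitting S x S x B*(5+C) raw predictions. Channel counts are
# a small base profile scaled by `width_multiplier`; the full 53-layer
# backbone and pretrained weights are deliberately out of scope.

LEAKY_SLOPE <- 0.1

leaky <- function(z) ifelse(z > 0, z, LEAKY_SLOPE * z)
leaky_grad <- function(z, g) g * ifelse(z > 0, 1, LEAKY_SLOPE)

NORM_EPS <- 1e-5

new_conv <- function(cin, cout, k = 3L, stride = 1L, act = "leaky",
                     norm = (act == "leaky")) {
  sd <- sqrt(2 / (k * k * cin))
  l <- list(W = matrix(stats::rnorm(k * k * cin * cout, sd = sd),
                       nrow = k * k * cin, ncol = cout),
            b = numeric(cout), kh = k, kw = k, stride = as.integer(stride),
            pad = if (k == 1L) 0L else 1L, act = act, norm = norm)
  if (norm) {
    # channel-wise normalization with learned scale/shift; the conv bias is
    # redundant under it and stays frozen at zero
    l$gamma <- rep(1, cout)
    l$beta <- numeric(cout)
  }
  l
}

#' Build the desk-scale multi-scale detector
#'
#' Constructs a randomly initialized convolutional detector with three
#' prediction scales at strides 32/16/8 and upsample-plus-concatenate
#' fusion between them. A 416-pixel input yields 13/26/52 grids; a
#' 128-pixel input yields 4/8/16.
#'
#' @param input_size Input side in pixels; must be divisible by 32.
#' @param width_multiplier Fraction scaling the channel profile
#'   (16, 32, 64, 128, 256, 512 at 1.0 — half the reference backbone's
#'   widths); 0.25 is the desk-scale setting.
#' @param B Priors per cell.
#' @param C Class count.
#' @param seed Integer seed for weight initialization.
#' @return An object of class `fy_net`: `params` (named conv layers),
#'   `spec` (the `fy_gridspec`), `width_multiplier`.
#' @export
build_backbone <- function(input_size = 416L, width_multiplier = 1,
                           B = 3L, C = 2L, seed = 1L) {
  spec <- grid_spec(input_size, B = B, C = C)  # errors if not divisible
  w <- pmax(2L, round(c(16, 32, 64, 128, 256, 512) * width_multiplier))
  nout <- B * (5L + C)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))
  p <- list(
    stem  = new_conv(3L, w[1]),
    d2    = new_conv(w[1], w[2], stride = 2L),
    c2    = new_conv(w[2], w[2]),
    d4    = new_conv(w[2], w[3], stride = 2L),
    c4    = new_conv(w[3], w[3]),
    d8    = new_conv(w[3], w[4], stride = 2L),
    c8    = new_conv(w[4], w[4]),
    d16   = new_conv(w[4], w[5], stride = 2L),
    c16   = new_conv(w[5], w[5]),
    d32   = new_conv(w[5], w[6], stride = 2L),
    c32   = new_conv(w[6], w[6]),
    head32 = new_conv(w[6], nout, k = 1L, act = "linear"),
    f16   = new_conv(w[6] + w[5], w[5]),
    head16 = new_conv(w[5], nout, k = 1L, act = "linear"),
    f8    = new_conv(w[5] + w[4], w[4]),
    head8 = new_conv(w[4], nout, k = 1L, act = "linear")
  )
  # bias the objectness logit negative so an untrained net predicts
  # background nearly everywhere, and damp the box-regression weights so
  # predictions start near the priors (both stabilize the first SGD steps)
  for (hd in c("head32", "head16", "head8")) {
    p[[hd]]$b[5L + (0:(B - 1L)) * (5L + C)] <- -4
    box_cols <- as.vector(outer(1:4, (0:(B - 1L)) * (5L + C), `+`))
    p[[hd]]$W[, box_cols] <- p[[hd]]$W[, box_cols] * 0.1
  }
  structure(list(params = p, spec = spec, width_multiplier = width_multiplier),
            class = "fy_net")
}

#' @export
print.fy_net <- function(x, ...) {
  np <- sum(vapply(x$params, function(l) length(l$W) + length(l$b), 0))
  cat(sprintf("fy_net: input %d, grids %s, %d parameters\n",
              x$spec$input_size, paste(x$spec$S, collapse = "/"), np))
  invisible(x)
}

conv_fw <- function(layer, x) {
  z <- conv2d_forward(x, layer$W, layer$b, layer$kh, layer$kw,
                      layer$stride, layer$pad)
  if (isTRUE(layer$norm)) {
    d <- dim(z)
    zm <- matrix(z, d[1] * d[2], d[3])
    mu <- colMeans(zm)
    v <- colMeans(zm^2) - mu^2
    inv <- 1 / sqrt(v + NORM_EPS)
    zhat <- sweep(zm, 2L, mu) * rep(inv, each = d[1] * d[2])
    pre <- sweep(zhat * rep(layer$gamma, each = d[1] * d[2]), 2L,
                 layer$beta, `+`)
    y <- array(leaky(pre), dim = d)
    list(y = y, x = x, zhat = zhat, inv = inv, pre = pre, d = d)
  } else {
    y <- if (layer$act == "leaky") leaky(z) else z
    list(y = y, z = z, x = x)
  }
}

upsample2 <- function(x) {
  x[rep(seq_len(dim(x)[1]), each = 2L),
    rep(seq_len(dim(x)[2]), each = 2L), , drop = FALSE]
}

downsum2 <- function(g) {
  H <- dim(g)[1] / 2L; W <- dim(g)[2] / 2L
  out <- array(0, dim = c(H, W, dim(g)[3]))
  for (di in 0:1) for (dj in 0:1) {
    out <- out + g[seq(1L + di, by = 2L, length.out = H),
                   seq(1L + dj, by = 2L, length.out = W), , drop = FALSE]
  }
  out
}

concat3 <- function(a, b) {
  array(c(a, b), dim = c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
}

# head output (S,S,B*(5+C)) -> (S,S,B,5+C); channels are prior-major
head_to_raw <- function(h, B, C) {
  S <- dim(h)[1]
  aperm(array(h, dim = c(S, S, 5L + C, B)), c(1, 2, 4, 3))
}

raw_grad_to_head <- function(g4, B, C) {
  S <- dim(g4)[1]
  array(aperm(g4, c(1, 2, 4, 3)), dim = c(S, S, (5L + C) * B))
}

#' Forward pass of the detector
#'
#' @param net An `fy_net`.
#' @param x Input image array `H x W x 3` in `[0, 1]` with
#'   `H = W = input_size`.
#' @param keep_cache Keep intermediates for a subsequent backward pass.
#' @return A list: `raw` — named list of per-scale `S x S x B x (5+C)`
#'   arrays keyed by grid size (coarsest first); `cache` when requested.
#' @export
net_forward <- function(net, x, keep_cache = FALSE) {
  p <- net$params
  spec <- net$spec
  stopifnot(all(dim(x)[1:2] == spec$input_size), dim(x)[3] == 3L)
  cc <- list()
  cc$stem <- conv_fw(p$stem, x)
  cc$d2 <- conv_fw(p$d2, cc$stem$y);  cc$c2 <- conv_fw(p$c2, cc$d2$y)
  cc$d4 <- conv_fw(p$d4, cc$c2$y);    cc$c4 <- conv_fw(p$c4, cc$d4$y)
  cc$d8 <- conv_fw(p$d8, cc$c4$y);    cc$c8 <- conv_fw(p$c8, cc$d8$y)
  cc$d16 <- conv_fw(p$d16, cc$c8$y);  cc$c16 <- conv_fw(p$c16, cc$d16$y)
  cc$d32 <- conv_fw(p$d32, cc$c16$y); cc$c32 <- conv_fw(p$c32, cc$d32$y)
  cc$head32 <- conv_fw(p$head32, cc$c32$y)
  cc$cat16_in <- concat3(upsample2(cc$c32$y), cc$c16$y)
  cc$f16 <- conv_fw(p$f16, cc$cat16_in)
  cc$head16 <- conv_fw(p$head16, cc$f16$y)
  cc$cat8_in <- concat3(upsample2(cc$f16$y), cc$c8$y)
  cc$f8 <- conv_fw(p$f8, cc$cat8_in)
  cc$head8 <- conv_fw(p$head8, cc$f8$y)
  raw <- list(head_to_raw(cc$head32$y, spec$B, spec$C),
              head_to_raw(cc$head16$y, spec$B, spec$C),
              head_to_raw(cc$head8$y, spec$B, spec$C))
  names(raw) <- as.character(spec$S)
  list(raw = raw, cache = if (keep_cache) cc else NULL)
}

conv_bw <- function(layer, cache, gy) {
  if (isTRUE(layer$norm)) {
    d <- cache$d
    n <- d[1] * d[2]
    g0 <- matrix(leaky_grad(cache$pre, as.vector(gy)), n, d[3])
    ggamma <- colSums(g0 * cache$zhat)
    gbeta <- colSums(g0)
    gzhat <- g0 * rep(layer$gamma, each = n)
    m1 <- colMeans(gzhat)
    m2 <- colMeans(gzhat * cache$zhat)
    gz <- (sweep(gzhat, 2L, m1) - cache$zhat * rep(m2, each = n)) *
      rep(cache$inv, each = n)
    r <- conv2d_backward(cache$x, layer$W, array(gz, dim = d), layer$kh,
                         layer$kw, layer$stride, layer$pad)
    r$gb <- r$gb * 0  # bias frozen under normalization
    r$ggamma <- ggamma
    r$gbeta <- gbeta
    r
  } else {
    if (layer$act == "leaky") gy <- leaky_grad(cache$z, gy)
    conv2d_backward(cache$x, layer$W, gy, layer$kh, layer$kw,
                    layer$stride, layer$pad)
  }
}

#' Backward pass of the detector
#'
#' Backpropagates per-scale gradients on the raw prediction tensors through
#' the fusion topology and all convolutions.
#'
#' @param net An `fy_net`.
#' @param cache Forward cache from [net_forward()].
#' @param graw Named list of gradients matching the `raw` output layout.
#' @return Named list of parameter gradients (`W`, `b` per layer).
#' @export
net_backward <- function(net, cache, graw) {
  p <- net$params
  spec <- net$spec
  B <- spec$B; C <- spec$C
  gp <- list()
  g32 <- raw_grad_to_head(graw[[as.character(spec$S[1])]], B, C)
  g16 <- raw_grad_to_head(graw[[as.character(spec$S[2])]], B, C)
  g8  <- raw_grad_to_head(graw[[as.character(spec$S[3])]], B, C)

  r <- conv_bw(p$head8, cache$head8, g8);   gp$head8 <- param_grads(r)
  r <- conv_bw(p$f8, cache$f8, r$gx);       gp$f8 <- param_grads(r)
  ncat8 <- dim(cache$cat8_in)[3]
  nup8 <- ncat8 - dim(cache$c8$y)[3]
  g_f16y <- downsum2(r$gx[, , seq_len(nup8), drop = FALSE])
  g_c8y <- r$gx[, , nup8 + seq_len(ncat8 - nup8), drop = FALSE]

  r <- conv_bw(p$head16, cache$head16, g16); gp$head16 <- param_grads(r)
  g_f16y <- g_f16y + r$gx
  r <- conv_bw(p$f16, cache$f16, g_f16y);   gp$f16 <- param_grads(r)
  ncat16 <- dim(cache$cat16_in)[3]
  nup16 <- ncat16 - dim(cache$c16$y)[3]
  g_c32y <- downsum2(r$gx[, , seq_len(nup16), drop = FALSE])
  g_c16y <- r$gx[, , nup16 + seq_len(ncat16 - nup16), drop = FALSE]

  r <- conv_bw(p$head32, cache$head32, g32); gp$head32 <- param_grads(r)
  g_c32y <- g_c32y + r$gx

  r <- conv_bw(p$c32, cache$c32, g_c32y); gp$c32 <- param_grads(r)
  r <- conv_bw(p$d32, cache$d32, r$gx);   gp$d32 <- param_grads(r)
  g_c16y <- g_c16y + r$gx
  r <- conv_bw(p$c16, cache$c16, g_c16y); gp$c16 <- param_grads(r)
  r <- conv_bw(p$d16, cache$d16, r$gx);   gp$d16 <- param_grads(r)
  g_c8y <- g_c8y + r$gx
  r <- conv_bw(p$c8, cache$c8, g_c8y);    gp$c8 <- param_grads(r)
  r <- conv_bw(p$d8, cache$d8, r$gx);     gp$d8 <- param_grads(r)
  r <- conv_bw(p$c4, cache$c4, r$gx);     gp$c4 <- param_grads(r)
  r <- conv_bw(p$d4, cache$d4, r$gx);     gp$d4 <- param_grads(r)
  r <- conv_bw(p$c2, cache$c2, r$gx);     gp$c2 <- param_grads(r)
  r <- conv_bw(p$d2, cache$d2, r$gx);     gp$d2 <- param_grads(r)
  r <- conv_bw(p$stem, cache$stem, r$gx); gp$stem <- param_grads(r)
  gp
}

# gradient fields of a conv_bw result, keyed like the layer's parameters
param_grads <- function(r) {
  r[intersect(names(r), c("gW", "gb", "ggamma", "gbeta"))]
}

zero_like_params <- function(params) {
  lapply(params, function(l) {
    z <- list(gW = l$W * 0, gb = l$b * 0)
    if (isTRUE(l$norm)) {
      z$ggamma <- l$gamma * 0
      z$gbeta <- l$beta * 0
    }
    z
  })
}

accumulate_grads <- function(acc, g) {
  for (nm in names(g)) {
    for (f in names(g[[nm]])) acc[[nm]][[f]] <- acc[[nm]][[f]] + g[[nm]][[f]]
  }
  acc
}

scale_grads <- function(g, s) {
  lapply(g, function(l) lapply(l, `*`, s))
}

grad_global_norm <- function(g) {
  sqrt(sum(vapply(g, function(l) sum(vapply(l, function(x) sum(x^2), 0)), 0)))
}

# SGD with momentum; returns updated net and velocity
sgd_step <- function(net, grads, velocity, lr, momentum, clip_norm = 25) {
  gn <- grad_global_norm(grads)
  if (is.finite(gn) && gn > clip_norm) grads <- scale_grads(grads, clip_norm / gn)
  field_of <- c(gW = "W", gb = "b", ggamma = "gamma", gbeta = "beta")
  for (nm in names(net$params)) {
    for (f in names(grads[[nm]])) {
      velocity[[nm]][[f]] <- momentum * velocity[[nm]][[f]] -
        lr * grads[[nm]][[f]]
      pf <- field_of[[f]]
      net$params[[nm]][[pf]] <- net$params[[nm]][[pf]] + velocity[[nm]][[f]]
    }
  }
  list(net = net, velocity = velocity)
}
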