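# Minimal layer framework backing the three RegGAN networks.
#
# Layers are environments holding parameters, Adam state and the forward
# cache; `ly_forward()` / `ly_backward()` dispatch on `$type`. Feature maps
# are (H, W, C) arrays throughout; batches are processed one slice at a time
# (the reference training regime uses batch size 1).

as_feature_map <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("expected a (H, W, C) array or a matrix")
  x
}

reflect_idx <- function(n, p) {
  if (p == 0L) return(seq_len(n))
  if (n < p + 1L) stop("image too small for reflection padding of width ", p)
  c(seq(p + 1L, 2L), seq_len(n), seq(n - 1L, n - p))
}

pad_reflect <- function(x, p) {
  if (p == 0L) return(x)
  x[reflect_idx(dim(x)[1], p), reflect_idx(dim(x)[2], p), , drop = FALSE]
}

# adjoint of pad_reflect: fold padded-gradient contributions back
unpad_reflect <- function(g, p) {
  if (p == 0L) return(g)
  d <- dim(g)
  H <- d[1] - 2L * p; W <- d[2] - 2L * p
  ri <- reflect_idx(H, p); ci <- reflect_idx(W, p)
  Pr <- matrix(0, length(ri), H); Pr[cbind(seq_along(ri), ri)] <- 1
  Pc <- matrix(0, length(ci), W); Pc[cbind(seq_along(ci), ci)] <- 1
  out <- array(0, c(H, W, d[3]))
  for (c in seq_len(d[3])) out[, , c] <- crossprod(Pr, g[, , c]) %*% Pc
  out
}

nn_conv <- function(in_ch, out_ch, k, stride = 1L, pad = 0L,
                    transpose = FALSE, pad_mode = "zero",
                    init = c("normal", "zero"), init_sd = 0.02) {
  init <- match.arg(init)
  l <- new.env(parent = emptyenv())
  l$type <- if (transpose) "convt" else "conv"
  wdim <- if (transpose) c(k, k, out_ch, in_ch) else c(k, k, in_ch, out_ch)
  l$W <- if (init == "zero") array(0, wdim) else
    array(stats::rnorm(prod(wdim), 0, init_sd), wdim)
  l$b <- numeric(out_ch)
  l$stride <- as.integer(stride); l$pad <- as.integer(pad)
  l$pad_mode <- pad_mode
  l
}

nn_inorm <- function(eps = 1e-5) {
  l <- new.env(parent = emptyenv())
  l$type <- "inorm"; l$eps <- eps
  l
}

nn_act <- function(kind = c("relu", "lrelu", "tanh"), slope = 0.2) {
  kind <- match.arg(kind)
  l <- new.env(parent = emptyenv())
  l$type <- kind; l$slope <- slope
  l
}

ly_forward <- function(l, x) {
  switch(l$type,
    conv = {
      if (l$pad_mode == "reflect") {
        xp <- pad_reflect(x, l$pad)
        l$x <- xp
        cpp_conv_fwd(xp, l$W, l$b, l$stride, 0L)
      } else {
        l$x <- x
        cpp_conv_fwd(x, l$W, l$b, l$stride, l$pad)
      }
    },
    convt = {
      l$x <- x
      d <- dim(x)
      cpp_convt_fwd(x, l$W, l$b, l$stride, l$pad,
                    l$stride * d[1], l$stride * d[2])
    },
    inorm = {
      d <- dim(x)
      m <- matrix(x, d[1] * d[2], d[3])
      mu <- colMeans(m)
      v <- colMeans(m * m) - mu * mu
      istd <- 1 / sqrt(v + l$eps)
      xhat <- (m - rep(mu, each = nrow(m))) * rep(istd, each = nrow(m))
      l$xhat <- xhat; l$istd <- istd; l$d <- d
      array(xhat, d)
    },
    relu = { l$mask <- x > 0; x * l$mask },
    lrelu = {
      m <- (x > 0) + 0
      l$scale <- m + l$slope * (1 - m)
      x * l$scale
    },
    tanh = { y <- tanh(x); l$y <- y; y }
  )
}

ly_backward <- function(l, gy) {
  switch(l$type,
    conv = {
      g <- cpp_conv_bwd(l$x, l$W, gy, l$stride,
                        if (l$pad_mode == "reflect") 0L else l$pad)
      l$gW <- if (is.null(l$gW)) g$gW else l$gW + g$gW
      l$gb <- if (is.null(l$gb)) g$gb else l$gb + g$gb
      if (l$pad_mode == "reflect") unpad_reflect(g$gx, l$pad) else g$gx
    },
    convt = {
      g <- cpp_convt_bwd(l$x, l$W, gy, l$stride, l$pad)
      l$gW <- if (is.null(l$gW)) g$gW else l$gW + g$gW
      l$gb <- if (is.null(l$gb)) g$gb else l$gb + g$gb
      g$gx
    },
    inorm = {
      d <- l$d
      gm <- matrix(gy, d[1] * d[2], d[3])
      mg <- colMeans(gm)
      mgx <- colMeans(gm * l$xhat)
      gx <- (gm - rep(mg, each = nrow(gm)) -
               l$xhat * rep(mgx, each = nrow(gm))) *
            rep(l$istd, each = nrow(gm))
      array(gx, d)
    },
    relu = gy * l$mask,
    lrelu = gy * l$scale,
    tanh = gy * (1 - l$y * l$y)
  )
}

ly_params <- function(l) if (l$type %in% c("conv", "convt")) l else NULL

seq_forward <- function(layers, x) {
  for (l in layers) x <- ly_forward(l, x)
  x
}

seq_backward <- function(layers, gy) {
  for (l in rev(layers)) gy <- ly_backward(l, gy)
  gy
}

collect_layers <- function(x) {
  if (is.environment(x)) {
    p <- ly_params(x)
    return(if (is.null(p)) list() else list(p))
  }
  if (is.list(x)) return(do.call(c, lapply(x, collect_layers)))
  list()
}

net_zero_grad <- function(net) {
  for (l in collect_layers(net$layers)) { l$gW <- NULL; l$gb <- NULL }
  invisible(net)
}

n_params <- function(net) {
  sum(vapply(collect_layers(net$layers),
             function(l) length(l$W) + length(l$b), numeric(1)))
}

# classic Adam with L2 weight decay folded into the gradient
make_adam <- function(lr = 1e-4, beta1 = 0.5, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 1e-4) {
  opt <- new.env(parent = emptyenv())
  opt$lr <- lr; opt$b1 <- beta1; opt$b2 <- beta2
  opt$eps <- eps; opt$wd <- weight_decay; opt$t <- 0L
  opt
}

adam_step <- function(opt, net) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - opt$b1^opt$t
  bc2 <- 1 - opt$b2^opt$t
  for (l in collect_layers(net$layers)) {
    if (is.null(l$gW)) next
    gW <- l$gW + opt$wd * l$W
    gb <- l$gb
    if (is.null(l$mW)) {
      l$mW <- array(0, dim(l$W)); l$vW <- array(0, dim(l$W))
      l$mb <- numeric(length(l$b)); l$vb <- numeric(length(l$b))
    }
    l$mW <- opt$b1 * l$mW + (1 - opt$b1) * gW
    l$vW <- opt$b2 * l$vW + (1 - opt$b2) * gW * gW
    l$mb <- opt$b1 * l$mb + (1 - opt$b1) * gb
    l$vb <- opt$b2 * l$vb + (1 - opt$b2) * gb * gb
    l$W <- l$W - opt$lr * (l$mW / bc1) / (sqrt(l$vW / bc2) + opt$eps)
    l$b <- l$b - opt$lr * (l$mb / bc1) / (sqrt(l$vb / bc2) + opt$eps)
  }
  invisible(net)
}

net_state <- function(net) {
  lapply(collect_layers(net$layers), function(l) list(W = l$W, b = l$b))
}

net_restore <- function(net, state) {
  ls <- collect_layers(net$layers)
  stopifnot(length(ls) == length(state))
  for (i in seq_along(ls)) { ls[[i]]$W <- state[[i]]$W; ls[[i]]$b <- state[[i]]$b }
  invisible(net)
}
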