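# Network definitions: ResNet-style generator, U-Net registration network,
# PatchGAN discriminator. Each build_* returns an environment with $cfg,
# $layers and (for the U-Net) a forward cache; *_apply run inference,
# the internal *_backward mirror the forward passes for training.

#' Generator configuration
#'
#' ResNet-style image-to-image generator: a 7x7 stem convolution, two
#' stride-2 downsampling blocks, `n_residual_blocks` residual blocks at the
#' bottleneck resolution, two stride-2 transposed-convolution upsampling
#' blocks, and a 7x7 head with a tanh activation bounding the output to
#' \[-1, 1\]. Instance normalization and reflection padding for the 7x7
#' convolutions follow the usual translation-network conventions.
#'
#' @param base_channels channels after the stem convolution (default 64)
#' @param n_residual_blocks number of residual blocks (default 9)
#' @return an object of class `"generator_config"`
#' @export
generator_config <- function(base_channels = 64L, n_residual_blocks = 9L) {
  base_channels <- as.integer(base_channels)
  n_residual_blocks <- as.integer(n_residual_blocks)
  if (is.na(base_channels) || base_channels < 1L)
    stop("configuration error: base_channels must be a positive integer")
  if (is.na(n_residual_blocks) || n_residual_blocks < 1L)
    stop("configuration error: n_residual_blocks must be >= 1")
  structure(list(in_channels = 1L, base_channels = base_channels,
                 n_residual_blocks = n_residual_blocks,
                 downsample_stages = 2L, upsample_stages = 2L),
            class = "generator_config")
}

#' Registration network configuration
#'
#' U-Net taking the channel-concatenation of the generated image and the
#' (possibly misaligned) label and returning a dense 2-component displacement
#' field in pixel units. The final convolution is zero-initialized so the
#' predicted field is exactly zero before any training.
#'
#' @param encoder_depth number of stride-2 encoder levels (default 4)
#' @param base_channels channels at the first encoder level (default 16)
#' @return an object of class `"registration_config"`
#' @export
registration_config <- function(encoder_depth = 4L, base_channels = 16L) {
  encoder_depth <- as.integer(encoder_depth)
  base_channels <- as.integer(base_channels)
  if (is.na(encoder_depth) || encoder_depth < 1L)
    stop("configuration error: encoder_depth must be >= 1")
  if (is.na(base_channels) || base_channels < 1L)
    stop("configuration error: base_channels must be a positive integer")
  structure(list(in_channels = 2L, encoder_depth = encoder_depth,
                 base_channels = base_channels, out_channels = 2L),
            class = "registration_config")
}

#' Discriminator configuration
#'
#' Patch discriminator built from four 4x4 convolutions. The first three use
#' stride 2 and the last stride 1, so a 256x256 input maps to a 31x31 score
#' map in which each score judges a local patch rather than the whole image.
#'
#' @param n_layers number of convolution layers (default 4)
#' @param kernel_size convolution kernel size (default 4)
#' @param base_channels channels after the first convolution (default 64)
#' @return an object of class `"discriminator_config"`
#' @export
discriminator_config <- function(n_layers = 4L, kernel_size = 4L,
                                 base_channels = 64L) {
  n_layers <- as.integer(n_layers); kernel_size <- as.integer(kernel_size)
  base_channels <- as.integer(base_channels)
  if (is.na(n_layers) || n_layers < 2L)
    stop("configuration error: n_layers must be >= 2")
  if (is.na(kernel_size) || kernel_size < 1L)
    stop("configuration error: kernel_size must be positive")
  if (is.na(base_channels) || base_channels < 1L)
    stop("configuration error: base_channels must be a positive integer")
  structure(list(n_layers = n_layers, kernel_size = kernel_size,
                 base_channels = base_channels),
            class = "discriminator_config")
}

#' Build the generator network
#'
#' @param cfg a [generator_config()]
#' @param zero_init_head zero-initialize the final convolution, so the
#'   untrained generator outputs a constant mid-window image (tanh(0) = 0)
#' @return a network object of class `"reggan_generator"`
#' @export
build_generator <- function(cfg = generator_config(), zero_init_head = FALSE) {
  stopifnot(inherits(cfg, "generator_config"))
  C <- cfg$base_channels
  res_blocks <- lapply(seq_len(cfg$n_residual_blocks), function(i) {
    list(nn_conv(4 * C, 4 * C, 3L, pad = 1L), nn_inorm(), nn_act("relu"),
         nn_conv(4 * C, 4 * C, 3L, pad = 1L), nn_inorm())
  })
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$layers <- list(
    stem = list(nn_conv(1L, C, 7L, pad = 3L, pad_mode = "reflect"),
                nn_inorm(), nn_act("relu")),
    down = list(
      list(nn_conv(C, 2L * C, 3L, stride = 2L, pad = 1L), nn_inorm(),
           nn_act("relu")),
      list(nn_conv(2L * C, 4L * C, 3L, stride = 2L, pad = 1L), nn_inorm(),
           nn_act("relu"))),
    res = res_blocks,
    up = list(
      list(nn_conv(4L * C, 2L * C, 3L, stride = 2L, pad = 1L,
                   transpose = TRUE), nn_inorm(), nn_act("relu")),
      list(nn_conv(2L * C, C, 3L, stride = 2L, pad = 1L,
                   transpose = TRUE), nn_inorm(), nn_act("relu"))),
    head = list(nn_conv(C, 1L, 7L, pad = 3L, pad_mode = "reflect",
                        init = if (zero_init_head) "zero" else "normal"),
                nn_act("tanh")))
  class(net) <- c("reggan_generator", "reggan_net")
  net
}

gen_forward <- function(net, x) {
  x <- as_feature_map(x)
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("generator input sides must be divisible by 4, got ",
         d[1], " x ", d[2])
  h <- seq_forward(net$layers$stem, x)
  for (blk in net$layers$down) h <- seq_forward(blk, h)
  for (blk in net$layers$res) h <- h + seq_forward(blk, h)
  for (blk in net$layers$up) h <- seq_forward(blk, h)
  seq_forward(net$layers$head, h)
}

gen_backward <- function(net, gy) {
  g <- seq_backward(net$layers$head, gy)
  for (blk in rev(net$layers$up)) g <- seq_backward(blk, g)
  for (blk in rev(net$layers$res)) g <- g + seq_backward(blk, g)
  for (blk in rev(net$layers$down)) g <- seq_backward(blk, g)
  seq_backward(net$layers$stem, g)
}

#' Apply the generator to a normalized image
#'
#' @param net a network from [build_generator()]
#' @param x a matrix or (H, W, 1) array with values in \[-1, 1\]; both sides
#'   must be divisible by 4
#' @return an (H, W, 1) array in \[-1, 1\]
#' @export
generator_apply <- function(net, x) {
  stopifnot(inherits(net, "reggan_generator"))
  gen_forward(net, x)
}

#' Build the registration network
#'
#' @param cfg a [registration_config()]
#' @return a network object of class `"reggan_registration"`
#' @export
build_registration <- function(cfg = registration_config()) {
  stopifnot(inherits(cfg, "registration_config"))
  C <- cfg$base_channels; d <- cfg$encoder_depth
  ch <- C * pmin(2L^(seq_len(d) - 1L), 2L)  # C, 2C, 2C, ...
  enc <- vector("list", d)
  for (i in seq_len(d)) {
    in_ch <- if (i == 1L) cfg$in_channels else ch[i - 1L]
    enc[[i]] <- list(nn_conv(in_ch, ch[i], 3L, stride = 2L, pad = 1L),
                     nn_act("lrelu"))
  }
  dec <- vector("list", d)
  cur <- ch[d]
  for (i in rev(seq_len(d))) {
    out_ch <- if (i > 1L) ch[i - 1L] else C
    skip_ch <- if (i > 1L) ch[i - 1L] else cfg$in_channels
    dec[[i]] <- list(
      up = list(nn_conv(cur, out_ch, 3L, stride = 2L, pad = 1L,
                        transpose = TRUE), nn_act("lrelu")),
      fuse = list(nn_conv(out_ch + skip_ch, out_ch, 3L, pad = 1L),
                  nn_act("lrelu")))
    cur <- out_ch
  }
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$layers <- list(enc = enc, dec = dec,
                     final = list(nn_conv(C, 2L, 3L, pad = 1L, init = "zero")))
  class(net) <- c("reggan_registration", "reggan_net")
  net
}

reg_forward <- function(net, a, b) {
  a <- as_feature_map(a); b <- as_feature_map(b)
  if (!all(dim(a)[1:2] == dim(b)[1:2]))
    stop("registration inputs must share the same spatial shape")
  x <- array(c(a, b), c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  d <- net$cfg$encoder_depth
  if (any(dim(x)[1:2] %% 2L^d != 0L))
    stop("registration input sides must be divisible by 2^encoder_depth")
  skips <- vector("list", d)  # skips[[i]]: input to encoder level i
  h <- x
  for (i in seq_len(d)) {
    skips[[i]] <- h
    h <- seq_forward(net$layers$enc[[i]], h)
  }
  net$skip_ch <- vapply(skips, function(s) dim(s)[3], integer(1))
  for (i in rev(seq_len(d))) {
    h <- seq_forward(net$layers$dec[[i]]$up, h)
    h <- array(c(h, skips[[i]]),
               c(dim(h)[1], dim(h)[2], dim(h)[3] + dim(skips[[i]])[3]))
    h <- seq_forward(net$layers$dec[[i]]$fuse, h)
  }
  seq_forward(net$layers$final, h)
}

reg_backward <- function(net, gfield) {
  d <- net$cfg$encoder_depth
  g <- seq_backward(net$layers$final, gfield)
  gskips <- vector("list", d)
  for (i in seq_len(d)) {
    g <- seq_backward(net$layers$dec[[i]]$fuse, g)
    nch <- dim(g)[3]
    skip_ch <- net$skip_ch[i]
    gskips[[i]] <- g[, , (nch - skip_ch + 1L):nch, drop = FALSE]
    g <- g[, , seq_len(nch - skip_ch), drop = FALSE]
    g <- seq_backward(net$layers$dec[[i]]$up, g)
  }
  for (i in rev(seq_len(d))) {
    g <- seq_backward(net$layers$enc[[i]], g)
    g <- g + gskips[[i]]
  }
  g  # gradient wrt the concatenated (a, b) input
}

#' Apply the registration network to an image pair
#'
#' Returns the dense displacement field aligning `a` towards `b` (pixel
#' units, (row, col) components in the third dimension). With the
#' zero-initialized final layer the field is exactly zero before training.
#'
#' @param net a network from [build_registration()]
#' @param a,b same-shape matrices or (H, W, 1) arrays
#' @return an (H, W, 2) displacement array
#' @export
registration_apply <- function(net, a, b) {
  stopifnot(inherits(net, "reggan_registration"))
  reg_forward(net, a, b)
}

#' Build the patch discriminator
#'
#' @param cfg a [discriminator_config()]
#' @return a network object of class `"reggan_discriminator"`
#' @export
build_discriminator <- function(cfg = discriminator_config()) {
  stopifnot(inherits(cfg, "discriminator_config"))
  C <- cfg$base_channels; k <- cfg$kernel_size; n <- cfg$n_layers
  layers <- list(nn_conv(1L, C, k, stride = 2L, pad = 1L), nn_act("lrelu"))
  ch <- C
  for (i in seq_len(n - 2L)) {
    nxt <- min(ch * 2L, 8L * C)
    layers <- c(layers, list(nn_conv(ch, nxt, k, stride = 2L, pad = 1L),
                             nn_inorm(), nn_act("lrelu")))
    ch <- nxt
  }
  layers <- c(layers, list(nn_conv(ch, 1L, k, stride = 1L, pad = 1L)))
  net <- new.env(parent = emptyenv())
  net$cfg <- cfg
  net$layers <- layers
  class(net) <- c("reggan_discriminator", "reggan_net")
  net
}

disc_forward <- function(net, x) seq_forward(net$layers, as_feature_map(x))
disc_backward <- function(net, gy) seq_backward(net$layers, gy)

#' Apply the discriminator
#'
#' @param net a network from [build_discriminator()]
#' @param x a matrix or (H, W, 1) array
#' @return an (N, N, 1) patch score map; errors if the input is too small to
#'   produce at least a 1x1 map
#' @export
discriminator_apply <- function(net, x) {
  stopifnot(inherits(net, "reggan_discriminator"))
  disc_forward(net, x)
}

#' Number of trainable parameters of a network
#' @param net a network object
#' @return integer count of weights and biases
#' @export
count_params <- function(net) n_params(net)

#' @export
print.reggan_net <- function(x, ...) {
  cat(sprintf("<%s> %s parameters\n", class(x)[1],
              format(n_params(x), big.mark = ",")))
  invisible(x)
}
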