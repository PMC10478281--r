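# Model fitting: the adversarial training loop with registration-corrected
# labels, plus the S3 modelling interface (print/summary/predict/plot/coef),
# checkpointing, and a registration-only fitting routine.

CHECKPOINT_VERSION <- "reggan-checkpoint-1"

#' Training configuration
#'
#' Optimizer and loop settings. Defaults follow the reference regime: Adam
#' with learning rate 1e-4, betas (0.5, 0.999), batch size 1, weight decay
#' 1e-4, 256x256 training grid. Toy phantom runs typically use a 64x64 grid
#' and few epochs (see the methods vignette).
#'
#' @param learning_rate Adam learning rate (> 0)
#' @param adam_betas length-2 Adam (beta1, beta2)
#' @param batch_size gradient-accumulation batch size (>= 1)
#' @param weight_decay L2 weight decay applied uniformly to all networks
#' @param epochs number of passes over the training set
#' @param seed integer seed controlling initialization and shuffling
#' @param image_size square training grid side in pixels
#' @return an object of class `"train_config"`
#' @export
train_config <- function(learning_rate = 1e-4, adam_betas = c(0.5, 0.999),
                         batch_size = 1L, weight_decay = 1e-4,
                         epochs = 80L, seed = 1L, image_size = 256L) {
  if (learning_rate <= 0) stop("configuration error: learning_rate must be > 0")
  batch_size <- as.integer(batch_size)
  if (is.na(batch_size) || batch_size < 1L)
    stop("configuration error: batch_size must be >= 1")
  epochs <- as.integer(epochs)
  if (is.na(epochs) || epochs < 1L)
    stop("configuration error: epochs must be >= 1")
  structure(list(learning_rate = learning_rate,
                 adam_betas = as.numeric(adam_betas),
                 batch_size = batch_size, weight_decay = weight_decay,
                 epochs = epochs, seed = as.integer(seed),
                 image_size = as.integer(image_size)),
            class = "train_config")
}

prep_sample <- function(img, window, size) {
  v <- image_values(clip_hu(img, window[1], window[2]))
  v <- bilinear_resize(v, size, size)
  m <- 2 * (v - window[1]) / (window[2] - window[1]) - 1
  array(m, c(size, size, 1L))
}

#' Fit a registration-corrected adversarial translation model
#'
#' Trains the generator, registration network and discriminator jointly on
#' paired (planning-CT-like, CBCT-like) slices whose labels may be
#' spatially misaligned. Per batch the discriminator is updated on its
#' least-squares term first, then the generator and registration network are
#' updated jointly on the weighted correction + smoothness + adversarial
#' loss. Validation MAE (in HU) is computed each epoch and the
#' lowest-validation-MAE parameters are retained.
#'
#' @param data list of [paired_sample()] objects
#' @param validation optional list of [paired_sample()] used for validation;
#'   if `NULL`, `val_fraction` of `data` is held out
#' @param val_fraction fraction of `data` held out when `validation` is NULL
#' @param config a [train_config()]
#' @param weights a [loss_weights()]
#' @param generator a [generator_config()]
#' @param registration a [registration_config()]
#' @param discriminator a [discriminator_config()]
#' @param window HU window used for preprocessing
#' @param verbose print per-epoch progress
#' @return an object of class `"reggan"` with the trained networks, loss
#'   history and per-epoch validation MAE
#' @export
reggan <- function(data, validation = NULL, val_fraction = 0.1,
                   config = train_config(), weights = loss_weights(),
                   generator = generator_config(),
                   registration = registration_config(),
                   discriminator = discriminator_config(),
                   window = c(-1000, 2000), verbose = FALSE) {
  if (!is.list(data) || length(data) == 0L)
    stop("data must be a non-empty list of paired samples")
  stopifnot(inherits(config, "train_config"), inherits(weights, "loss_weights"))
  set.seed(config$seed)
  size <- config$image_size

  if (is.null(validation) && val_fraction > 0 && length(data) >= 5L) {
    n_val <- max(1L, round(val_fraction * length(data)))
    idx <- sample(length(data), n_val)
    validation <- data[idx]
    data <- data[-idx]
  }

  xs <- lapply(data, function(s) prep_sample(s$cbct, window, size))
  ys <- lapply(data, function(s) prep_sample(s$pct, window, size))
  val_x <- lapply(validation, function(s) prep_sample(s$cbct, window, size))
  val_y_hu <- lapply(validation, function(s) {
    v <- image_values(clip_hu(s$pct, window[1], window[2]))
    bilinear_resize(v, size, size)
  })

  G <- build_generator(generator)
  R <- build_registration(registration)
  D <- build_discriminator(discriminator)
  b <- config$adam_betas
  optG <- make_adam(config$learning_rate, b[1], b[2],
                    weight_decay = config$weight_decay)
  optR <- make_adam(config$learning_rate, b[1], b[2],
                    weight_decay = config$weight_decay)
  optD <- make_adam(config$learning_rate, b[1], b[2],
                    weight_decay = config$weight_decay)

  n <- length(xs)
  hist_rows <- vector("list", config$epochs * n)
  val_mae <- rep(NA_real_, config$epochs)
  best <- list(mae = Inf, epoch = NA_integer_, state = NULL)
  it <- 0L
  bs <- config$batch_size
  in_batch <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(n)
    for (i in ord) {
      it <- it + 1L
      x <- xs[[i]]; y <- ys[[i]]
      fake <- gen_forward(G, x)

      # --- discriminator step (real = label, fake = detached G output)
      net_zero_grad(D)
      sr <- disc_forward(D, y)
      nscore <- length(sr)
      disc_backward(D, (sr - 1) / nscore)
      sf <- disc_forward(D, fake)
      disc_backward(D, sf / nscore)
      d_term <- 0.5 * mean((sr - 1)^2) + 0.5 * mean(sf^2)
      in_batch <- in_batch + 1L
      if (in_batch %% bs == 0L) adam_step(optD, D)

      # --- joint generator / registration step
      net_zero_grad(G); net_zero_grad(R)
      field <- reg_forward(R, fake, y)
      warped <- cpp_warp_fwd(fake, field)
      resid <- y - warped
      l_corr <- mean(abs(resid))
      l_smooth <- smoothness_loss(field)
      g_warped <- -sign(resid) / length(resid) * weights$w_corr
      wb <- cpp_warp_bwd(fake, field, g_warped)
      gfield <- wb$gfield + weights$w_smooth * smoothness_grad(field)
      g_rin <- reg_backward(R, gfield)
      g_fake <- wb$gimg + g_rin[, , 1L, drop = FALSE]
      if (weights$w_adv > 0) {
        sf2 <- disc_forward(D, fake)
        adv_g <- mean((sf2 - 1)^2)
        g_fake <- g_fake +
          disc_backward(D, 2 * (sf2 - 1) / length(sf2) * weights$w_adv)
      } else adv_g <- NA_real_
      gen_backward(G, g_fake)
      if (in_batch %% bs == 0L) { adam_step(optG, G); adam_step(optR, R) }

      if (!is.finite(l_corr) || !is.finite(l_smooth) ||
          (weights$w_adv > 0 && !is.finite(adv_g)))
        stop("training diverged at iteration ", it,
             ": non-finite loss (corr=", l_corr, ", smooth=", l_smooth, ")")
      hist_rows[[it]] <- c(iter = it, epoch = epoch, corr = l_corr,
                           smooth = l_smooth, adv_g = adv_g, adv_d = d_term)
    }

    if (length(val_x) > 0L) {
      maes <- vapply(seq_along(val_x), function(k) {
        sct <- gen_forward(G, val_x[[k]])[, , 1L]
        sct_hu <- (sct + 1) / 2 * (window[2] - window[1]) + window[1]
        mean(abs(sct_hu - val_y_hu[[k]]))
      }, numeric(1))
      val_mae[epoch] <- mean(maes)
      if (val_mae[epoch] < best$mae) {
        best$mae <- val_mae[epoch]
        best$epoch <- epoch
        best$state <- list(G = net_state(G), R = net_state(R),
                           D = net_state(D))
      }
    }
    if (verbose)
      message(sprintf(
        "epoch %d/%d  corr %.4f  smooth %.5f  val MAE %s HU", epoch,
        config$epochs, mean(vapply(hist_rows[(it - n + 1L):it],
                                   `[[`, numeric(1), "corr")),
        mean(vapply(hist_rows[(it - n + 1L):it], `[[`, numeric(1), "smooth")),
        if (is.na(val_mae[epoch])) "-" else sprintf("%.1f", val_mae[epoch])))
  }

  if (!is.null(best$state)) {
    net_restore(G, best$state$G)
    net_restore(R, best$state$R)
    net_restore(D, best$state$D)
  }

  history <- as.data.frame(do.call(rbind, hist_rows))
  structure(list(generator = G, registration = R, discriminator = D,
                 generator_config = generator,
                 registration_config = registration,
                 discriminator_config = discriminator,
                 config = config, weights = weights, window = window,
                 history = history, val_mae = val_mae,
                 best_epoch = best$epoch, best_val_mae = best$mae,
                 n_train = n, n_val = length(val_x),
                 version = CHECKPOINT_VERSION),
            class = "reggan")
}

#' @export
print.reggan <- function(x, ...) {
  cat("Registration-corrected adversarial CBCT-to-sCT model\n")
  cat(sprintf("  training grid: %d x %d, HU window [%g, %g]\n",
              x$config$image_size, x$config$image_size,
              x$window[1], x$window[2]))
  cat(sprintf("  trained %d epochs on %d samples (%d validation)\n",
              x$config$epochs, x$n_train, x$n_val))
  cat(sprintf("  parameters: G %s, R %s, D %s\n",
              format(n_params(x$generator), big.mark = ","),
              format(n_params(x$registration), big.mark = ","),
              format(n_params(x$discriminator), big.mark = ",")))
  if (!is.na(x$best_epoch))
    cat(sprintf("  best validation MAE %.2f HU at epoch %d\n",
                x$best_val_mae, x$best_epoch))
  invisible(x)
}

#' @export
summary.reggan <- function(object, ...) {
  h <- object$history
  last <- h[h$epoch == max(h$epoch), ]
  out <- list(
    n_iterations = nrow(h),
    final_losses = colMeans(last[c("corr", "smooth", "adv_g", "adv_d")],
                            na.rm = TRUE),
    val_mae = object$val_mae,
    best_epoch = object$best_epoch,
    best_val_mae = object$best_val_mae,
    params = c(generator = n_params(object$generator),
               registration = n_params(object$registration),
               discriminator = n_params(object$discriminator)))
  class(out) <- "summary.reggan"
  out
}

#' @export
print.summary.reggan <- function(x, ...) {
  cat("RegGAN fit summary\n")
  cat(sprintf("  iterations: %d\n", x$n_iterations))
  cat("  mean losses over the final epoch:\n")
  print(round(x$final_losses, 5))
  if (!all(is.na(x$val_mae))) {
    cat(sprintf("  validation MAE by epoch (HU): %s\n",
                paste(sprintf("%.1f", x$val_mae), collapse = ", ")))
    cat(sprintf("  best: %.2f HU at epoch %d\n", x$best_val_mae,
                x$best_epoch))
  }
  cat("  parameter counts:\n")
  print(x$params)
  invisible(x)
}

#' @export
coef.reggan <- function(object, ...) {
  list(generator = net_state(object$generator),
       registration = net_state(object$registration),
       discriminator = net_state(object$discriminator))
}

#' @export
plot.reggan <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$iter, h$corr, type = "l", col = "steelblue",
                 xlab = "iteration", ylab = "correction loss",
                 main = "Training loss", ...)
  if (!all(is.na(x$val_mae))) {
    graphics::plot(seq_along(x$val_mae), x$val_mae, type = "b", pch = 16,
                   xlab = "epoch", ylab = "validation MAE (HU)",
                   main = "Validation")
    if (!is.na(x$best_epoch))
      graphics::abline(v = x$best_epoch, lty = 2, col = "grey50")
  } else {
    graphics::plot(h$iter, h$smooth, type = "l", col = "darkorange",
                   xlab = "iteration", ylab = "smoothness loss",
                   main = "Field smoothness")
  }
  invisible(x)
}

#' Translate CBCT slices to synthetic CT
#'
#' Applies the full inference pipeline: clip to the training window,
#' normalize, resample to the training grid, apply the generator only (the
#' registration network and discriminator are training-time components),
#' map back to HU and resample to the input grid.
#'
#' @param object a fitted [reggan()] model
#' @param newdata an [hu_image()], matrix, [paired_sample()], or a list of
#'   these (for a paired sample, its `cbct` slice is translated)
#' @param ... unused
#' @return an [hu_image()] (or list of them) on the input grid
#' @export
predict.reggan <- function(object, newdata, ...) {
  if (inherits(newdata, "paired_sample")) newdata <- newdata$cbct
  if (is.list(newdata) && !inherits(newdata, "hu_image")) {
    return(lapply(newdata, function(s) predict(object, s)))
  }
  v <- image_values(newdata)
  window <- object$window
  size <- object$config$image_size
  x <- prep_sample(newdata, window, size)
  out <- gen_forward(object$generator, x)[, , 1L]
  hu <- (out + 1) / 2 * (window[2] - window[1]) + window[1]
  hu <- bilinear_resize(hu, nrow(v), ncol(v))
  hu <- pmin(pmax(hu, window[1]), window[2])
  if (inherits(newdata, "hu_image")) hu_image(hu, newdata$spacing)
  else hu_image(hu)
}

#' @rdname predict.reggan
#' @param cbct the CBCT input image
#' @param model a fitted [reggan()] model or a checkpoint path
#' @export
translate <- function(cbct, model) {
  if (is.character(model)) model <- load_reggan(model)
  stopifnot(inherits(model, "reggan"))
  predict(model, cbct)
}

#' Save / load a model checkpoint
#'
#' Checkpoints store all three networks' parameters, their configurations
#' and the preprocessing window, guarded by a version tag.
#'
#' @param model a fitted [reggan()] model
#' @param path destination `.rds` path
#' @return `save_reggan`: invisibly, the path; `load_reggan`: the model
#' @export
save_reggan <- function(model, path) {
  stopifnot(inherits(model, "reggan"))
  payload <- list(version = CHECKPOINT_VERSION,
                  generator_config = model$generator_config,
                  registration_config = model$registration_config,
                  discriminator_config = model$discriminator_config,
                  config = model$config, weights = model$weights,
                  window = model$window, states = coef(model),
                  history = model$history, val_mae = model$val_mae,
                  best_epoch = model$best_epoch,
                  best_val_mae = model$best_val_mae,
                  n_train = model$n_train, n_val = model$n_val)
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_reggan
#' @export
load_reggan <- function(path) {
  payload <- readRDS(path)
  if (!identical(payload$version, CHECKPOINT_VERSION))
    stop("incompatible checkpoint version: ", payload$version,
         " (expected ", CHECKPOINT_VERSION, ")")
  G <- build_generator(payload$generator_config)
  R <- build_registration(payload$registration_config)
  D <- build_discriminator(payload$discriminator_config)
  net_restore(G, payload$states$generator)
  net_restore(R, payload$states$registration)
  net_restore(D, payload$states$discriminator)
  structure(list(generator = G, registration = R, discriminator = D,
                 generator_config = payload$generator_config,
                 registration_config = payload$registration_config,
                 discriminator_config = payload$discriminator_config,
                 config = payload$config, weights = payload$weights,
                 window = payload$window, history = payload$history,
                 val_mae = payload$val_mae, best_epoch = payload$best_epoch,
                 best_val_mae = payload$best_val_mae,
                 n_train = payload$n_train, n_val = payload$n_val,
                 version = payload$version),
            class = "reggan")
}

#' Fit the registration network alone
#'
#' Trains only the registration network on (moving, fixed) image pairs with
#' the correction + smoothness objective, keeping the generator fixed to the
#' identity. This isolates the label-noise model: with pairs built as
#' `(y, y warped by a known field)`, the fitted field should recover a valid
#' alignment and drive the correction loss far below its zero-field value.
#'
#' @param pairs list of `list(moving = , fixed = )` matrices in \[-1, 1\]
#'   (or [normalized_image()] objects)
#' @param cfg a [registration_config()]; registration-only fits default to a
#'   wider net (base 32) than the full adversarial fit
#' @param iterations number of optimization steps (pairs are cycled)
#' @param learning_rate Adam learning rate (default 1e-3, the usual
#'   registration-network setting)
#' @param weights a [loss_weights()]; the adversarial weight is ignored
#' @param weight_decay L2 decay (default 0: decay pulls the zero-initialized
#'   field head back towards the identity transform, biasing displacement
#'   magnitudes low, so it is disabled for registration-only fits)
#' @param seed integer seed
#' @param verbose print progress every 100 iterations
#' @return an object of class `"registration_fit"` with elements `net`,
#'   `loss_history`, `initial_loss` and `final_loss` (mean correction loss
#'   over all pairs before and after fitting)
#' @export
train_registration <- function(pairs,
                               cfg = registration_config(base_channels = 32L),
                               iterations = 2000L, learning_rate = 1e-3,
                               weights = loss_weights(20, 1, 0),
                               weight_decay = 0, seed = 1L, verbose = FALSE) {
  if (!is.list(pairs) || length(pairs) == 0L) stop("pairs must be non-empty")
  pairs <- lapply(pairs, function(p) {
    list(moving = as_feature_map(image_values(p$moving)),
         fixed = as_feature_map(image_values(p$fixed)))
  })
  set.seed(seed)
  R <- build_registration(cfg)
  opt <- make_adam(learning_rate, 0.5, 0.999, weight_decay = weight_decay)
  eval_corr <- function() {
    mean(vapply(pairs, function(p) {
      field <- reg_forward(R, p$moving, p$fixed)
      mean(abs(p$fixed - cpp_warp_fwd(p$moving, field)))
    }, numeric(1)))
  }
  initial <- eval_corr()
  loss_history <- numeric(iterations)
  for (t in seq_len(iterations)) {
    p <- pairs[[(t - 1L) %% length(pairs) + 1L]]
    net_zero_grad(R)
    field <- reg_forward(R, p$moving, p$fixed)
    warped <- cpp_warp_fwd(p$moving, field)
    resid <- p$fixed - warped
    l_corr <- mean(abs(resid))
    g_warped <- -sign(resid) / length(resid) * weights$w_corr
    wb <- cpp_warp_bwd(p$moving, field, g_warped)
    gfield <- wb$gfield + weights$w_smooth * smoothness_grad(field)
    reg_backward(R, gfield)
    adam_step(opt, R)
    loss_history[t] <- l_corr
    if (!is.finite(l_corr))
      stop("registration fit diverged at iteration ", t)
    if (verbose && t %% 100L == 0L)
      message(sprintf("iter %d  corr %.5f", t, l_corr))
  }
  structure(list(net = R, loss_history = loss_history,
                 initial_loss = initial, final_loss = eval_corr(),
                 iterations = iterations),
            class = "registration_fit")
}

#' @export
print.registration_fit <- function(x, ...) {
  cat(sprintf(
    "<registration_fit> %d iterations, correction loss %.5f -> %.5f (%.1f%% reduction)\n",
    x$iterations, x$initial_loss, x$final_loss,
    100 * (1 - x$final_loss / x$initial_loss)))
  invisible(x)
}
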