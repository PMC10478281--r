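# The RegGAN loss system: correction (L1 after registration warp),
# displacement smoothness, and least-squares adversarial terms.

#' Loss weights
#'
#' The total objective is the weighted sum
#' `w_corr * L_corr + w_smooth * L_smooth + w_adv * L_adv`. The printed form
#' of the objective is the unweighted sum, so all weights default to 1; toy
#' training runs typically up-weight the correction term (see the methods
#' vignette).
#'
#' @param w_corr,w_smooth,w_adv non-negative weights; at least one must be
#'   positive
#' @return an object of class `"loss_weights"`
#' @export
loss_weights <- function(w_corr = 1, w_smooth = 1, w_adv = 1) {
  if (any(c(w_corr, w_smooth, w_adv) < 0))
    stop("configuration error: loss weights must be non-negative")
  if (w_corr + w_smooth + w_adv == 0)
    stop("configuration error: at least one loss weight must be positive")
  structure(list(w_corr = w_corr, w_smooth = w_smooth, w_adv = w_adv),
            class = "loss_weights")
}

#' Correction loss
#'
#' Mean absolute difference between the (possibly misaligned) label and the
#' generated image warped by the registration field:
#' `mean | noisy_label - warp(generated, field) |`. With a zero field this
#' reduces to the plain L1 loss.
#'
#' @param noisy_label,generated same-shape matrices or (H, W, 1) arrays
#' @param field an (H, W, 2) displacement array
#' @return a non-negative scalar
#' @export
correction_loss <- function(noisy_label, generated, field) {
  y <- image_values(noisy_label); g <- image_values(generated)
  if (!all(dim(y) == dim(g))) stop("shape mismatch between label and image")
  mean(abs(y - warp(g, field)))
}

#' Smoothness loss of a displacement field
#'
#' Penalizes the spatial gradient of the field: the sum over the two
#' displacement components and the two grid directions of the mean squared
#' forward difference. Constant fields score exactly 0, and a field whose
#' row component increases by one pixel per row scores exactly 1.
#'
#' @param field an (H, W, 2) displacement array
#' @return a non-negative scalar
#' @export
smoothness_loss <- function(field) {
  f <- unclass(field)
  if (any(!is.finite(f))) stop("field must be finite")
  H <- dim(f)[1]; W <- dim(f)[2]
  total <- 0
  for (c in 1:2) {
    dr <- f[-1, , c] - f[-H, , c]
    dc <- f[, -1, c] - f[, -W, c]
    total <- total + mean(dr * dr) + mean(dc * dc)
  }
  total
}

# gradient of smoothness_loss wrt the field (linear operator)
smoothness_grad <- function(field) {
  f <- unclass(field)
  H <- dim(f)[1]; W <- dim(f)[2]
  g <- array(0, dim(f))
  nr <- (H - 1) * W; nc <- H * (W - 1)
  for (c in 1:2) {
    dr <- f[-1, , c] - f[-H, , c]
    dc <- f[, -1, c] - f[, -W, c]
    gr <- matrix(0, H, W); gc <- matrix(0, H, W)
    gr[-H, ] <- gr[-H, ] - dr; gr[-1, ] <- gr[-1, ] + dr
    gc[, -W] <- gc[, -W] - dc; gc[, -1] <- gc[, -1] + dc
    g[, , c] <- 2 * gr / nr + 2 * gc / nc
  }
  g
}

#' Least-squares adversarial terms
#'
#' Real patches are labelled 1 and generated ("fake") patches 0. The
#' discriminator objective is
#' `d_term = mean((score_real - 1)^2)/2 + mean(score_fake^2)/2`; the
#' generator objective is `g_term = mean((score_fake - 1)^2)`.
#'
#' @param score_real,score_fake same-shape patch score maps
#' @return list with scalar elements `g_term` and `d_term`
#' @export
adversarial_terms <- function(score_real, score_fake) {
  if (!all(dim(score_real) == dim(score_fake)))
    stop("shape mismatch between score maps")
  list(g_term = mean((score_fake - 1)^2),
       d_term = 0.5 * mean((score_real - 1)^2) + 0.5 * mean(score_fake^2))
}

#' Total training loss for the generator/registration update
#'
#' `w_corr * corr + w_smooth * smooth + w_adv * adv_g`. The discriminator is
#' updated separately on its own term under the usual min–max contract.
#'
#' @param components named list or vector with elements `corr`, `smooth`,
#'   `adv_g`
#' @param weights a [loss_weights()]
#' @return scalar total loss
#' @export
total_loss <- function(components, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  comp <- as.list(components)
  if (is.null(names(comp)) || !all(c("corr", "smooth", "adv_g") %in% names(comp)))
    comp <- stats::setNames(comp[1:3], c("corr", "smooth", "adv_g"))
  vals <- unlist(comp[c("corr", "smooth", "adv_g")])
  if (any(!is.finite(vals))) stop("loss components must be finite")
  weights$w_corr * vals[["corr"]] + weights$w_smooth * vals[["smooth"]] +
    weights$w_adv * vals[["adv_g"]]
}
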