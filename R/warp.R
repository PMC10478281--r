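# Dense displacement fields and the differentiable resampling operator.

#' Dense displacement field
#'
#' An (H, W, 2) array of per-pixel displacements in pixel units; `[, , 1]`
#' is the row offset and `[, , 2]` the column offset. Applying a field to an
#' image with [warp()] samples the image at `p + field(p)`.
#'
#' @param values an (H, W, 2) numeric array
#' @return an object of class `"deformation_field"`
#' @export
deformation_field <- function(values) {
  if (!(is.array(values) && length(dim(values)) == 3L && dim(values)[3] == 2L))
    stop("a deformation field must be an (H, W, 2) array")
  if (any(!is.finite(values))) stop("displacements must be finite")
  structure(values, class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  mag <- sqrt(unclass(x)[, , 1]^2 + unclass(x)[, , 2]^2)
  cat(sprintf("<deformation_field> %d x %d, |u| max %.3f px, mean %.3f px\n",
              dim(x)[1], dim(x)[2], max(mag), mean(mag)))
  invisible(x)
}

zero_field <- function(shape) {
  deformation_field(array(0, c(shape[1], shape[2], 2L)))
}

field_magnitude <- function(field) {
  f <- unclass(field)
  sqrt(f[, , 1]^2 + f[, , 2]^2)
}

#' Warp an image by a displacement field
#'
#' Bilinear resampling: the output at pixel `p` is the input interpolated at
#' `p + field(p)`. Out-of-bounds sample positions are clamped to the image
#' border. The operation is differentiable in both arguments (used internally
#' for training); a zero field is the identity and warping is linear in the
#' image argument.
#'
#' @param image an [hu_image()], matrix, or (H, W, C) array
#' @param field an (H, W, 2) displacement array matching the image grid
#' @return the warped image, same type as the input
#' @export
warp <- function(image, field) {
  v <- if (inherits(image, c("hu_image", "normalized_image")))
    image_values(image) else image
  f <- unclass(field)
  if (!(is.array(f) && length(dim(f)) == 3L && dim(f)[3] == 2L))
    stop("field must be an (H, W, 2) array")
  ism <- is.matrix(v)
  arr <- if (ism) array(v, c(dim(v), 1L)) else v
  if (!all(dim(arr)[1:2] == dim(f)[1:2]))
    stop("image and field must share the same spatial shape")
  out <- cpp_warp_fwd(arr, f)
  res <- if (ism) out[, , 1L] else out
  if (inherits(image, c("hu_image", "normalized_image")))
    image_like(res, image) else res
}

#' Random smooth deformation field
#'
#' Gaussian-smoothed white noise rescaled so the largest displacement
#' magnitude equals `amplitude` (pixels). Used by the phantom simulator to
#' emulate anatomy change between the planning CT and a later CBCT.
#'
#' @param shape length-2 grid dimensions (rows, cols)
#' @param amplitude maximum displacement magnitude in pixels (>= 0)
#' @param smoothness standard deviation of the Gaussian smoothing kernel in
#'   pixels (> 0); larger values give smoother, more global deformations
#' @param seed integer seed; the field is a pure function of its arguments
#' @return an (H, W, 2) [deformation_field()]
#' @export
random_deformation <- function(shape, amplitude, smoothness, seed) {
  if (!is.numeric(smoothness) || smoothness <= 0)
    stop("configuration error: smoothness must be positive")
  if (!is.numeric(amplitude) || amplitude < 0)
    stop("configuration error: amplitude must be non-negative")
  H <- as.integer(shape[1]); W <- as.integer(shape[2])
  if (amplitude == 0) return(zero_field(c(H, W)))
  f <- with_seed(seed, {
    noise <- array(stats::rnorm(H * W * 2L), c(H, W, 2L))
    noise
  })
  f[, , 1] <- gaussian_smooth(f[, , 1], smoothness)
  f[, , 2] <- gaussian_smooth(f[, , 2], smoothness)
  mag <- sqrt(f[, , 1]^2 + f[, , 2]^2)
  mx <- max(mag)
  if (mx > 0) f <- f * (amplitude / mx)
  deformation_field(f)
}

# separable Gaussian smoothing with replicate edge handling
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  n <- nrow(m); p <- ncol(m)
  ridx <- pmin(pmax(outer(seq_len(n), seq(-r, r), `+`), 1L), n)
  sm <- matrix(0, n, p)
  for (t in seq_along(k)) sm <- sm + k[t] * m[ridx[, t], , drop = FALSE]
  cidx <- pmin(pmax(outer(seq_len(p), seq(-r, r), `+`), 1L), p)
  out <- matrix(0, n, p)
  for (t in seq_along(k)) out <- out + k[t] * sm[, cidx[, t], drop = FALSE]
  out
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
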