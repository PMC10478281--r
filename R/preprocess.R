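# Intensity windowing, [-1, 1] normalization and grid resampling.
#
# The training pipeline clips HU to [-1000, 2000] (so very dense bone does
# not dominate), maps the window affinely onto [-1, 1], and resamples slices
# onto a square training grid. All metrics are computed on clipped HU after
# the exact inverse mapping.

#' Normalized image
#'
#' A 2-D image with values in \[-1, 1\] together with the HU window used to
#' produce it, so the mapping is always invertible.
#'
#' @param values numeric matrix in \[-1, 1\]
#' @param window length-2 HU window (lo, hi) used for normalization
#' @return an object of class `"normalized_image"`
#' @export
normalized_image <- function(values, window = c(-1000, 2000)) {
  if (!is.matrix(values)) stop("values must be a matrix")
  if (window[1] >= window[2]) stop("configuration error: window lo must be < hi")
  if (min(values) < -1 - 1e-9 || max(values) > 1 + 1e-9)
    stop("normalized values must lie in [-1, 1]")
  structure(list(values = values, window = as.numeric(window)),
            class = "normalized_image")
}

#' @export
print.normalized_image <- function(x, ...) {
  cat(sprintf("<normalized_image> %d x %d, window [%g, %g] HU\n",
              nrow(x$values), ncol(x$values), x$window[1], x$window[2]))
  invisible(x)
}

#' Clip HU values to a window
#'
#' @param image an [hu_image()] or matrix
#' @param lo,hi window bounds in HU (defaults -1000 and 2000)
#' @return same type as the input, with every value clamped into \[lo, hi\]
#' @export
clip_hu <- function(image, lo = -1000, hi = 2000) {
  if (lo >= hi) stop("configuration error: lo must be < hi")
  v <- image_values(image)
  image_like(pmin(pmax(v, lo), hi), image)
}

#' Normalize a clipped HU image to \[-1, 1\]
#'
#' Affine map `v -> 2 (v - lo) / (hi - lo) - 1`. The image must already be
#' clipped to the window.
#'
#' @param image an [hu_image()] or matrix with values inside `window`
#' @param window length-2 HU window (lo, hi)
#' @return a [normalized_image()]
#' @export
normalize_hu <- function(image, window = c(-1000, 2000)) {
  lo <- window[1]; hi <- window[2]
  if (lo >= hi) stop("configuration error: window lo must be < hi")
  v <- image_values(image)
  tol <- 1e-9 * (hi - lo)  # bilinear interpolation can overshoot by rounding
  if (min(v) < lo - tol || max(v) > hi + tol)
    stop("values outside the window [", lo, ", ", hi,
         "]: clip with clip_hu() first")
  v <- pmin(pmax(v, lo), hi)
  normalized_image(2 * (v - lo) / (hi - lo) - 1, window)
}

#' Map a normalized image back to HU
#'
#' Exact affine inverse of [normalize_hu()]; a normalize/denormalize round
#' trip reproduces a clipped image to within 1e-6 HU.
#'
#' @param image a [normalized_image()], or a matrix in \[-1, 1\] with
#'   `window` supplied
#' @param window HU window; taken from the object when available
#' @return an [hu_image()]
#' @export
denormalize_hu <- function(image, window = NULL) {
  if (inherits(image, "normalized_image")) {
    window <- image$window
    v <- image$values
  } else {
    if (is.null(window)) stop("window required for plain matrices")
    v <- image_values(image)
  }
  if (min(v) < -1 - 1e-9 || max(v) > 1 + 1e-9)
    stop("values outside [-1, 1]")
  hu_image((v + 1) / 2 * (window[2] - window[1]) + window[1])
}

#' Bilinearly resample an image onto a square grid
#'
#' Pixel-center convention: target pixel `t` samples the source at
#' `(t + 0.5) * n / size - 0.5`, clamped to the border; spacing is rescaled
#' so the physical extent is preserved. Constant images are preserved
#' exactly, and resampling to the native size is the identity.
#'
#' @param image an [hu_image()] or matrix
#' @param size target side length in pixels (>= 8)
#' @return same type as the input on a `size x size` grid
#' @export
resample_to <- function(image, size) {
  size <- as.integer(size)
  if (is.na(size) || size < 8L)
    stop("configuration error: size must be an integer >= 8")
  v <- image_values(image)
  n <- nrow(v); p <- ncol(v)
  out <- bilinear_resize(v, size, size)
  if (inherits(image, "hu_image")) {
    hu_image(out, image$spacing * c(n, p) / size)
  } else if (inherits(image, "normalized_image")) {
    normalized_image(pmin(pmax(out, -1), 1), image$window)
  } else out
}

bilinear_resize <- function(v, nh, nw) {
  n <- nrow(v); p <- ncol(v)
  if (nh == n && nw == p) return(v)
  si <- pmin(pmax((seq_len(nh) - 0.5) * n / nh - 0.5, 0), n - 1)
  sj <- pmin(pmax((seq_len(nw) - 0.5) * p / nw - 0.5, 0), p - 1)
  i0 <- pmin(floor(si), n - 2); i0 <- pmax(i0, 0)
  j0 <- pmin(floor(sj), p - 2); j0 <- pmax(j0, 0)
  wi <- si - i0; wj <- sj - j0
  if (n == 1L) { i0 <- rep(0, nh); wi <- rep(0, nh) }
  if (p == 1L) { j0 <- rep(0, nw); wj <- rep(0, nw) }
  i1 <- pmin(i0 + 1, n - 1)
  j1 <- pmin(j0 + 1, p - 1)
  A <- v[i0 + 1, j0 + 1, drop = FALSE]; B <- v[i1 + 1, j0 + 1, drop = FALSE]
  C <- v[i0 + 1, j1 + 1, drop = FALSE]; D <- v[i1 + 1, j1 + 1, drop = FALSE]
  Wi <- matrix(wi, nh, nw); Wj <- matrix(wj, nh, nw, byrow = TRUE)
  (1 - Wi) * (1 - Wj) * A + Wi * (1 - Wj) * B + (1 - Wi) * Wj * C + Wi * Wj * D
}
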