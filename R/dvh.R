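# Dose-volume-histogram statistics for planning target volumes: cumulative
# DVH curves, D_p order statistics, dose-difference rates and pass rates.

#' Cumulative dose-volume histogram
#'
#' Fraction of the masked volume receiving at least each dose level, on a
#' uniform grid of `bins` levels from 0 to the masked maximum. The curve is
#' monotone non-increasing, starts at 1 at dose 0 and reaches 0 beyond the
#' maximum dose.
#'
#' @param dose non-negative dose matrix/array in Gy
#' @param mask logical (or 0/1) grid of the same shape; must select at
#'   least one voxel
#' @param bins number of dose levels (default 1000)
#' @return an object of class `"dvh_curve"`: list with `dose` (levels in
#'   Gy) and `volume` (fractional volume >= level)
#' @export
cumulative_dvh <- function(dose, mask, bins = 1000L) {
  d <- image_values(dose)
  if (any(d < 0) || any(!is.finite(d))) stop("dose must be non-negative and finite")
  m <- as.logical(mask)
  if (!all(dim(dose) == dim(mask))) stop("dose and mask shapes differ")
  v <- d[m]
  if (length(v) == 0L) stop("empty mask")
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("configuration error: bins must be >= 2")
  dmax <- max(v)
  levels <- seq(0, dmax, length.out = bins + 1L)
  vol <- vapply(levels, function(l) mean(v >= l), numeric(1))
  structure(list(dose = levels, volume = vol, n_voxels = length(v)),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> %d voxels, dose range [0, %.2f] Gy, %d levels\n",
              x$n_voxels, max(x$dose), length(x$dose)))
  invisible(x)
}

#' @export
plot.dvh_curve <- function(x, ...) {
  graphics::plot(x$dose, 100 * x$volume, type = "l", lwd = 2,
                 xlab = "Dose (Gy)", ylab = "Volume (%)",
                 main = "Cumulative DVH", ...)
  invisible(x)
}

#' Dose received by at least p% of the volume
#'
#' The largest dose level `d` such that at least `p` percent of the masked
#' volume receives `>= d`, with linear interpolation between the curve's
#' dose levels. `p = 100` is rejected (use the masked minimum instead).
#'
#' @param curve a [cumulative_dvh()] result
#' @param p percent volume, strictly between 0 and 100
#' @return dose in Gy
#' @export
dose_at_volume <- function(curve, p) {
  stopifnot(inherits(curve, "dvh_curve"))
  if (!is.numeric(p) || p <= 0 || p >= 100)
    stop("p must be strictly between 0 and 100")
  target <- p / 100
  v <- curve$volume; d <- curve$dose
  idx <- which(v >= target)
  if (length(idx) == 0L) return(d[1])
  i <- max(idx)
  if (i == length(v)) return(d[i])
  # interpolate within the bin where the curve crosses the target
  if (v[i + 1L] < v[i])
    d[i] + (v[i] - target) / (v[i] - v[i + 1L]) * (d[i + 1L] - d[i])
  else d[i]
}

#' PTV dose statistics
#'
#' Dmin/Dmax/Dmean directly from the masked voxels; D2/D50/D95/D98 from the
#' cumulative DVH via [dose_at_volume()]. The ordering invariant
#' `dmin <= d98 <= d95 <= d50 <= d2 <= dmax` is enforced.
#'
#' @param dose dose grid in Gy
#' @param mask PTV mask (same shape, at least one voxel)
#' @param bins DVH resolution (default 1000)
#' @return an object of class `"dvh_metrics"`: named list with `dmin`,
#'   `dmax`, `dmean`, `d2`, `d50`, `d95`, `d98` in Gy
#' @export
dvh_metrics <- function(dose, mask, bins = 1000L) {
  d <- image_values(dose)
  m <- as.logical(mask)
  v <- d[m]
  if (length(v) == 0L) stop("empty mask")
  curve <- cumulative_dvh(dose, mask, bins)
  # D_p interpolation can undershoot the voxel extremes by up to one bin
  # width; clamp into the attained dose range
  dp <- function(p) min(max(dose_at_volume(curve, p), min(v)), max(v))
  out <- list(dmin = min(v), dmax = max(v), dmean = mean(v),
              d2 = dp(2), d50 = dp(50), d95 = dp(95), d98 = dp(98))
  ord <- c(out$dmin, out$d98, out$d95, out$d50, out$d2, out$dmax)
  if (any(diff(ord) < -1e-9))
    stop("internal error: DVH ordering invariant violated")
  structure(out, class = "dvh_metrics")
}

#' @export
print.dvh_metrics <- function(x, ...) {
  cat(sprintf(
    "<dvh_metrics> Dmin %.2f  D98 %.2f  D95 %.2f  D50 %.2f  D2 %.2f  Dmax %.2f  Dmean %.2f (Gy)\n",
    x$dmin, x$d98, x$d95, x$d50, x$d2, x$dmax, x$dmean))
  invisible(x)
}

#' Dose difference rate
#'
#' Signed relative difference `(d_sct - d_pct) / d_pct` between a dose
#' metric computed on the synthetic-CT plan and on the planning-CT plan.
#' Undefined (NA with a warning) when the reference dose is not positive.
#'
#' @param d_sct,d_pct dose values in Gy
#' @return signed fraction (multiply by 100 for percent)
#' @export
difference_rate <- function(d_sct, d_pct) {
  if (!is.numeric(d_sct) || !is.numeric(d_pct)) stop("doses must be numeric")
  out <- (d_sct - d_pct) / d_pct
  bad <- d_pct <= 0
  if (any(bad)) {
    warning("difference rate undefined for non-positive reference dose")
    out[bad] <- NA_real_
  }
  out
}

#' Fraction of cases within a dose-difference tolerance
#'
#' @param dr_values collection of signed difference rates (fractions)
#' @param threshold positive tolerance on |Dr| (fraction, e.g. 0.01 for 1%)
#' @return fraction of cases with `|Dr| <= threshold`
#' @export
pass_rate <- function(dr_values, threshold) {
  dr_values <- dr_values[!is.na(dr_values)]
  if (length(dr_values) == 0L) stop("empty input")
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive")
  mean(abs(dr_values) <= threshold)
}

#' Per-metric difference report between two DVH metric sets
#'
#' @param m_sct,m_pct [dvh_metrics()] objects from the sCT and pCT plans
#' @return named numeric vector of signed difference rates (fractions) for
#'   the seven PTV metrics
#' @export
dvh_difference <- function(m_sct, m_pct) {
  stopifnot(inherits(m_sct, "dvh_metrics"), inherits(m_pct, "dvh_metrics"))
  keys <- c("dmin", "dmax", "dmean", "d2", "d50", "d95", "d98")
  vapply(keys, function(k) difference_rate(m_sct[[k]], m_pct[[k]]),
         numeric(1))
}
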