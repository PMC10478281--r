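# Image-quality metrics (MAE, MSE, PSNR, SSIM), restricted-range HU
# histograms, dataset-level evaluation against the planning CT "gold
# standard", and nonparametric group comparison across accelerators.

check_same_shape <- function(a, b) {
  if (!all(dim(a) == dim(b)))
    stop("shape mismatch: ", paste(dim(a), collapse = "x"), " vs ",
         paste(dim(b), collapse = "x"))
}

#' Mean absolute error between two images
#' @param a,b same-shape images ([hu_image()] or matrix)
#' @return scalar MAE in HU
#' @export
mae <- function(a, b) {
  va <- image_values(a); vb <- image_values(b)
  check_same_shape(va, vb)
  mean(abs(va - vb))
}

#' Mean squared error between two images
#' @param a,b same-shape images
#' @return scalar MSE in HU^2
#' @export
mse <- function(a, b) {
  va <- image_values(a); vb <- image_values(b)
  check_same_shape(va, vb)
  mean((va - vb)^2)
}

#' Peak signal-to-noise ratio
#'
#' `10 log10(peak^2 / MSE)` in dB. By default `peak` is the maximum pixel
#' value of the reference image `b`; a fixed window span (e.g. 3000 for the
#' \[-1000, 2000\] HU window) can be supplied instead for comparability
#' across cases. Identical images yield `Inf` (flagged, not an error).
#'
#' @param a test image
#' @param b reference image
#' @param peak positive scalar, or `"auto"` for `max(b)`
#' @return scalar PSNR in dB (possibly `Inf`)
#' @export
psnr <- function(a, b, peak = "auto") {
  m <- mse(a, b)
  if (identical(peak, "auto")) peak <- max(image_values(b))
  if (!is.numeric(peak) || peak <= 0)
    stop("peak must be a positive number or \"auto\"")
  if (m == 0) return(Inf)
  10 * log10(peak^2 / m)
}

#' Structural similarity index
#'
#' Global-statistics SSIM: means, variances and the cross-covariance are
#' taken over the whole image,
#' `SSIM = (2 mu_a mu_b + c1)(2 cov_ab + c2) /
#'        ((mu_a^2 + mu_b^2 + c1)(var_a + var_b + c2))`,
#' with `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` and `L` the intensity window
#' span (default 3000 HU). `method = "windowed"` instead mean-pools local
#' SSIM over an 11x11 Gaussian window (sigma 1.5), the convention used by
#' most image-quality toolboxes.
#'
#' @param a,b same-shape images
#' @param L dynamic range used for the stabilizing constants
#' @param method `"global"` (default) or `"windowed"`
#' @return scalar in \[-1, 1\]
#' @export
ssim <- function(a, b, L = 3000, method = c("global", "windowed")) {
  method <- match.arg(method)
  va <- image_values(a); vb <- image_values(b)
  check_same_shape(va, vb)
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- length(va)
  if (method == "global") {
    mu_a <- mean(va); mu_b <- mean(vb)
    var_a <- mean((va - mu_a)^2); var_b <- mean((vb - mu_b)^2)
    cov_ab <- mean((va - mu_a) * (vb - mu_b))
    ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
  } else {
    sm <- function(m) gaussian_smooth(m, 1.5)
    mu_a <- sm(va); mu_b <- sm(vb)
    var_a <- sm(va * va) - mu_a^2
    var_b <- sm(vb * vb) - mu_b^2
    cov_ab <- sm(va * vb) - mu_a * mu_b
    s <- ((2 * mu_a * mu_b + c1) * (2 * cov_ab + c2)) /
      ((mu_a^2 + mu_b^2 + c1) * (var_a + var_b + c2))
    mean(s)
  }
}

#' Restricted-range HU histogram
#'
#' Voxels outside `[lo, hi]` are discarded before binning (the bulk air
#' background at -1000 HU would otherwise dominate), and counts are
#' normalized over the included voxels.
#'
#' @param image an [hu_image()] or matrix
#' @param lo,hi inclusion range in HU (defaults -500, 500)
#' @param bins number of bins (>= 2)
#' @return an object of class `"hu_histogram"`: list with `breaks`, `mids`,
#'   `density` (summing to 1) and `n_included`; if no voxel falls in range,
#'   `empty = TRUE` and the densities are all zero
#' @export
hu_histogram <- function(image, lo = -500, hi = 500, bins = 100L) {
  bins <- as.integer(bins)
  if (is.na(bins) || bins < 2L) stop("configuration error: bins must be >= 2")
  v <- image_values(image)
  v <- v[v >= lo & v <= hi]
  breaks <- seq(lo, hi, length.out = bins + 1L)
  if (length(v) == 0L) {
    return(structure(list(breaks = breaks,
                          mids = (breaks[-1] + breaks[-(bins + 1L)]) / 2,
                          density = rep(0, bins), n_included = 0L,
                          empty = TRUE),
                     class = "hu_histogram"))
  }
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  structure(list(breaks = breaks, mids = h$mids,
                 density = h$counts / length(v), n_included = length(v),
                 empty = FALSE),
            class = "hu_histogram")
}

#' @export
print.hu_histogram <- function(x, ...) {
  if (x$empty) cat("<hu_histogram> empty (no voxels in range)\n")
  else cat(sprintf("<hu_histogram> %d voxels in [%g, %g], peak bin at %g HU\n",
                   x$n_included, min(x$breaks), max(x$breaks),
                   x$mids[which.max(x$density)]))
  invisible(x)
}

#' Evaluate a translation model over a paired dataset
#'
#' For every sample, computes MAE/MSE/PSNR/SSIM in HU space for both
#' CBCT-vs-pCT and sCT-vs-pCT (the planning CT is the gold standard), and
#' aggregates mean +/- sd per profile group.
#'
#' @param samples list of [paired_sample()] objects
#' @param model a fitted [reggan()] model, the string `"identity"` (sCT :=
#'   CBCT), or a function mapping an [hu_image()] CBCT to an sCT
#' @param window HU window; metrics are computed on clipped HU
#' @param ssim_method passed to [ssim()]
#' @return an object of class `"metrics_report"`: list with `per_case` (one
#'   row per sample per comparison) and `aggregate` (mean and sd by profile
#'   group and comparison)
#' @export
evaluate_dataset <- function(samples, model = "identity",
                             window = c(-1000, 2000),
                             ssim_method = "global") {
  if (!is.list(samples) || length(samples) == 0L)
    stop("samples must be a non-empty list")
  translate_fn <-
    if (inherits(model, "reggan")) function(img) predict(model, img)
    else if (identical(model, "identity")) function(img) img
    else if (is.function(model)) model
    else stop("model must be a reggan fit, \"identity\", or a function")
  span <- window[2] - window[1]
  rows <- vector("list", 2L * length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    pct <- clip_hu(s$pct, window[1], window[2])
    cbct <- clip_hu(s$cbct, window[1], window[2])
    sct <- clip_hu(translate_fn(s$cbct), window[1], window[2])
    for (cmp in c("cbct_vs_pct", "sct_vs_pct")) {
      img <- if (cmp == "cbct_vs_pct") cbct else sct
      rows[[2L * (i - 1L) + (cmp == "sct_vs_pct") + 1L]] <- data.frame(
        case = i, profile = s$profile_name, comparison = cmp,
        mae = mae(img, pct), mse = mse(img, pct),
        psnr = psnr(img, pct, peak = span),
        ssim = ssim(img, pct, L = span, method = ssim_method),
        stringsAsFactors = FALSE)
    }
  }
  per_case <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(
    split(per_case, list(per_case$profile, per_case$comparison), drop = TRUE),
    function(d) data.frame(
      profile = d$profile[1], comparison = d$comparison[1], n = nrow(d),
      mae_mean = mean(d$mae), mae_sd = stats::sd(d$mae),
      psnr_mean = mean(d$psnr[is.finite(d$psnr)]),
      psnr_sd = stats::sd(d$psnr[is.finite(d$psnr)]),
      ssim_mean = mean(d$ssim), ssim_sd = stats::sd(d$ssim),
      stringsAsFactors = FALSE)))
  rownames(agg) <- NULL
  agg <- agg[order(agg$profile, agg$comparison), ]
  structure(list(per_case = per_case, aggregate = agg),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Image-quality report (pCT as gold standard)\n")
  a <- x$aggregate
  for (i in seq_len(nrow(a))) {
    cat(sprintf("  %-10s %-12s MAE %6.2f +/- %5.2f  PSNR %5.2f +/- %4.2f  SSIM %.3f +/- %.3f\n",
                a$profile[i], a$comparison[i], a$mae_mean[i], a$mae_sd[i],
                a$psnr_mean[i], a$psnr_sd[i], a$ssim_mean[i], a$ssim_sd[i]))
  }
  invisible(x)
}

#' Nonparametric comparison of a metric across profile groups
#'
#' Kruskal-Wallis test of a per-case metric across the profile groups, with
#' pairwise Wilcoxon comparisons under Holm correction. A thin wrapper over
#' the standard routines.
#'
#' @param report a `"metrics_report"` from [evaluate_dataset()], or its
#'   `per_case` data frame
#' @param metric one of `"mae"`, `"mse"`, `"psnr"`, `"ssim"`
#' @param comparison which comparison rows to test (default `"sct_vs_pct"`)
#' @return list with the `kruskal` htest object, the `pairwise` corrected
#'   comparison, and `p_value`
#' @export
compare_groups <- function(report, metric = "mae",
                           comparison = "sct_vs_pct") {
  d <- if (inherits(report, "metrics_report")) report$per_case else report
  if (!is.null(d$comparison)) d <- d[d$comparison == comparison, ]
  if (!metric %in% names(d)) stop("unknown metric: ", metric)
  groups <- factor(d$profile)
  if (nlevels(groups) < 2L)
    stop("at least two profile groups are required")
  if (any(table(groups) < 3L))
    stop("each group needs at least 3 cases")
  x <- d[[metric]]
  kw <- stats::kruskal.test(x, groups)
  pw <- stats::pairwise.wilcox.test(x, groups, p.adjust.method = "holm",
                                    exact = FALSE)
  list(kruskal = kw, pairwise = pw, p_value = kw$p.value)
}
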