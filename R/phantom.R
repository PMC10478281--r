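# Multi-accelerator head-and-neck phantom simulator.
#
# Generates paired planning-CT-like / CBCT-like slices with a known
# ground-truth deformation, so the registration-corrected training scheme
# can be exercised and validated end to end without patient data. The CBCT
# degradation is parameterized per accelerator: a global HU shift, a
# low-frequency radial "cupping" bias (the canonical cone-beam scatter
# artifact shape), additive noise, blur, and a random smooth deformation
# standing in for anatomy change between acquisition times.

#' Phantom geometry specification
#'
#' Describes a head-and-neck-like 2-D slice: background air at -1000 HU, an
#' elliptical soft-tissue head, an enclosing bone ring (skull), and
#' optionally a number of interior air cavities (sinuses/airways).
#'
#' @param grid_size pixels per side (>= 32)
#' @param tissue_hu soft-tissue HU (default 40)
#' @param bone_hu skull ring HU (default 700, must be <= 2000)
#' @param air_hu cavity HU (default -1000, must be >= -1000)
#' @param shape_jitter fractional random perturbation of the geometry
#'   (0 disables all geometric randomness)
#' @param n_air_cavities number of interior air cavities (>= 0)
#' @return an object of class `"phantom_spec"`
#' @export
phantom_spec <- function(grid_size = 256L, tissue_hu = 40, bone_hu = 700,
                         air_hu = -1000, shape_jitter = 0.05,
                         n_air_cavities = 3L) {
  grid_size <- as.integer(grid_size)
  if (is.na(grid_size) || grid_size < 32L)
    stop("configuration error: grid_size must be >= 32")
  if (air_hu < -1000) stop("configuration error: air_hu must be >= -1000")
  if (bone_hu > 2000) stop("configuration error: bone_hu must be <= 2000")
  if (shape_jitter < 0) stop("configuration error: shape_jitter must be >= 0")
  n_air_cavities <- as.integer(n_air_cavities)
  if (is.na(n_air_cavities) || n_air_cavities < 0L)
    stop("configuration error: n_air_cavities must be >= 0")
  structure(list(grid_size = grid_size, tissue_hu = tissue_hu,
                 bone_hu = bone_hu, air_hu = air_hu,
                 shape_jitter = shape_jitter,
                 n_air_cavities = n_air_cavities),
            class = "phantom_spec")
}

#' CBCT degradation profile
#'
#' Named degradation settings emulating how CBCT acquisition differs across
#' linear accelerators. The built-in profiles are qualitative: "synergy" is
#' parameterized to produce by far the largest CBCT/pCT discrepancy (its HU
#' shift moves the soft-tissue peak from about 70 towards about -220),
#' while the three Varian-style profiles differ moderately.
#'
#' @param name one of `"halcyon"`, `"trilogy"`, `"vitalbeam"`, `"synergy"`,
#'   or `"custom"`
#' @param hu_shift global additive HU offset
#' @param cupping_amplitude HU amplitude of the radial `(r/r_max)^2` bias
#' @param noise_sd standard deviation of additive HU noise (>= 0)
#' @param blur_sigma Gaussian blur in pixels (>= 0)
#' @param deform_amplitude maximum displacement of the random anatomy-change
#'   deformation, in pixels (>= 0)
#' @param deform_smoothness Gaussian scale of the deformation in pixels (> 0)
#' @return an object of class `"degradation_profile"`
#' @export
degradation_profile <- function(name = "custom", hu_shift = 0,
                                cupping_amplitude = 0, noise_sd = 0,
                                blur_sigma = 0, deform_amplitude = 0,
                                deform_smoothness = 8) {
  defaults <- list(
    halcyon   = list(hu_shift = -25, cupping_amplitude = 30, noise_sd = 20,
                     blur_sigma = 0.8, deform_amplitude = 3),
    trilogy   = list(hu_shift = -45, cupping_amplitude = 35, noise_sd = 25,
                     blur_sigma = 1.0, deform_amplitude = 3),
    vitalbeam = list(hu_shift = -35, cupping_amplitude = 30, noise_sd = 20,
                     blur_sigma = 0.9, deform_amplitude = 3),
    synergy   = list(hu_shift = -250, cupping_amplitude = 60, noise_sd = 35,
                     blur_sigma = 1.2, deform_amplitude = 3))
  if (name %in% names(defaults) &&
      missing(hu_shift) && missing(cupping_amplitude) && missing(noise_sd) &&
      missing(blur_sigma) && missing(deform_amplitude)) {
    d <- defaults[[name]]
    hu_shift <- d$hu_shift; cupping_amplitude <- d$cupping_amplitude
    noise_sd <- d$noise_sd; blur_sigma <- d$blur_sigma
    deform_amplitude <- d$deform_amplitude
  } else if (!name %in% c(names(defaults), "custom")) {
    stop("configuration error: unknown profile name '", name, "'")
  }
  vals <- c(hu_shift, cupping_amplitude, noise_sd, blur_sigma,
            deform_amplitude, deform_smoothness)
  if (any(!is.finite(vals)))
    stop("configuration error: profile fields must be finite")
  if (noise_sd < 0) stop("configuration error: noise_sd must be >= 0")
  if (deform_amplitude < 0)
    stop("configuration error: deform_amplitude must be >= 0")
  if (deform_smoothness <= 0)
    stop("configuration error: deform_smoothness must be > 0")
  if (blur_sigma < 0) stop("configuration error: blur_sigma must be >= 0")
  structure(list(name = name, hu_shift = hu_shift,
                 cupping_amplitude = cupping_amplitude, noise_sd = noise_sd,
                 blur_sigma = blur_sigma, deform_amplitude = deform_amplitude,
                 deform_smoothness = deform_smoothness),
            class = "degradation_profile")
}

#' Built-in accelerator profile names
#' @return character vector of the four named profiles
#' @export
profile_names <- function() c("halcyon", "trilogy", "vitalbeam", "synergy")

# ellipse interior mask on the unit square grid
ellipse_mask <- function(n, cx, cy, rx, ry, theta = 0) {
  u <- (seq_len(n) - (n + 1) / 2) / (n / 2)
  X <- matrix(u, n, n); Y <- matrix(u, n, n, byrow = TRUE)
  Xr <- (X - cx) * cos(theta) + (Y - cy) * sin(theta)
  Yr <- -(X - cx) * sin(theta) + (Y - cy) * cos(theta)
  (Xr / rx)^2 + (Yr / ry)^2 <= 1
}

#' Generate a head-and-neck-like phantom slice
#'
#' Deterministic given `(spec, seed)`. With `shape_jitter = 0` and no air
#' cavities the image contains exactly the three values
#' `{-1000, tissue_hu, bone_hu}`.
#'
#' @param spec a [phantom_spec()]
#' @param seed integer seed for the geometric jitter and cavity placement
#' @return an [hu_image()] with values in \[-1000, 2000\]
#' @export
generate_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid_size
  with_seed(seed, {
    j <- function(scale) if (spec$shape_jitter > 0)
      stats::rnorm(1, 0, spec$shape_jitter * scale) else 0
    cx <- j(0.2); cy <- j(0.2)
    rx <- 0.62 * (1 + j(1)); ry <- 0.74 * (1 + j(1))
    rx <- min(max(rx, 0.3), 0.92); ry <- min(max(ry, 0.3), 0.92)
    thick <- 0.1 * (1 + j(0.5))
    outer_m <- ellipse_mask(n, cx, cy, rx, ry)
    inner_m <- ellipse_mask(n, cx, cy, max(rx - thick, 0.1),
                            max(ry - thick, 0.1))
    img <- matrix(-1000, n, n)
    img[outer_m] <- spec$bone_hu
    img[inner_m] <- spec$tissue_hu
    if (spec$n_air_cavities > 0L) {
      for (k in seq_len(spec$n_air_cavities)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- stats::runif(1, 0, 0.45)
        ccx <- cx + rad * cos(ang) * rx
        ccy <- cy + rad * sin(ang) * ry
        crx <- stats::runif(1, 0.03, 0.1)
        cry <- stats::runif(1, 0.03, 0.1)
        cav <- ellipse_mask(n, ccx, ccy, crx, cry, stats::runif(1, 0, pi))
        img[cav & inner_m] <- spec$air_hu
      }
    }
    hu_image(pmin(pmax(img, -1000), 2000))
  })
}

#' Degrade a planning-CT-like slice into a CBCT-like slice
#'
#' Applies, in order: a random smooth deformation (anatomy change between
#' acquisition times), Gaussian blur, the global HU shift, the radial
#' cupping bias `cupping_amplitude * (r/r_max)^2`, additive Gaussian noise,
#' and a final clip to \[-1000, 2000\]. A profile with all parameters zero
#' returns the input unchanged. Deterministic given `(pct, profile, seed)`.
#'
#' @param pct an [hu_image()] (values within \[-1000, 2000\])
#' @param profile a [degradation_profile()]
#' @param seed integer seed
#' @return a list with elements `cbct` ([hu_image()]) and `field` (the
#'   [deformation_field()] that was applied)
#' @export
degrade_to_cbct <- function(pct, profile, seed = 1L) {
  stopifnot(inherits(profile, "degradation_profile"))
  v <- image_values(pct)
  if (min(v) < -1000 || max(v) > 2000)
    stop("pct values must lie within [-1000, 2000]; clip first")
  n <- nrow(v); p <- ncol(v)
  field <- if (profile$deform_amplitude > 0)
    random_deformation(c(n, p), profile$deform_amplitude,
                       profile$deform_smoothness, seed)
  else zero_field(c(n, p))
  out <- if (profile$deform_amplitude > 0) warp(v, field) else v
  if (profile$blur_sigma > 0) out <- gaussian_smooth(out, profile$blur_sigma)
  if (profile$hu_shift != 0) out <- out + profile$hu_shift
  if (profile$cupping_amplitude != 0) {
    u <- (seq_len(n) - (n + 1) / 2) / (n / 2)
    w <- (seq_len(p) - (p + 1) / 2) / (p / 2)
    r2 <- outer(u^2, w^2, `+`) / 2  # (r/r_max)^2, r_max at the grid corner scale
    out <- out + profile$cupping_amplitude * r2
  }
  if (profile$noise_sd > 0) {
    out <- out + with_seed(seed + 1L,
      matrix(stats::rnorm(n * p, 0, profile$noise_sd), n, p))
  }
  changed <- profile$deform_amplitude > 0 || profile$blur_sigma > 0 ||
    profile$hu_shift != 0 || profile$cupping_amplitude != 0 ||
    profile$noise_sd > 0
  if (changed) out <- pmin(pmax(out, -1000), 2000)
  list(cbct = image_like(out, pct), field = field)
}

#' Paired training/evaluation sample
#'
#' @param pct,cbct [hu_image()] pair on the same grid
#' @param true_field the [deformation_field()] used to build `cbct`
#' @param profile_name degradation profile identifier
#' @param seed the per-sample seed it was generated from
#' @return an object of class `"paired_sample"`
#' @export
paired_sample <- function(pct, cbct, true_field, profile_name, seed) {
  if (!all(dim(image_values(pct)) == dim(image_values(cbct))))
    stop("pct and cbct must share the same grid")
  if (!all(dim(true_field)[1:2] == dim(image_values(pct))))
    stop("true_field must have one 2-vector per pixel")
  structure(list(pct = pct, cbct = cbct, true_field = true_field,
                 profile_name = profile_name, seed = seed),
            class = "paired_sample")
}

# documented master-seed -> per-sample seed splitting rule: any single
# sample is reproducible in isolation from (master seed, index)
sample_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed) + 104729 * as.double(i)) %% 2147483647)
}

#' Generate a paired phantom dataset
#'
#' Produces `n` paired samples cycling over the given degradation profiles.
#' Each sample gets its own seed derived from the master seed by a fixed
#' splitting rule, so the dataset is a pure function of
#' `(n, spec, profiles, seed)` and any single sample can be regenerated in
#' isolation.
#'
#' @param n number of samples (>= 1)
#' @param spec a [phantom_spec()]
#' @param profiles list of [degradation_profile()] objects (at least one)
#' @param seed master integer seed
#' @return a list of [paired_sample()] objects
#' @export
make_dataset <- function(n, spec = phantom_spec(),
                         profiles = lapply(profile_names(),
                                           degradation_profile),
                         seed = 1L) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("configuration error: n must be >= 1")
  if (inherits(profiles, "degradation_profile")) profiles <- list(profiles)
  if (length(profiles) == 0L)
    stop("configuration error: at least one profile is required")
  lapply(seq_len(n), function(i) {
    prof <- profiles[[(i - 1L) %% length(profiles) + 1L]]
    s <- sample_seed(seed, i)
    pct <- generate_phantom(spec, s)
    deg <- degrade_to_cbct(pct, prof, s + 1L)
    paired_sample(pct, deg$cbct, deg$field, prof$name, s)
  })
}

#' Synthetic dose grid
#'
#' Analytic dose distributions for exercising the DVH statistics:
#' `"uniform"` (`params$dose`, default 60 Gy), `"linear_gradient"`
#' (`params$from`/`params$to` along `params$axis`, defaults 0 to 60 along
#' columns), or `"gaussian_blob"` (`params$peak`, `params$sigma` fraction of
#' the grid, centered blob).
#'
#' @param shape length-2 grid dimensions
#' @param kind one of `"uniform"`, `"linear_gradient"`, `"gaussian_blob"`
#' @param params named list of parameters for the chosen kind
#' @return a non-negative dose matrix in Gy
#' @export
synthetic_dose <- function(shape, kind = "uniform", params = list()) {
  n <- as.integer(shape[1]); p <- as.integer(shape[2])
  if (kind == "uniform") {
    dose <- if (is.null(params$dose)) 60 else params$dose
    matrix(dose, n, p)
  } else if (kind == "linear_gradient") {
    from <- if (is.null(params$from)) 0 else params$from
    to <- if (is.null(params$to)) 60 else params$to
    axis <- if (is.null(params$axis)) 2L else params$axis
    ramp <- if (axis == 1L) seq(from, to, length.out = n) else
      seq(from, to, length.out = p)
    if (axis == 1L) matrix(ramp, n, p) else matrix(ramp, n, p, byrow = TRUE)
  } else if (kind == "gaussian_blob") {
    peak <- if (is.null(params$peak)) 70 else params$peak
    sigma <- if (is.null(params$sigma)) 0.2 else params$sigma
    # center on an actual pixel so the maximum attains `peak` exactly
    u <- (seq_len(n) - ceiling(n / 2)) / n
    w <- (seq_len(p) - ceiling(p / 2)) / p
    peak * exp(-outer(u^2, w^2, `+`) / (2 * sigma^2))
  } else {
    stop("configuration error: unknown dose kind '", kind, "'")
  }
}
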