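# Shared fixtures: small phantoms and profiles used across test files.

test_spec <- function(grid = 64L, ...) phantom_spec(grid_size = grid, ...)

# profile with every degradation switched off (identity)
identity_profile <- function() degradation_profile("custom")

# deterministic plain phantom: three tissue classes, no randomness
flat_phantom <- function(grid = 64L) {
  generate_phantom(phantom_spec(grid_size = grid, shape_jitter = 0,
                                n_air_cavities = 0L), seed = 7L)
}

# smooth test image in [-1, 1] for warp/loss tests
smooth_norm_image <- function(n = 64L, seed = 1L) {
  img <- image_values(clip_hu(flat_phantom(n)))
  img <- reggan:::gaussian_smooth(img, 2)
  normalize_hu(clip_hu(hu_image(img)))$values
}

# registration-recovery pair set: (y, y warped by known field)
recovery_pairs <- function(n_pairs, amplitude = 5, grid = 64L,
                           seed_offset = 1000L) {
  spec <- test_spec(grid)
  lapply(seq_len(n_pairs), function(i) {
    y <- clip_hu(generate_phantom(spec, i))
    f <- random_deformation(c(grid, grid), amplitude, 8, i + seed_offset)
    yt <- warp(y, f)
    list(moving = normalize_hu(y)$values, fixed = normalize_hu(yt)$values,
         true_field = f)
  })
}
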