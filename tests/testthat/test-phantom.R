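test_that("plain phantom contains exactly the three tissue HU values", {
  spec <- phantom_spec(grid_size = 64, shape_jitter = 0, n_air_cavities = 0)
  img <- generate_phantom(spec, seed = 7)
  expect_setequal(unique(as.vector(img$values)), c(-1000, 40, 700))
})

test_that("phantom generation is deterministic and validates its spec", {
  spec <- phantom_spec(grid_size = 64)
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  expect_identical(a$values, b$values)
  expect_false(identical(generate_phantom(spec, 8)$values, a$values))
  expect_error(phantom_spec(grid_size = 16), "grid_size")
  expect_error(phantom_spec(air_hu = -1500), "air_hu")
  expect_error(phantom_spec(bone_hu = 2500), "bone_hu")
})

test_that("random deformation honours amplitude, smoothness and seed", {
  f0 <- random_deformation(c(32, 32), 0, 4, 1)
  expect_true(all(unclass(f0) == 0))
  f5 <- random_deformation(c(32, 32), 5, 4, 1)
  expect_equal(max(reggan:::field_magnitude(f5)), 5, tolerance = 1e-6)
  f5b <- random_deformation(c(32, 32), 5, 4, 2)
  expect_false(identical(unclass(f5), unclass(f5b)))
  expect_identical(unclass(random_deformation(c(32, 32), 5, 4, 1)),
                   unclass(f5))
  expect_error(random_deformation(c(32, 32), 5, 0, 1), "smoothness")
})

test_that("identity degradation profile is a bit-exact identity", {
  pct <- flat_phantom(64)
  out <- degrade_to_cbct(pct, identity_profile(), seed = 3)
  expect_identical(out$cbct$values, pct$values)
  expect_true(all(unclass(out$field) == 0))
})

test_that("degradation shifts the body mean by about hu_shift", {
  # constant-tissue phantom (bone set to tissue HU) evaluated deep inside the
  # body, away from the air boundary that blur and deformation mix in: the
  # mean output-minus-input tracks hu_shift plus the small cupping integral
  spec <- phantom_spec(grid_size = 96, tissue_hu = 40, bone_hu = 40,
                       shape_jitter = 0, n_air_cavities = 0)
  pct <- generate_phantom(spec, 1)
  prof <- degradation_profile("synergy")
  interior <- reggan:::gaussian_smooth((pct$values > -200) + 0, 3) > 0.999
  out <- degrade_to_cbct(pct, prof, seed = 5)
  shift <- mean(out$cbct$values[interior] - pct$values[interior])
  expect_lt(abs(shift - prof$hu_shift), 20)
})

test_that("degradation is deterministic given (pct, profile, seed)", {
  pct <- flat_phantom(64)
  prof <- degradation_profile("halcyon")
  a <- degrade_to_cbct(pct, prof, seed = 9)
  b <- degrade_to_cbct(pct, prof, seed = 9)
  expect_identical(a$cbct$values, b$cbct$values)
  expect_identical(unclass(a$field), unclass(b$field))
})

test_that("datasets cycle profiles and are pure functions of their seed", {
  spec <- test_spec(64)
  profs <- lapply(profile_names(), degradation_profile)
  ds <- make_dataset(4, spec, profs, seed = 1)
  expect_setequal(vapply(ds, `[[`, character(1), "profile_name"),
                  profile_names())
  ds2 <- make_dataset(4, spec, profs, seed = 1)
  for (i in 1:4) expect_identical(ds[[i]]$cbct$values, ds2[[i]]$cbct$values)
  expect_error(make_dataset(0, spec, profs, 1), "n must be")
  expect_error(make_dataset(2, spec, list(), 1), "profile")
})

test_that("all emitted HU images stay within the scanner window", {
  spec <- test_spec(48)
  profs <- lapply(profile_names(), degradation_profile)
  ds <- make_dataset(16, spec, profs, seed = 42)
  for (s in ds) {
    expect_true(all(s$pct$values >= -1000 & s$pct$values <= 2000))
    expect_true(all(s$cbct$values >= -1000 & s$cbct$values <= 2000))
  }
})

test_that("the recorded true field reproduces the cbct geometry", {
  # with intensity degradation off, cbct is exactly the warped pct
  spec <- test_spec(64)
  prof <- degradation_profile("custom", deform_amplitude = 4)
  ds <- make_dataset(3, spec, list(prof), seed = 5)
  for (s in ds) {
    rewarped <- warp(s$pct, s$true_field)
    expect_lt(mae(rewarped, s$cbct), 1)
  }
})

test_that("synthetic dose grids follow their analytic definitions", {
  u <- synthetic_dose(c(8, 8), "uniform", list(dose = 60))
  expect_true(all(u == 60))
  g <- synthetic_dose(c(9, 9), "linear_gradient",
                      list(from = 0, to = 60, axis = 2))
  expect_equal(g[5, 5], 30)
  blob <- synthetic_dose(c(16, 16), "gaussian_blob", list(peak = 70))
  expect_equal(max(blob), 70, tolerance = 1e-9)
  expect_true(all(blob >= 0))
  expect_error(synthetic_dose(c(8, 8), "donut"), "unknown dose kind")
})

test_that("named profiles order the degradation severity as intended", {
  # synergy must be by far the most degraded (largest CBCT-vs-pCT error)
  spec <- test_spec(64)
  maes <- vapply(profile_names(), function(nm) {
    ds <- make_dataset(4, spec, list(degradation_profile(nm)), seed = 3)
    mean(vapply(ds, function(s) mae(s$cbct, s$pct), numeric(1)))
  }, numeric(1))
  expect_gt(maes[["synergy"]], 1.5 * max(maes[c("halcyon", "trilogy",
                                                "vitalbeam")]))
})
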