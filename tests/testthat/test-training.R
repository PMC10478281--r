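# Small-scale training behaviour: bookkeeping, determinism, and the
# inference pipeline. Heavier convergence runs live in test-acceptance.R.

tiny_fit <- function(seed = 1, epochs = 1, n = 1) {
  ds <- make_dataset(n, test_spec(32),
                     list(degradation_profile("halcyon")), seed = 4)
  reggan(ds, val_fraction = 0,
         config = train_config(learning_rate = 2e-4, epochs = epochs,
                               seed = seed, image_size = 32),
         weights = loss_weights(20, 1, 1),
         generator = generator_config(base_channels = 4,
                                      n_residual_blocks = 1),
         registration = registration_config(encoder_depth = 3,
                                            base_channels = 4),
         discriminator = discriminator_config(base_channels = 4))
}

test_that("one sample for one epoch records exactly one iteration", {
  fit <- tiny_fit(epochs = 1, n = 1)
  expect_equal(nrow(fit$history), 1)
  expect_equal(fit$history$iter, 1)
  expect_true(all(is.finite(unlist(
    fit$history[c("corr", "smooth", "adv_g", "adv_d")]))))
})

test_that("training is deterministic given the seed", {
  f1 <- tiny_fit(seed = 5, epochs = 2, n = 3)
  f2 <- tiny_fit(seed = 5, epochs = 2, n = 3)
  expect_identical(f1$history, f2$history)
  f3 <- tiny_fit(seed = 6, epochs = 2, n = 3)
  expect_false(identical(f1$history$corr, f3$history$corr))
})

test_that("training rejects empty datasets", {
  expect_error(reggan(list()), "non-empty")
})

test_that("prediction runs clip/normalize/resample and returns the input grid", {
  fit <- tiny_fit()
  cbct <- generate_phantom(test_spec(48), 3)  # grid differs from train size
  sct <- predict(fit, cbct)
  expect_s3_class(sct, "hu_image")
  expect_equal(dim(sct$values), c(48, 48))
  expect_true(all(sct$values >= -1000 & sct$values <= 2000))
  # translate() accepts paired samples and lists too
  ds <- make_dataset(2, test_spec(48), list(identity_profile()), seed = 1)
  out <- predict(fit, ds)
  expect_length(out, 2)
  expect_s3_class(out[[1]], "hu_image")
})

test_that("checkpoints round-trip through save/load and reject bad versions", {
  fit <- tiny_fit()
  path <- tempfile(fileext = ".rds")
  save_reggan(fit, path)
  back <- load_reggan(path)
  cbct <- generate_phantom(test_spec(32), 9)
  expect_equal(predict(fit, cbct)$values, predict(back, cbct)$values)
  bad <- readRDS(path); bad$version <- "other-0"
  path2 <- tempfile(fileext = ".rds"); saveRDS(bad, path2)
  expect_error(load_reggan(path2), "incompatible checkpoint")
  expect_error(translate(cbct, path2), "incompatible checkpoint")
})

test_that("model object methods summarise the fit", {
  fit <- tiny_fit(epochs = 1, n = 2)
  expect_output(print(fit), "CBCT-to-sCT")
  s <- summary(fit)
  expect_s3_class(s, "summary.reggan")
  expect_output(print(s), "iterations")
  cf <- coef(fit)
  expect_named(cf, c("generator", "registration", "discriminator"))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("a larger smoothness weight yields a smoother fitted field", {
  pairs <- recovery_pairs(4, amplitude = 4, grid = 32)
  fit_lo <- train_registration(pairs,
                               registration_config(encoder_depth = 3,
                                                   base_channels = 8),
                               iterations = 150, seed = 3,
                               weights = loss_weights(20, 0.5, 0))
  fit_hi <- train_registration(pairs,
                               registration_config(encoder_depth = 3,
                                                   base_channels = 8),
                               iterations = 150, seed = 3,
                               weights = loss_weights(20, 5, 0))
  sm <- function(fit) mean(vapply(pairs, function(p) {
    smoothness_loss(registration_apply(fit$net, p$moving, p$fixed))
  }, numeric(1)))
  expect_lt(sm(fit_hi), sm(fit_lo))
})
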