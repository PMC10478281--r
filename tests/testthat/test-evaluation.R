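# independent brute-force loop implementations used as oracles
loop_mae <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + abs(a[i, j] - b[i, j])
  s / length(a)
}
loop_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / length(a)
}
loop_psnr <- function(a, b, peak) 10 * log10(peak^2 / loop_mse(a, b))
loop_ssim <- function(a, b, L) {
  n <- length(a)
  mu_a <- sum(a) / n; mu_b <- sum(b) / n
  va <- 0; vb <- 0; cab <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    va <- va + (a[i, j] - mu_a)^2
    vb <- vb + (b[i, j] - mu_b)^2
    cab <- cab + (a[i, j] - mu_a) * (b[i, j] - mu_b)
  }
  va <- va / n; vb <- vb / n; cab <- cab / n
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}

test_that("metrics match brute-force loop oracles on random image pairs", {
  set.seed(99)
  for (k in 1:50) {
    a <- matrix(runif(256, -1000, 2000), 16, 16)
    b <- matrix(runif(256, -1000, 2000), 16, 16)
    expect_equal(mae(a, b), loop_mae(a, b), tolerance = 1e-6)
    expect_equal(mse(a, b), loop_mse(a, b), tolerance = 1e-6)
    expect_equal(psnr(a, b, peak = 3000), loop_psnr(a, b, 3000),
                 tolerance = 1e-6)
    expect_equal(ssim(a, b), loop_ssim(a, b, 3000), tolerance = 1e-6)
  }
})

test_that("metric edge cases and symmetry behave as defined", {
  a <- matrix(c(0, 200, 100, 300), 2, 2)
  b <- matrix(0, 2, 2)
  expect_equal(mae(a, a), 0)
  expect_equal(mae(a + 100, a), 100)
  expect_equal(mae(a, b), 150)
  expect_equal(mse(a, b), (0 + 100^2 + 200^2 + 300^2) / 4)
  expect_equal(mse(a + 10, a), 100)
  expect_equal(mae(a, b), mae(b, a))
  expect_equal(mse(a, b), mse(b, a))
  expect_equal(ssim(a, b), ssim(b, a))
  expect_error(mae(a, matrix(0, 3, 3)), "shape")
})

test_that("psnr follows its algebra and flags identical images", {
  set.seed(3)
  a <- matrix(runif(64, 0, 100), 8, 8)
  b <- a + sqrt(100^2 / 10)  # mse = peak^2 / 10
  expect_equal(psnr(b, a, peak = 100), 10)
  expect_true(is.infinite(psnr(a, a)))
  b2 <- a + 100              # mse = peak^2
  expect_equal(psnr(b2, a, peak = 100), 0)
})

test_that("psnr decreases monotonically with the noise level", {
  set.seed(8)
  base <- image_values(clip_hu(flat_phantom(64)))
  vals <- vapply(c(5, 10, 20, 40), function(sd) {
    noisy <- base + matrix(rnorm(length(base), 0, sd), nrow(base))
    psnr(noisy, base, peak = 3000)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("ssim is 1 for identical images, bounded, and negative for
           anticorrelated ones", {
  set.seed(12)
  a <- matrix(rnorm(256, 0, 400), 16, 16)
  expect_equal(ssim(a, a), 1, tolerance = 1e-12)
  expect_lt(ssim(a, -a), 0)
  for (k in 1:200) {
    x <- matrix(runif(64, -1000, 2000), 8, 8)
    y <- matrix(runif(64, -1000, 2000), 8, 8)
    s <- ssim(x, y)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("windowed ssim agrees with the global form on constant offsets", {
  set.seed(13)
  a <- matrix(runif(256, 0, 500), 16, 16)
  expect_equal(ssim(a, a, method = "windowed"), 1, tolerance = 1e-9)
  expect_lt(ssim(a, a + 300, method = "windowed"), 1)
})

test_that("restricted-range histograms discard out-of-range voxels", {
  h <- hu_histogram(matrix(70, 10, 10))
  expect_false(h$empty)
  expect_equal(sum(h$density), 1)
  expect_equal(sum(h$density > 0), 1)
  expect_true(h$mids[which(h$density > 0)] > 60 &&
                h$mids[which(h$density > 0)] < 80)
  h_air <- hu_histogram(matrix(-1000, 5, 5))
  expect_true(h_air$empty)
  ramp <- matrix(seq(-500, 500, length.out = 10000), 100, 100)
  hr <- hu_histogram(ramp, bins = 20)
  expect_lt(max(hr$density) / min(hr$density), 1.3)
})

test_that("dataset evaluation honours identity and perfect translators", {
  ds <- make_dataset(4, test_spec(48),
                     list(degradation_profile("halcyon")), seed = 2)
  rep_id <- evaluate_dataset(ds, "identity")
  for (cs in unique(rep_id$per_case$case)) {
    rows <- rep_id$per_case[rep_id$per_case$case == cs, ]
    expect_equal(rows$mae[1], rows$mae[2])
    expect_equal(rows$ssim[1], rows$ssim[2])
  }
  perfect <- function(cbct) NULL  # replaced per sample below
  rep_perf <- evaluate_dataset(ds, local({
    i <- 0
    function(cbct) { i <<- i + 1; ds[[i]]$pct }
  }))
  sct_rows <- rep_perf$per_case[rep_perf$per_case$comparison == "sct_vs_pct", ]
  expect_true(all(sct_rows$mae == 0))
  expect_true(all(sct_rows$ssim == 1))
})

test_that("group comparison rejects degenerate designs and separates
           disjoint groups", {
  d <- data.frame(
    case = 1:20, profile = rep(c("a", "b"), each = 10),
    comparison = "sct_vs_pct",
    mae = c(runif(10, 0, 1), runif(10, 10, 11)))
  out <- compare_groups(d, "mae")
  expect_lt(out$p_value, 0.01)
  single <- d[d$profile == "a", ]
  expect_error(compare_groups(single, "mae"), "two profile groups")
  tiny <- d[c(1:2, 11:12), ]
  expect_error(compare_groups(tiny, "mae"), "at least 3")
})

test_that("null kruskal-wallis rejection rate is calibrated near alpha", {
  set.seed(31)
  reps <- 400
  rejections <- 0
  for (r in seq_len(reps)) {
    d <- data.frame(profile = rep(letters[1:4], each = 10),
                    comparison = "sct_vs_pct",
                    mae = rnorm(40))
    out <- compare_groups(d, "mae")
    if (out$p_value < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / reps, 0.02)
  expect_lt(rejections / reps, 0.08)
})
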