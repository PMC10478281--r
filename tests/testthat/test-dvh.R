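# exhaustive sorted-voxel oracle for D_p: the dose received by at least p%
# of the masked voxels
oracle_dp <- function(doses, p) {
  s <- sort(doses, decreasing = TRUE)
  k <- ceiling(p / 100 * length(s))
  s[max(k, 1L)]
}

test_that("cumulative DVH is a step curve with the right plateaus", {
  dose <- matrix(60, 8, 8)
  mask <- matrix(TRUE, 8, 8)
  curve <- cumulative_dvh(dose, mask, bins = 100)
  expect_equal(curve$volume[1], 1)
  expect_true(all(curve$volume == 1))  # every voxel receives 60
  two <- matrix(c(40, 60), 1, 2)
  c2 <- cumulative_dvh(two, matrix(TRUE, 1, 2), bins = 600)
  mid <- c2$volume[c2$dose > 40 + 1e-9 & c2$dose <= 60]
  expect_true(all(mid == 0.5))
  expect_error(cumulative_dvh(dose, matrix(FALSE, 8, 8)), "empty mask")
})

test_that("DVH curves are monotone non-increasing on random grids", {
  set.seed(21)
  for (k in 1:100) {
    dose <- matrix(runif(64, 0, 70), 8, 8)
    mask <- matrix(runif(64) > 0.3, 8, 8)
    if (!any(mask)) mask[1, 1] <- TRUE
    curve <- cumulative_dvh(dose, mask, bins = 50)
    expect_true(all(diff(curve$volume) <= 1e-12))
  }
})

test_that("dose_at_volume matches the sorted-voxel oracle within a bin", {
  set.seed(22)
  for (k in 1:20) {
    n <- sample(3:10, 1)
    dose <- matrix(runif(n * n, 0, 70), n, n)
    mask <- matrix(TRUE, n, n)
    curve <- cumulative_dvh(dose, mask, bins = 1000)
    bw <- max(dose) / 1000
    for (p in c(2, 50, 95, 98)) {
      expect_lt(abs(dose_at_volume(curve, p) - oracle_dp(dose[mask], p)),
                bw + 1e-9)
    }
  }
  curve <- cumulative_dvh(matrix(60, 4, 4), matrix(TRUE, 4, 4))
  expect_error(dose_at_volume(curve, 100), "strictly between")
  expect_error(dose_at_volume(curve, 0), "strictly between")
})

test_that("uniform dose collapses all seven PTV statistics to one value", {
  m <- dvh_metrics(matrix(60, 10, 10), matrix(TRUE, 10, 10))
  for (k in c("dmin", "dmax", "dmean", "d2", "d50", "d95", "d98"))
    expect_equal(m[[k]], 60, tolerance = 1e-9)
})

test_that("the DVH ordering invariant holds on random dose grids", {
  set.seed(23)
  for (k in 1:100) {
    dose <- matrix(runif(100, 0, 75), 10, 10)
    mask <- matrix(runif(100) > 0.4, 10, 10)
    if (sum(mask) < 2) mask[1:2] <- TRUE
    m <- dvh_metrics(dose, mask)
    expect_true(m$dmin <= m$d98 + 1e-9)
    expect_true(m$d98 <= m$d95 + 1e-9)
    expect_true(m$d95 <= m$d50 + 1e-9)
    expect_true(m$d50 <= m$d2 + 1e-9)
    expect_true(m$d2 <= m$dmax + 1e-9)
  }
})

test_that("d50 of a hand-built masked grid matches exhaustive sorting", {
  dose <- matrix(c(10, 20, 30, 40, 50, 60, 70, 80, 90), 3, 3)
  mask <- matrix(TRUE, 3, 3)
  m <- dvh_metrics(dose, mask, bins = 2000)
  expect_lt(abs(m$d50 - oracle_dp(as.vector(dose), 50)), 90 / 2000 + 1e-9)
  expect_equal(m$dmin, 10)
  expect_equal(m$dmax, 90)
  expect_equal(m$dmean, 50)
})

test_that("difference rate arithmetic is exact", {
  expect_equal(difference_rate(60, 60), 0)
  expect_equal(difference_rate(61.8, 60), 0.03)
  expect_equal(difference_rate(58.2, 60), -0.03)
  expect_warning(dr0 <- difference_rate(10, 0), "undefined")
  expect_true(is.na(dr0))
})

test_that("pass rate counts tolerance compliance and is monotone", {
  expect_equal(pass_rate(rep(0, 5), 0.01), 1)
  expect_equal(pass_rate(c(0.005, 0.02, -0.002, 0.04), 0.01), 0.5)
  expect_equal(pass_rate(c(0.5, -0.3, 0.9), 1), 1)
  set.seed(24)
  dr <- rnorm(50, 0, 0.02)
  rates <- vapply(c(0.005, 0.01, 0.02, 0.05), function(th)
    pass_rate(dr, th), numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_error(pass_rate(numeric(0), 0.01), "empty")
})

test_that("dvh_difference reports the seven per-metric rates", {
  m1 <- dvh_metrics(matrix(61.8, 5, 5), matrix(TRUE, 5, 5))
  m0 <- dvh_metrics(matrix(60, 5, 5), matrix(TRUE, 5, 5))
  dr <- dvh_difference(m1, m0)
  expect_equal(length(dr), 7)
  expect_true(all(abs(dr - 0.03) < 1e-9))
})
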