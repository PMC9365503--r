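test_that("BED reproduces hand-evaluated courses and edge cases", {
  expect_equal(bed(50, fractionation(25, 2)), 50 * (1 + 2 / 3),
               tolerance = 1e-12)
  expect_equal(bed(12, fractionation(2, 6)), 36, tolerance = 1e-12)
  expect_equal(bed(0, fractionation(25, 2)), 0)
  # off-prescription dose re-derives the local fraction dose
  expect_equal(bed(25, fractionation(25, 2)), 25 * (1 + 1 / 3),
               tolerance = 1e-12)
  expect_error(bed(50, fractionation(25, 2), alpha_beta = 0), "alpha_beta")
  expect_error(bed(-1, fractionation(25, 2)), "non-negative")
})

test_that("BED is monotone and approaches physical dose for large alpha/beta", {
  sch <- fractionation(10, 3)
  doses <- seq(0, 60, by = 5)
  expect_true(all(diff(bed(doses, sch)) > 0))
  # fixed total dose, larger dose per fraction -> larger BED
  b <- vapply(c(2, 4, 5, 10), function(d) {
    bed(20, fractionation(20 / d, d))
  }, numeric(1))
  expect_true(all(diff(b) > 0))
  expect_equal(bed(40, sch, alpha_beta = 1e9), 40, tolerance = 1e-6)
})

test_that("EQD2 inverts BED for 2-Gy courses and scales as expected", {
  expect_equal(eqd2(36), 21.6, tolerance = 1e-12)
  expect_equal(eqd2(0), 0)
  sch2 <- fractionation(25, 2)
  expect_equal(eqd2(bed(50, sch2)), 50, tolerance = 1e-9)
  # round trip at several alpha/beta values
  for (ab in c(1, 3, 10)) {
    expect_equal(eqd2(bed(50, sch2, ab), ab), 50, tolerance = 1e-9)
  }
})

test_that("course summation matches the per-course BED arithmetic", {
  wbi <- dose_distribution("breast", rep(50, 5), scheme = fractionation(25, 2))
  boost <- dose_distribution("breast", rep(12, 5), scheme = fractionation(2, 6))
  s <- sum_courses(list(wbi, boost))
  expect_equal(s$voxel_doses, rep(71.6, 5), tolerance = 1e-9)
  expect_identical(s$dose_type, "eqd2")

  # single 2-Gy course is the identity
  one <- sum_courses(list(wbi))
  expect_equal(one$voxel_doses, wbi$voxel_doses, tolerance = 1e-9)

  # all-zero boost is the additive identity
  zero <- dose_distribution("breast", rep(0, 5), scheme = fractionation(2, 6))
  expect_equal(sum_courses(list(wbi, zero))$voxel_doses, one$voxel_doses,
               tolerance = 1e-12)
})

test_that("course summation is commutative and associative", {
  set.seed(11)
  sch <- list(fractionation(25, 2), fractionation(2, 6), fractionation(5, 2))
  courses <- lapply(sch, function(s) {
    dose_distribution("lung", runif(20, 0, s$total_dose), scheme = s)
  })
  ab <- sum_courses(courses[c(1, 2, 3)])$voxel_doses
  ba <- sum_courses(courses[c(3, 1, 2)])$voxel_doses
  expect_equal(ab, ba, tolerance = 1e-12)
  # associativity: summing an already-summed EQD2 plan with the third course
  nested <- sum_courses(list(sum_courses(courses[1:2]), courses[[3]]))
  expect_equal(nested$voxel_doses, ab, tolerance = 1e-12)
})

test_that("mismatched voxel grids are rejected", {
  a <- dose_distribution("lung", rep(1, 4), scheme = fractionation(25, 2))
  b <- dose_distribution("lung", rep(1, 5), scheme = fractionation(25, 2))
  c <- dose_distribution("heart", rep(1, 4), scheme = fractionation(25, 2))
  expect_error(sum_courses(list(a, b)), "grid")
  expect_error(sum_courses(list(a, c)), "organ")
})

test_that("DVH construction counts voxels into half-open bins", {
  d <- dose_distribution("lung", c(1, 1, 3, 3), scheme = fractionation(25, 2))
  h <- dvh_from_distribution(d, bin_width = 2)
  expect_equal(h$bin_lo, c(0, 2))
  expect_equal(h$volume, c(0.5, 0.5))
  expect_equal(h$dose_gy, c(1, 3))

  # uniform dose occupies a single bin with volume 1
  u <- dose_distribution("lung", rep(7.03, 9), scheme = fractionation(25, 2))
  hu <- dvh_from_distribution(u, 0.1)
  expect_equal(sum(hu$volume > 0), 1)
  expect_equal(sum(hu$volume), 1, tolerance = 1e-12)
})

test_that("DVH conserves volume and mean dose within one bin width", {
  set.seed(42)
  for (bw in c(0.1, 0.5, 2)) {
    doses <- rexp(500, 1 / 8)
    d <- dose_distribution("lung", doses, scheme = fractionation(25, 2))
    h <- dvh_from_distribution(d, bw)
    expect_equal(sum(h$volume), 1, tolerance = 1e-12)
    expect_lt(abs(sum(h$volume * h$dose_gy) - mean(doses)), bw)
  }
})

test_that("dose metrics match direct arithmetic", {
  m <- dose_metrics(two_bin_dvh(), v_at = c(0, 20), d_at = c(1, 50))
  expect_equal(m$d_mean_gy, 20)
  expect_equal(m$v_0gy_pct, 100)
  expect_equal(m$v_20gy_pct, 50)
  expect_equal(m$d_1pct_gy, 30)

  u <- dose_metrics(uniform_dvh(10), v_at = 20, d_at = 1)
  expect_equal(u$d_mean_gy, 10)
  expect_equal(u$v_20gy_pct, 0)
  expect_equal(u$d_1pct_gy, 10)

  expect_error(dose_metrics(uniform_dvh(10), d_at = 0), "\\(0, 100\\]")
  expect_error(dose_metrics(uniform_dvh(10), d_at = 101), "\\(0, 100\\]")
})

test_that("D_y% is non-increasing in y and V_x non-increasing in x", {
  set.seed(5)
  d <- dose_distribution("lung", rgamma(400, 2, 0.2),
                         scheme = fractionation(25, 2))
  h <- dvh_from_distribution(d, 0.25)
  ys <- c(1, 5, 20, 50, 90, 100)
  dys <- vapply(ys, function(y) {
    dose_metrics(h, v_at = numeric(0), d_at = y)[[sprintf("d_%gpct_gy", y)]]
  }, numeric(1))
  expect_true(all(diff(dys) <= 1e-9))
  xs <- c(0, 2, 5, 10, 20, 40)
  vxs <- vapply(xs, function(x) {
    dose_metrics(h, v_at = x, d_at = numeric(0))[[sprintf("v_%ggy_pct", x)]]
  }, numeric(1))
  expect_true(all(diff(vxs) <= 1e-9))
})
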