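test_that("age modifier is normalised at the reference ages", {
  expect_equal(age_modifier(30, 70, schneider_lung()), 1, tolerance = 1e-12)
  expect_equal(age_modifier(30, 70, schneider_breast()), 1, tolerance = 1e-12)
})

test_that("age modifier matches direct evaluation of the exponential form", {
  expect_equal(age_modifier(55, 75, schneider_lung()), 1.407535,
               tolerance = 1e-6)
  expect_equal(age_modifier(55, 95, schneider_breast()), 0.666409,
               tolerance = 1e-6)
  expect_error(age_modifier(60, 50, schneider_lung()), "attained age")
})

test_that("linear no-threshold EAR is the slope-dose-age product", {
  lung <- schneider_lung()
  expect_equal(ear_lnt(0, 55, 75, lung), 0)
  expect_equal(ear_lnt(0.5, 55, 75, lung), 5.63014, tolerance = 1e-5)
  # linearity in dose
  expect_equal(ear_lnt(1.2, 55, 75, lung), 2 * ear_lnt(0.6, 55, 75, lung),
               tolerance = 1e-12)
  expect_error(ear_lnt(-0.1, 55, 75, lung), "non-negative")
})

test_that("alpha-prime follows the fraction-size scaling", {
  lung <- schneider_lung()
  sch <- fractionation(25, 2)
  expect_equal(alpha_prime(0, sch, lung), 0.042, tolerance = 1e-12)
  expect_equal(alpha_prime(10, sch, lung), 0.0476, tolerance = 1e-10)
  # at the prescription dose: alpha + beta * d_T
  expect_equal(alpha_prime(50, sch, lung),
               0.042 + (0.042 / 3) * 2, tolerance = 1e-12)
})

test_that("RED has unit low-dose slope and the frozen mid-dose value", {
  expect_equal(red(0, 0.0476, 0.83), 0)
  expect_equal(red(0.001, 0.0476, 0.83) / 0.001, 1, tolerance = 1e-3)
  # frozen high-precision evaluation, bracketed by the R=0 / R=1 forms
  expect_equal(red(10, 0.0476, 0.83), 7.013989, tolerance = 1e-5)
  r0 <- 10 * exp(-0.0476 * 10)
  r1 <- (1 - exp(-0.0476 * 10)) / 0.0476
  expect_gt(red(10, 0.0476, 0.83), min(r0, r1))
  expect_lt(red(10, 0.0476, 0.83), max(r0, r1))
})

test_that("RED never exceeds the physical dose on a parameter grid", {
  for (a in c(0.01, 0.042, 0.1)) {
    for (r in c(0, 0.15, 0.5, 0.83, 1)) {
      d <- seq(0, 80, by = 2)
      expect_true(all(red(d, a, r) <= d + 1e-9))
    }
  }
})

test_that("general-R formula converges to the closed boundary forms", {
  d <- c(0.5, 5, 20, 60)
  for (a in c(0.042, 0.07)) {
    expect_lt(max(abs(red(d, a, 1e-7) - d * exp(-a * d))), 1e-6)
    expect_lt(max(abs(red(d, a, 1 - 1e-7) - (1 - exp(-a * d)) / a)), 1e-6)
  }
})

test_that("full-model EAR collapses to delta * RED * mu on a uniform DVH", {
  lung <- schneider_lung()
  sch <- fractionation(25, 2)
  h <- uniform_dvh(10, organ = "lung")
  a_p <- alpha_prime(10, sch, lung)
  expect_equal(ear_full(h, sch, 55, 75, lung),
               lung$delta * red(10, a_p, lung$repop) *
                 age_modifier(55, 75, lung),
               tolerance = 1e-12)
})

test_that("full-model EAR is the volume-weighted mix of single-bin results", {
  lung <- schneider_lung()
  sch <- fractionation(25, 2)
  h <- two_bin_dvh(5, 40, v1 = 0.7, organ = "lung")
  parts <- 0.7 * ear_full(uniform_dvh(5), sch, 55, 75, lung) +
    0.3 * ear_full(uniform_dvh(40), sch, 55, 75, lung)
  expect_equal(ear_full(h, sch, 55, 75, lung), parts, tolerance = 1e-12)
})

test_that("full model meets the LNT model in the low-dose limit", {
  lung <- schneider_lung()
  sch <- fractionation(25, 2)
  for (d in c(0.01, 0.05, 0.1)) {
    full <- ear_full(uniform_dvh(d), sch, 55, 75, lung)
    lnt <- ear_lnt(d, 55, 75, lung)
    expect_equal(full, lnt, tolerance = 0.01)
  }
  expect_equal(ear_full(uniform_dvh(0), sch, 55, 75, lung), 0)
})

test_that("the EQD2 pathway uses the 2-Gy-fraction alpha-prime", {
  lung <- schneider_lung()
  h <- uniform_dvh(50, organ = "lung")
  a_p <- lung$alpha_lq * (1 + 2 / 3)
  expect_equal(ear_full(h, "eqd2", 55, 75, lung),
               lung$delta * red(50, a_p, lung$repop) *
                 age_modifier(55, 75, lung),
               tolerance = 1e-12)
})

test_that("the bundled Schneider registry carries lung and breast", {
  reg <- schneider_registry()
  expect_setequal(reg$organ, c("lung", "breast"))
  expect_equal(reg$delta[reg$organ == "breast"], 8.2)
  expect_equal(reg$repop[reg$organ == "lung"], 0.83)
  # beta derived from alpha / (alpha/beta)
  p <- schneider_params("lung", 8, 0.002, 4.23, 0.042, 0.83)
  expect_equal(p$beta_lq, 0.014, tolerance = 1e-12)
})

test_that("invalid Schneider parameters are rejected", {
  expect_error(schneider_params("x", -1, 0, 0, 0.04, 0.5), "delta")
  expect_error(schneider_params("x", 8, 0, 0, 0.04, 1.5), "repop")
  expect_error(red(10, 0, 0.5), "alpha_p")
  expect_error(red(-1, 0.04, 0.5), "non-negative")
})
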