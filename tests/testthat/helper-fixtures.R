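# shared fixture builders for the test suite

uniform_dvh <- function(dose, organ = "organ") {
  dvh(dose_gy = dose, volume = 1, organ = organ)
}

two_bin_dvh <- function(d1 = 10, d2 = 30, v1 = 0.5, organ = "organ") {
  dvh(dose_gy = c(d1, d2), volume = c(v1, 1 - v1), organ = organ)
}

lung_sympt <- function() lkb_params("symptomatic_pneumonitis", 1, 0.35, 37.6)

schneider_lung <- function() {
  schneider_params("lung", 8.0, 0.002, 4.23, 0.042, 0.83)
}

schneider_breast <- function() {
  schneider_params("breast", 8.2, -0.037, 1.70, 0.044, 0.15)
}

# one tiny two-course patient (few voxels, fast) for pipeline tests
tiny_patient <- function(heart_dose = 1, n_vox = 50) {
  wbi <- fractionation(25, 2)
  boost <- fractionation(2, 6)
  mk <- function(org, d_wbi, d_boost) {
    tibble::tibble(
      organ = org, course = c("wbi", "boost"),
      distribution = list(
        dose_distribution(org, rep(d_wbi, n_vox), scheme = wbi),
        dose_distribution(org, rep(d_boost, n_vox), scheme = boost)
      )
    )
  }
  dplyr::bind_rows(
    mk("heart", heart_dose, 0),
    mk("lung_ipsi", 8, 0.3),
    mk("lung_contra", 0.4, 0.01),
    mk("breast_contra", 1.2, 0.05)
  )
}
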