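#' Schneider secondary-cancer model parameters
#'
#' Organ-specific parameters of the mechanistic secondary-cancer risk model:
#' the initial slope `delta` in (10,000 person-years x Gy)^-1, the
#' age-modifier coefficients `gamma_e` (per year of age at exposure) and
#' `gamma_a` (attained-age exponent), the linear-quadratic coefficient
#' `alpha_lq` in Gy^-1, and the repopulation/repair capacity `R` in [0, 1]
#' (0 = no regeneration between fractions, 1 = complete regeneration).
#' `beta_lq` is derived as `alpha_lq / alpha_beta` since only alpha is
#' tabulated.
#'
#' @param organ Organ label.
#' @param delta Initial slope, per 10,000 PY per Gy (> 0).
#' @param gamma_e Age-at-exposure modifier coefficient.
#' @param gamma_a Attained-age exponent.
#' @param alpha_lq Linear-quadratic alpha in Gy^-1 (> 0).
#' @param repop Repopulation parameter R in [0, 1].
#' @param alpha_beta Alpha/beta ratio in Gy used to derive beta (default 3).
#' @return An object of class `schneider_params`.
#' @export
schneider_params <- function(organ, delta, gamma_e, gamma_a, alpha_lq, repop,
                             alpha_beta = 3) {
  if (delta <= 0) stop("`delta` must be positive", call. = FALSE)
  if (alpha_lq <= 0) stop("`alpha_lq` must be positive", call. = FALSE)
  if (repop < 0 || repop > 1) stop("`repop` must lie in [0, 1]", call. = FALSE)
  ab <- check_alpha_beta(alpha_beta)
  structure(
    list(organ = as.character(organ), delta = as.numeric(delta),
         gamma_e = as.numeric(gamma_e), gamma_a = as.numeric(gamma_a),
         alpha_lq = as.numeric(alpha_lq), repop = as.numeric(repop),
         beta_lq = as.numeric(alpha_lq) / ab, alpha_beta = ab),
    class = "schneider_params"
  )
}

#' Bundled Schneider parameter registry
#'
#' Literature fits for the lung (delta 8.0, gamma_e 0.002, gamma_a 4.23,
#' alpha 0.042 Gy^-1, R 0.83) and the breast (delta 8.2, gamma_e -0.037,
#' gamma_a 1.70, alpha 0.044 Gy^-1, R 0.15). A YAML file in the same layout
#' (`organ: {delta, gamma_e, gamma_a, alpha, repop, source}`) can extend or
#' override the registry.
#'
#' @param path Optional YAML file with additional/overriding organs.
#' @return A tibble with one row per organ.
#' @export
schneider_registry <- function(path = NULL) {
  file <- system.file("extdata", "schneider_params.yaml", package = "oarrisk")
  reg <- schneider_registry_from_yaml(file)
  if (!is.null(path)) {
    user <- schneider_registry_from_yaml(path)
    reg <- dplyr::rows_upsert(reg, user, by = "organ")
  }
  reg
}

schneider_registry_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(names(raw), function(org) {
    e <- raw[[org]]
    tibble::tibble(organ = org, delta = e$delta, gamma_e = e$gamma_e,
                   gamma_a = e$gamma_a, alpha_lq = e$alpha, repop = e$repop,
                   source = e$source %||% NA_character_)
  })
}

schneider_from_registry <- function(organ, registry = schneider_registry(),
                                    alpha_beta = 3) {
  row <- registry[registry$organ == organ, ]
  if (nrow(row) != 1L) {
    stop(sprintf("organ '%s' not found in Schneider registry", organ),
         call. = FALSE)
  }
  schneider_params(organ, row$delta, row$gamma_e, row$gamma_a, row$alpha_lq,
                   row$repop, alpha_beta)
}

check_ages <- function(age_x, age_a) {
  if (any(age_x <= 0) || any(age_a < age_x)) {
    stop("ages must satisfy attained age >= age at exposure > 0",
         call. = FALSE)
  }
  invisible(NULL)
}

#' Age modifier of the secondary-cancer risk models
#'
#' `mu = exp(gamma_e * (age_x - 30) + gamma_a * ln(age_a / 70))`, normalised
#' to 1 at the reference ages (exposure at 30, attained age 70).
#'
#' @param age_x Age at exposure in years.
#' @param age_a Attained age in years (>= `age_x`).
#' @param params A [schneider_params()] object.
#' @return Dimensionless modifier.
#' @examples
#' lung <- schneider_params("lung", 8.0, 0.002, 4.23, 0.042, 0.83)
#' age_modifier(30, 70, lung)  # 1
#' age_modifier(55, 75, lung)  # 1.408
#' @export
age_modifier <- function(age_x, age_a, params) {
  check_ages(age_x, age_a)
  exp(params$gamma_e * (age_x - 30) + params$gamma_a * log(age_a / 70))
}

#' Linear no-threshold excess absolute risk (out-of-field)
#'
#' `EAR = delta * D * mu(age_x, age_a)` with `D` the mean organ dose —
#' appropriate in the low-dose out-of-field regime where the dose response
#' is linear without threshold.
#'
#' @param mean_dose Mean organ dose in Gy (>= 0, vectorised).
#' @inheritParams age_modifier
#' @return EAR per 10,000 person-years.
#' @examples
#' lung <- schneider_params("lung", 8.0, 0.002, 4.23, 0.042, 0.83)
#' ear_lnt(0.5, 55, 75, lung)  # about 5.6 per 10,000 PY
#' @export
ear_lnt <- function(mean_dose, age_x, age_a, params) {
  if (any(is.na(mean_dose)) || any(mean_dose < 0)) {
    stop("`mean_dose` must be non-negative", call. = FALSE)
  }
  params$delta * mean_dose * age_modifier(age_x, age_a, params)
}

#' Fraction-size-corrected linear-quadratic coefficient
#'
#' `alpha'(D) = alpha + beta * (d_T / D_T) * D`: the effective linear
#' coefficient at a point receiving total dose `D` when the prescription
#' delivers `d_T` per fraction to a total of `D_T`, so the local dose per
#' fraction scales proportionally with the local dose.
#'
#' @param point_dose Local total dose in Gy (>= 0, vectorised).
#' @param scheme A [fractionation()] object of the course.
#' @param params A [schneider_params()] object.
#' @return alpha' in Gy^-1.
#' @examples
#' lung <- schneider_params("lung", 8.0, 0.002, 4.23, 0.042, 0.83)
#' alpha_prime(10, fractionation(25, 2), lung)  # 0.0476
#' @export
alpha_prime <- function(point_dose, scheme, params) {
  if (!is_fractionation(scheme)) {
    stop("`scheme` must be a fractionation() object", call. = FALSE)
  }
  if (scheme$total_dose <= 0) {
    stop("prescribed total dose must be positive", call. = FALSE)
  }
  if (any(point_dose < 0)) {
    stop("`point_dose` must be non-negative", call. = FALSE)
  }
  params$alpha_lq +
    params$beta_lq * (scheme$dose_per_fraction / scheme$total_dose) * point_dose
}

#' Risk-equivalent dose
#'
#' Dose-response transform of the local dose accounting for cell killing and
#' inter-fraction repopulation/repair with capacity `R`:
#' `RED = exp(-a D) / (a R) * [1 - 2R + R^2 exp(a D) -
#' (1 - R)^2 exp(-a D R / (1 - R))]` with `a = alpha'`. Analytic limit forms
#' are substituted near the boundary: `R -> 0` gives the bell-shaped
#' cell-kill model `D exp(-a D)`, `R -> 1` the plateau model
#' `(1 - exp(-a D)) / a`. In the low-dose limit `RED -> D`, recovering the
#' linear no-threshold behaviour.
#'
#' @param point_dose Local total dose in Gy (>= 0, vectorised).
#' @param alpha_p alpha' in Gy^-1 (> 0; scalar or same length as
#'   `point_dose`).
#' @param repop Repopulation parameter R in [0, 1].
#' @return RED in Gy; always <= `point_dose`.
#' @examples
#' red(10, 0.0476, 0.83)  # about 7.0 Gy
#' @export
red <- function(point_dose, alpha_p, repop) {
  if (any(alpha_p <= 0)) stop("`alpha_p` must be positive", call. = FALSE)
  if (repop < 0 || repop > 1) stop("`repop` must lie in [0, 1]", call. = FALSE)
  if (any(point_dose < 0)) {
    stop("`point_dose` must be non-negative", call. = FALSE)
  }
  eps <- 1e-6
  ad <- alpha_p * point_dose
  if (repop <= eps) {
    return(point_dose * exp(-ad))
  }
  if (repop >= 1 - eps) {
    return((1 - exp(-ad)) / alpha_p)
  }
  r <- repop
  out <- exp(-ad) / (alpha_p * r) *
    (1 - 2 * r + r^2 * exp(ad) - (1 - r)^2 * exp(-ad * r / (1 - r)))
  out[point_dose == 0] <- 0   # exact zero, not floating-point residue
  out
}

#' Full-model excess absolute risk (in-field)
#'
#' Mechanistic in-field secondary-cancer risk:
#' `EAR = delta * mu * sum_i v_i * RED(D_i)` over the DVH of the summed
#' plan — the volume-weighted organ-equivalent dose multiplied by the
#' initial slope and the age modifier.
#'
#' For a single physical course, `alpha'` follows the fraction-size rule of
#' [alpha_prime()]. For a biologically summed plan (an EQD2 DVH from
#' [sum_courses()]), each course's contribution enters as
#' `alpha * BED_course`, which for the accumulated EQD2 dose collapses to a
#' local dose per fraction of exactly 2 Gy, i.e.
#' `alpha' = alpha * (1 + 2 / (alpha/beta))`; pass `scheme = "eqd2"` for
#' this pathway.
#'
#' @param x An `oar_dvh` of the (summed) plan.
#' @param scheme A [fractionation()] object of the delivering course, or the
#'   string `"eqd2"` when `x` is an EQD2-summed DVH.
#' @inheritParams age_modifier
#' @return EAR per 10,000 person-years.
#' @export
ear_full <- function(x, scheme, age_x, age_a, params) {
  check_dvh(x)
  if (identical(scheme, "eqd2")) {
    a_p <- params$alpha_lq + params$beta_lq * 2
    a_p <- rep(a_p, nrow(x))
  } else {
    a_p <- alpha_prime(x$dose_gy, scheme, params)
  }
  oed <- sum(x$volume * red(x$dose_gy, a_p, params$repop))
  params$delta * age_modifier(age_x, age_a, params) * oed
}
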