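#' Fractionation scheme of a radiotherapy course
#'
#' A course is characterised by its number of fractions and the physical dose
#' delivered per fraction; the total prescribed dose is derived as
#' `n_fractions * dose_per_fraction`.
#'
#' @param n_fractions Number of fractions (positive integer).
#' @param dose_per_fraction Dose per fraction in Gy (positive).
#' @return An object of class `fractionation` with fields `n_fractions`,
#'   `dose_per_fraction` and `total_dose` (Gy).
#' @examples
#' fractionation(25, 2)   # conventional 50 Gy whole-breast course
#' fractionation(2, 6)    # HDR brachytherapy boost
#' @export
fractionation <- function(n_fractions, dose_per_fraction) {
  if (length(n_fractions) != 1L || is.na(n_fractions) ||
      n_fractions < 1 || n_fractions != as.integer(n_fractions)) {
    stop("`n_fractions` must be a single positive integer", call. = FALSE)
  }
  if (length(dose_per_fraction) != 1L || is.na(dose_per_fraction) ||
      dose_per_fraction <= 0) {
    stop("`dose_per_fraction` must be a single positive dose in Gy",
         call. = FALSE)
  }
  structure(
    list(
      n_fractions = as.integer(n_fractions),
      dose_per_fraction = as.numeric(dose_per_fraction),
      total_dose = as.integer(n_fractions) * as.numeric(dose_per_fraction)
    ),
    class = "fractionation"
  )
}

#' @export
print.fractionation <- function(x, ...) {
  cat(sprintf("<fractionation> %d x %.4g Gy = %.4g Gy total\n",
              x$n_fractions, x$dose_per_fraction, x$total_dose))
  invisible(x)
}

is_fractionation <- function(x) inherits(x, "fractionation")

check_alpha_beta <- function(alpha_beta) {
  if (length(alpha_beta) != 1L || is.na(alpha_beta) || alpha_beta <= 0) {
    stop("`alpha_beta` must be a single positive dose ratio in Gy",
         call. = FALSE)
  }
  as.numeric(alpha_beta)
}

#' Biologically effective dose of a fractionated course
#'
#' Linear-quadratic BED, `n * d * (1 + d / (alpha/beta))`, for late-responding
#' tissue. High-dose-rate delivery is assumed, so no protracted-irradiation
#' correction is applied. When `total_dose` differs from the scheme's
#' prescribed total (e.g. an off-prescription voxel), the local dose per
#' fraction is re-derived as `total_dose / n_fractions` (proportional
#' fractionation: every voxel is treated in all fractions of the course).
#'
#' @param total_dose Physical total dose in Gy (vectorised, each >= 0).
#' @param scheme A [fractionation()] object giving the number of fractions.
#' @param alpha_beta The alpha/beta ratio in Gy; defaults to 3 Gy
#'   (late-responding normal tissue).
#' @return BED in Gy, same length as `total_dose`.
#' @examples
#' bed(50, fractionation(25, 2))  # 83.33 Gy
#' bed(12, fractionation(2, 6))   # 36 Gy
#' @seealso [eqd2()] for conversion to the 2-Gy-fraction equivalent dose.
#' @export
bed <- function(total_dose, scheme, alpha_beta = 3) {
  ab <- check_alpha_beta(alpha_beta)
  if (!is_fractionation(scheme)) {
    stop("`scheme` must be a fractionation() object", call. = FALSE)
  }
  if (any(is.na(total_dose)) || any(total_dose < 0)) {
    stop("`total_dose` must be non-negative", call. = FALSE)
  }
  d_local <- total_dose / scheme$n_fractions
  total_dose * (1 + d_local / ab)
}

#' Equivalent dose in 2-Gy fractions
#'
#' Converts a BED value to the total dose of the isoeffective course delivered
#' in 2-Gy fractions ("EQD2" or "BED2"): `bed / (1 + 2 / (alpha/beta))`. The
#' composition `eqd2(bed(D, scheme))` is the identity on `D` for any course
#' with 2 Gy per fraction.
#'
#' @param bed_value BED in Gy (vectorised, each >= 0).
#' @inheritParams bed
#' @return EQD2 in Gy.
#' @examples
#' eqd2(36)                             # 21.6 Gy
#' eqd2(bed(50, fractionation(25, 2)))  # 50 Gy: 2-Gy course maps to itself
#' @export
eqd2 <- function(bed_value, alpha_beta = 3) {
  ab <- check_alpha_beta(alpha_beta)
  if (any(is.na(bed_value)) || any(bed_value < 0)) {
    stop("`bed_value` must be non-negative", call. = FALSE)
  }
  bed_value / (1 + 2 / ab)
}
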