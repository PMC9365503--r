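#' Per-organ voxel dose distribution
#'
#' The package's stand-in for a treatment-planning-system dose grid restricted
#' to an organ mask: a vector of voxel doses with a uniform voxel volume and
#' the fractionation scheme of the course that delivered it. Voxel vectors
#' from different courses of the same patient are assumed pre-aligned (same
#' voxel order); no registration is attempted.
#'
#' @param organ Organ label, e.g. `"heart"`.
#' @param voxel_doses Numeric vector of per-voxel doses in Gy (all >= 0).
#' @param voxel_volume Uniform voxel volume in cm^3 (> 0).
#' @param scheme A [fractionation()] object, or `NULL` for a summed
#'   equivalent-dose distribution.
#' @param dose_type `"physical"` for a delivered course, `"eqd2"` for a
#'   biologically summed distribution expressed in 2-Gy-fraction equivalents.
#' @return An object of class `dose_distribution`.
#' @export
dose_distribution <- function(organ, voxel_doses, voxel_volume = 0.008,
                              scheme = NULL,
                              dose_type = c("physical", "eqd2")) {
  dose_type <- match.arg(dose_type)
  if (length(voxel_doses) == 0L) {
    stop("`voxel_doses` must be non-empty", call. = FALSE)
  }
  if (any(is.na(voxel_doses)) || any(voxel_doses < 0)) {
    stop("voxel doses must be non-negative", call. = FALSE)
  }
  if (length(voxel_volume) != 1L || is.na(voxel_volume) || voxel_volume <= 0) {
    stop("`voxel_volume` must be a single positive volume in cm^3",
         call. = FALSE)
  }
  if (!is.null(scheme) && !is_fractionation(scheme)) {
    stop("`scheme` must be a fractionation() object or NULL", call. = FALSE)
  }
  structure(
    list(
      organ = as.character(organ),
      voxel_doses = as.numeric(voxel_doses),
      voxel_volume = as.numeric(voxel_volume),
      scheme = scheme,
      dose_type = dose_type
    ),
    class = "dose_distribution"
  )
}

#' @export
print.dose_distribution <- function(x, ...) {
  cat(sprintf(
    "<dose_distribution> %s: %d voxels x %.4g cm^3, mean %.3g Gy (%s)\n",
    x$organ, length(x$voxel_doses), x$voxel_volume,
    mean(x$voxel_doses), x$dose_type))
  invisible(x)
}

#' @export
as_tibble.dose_distribution <- function(x, ...) {
  tibble::tibble(
    organ = x$organ,
    voxel = seq_along(x$voxel_doses),
    dose_gy = x$voxel_doses
  )
}

is_dose_distribution <- function(x) inherits(x, "dose_distribution")

#' Biologically weighted summation of treatment courses
#'
#' Sums two or more pre-aligned dose distributions of the same organ across
#' courses with different fractionation. Each voxel's per-course dose is
#' converted to BED under proportional fractionation (the local dose per
#' fraction is the voxel dose divided by the course's number of fractions),
#' the BEDs are added, and the result is reported as EQD2 so that plans with
#' mixed fractionation are compared on a common biological scale. Setting
#' `physical = TRUE` instead returns the plain voxelwise physical sum (used
#' on the secondary-cancer pathway where the fraction-size dependence is
#' handled inside the risk model).
#'
#' @param distributions List of [dose_distribution()] objects on a common
#'   voxel grid (same organ, voxel count and voxel volume).
#' @param alpha_beta Alpha/beta ratio in Gy (default 3, late effects).
#' @param physical If `TRUE`, sum physical dose voxelwise without biological
#'   weighting.
#' @return A [dose_distribution()] with `dose_type = "eqd2"` (or
#'   `"physical"`), `scheme = NULL`.
#' @examples
#' wbi <- dose_distribution("breast", rep(50, 10), scheme = fractionation(25, 2))
#' boost <- dose_distribution("breast", rep(12, 10), scheme = fractionation(2, 6))
#' sum_courses(list(wbi, boost))$voxel_doses[1]  # 71.6 Gy EQD2
#' @export
sum_courses <- function(distributions, alpha_beta = 3, physical = FALSE) {
  if (!is.list(distributions) || length(distributions) == 0L ||
      !all(vapply(distributions, is_dose_distribution, logical(1)))) {
    stop("`distributions` must be a non-empty list of dose_distribution objects",
         call. = FALSE)
  }
  ref <- distributions[[1]]
  for (d in distributions[-1]) {
    if (!identical(d$organ, ref$organ)) {
      stop("all distributions must belong to the same organ", call. = FALSE)
    }
    if (length(d$voxel_doses) != length(ref$voxel_doses) ||
        d$voxel_volume != ref$voxel_volume) {
      stop("voxel grids do not match (count or voxel volume differ)",
           call. = FALSE)
    }
  }
  if (physical) {
    total <- Reduce(`+`, lapply(distributions, `[[`, "voxel_doses"))
    return(dose_distribution(ref$organ, total, ref$voxel_volume,
                             scheme = NULL, dose_type = "physical") |>
             set_summed_physical())
  }
  bed_sum <- Reduce(`+`, lapply(distributions, function(d) {
    if (d$dose_type == "eqd2") {
      # an already-summed EQD2 distribution re-enters as a 2-Gy course
      return(d$voxel_doses * (1 + 2 / alpha_beta))
    }
    if (is.null(d$scheme)) {
      stop("all input courses must carry a fractionation scheme", call. = FALSE)
    }
    bed(d$voxel_doses, d$scheme, alpha_beta)
  }))
  dose_distribution(ref$organ, eqd2(bed_sum, alpha_beta), ref$voxel_volume,
                    scheme = NULL, dose_type = "eqd2")
}

# a physical sum of courses has no single scheme; flag it so downstream
# models that need fraction-size information refuse it explicitly
set_summed_physical <- function(x) {
  x$summed <- TRUE
  x
}
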