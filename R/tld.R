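#' TLD measurement set for one organ and plan
#'
#' Point-dose readings from thermoluminescent dosimeters placed in an
#' anthropomorphic phantom (nominally five chips per organ at risk) for a
#' single delivered plan, together with background readings from chips kept
#' outside the treatment room (nominally three) and the number of fractions
#' needed to scale a per-plan reading to the full course.
#'
#' @param organ Organ label.
#' @param scenario Treatment-scenario label.
#' @param breast_size `"small"` or `"large"` phantom breast attachment.
#' @param readings Per-TLD absorbed dose per delivered plan in Gy.
#' @param background Background TLD readings in Gy.
#' @param n_fractions Number of fractions of the full course.
#' @return An object of class `tld_set`.
#' @export
tld_set <- function(organ, scenario, breast_size, readings, background,
                    n_fractions) {
  if (length(readings) == 0L || length(background) == 0L) {
    stop("`readings` and `background` must be non-empty", call. = FALSE)
  }
  if (any(readings < 0) || any(background < 0)) {
    stop("TLD readings must be non-negative", call. = FALSE)
  }
  if (n_fractions < 1 || n_fractions != as.integer(n_fractions)) {
    stop("`n_fractions` must be a positive integer", call. = FALSE)
  }
  structure(
    list(organ = as.character(organ), scenario = as.character(scenario),
         breast_size = as.character(breast_size),
         readings = as.numeric(readings),
         background = as.numeric(background),
         n_fractions = as.integer(n_fractions)),
    class = "tld_set"
  )
}

#' Mean organ dose from TLD readings
#'
#' Background correction and fraction scaling: the mean background reading
#' is subtracted from each chip reading, the net per-plan readings are
#' scaled by the number of fractions, and their mean is the full-course
#' mean organ dose. Negative net readings are floored at zero with a
#' warning (absorbed dose cannot be negative). Per-chip full-course values
#' with their SD and range are returned alongside for reporting.
#'
#' @param m A [tld_set()].
#' @param exclude Optional integer indices of chips to drop (e.g. a chip
#'   found to sit barely in-field); at least one reading must remain.
#' @return A one-row tibble: `organ`, `scenario`, `breast_size`, `n_tld`,
#'   `mean_dose_gy` (full course), `sd_gy`, `min_gy`, `max_gy`, and
#'   `per_tld_gy` (list column of per-chip full-course doses).
#' @examples
#' m <- tld_set("heart", "imrt_brachy", "small",
#'              readings = rep(0.044, 5), background = rep(0.004, 3),
#'              n_fractions = 25)
#' mean_organ_dose(m)$mean_dose_gy  # 1 Gy
#' @export
mean_organ_dose <- function(m, exclude = integer(0)) {
  if (!inherits(m, "tld_set")) stop("`m` must be a tld_set", call. = FALSE)
  readings <- m$readings
  if (length(exclude)) {
    if (any(exclude < 1) || any(exclude > length(readings))) {
      stop("`exclude` indices out of range", call. = FALSE)
    }
    readings <- readings[-exclude]
    if (length(readings) == 0L) {
      stop("cannot exclude every reading", call. = FALSE)
    }
  }
  bg <- mean(m$background)
  net <- readings - bg
  if (any(net < 0)) {
    warning(sprintf(
      "%d net TLD reading(s) below background were floored at 0 (%s/%s)",
      sum(net < 0), m$organ, m$scenario), call. = FALSE)
    net <- pmax(net, 0)
  }
  per_tld <- net * m$n_fractions
  tibble::tibble(
    organ = m$organ, scenario = m$scenario, breast_size = m$breast_size,
    n_tld = length(per_tld),
    mean_dose_gy = mean(per_tld),
    sd_gy = stats::sd(per_tld),
    min_gy = min(per_tld), max_gy = max(per_tld),
    per_tld_gy = list(per_tld)
  )
}

#' Mean organ dose excluding flagged chips
#'
#' Convenience wrapper around [mean_organ_dose()] for the with/without
#' outlier comparison (e.g. one ipsilateral-lung chip located barely
#' in-field).
#'
#' @inheritParams mean_organ_dose
#' @param exclude_indices Integer indices of the chips to exclude.
#' @return Same layout as [mean_organ_dose()].
#' @export
outlier_excluded_mean <- function(m, exclude_indices) {
  mean_organ_dose(m, exclude = exclude_indices)
}

#' Build TLD sets from a readings table
#'
#' Splits a long readings table (the [read_tld_readings()] layout) into one
#' [tld_set()] per organ, pairing measurement rows with the background rows
#' of the same scenario and breast size.
#'
#' @param readings Tibble with columns `scenario`, `breast_size`, `organ`,
#'   `tld_id`, `reading_gy`, `is_background`.
#' @param n_fractions Number of fractions of the full course.
#' @return A list of `tld_set` objects keyed by organ.
#' @export
tld_sets_from_table <- function(readings, n_fractions) {
  bg <- readings$reading_gy[readings$is_background]
  meas <- readings[!readings$is_background, ]
  sets <- lapply(split(meas, meas$organ), function(df) {
    tld_set(df$organ[1], df$scenario[1], df$breast_size[1],
            df$reading_gy, bg, n_fractions)
  })
  sets
}

#' Photoneutron dose order-of-magnitude estimate
#'
#' Chain estimate of the total neutron dose from the high-energy (18 MV)
#' portion of a plan: the 18-MV dose share, times a neutron dose coefficient
#' (mSv of neutron dose per Gy of 18-MV photon dose), scaled up by the
#' monitor-unit factor of IMRT relative to 3D-CRT and corrected down by the
#' relative photoneutron emission of the linac model in use. The final
#' fraction of prescription treats mSv and mGy as numerically equal — an
#' order-of-magnitude comparison only.
#'
#' @param prescribed_dose Prescribed total dose in Gy.
#' @param fraction_18mv Fraction of the plan dose delivered at 18 MV, in
#'   [0, 1].
#' @param neutron_coeff Neutron dose coefficient in mSv per Gy (default 4).
#' @param imrt_mu_factor IMRT-to-3D-CRT fluence factor (default 3).
#' @param linac_emission_ratio Photoneutron emission ratio of the reference
#'   linac to the local machine (default 2.5).
#' @return A one-row tibble: `dose_18mv_gy`, `neutron_3dcrt_msv`,
#'   `neutron_imrt_raw_msv`, `neutron_imrt_corrected_msv`,
#'   `fraction_of_prescription`.
#' @examples
#' neutron_estimate(60, 0.2)  # 12 Gy -> 48 -> 144 -> 57.6 mSv, about 1 permille
#' @export
neutron_estimate <- function(prescribed_dose, fraction_18mv,
                             neutron_coeff = 4, imrt_mu_factor = 3,
                             linac_emission_ratio = 2.5) {
  if (prescribed_dose <= 0 || neutron_coeff <= 0 || imrt_mu_factor <= 0 ||
      linac_emission_ratio <= 0) {
    stop("all estimate inputs must be positive", call. = FALSE)
  }
  if (fraction_18mv < 0 || fraction_18mv > 1) {
    stop("`fraction_18mv` must lie in [0, 1]", call. = FALSE)
  }
  dose_18mv <- fraction_18mv * prescribed_dose
  n_3dcrt <- neutron_coeff * dose_18mv
  n_imrt_raw <- imrt_mu_factor * n_3dcrt
  n_imrt_corr <- n_imrt_raw / linac_emission_ratio
  tibble::tibble(
    dose_18mv_gy = dose_18mv,
    neutron_3dcrt_msv = n_3dcrt,
    neutron_imrt_raw_msv = n_imrt_raw,
    neutron_imrt_corrected_msv = n_imrt_corr,
    fraction_of_prescription = (n_imrt_corr / 1000) / prescribed_dose
  )
}
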