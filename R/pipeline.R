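#' Default organ-to-risk-model routing
#'
#' In-field organs (ipsilateral lung; the heart for its mean-dose ERR) are
#' assessed on the planned summed dose distribution with the mechanistic
#' in-field secondary-cancer model; organs essentially outside the treatment
#' fields (contralateral lung and breast) use the linear no-threshold model
#' on the mean organ dose. The `schneider_organ` column maps each organ at
#' risk to the parameter organ of the secondary-cancer registry; `NA` means
#' no secondary-cancer estimate is made for that organ.
#'
#' @return A tibble with columns `organ`, `route`, `schneider_organ`.
#' @export
organ_routing <- function() {
  tibble::tibble(
    organ = c("heart", "lung_ipsi", "lung_contra", "breast_contra"),
    route = c("in_field", "in_field", "out_of_field", "out_of_field"),
    schneider_organ = c(NA, "lung", "lung", "breast")
  )
}

#' Per-patient, per-organ risk profile
#'
#' Composes the full modelling chain for one patient: biologically weighted
#' course summation, DVH construction and dose metrics, equivalent uniform
#' dose and LKB NTCP for the lung endpoints, secondary-cancer excess
#' absolute risk routed per organ (mechanistic in-field model on the
#' EQD2-summed DVH; linear no-threshold model on the mean organ dose
#' out-of-field), and the linear cardiac excess relative risk from the mean
#' heart dose. A `whole_lung` record is derived by pooling the two lung
#' distributions. Dose metrics, out-of-field mean doses and the cardiac ERR
#' use the physical dose sum; NTCP and the in-field secondary-cancer model
#' use the biologically accumulated EQD2 sum.
#'
#' @param patient Tibble with columns `organ`, `course`, `distribution`
#'   (one patient's rows from [generate_patient()] or equivalent).
#' @param age_x Age at exposure in years (default 55).
#' @param age_a Attained ages in years (default 75 and 95).
#' @param lkb LKB registry tibble, see [lkb_registry()].
#' @param schneider Schneider registry tibble, see [schneider_registry()].
#' @param routing Organ routing table, see [organ_routing()].
#' @param tld_mean_doses Optional named vector of measured full-course mean
#'   organ doses in Gy; overrides the distribution mean for out-of-field
#'   organs (the measured dose is the better estimate there).
#' @param alpha_beta Alpha/beta ratio in Gy (default 3).
#' @param bin_width DVH bin width in Gy (default 0.1).
#' @return A tibble with one row per organ (plus `whole_lung`): dose
#'   metrics, `eud_gy`, NTCP per endpoint (percent), `ear_10kpy_a<age>`
#'   (per 10,000 person-years, one column per attained age) and `err_pct`
#'   (heart only). Organs absent from the input are simply absent from the
#'   output, not imputed.
#' @export
patient_risk_profile <- function(patient, age_x = 55, age_a = c(75, 95),
                                 lkb = lkb_registry(),
                                 schneider = schneider_registry(),
                                 routing = organ_routing(),
                                 tld_mean_doses = NULL,
                                 alpha_beta = 3, bin_width = 0.1) {
  stopifnot(all(c("organ", "course", "distribution") %in% names(patient)))
  organs <- sort(unique(patient$organ))
  summed <- lapply(stats::setNames(organs, organs), function(org) {
    dists <- patient$distribution[patient$organ == org]
    list(
      eqd2 = sum_courses(dists, alpha_beta = alpha_beta),
      physical = sum_courses(dists, physical = TRUE)
    )
  })
  if (all(c("lung_ipsi", "lung_contra") %in% organs)) {
    summed$whole_lung <- list(
      eqd2 = pool_distributions(
        list(summed$lung_ipsi$eqd2, summed$lung_contra$eqd2), "whole_lung"),
      physical = pool_distributions(
        list(summed$lung_ipsi$physical, summed$lung_contra$physical),
        "whole_lung")
    )
  }
  sympt <- lkb_from_registry("symptomatic_pneumonitis", lkb)
  radg2 <- lkb_from_registry("radiation_pneumonitis_g2", lkb)

  purrr::map_dfr(names(summed), function(org) {
    s <- summed[[org]]
    dvh_eqd2 <- dvh_from_distribution(s$eqd2, bin_width)
    mean_physical <- mean(s$physical$voxel_doses)
    route <- routing$route[match(org, routing$organ)]
    sch_org <- routing$schneider_organ[match(org, routing$organ)]
    row <- dose_metrics(dvh_from_distribution(s$physical, bin_width),
                        v_at = 20, d_at = 1)
    row$route <- route %|NA|% "derived"

    # NTCP: lung endpoints on the EQD2-summed DVH
    if (org %in% c("lung_ipsi", "whole_lung")) {
      row$eud_gy <- eud(dvh_eqd2, sympt$n_volume)
      row$ntcp_pct_symptomatic <- 100 * ntcp_from_dvh(dvh_eqd2, sympt)
    } else {
      row$eud_gy <- NA_real_
      row$ntcp_pct_symptomatic <- NA_real_
    }
    row$ntcp_pct_radiation_g2 <- if (org == "whole_lung")
      100 * ntcp_from_dvh(dvh_eqd2, radg2) else NA_real_

    # secondary cancer, routed
    for (aa in age_a) {
      col <- sprintf("ear_10kpy_a%d", aa)
      row[[col]] <- if (is.na(sch_org) || is.na(route)) {
        NA_real_
      } else {
        pars <- schneider_from_registry(sch_org, schneider, alpha_beta)
        if (route == "in_field") {
          ear_full(dvh_eqd2, "eqd2", age_x, aa, pars)
        } else {
          d <- unname(tld_mean_doses[org])
          if (length(d) == 0L || is.na(d)) d <- mean_physical
          ear_lnt(d, age_x, aa, pars)
        }
      }
    }

    row$err_pct <- if (org == "heart") 100 * err_mce(mean_physical)
      else NA_real_
    row
  })
}

`%|NA|%` <- function(x, y) if (length(x) == 0L || is.na(x)) y else x

#' Risk profiles for a whole synthetic study
#'
#' Maps [patient_risk_profile()] over every patient of a generated dataset.
#'
#' @param cohort The `doses` tibble of [generate_cohorts()] (columns
#'   `scenario`, `patient_id`, `organ`, `course`, `distribution`).
#' @param ... Passed on to [patient_risk_profile()].
#' @return A tibble: one row per scenario x patient x organ.
#' @export
cohort_risk_profiles <- function(cohort, ...) {
  cohort |>
    dplyr::group_by(.data$scenario, .data$patient_id) |>
    dplyr::group_modify(function(df, key) patient_risk_profile(df, ...)) |>
    dplyr::ungroup()
}

#' Normality-gated two-sample comparison
#'
#' Shapiro-Wilk normality check at the 0.05 level on each group: if both
#' pass, a Welch two-sample t-test is used; otherwise a two-sided
#' Mann-Whitney U test (normal approximation with tie and continuity
#' correction). Groups with essentially constant values cannot be assessed
#' for normality and fall back to the Mann-Whitney branch with a warning.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 3).
#' @param alpha Significance level for the reported `significant` flag
#'   (default 0.05).
#' @return A one-row tibble: `test` (`"welch_t"` or `"mann_whitney"`),
#'   `statistic`, `p_value`, `significant`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) < 3 || length(values_b) < 3) {
    stop("each group needs at least 3 observations", call. = FALSE)
  }
  normal_p <- function(x) {
    tryCatch(stats::shapiro.test(x)$p.value,
             error = function(e) {
               warning("group is (near-)constant; using Mann-Whitney U",
                       call. = FALSE)
               0
             })
  }
  both_normal <- normal_p(values_a) > 0.05 && normal_p(values_b) > 0.05
  if (both_normal) {
    ht <- stats::t.test(values_a, values_b, var.equal = FALSE)
    test <- "welch_t"
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(values_a, values_b, exact = FALSE, correct = TRUE))
    test <- "mann_whitney"
  }
  tibble::tibble(
    test = test,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    significant = ht$p.value < alpha,
    n_a = length(values_a), n_b = length(values_b)
  )
}

#' Sample-size-weighted pooling of group means
#'
#' `sum(n_i * mean_i) / sum(n_i)` — used to combine scenario means into
#' technique-level (IMRT vs 3D-CRT) or boost-level (brachytherapy vs
#' teletherapy) averages.
#'
#' @param means Numeric vector of group means.
#' @param ns Integer vector of group sizes (same length, all >= 1).
#' @return The pooled mean. Equals the plain mean of the concatenated
#'   per-patient values when those all exist.
#' @examples
#' pooled_mean(c(54, 56), c(10, 10))  # 55
#' @export
pooled_mean <- function(means, ns) {
  if (length(means) == 0L || length(means) != length(ns)) {
    stop("`means` and `ns` must be non-empty and equal length", call. = FALSE)
  }
  if (any(ns < 1)) stop("all group sizes must be >= 1", call. = FALSE)
  sum(ns * means) / sum(ns)
}

#' Boxplot-style group summary
#'
#' Per-group descriptive statistics in the convention of the study's
#' boxplots: quartiles, whiskers at the most extreme values within 1.5 times
#' the interquartile range of the box, and the values beyond them flagged as
#' outliers.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to summarise.
#' @param group Name of the grouping column.
#' @return A tibble: one row per group with `n`, `mean`, `sd`, `min`, `q1`,
#'   `median`, `q3`, `max`, `whisker_lo`, `whisker_hi` and `outliers`
#'   (list column).
#' @export
cohort_summary <- function(data, value, group) {
  vals <- data[[value]]
  grp <- data[[group]]
  purrr::map_dfr(split(vals, grp), function(x) {
    x <- x[!is.na(x)]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    iqr <- q[3] - q[1]
    in_lo <- x[x >= q[1] - 1.5 * iqr]
    in_hi <- x[x <= q[3] + 1.5 * iqr]
    tibble::tibble(
      n = length(x), mean = mean(x), sd = stats::sd(x),
      min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
      whisker_lo = min(in_lo), whisker_hi = max(in_hi),
      outliers = list(x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr])
    )
  }, .id = group)
}

#' Format "mean +/- SD (min - max)" report cells
#'
#' @param x Numeric vector.
#' @param digits Decimals (1 for doses, percentages and ERR; 0 for EAR per
#'   10,000 PY).
#' @return A single formatted string, e.g. `"4.5 ± 1.3 (3.3 – 7.9)"`.
#' @export
format_cell <- function(x, digits = 1) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  f <- function(v) formatC(v, format = "f", digits = digits)
  sprintf("%s ± %s (%s – %s)",
          f(mean(x)), f(stats::sd(x)), f(min(x)), f(max(x)))
}

#' Report tables for a computed study
#'
#' Aggregates per-patient risk profiles into the study's report tables:
#' dose statistics, secondary-cancer EAR, and NTCP/ERR per scenario, each
#' cell formatted as "mean +/- SD (min - max)", plus a long table of all
#' pairwise scenario comparisons per quantity (raw p-values from the
#' normality-gated test and a Holm-adjusted column as a clearly labelled
#' extension). Ordering is deterministic: scenarios and organs in the input
#' order of first appearance, comparisons alphabetical.
#'
#' @param profiles Output of [cohort_risk_profiles()].
#' @param tld Optional long tibble of TLD-derived organ doses with columns
#'   `scenario`, `breast_size`, `organ`, `mean_dose_gy` for the TLD dose
#'   table.
#' @return A list of tibbles: `dose_stats`, `ear`, `ntcp_err`,
#'   `pairwise_tests`, and `tld_doses` (if `tld` given).
#' @export
build_report <- function(profiles, tld = NULL) {
  if (nrow(profiles) == 0L) stop("no computed profiles", call. = FALSE)
  scen_order <- unique(profiles$scenario)
  organ_order <- unique(profiles$organ)
  profiles <- profiles |>
    dplyr::mutate(scenario = factor(.data$scenario, levels = scen_order),
                  organ = factor(.data$organ, levels = organ_order))

  cell_table <- function(col, digits) {
    profiles |>
      dplyr::filter(!is.na(.data[[col]])) |>
      dplyr::group_by(.data$organ, .data$scenario) |>
      dplyr::summarise(cell = format_cell(.data[[col]], digits),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "scenario", values_from = "cell") |>
      dplyr::mutate(quantity = col, .after = "organ")
  }
  ear_cols <- grep("^ear_10kpy_", names(profiles), value = TRUE)
  dose_stats <- dplyr::bind_rows(
    cell_table("d_mean_gy", 1),
    cell_table("v_20gy_pct", 1),
    cell_table("d_1pct_gy", 1)
  )
  ear <- dplyr::bind_rows(lapply(ear_cols, cell_table, digits = 0))
  ntcp_err <- dplyr::bind_rows(
    cell_table("ntcp_pct_symptomatic", 1),
    cell_table("ntcp_pct_radiation_g2", 1),
    cell_table("err_pct", 1)
  )

  quantities <- c("d_mean_gy", ear_cols, "ntcp_pct_symptomatic",
                  "ntcp_pct_radiation_g2", "err_pct")
  pairs <- utils::combn(sort(as.character(scen_order)), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(quantities, function(q) {
    purrr::map_dfr(as.character(unique(profiles$organ)), function(org) {
      sub <- profiles[profiles$organ == org & !is.na(profiles[[q]]), ]
      if (nrow(sub) == 0L) return(NULL)
      purrr::map_dfr(pairs, function(p) {
        a <- sub[[q]][sub$scenario == p[1]]
        b <- sub[[q]][sub$scenario == p[2]]
        if (length(a) < 3 || length(b) < 3) return(NULL)
        res <- suppressWarnings(compare_groups(a, b))
        dplyr::bind_cols(
          tibble::tibble(quantity = q, organ = org,
                         group_a = p[1], group_b = p[2]), res)
      })
    })
  })
  if (nrow(pairwise) > 0L) {
    pairwise <- pairwise |>
      dplyr::group_by(.data$quantity, .data$organ) |>
      dplyr::mutate(p_holm = stats::p.adjust(.data$p_value, "holm")) |>
      dplyr::ungroup()
  }
  out <- list(dose_stats = dose_stats, ear = ear, ntcp_err = ntcp_err,
              pairwise_tests = pairwise)
  if (!is.null(tld)) {
    out$tld_doses <- tld |>
      dplyr::group_by(.data$organ, .data$breast_size, .data$scenario) |>
      dplyr::summarise(cell = format_cell(.data$mean_dose_gy, 1),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "scenario", values_from = "cell")
  }
  structure(out, class = "oar_report")
}

#' Write report tables to disk
#'
#' @param report An `oar_report` from [build_report()].
#' @param dir Output directory.
#' @param format `"csv"` or `"json"`.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "json")) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(report)) {
    tab <- report[[nm]]
    if (!is.data.frame(tab)) next
    if (format == "csv") {
      tab <- dplyr::select(tab, -dplyr::any_of("outliers"))
      readr::write_csv(tab, file.path(dir, paste0(nm, ".csv")))
    } else {
      jsonlite::write_json(tab, file.path(dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
  }
  invisible(dir)
}

#' Boxplot of a risk quantity across scenarios
#'
#' @param profiles Output of [cohort_risk_profiles()].
#' @param value Column to plot (e.g. `"ntcp_pct_symptomatic"`).
#' @param organ Organ to restrict to.
#' @return A ggplot object in the study's boxplot convention (box = IQR,
#'   whiskers at 1.5 IQR, mean marked as a point).
#' @export
plot_cohort <- function(profiles, value, organ) {
  df <- profiles[profiles$organ == organ & !is.na(profiles[[value]]), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario,
                                   y = .data[[value]])) +
    ggplot2::geom_boxplot(coef = 1.5, outlier.shape = 4) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 21,
                          fill = "black") +
    ggplot2::labs(x = NULL, y = value, title = organ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
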