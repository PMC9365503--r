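#' Load the scenario calibration configuration
#'
#' Reads the YAML file that defines the four treatment scenarios (whole-breast
#' and boost fractionation, cohort sizes, per-organ mean-dose targets with
#' their risk-model routing, boost dose shares, and TLD dose targets per
#' phantom breast size) together with the generator settings (voxel count,
#' mixture-component parameters, TLD noise model). The bundled file
#' transcribes published cohort statistics for the four scenarios; edit a
#' copy to change the emulated study conditions without touching code.
#'
#' @param path Path to a calibration YAML; default the bundled file.
#' @return A list with elements `generator` and `scenarios`.
#' @export
scenario_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "scenario_calibration.yaml",
                        package = "oarrisk")
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenarios) || is.null(cfg$generator)) {
    stop("calibration file must define `generator` and `scenarios`",
         call. = FALSE)
  }
  cfg
}

#' Scenario specification
#'
#' Resolves one named scenario from a calibration configuration into the
#' object consumed by the generators.
#'
#' @param name One of the scenario names in the configuration (bundled:
#'   `"imrt_brachy"`, `"imrt_sib"`, `"3dcrt_brachy"`, `"3dcrt_seq"`).
#' @param config A [scenario_config()] list.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name, config = scenario_config()) {
  sc <- config$scenarios[[name]]
  if (is.null(sc)) {
    stop(sprintf("unknown scenario '%s'; available: %s", name,
                 paste(names(config$scenarios), collapse = ", ")),
         call. = FALSE)
  }
  organs <- purrr::map_dfr(names(sc$organs), function(org) {
    o <- sc$organs[[org]]
    tibble::tibble(organ = org, dmean_mean = o$dmean_mean,
                   dmean_sd = o$dmean_sd, route = o$route)
  })
  if (any(organs$dmean_mean <= 0) || any(organs$dmean_sd < 0)) {
    stop("organ mean-dose targets must be positive", call. = FALSE)
  }
  structure(
    list(
      name = name,
      label = sc$label %||% name,
      wbi_scheme = fractionation(sc$wbi$n_fractions, sc$wbi$dose_per_fraction),
      boost_scheme = fractionation(sc$boost$n_fractions,
                                   sc$boost$dose_per_fraction),
      boost_type = sc$boost$type,
      cohort_size = sc$cohort_size,
      boost_oar_share = sc$boost_oar_share,
      organs = organs,
      tld = sc$tld,
      generator = config$generator
    ),
    class = "scenario_spec"
  )
}

# deterministic sub-seed from a base seed and integer keys; stays below 2^31
mix_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 69069 + as.numeric(k)) %% 2147483647
  }
  as.integer(h)
}

scenario_index <- function(name) {
  match(name, c("imrt_brachy", "imrt_sib", "3dcrt_brachy", "3dcrt_seq"),
        nomatch = 97L + (utf8ToInt(substr(name, 1, 1)) %% 19L))
}

# mean of an exponential truncated at `cap` whose untruncated mean is `m`
trunc_exp_mean <- function(m, cap) {
  e <- exp(-cap / m)
  m - cap * e / (1 - e)
}

# sample an exponential truncated at `cap`, calibrated so the truncated mean
# equals `target`
r_trunc_exp <- function(n, target, cap) {
  if (n == 0L) return(numeric(0))
  if (target <= 0) return(rep(0, n))
  if (target >= cap / 2) {
    # truncation can push the achievable mean no higher than cap/2-ish;
    # fall back to a uniform with the right mean
    return(stats::runif(n, 0, min(2 * target, cap)))
  }
  m <- tryCatch(
    stats::uniroot(function(m) trunc_exp_mean(m, cap) - target,
                   lower = target, upper = cap * 50, tol = 1e-10)$root,
    error = function(e) target
  )
  u <- stats::runif(n, 0, stats::pexp(cap, rate = 1 / m))
  stats::qexp(u, rate = 1 / m)
}

# voxel doses for one course of one organ: three-component mixture with
# expected mean `target` given course prescription `presc`
sample_course_doses <- function(n, target, presc, route, gen, organ) {
  cap <- gen$penumbra_lo * presc
  if (route == "out_of_field") {
    return(r_trunc_exp(n, target, cap))
  }
  mix <- gen$organ_mixture[[organ]]
  if (is.null(mix)) {
    stop(sprintf("no mixture parameters configured for in-field organ '%s'",
                 organ), call. = FALSE)
  }
  f_p <- mix$penumbra_fraction
  m_o <- trunc_exp_mean(mix$out_of_field_mean_gy, cap)
  pen_mean <- (gen$penumbra_lo + gen$penumbra_hi) / 2 * presc
  f_i <- (target - f_p * pen_mean - (1 - f_p) * m_o) / (presc - m_o)
  if (f_i < 0) {
    f_i <- 0
    f_p <- if (target > m_o) (target - m_o) / (pen_mean - m_o) else 0
  }
  if (f_p == 0 && f_i == 0) {
    return(r_trunc_exp(n, target, cap))
  }
  if (f_i + f_p > 1) {
    stop(sprintf(
      "infeasible dose model for '%s': required in-field fraction %.2f",
      organ, f_i), call. = FALSE)
  }
  u <- stats::runif(n)
  comp <- ifelse(u < f_i, 1L, ifelse(u < f_i + f_p, 2L, 3L))
  doses <- numeric(n)
  n1 <- sum(comp == 1L); n2 <- sum(comp == 2L); n3 <- sum(comp == 3L)
  w <- gen$in_field_rel_width
  doses[comp == 1L] <- stats::runif(n1, presc * (1 - w), presc * (1 + w))
  doses[comp == 2L] <- stats::runif(n2, gen$penumbra_lo * presc,
                                    gen$penumbra_hi * presc)
  doses[comp == 3L] <- r_trunc_exp(n3, trunc_exp_mean(
    mix$out_of_field_mean_gy, cap), cap)
  doses
}

#' Generate one synthetic patient
#'
#' Draws per-organ, per-course voxel dose distributions for one patient of a
#' scenario. Each organ's summed mean dose is drawn from the scenario's
#' configured target distribution; the voxel vector is an exchangeable
#' three-component mixture (in-field near the prescription, penumbra between
#' 20% and 80% of it, and an out-of-field exponential tail) whose expected
#' mean matches the draw. Brachytherapy boost courses contribute only a
#' short-range exponential tail to the organs at risk; a simultaneously
#' integrated boost adds no separate course. Voxel vectors are exchangeable
#' draws calibrated at DVH level: no spatial structure is modelled, since
#' all downstream models consume DVHs or mean doses. Reproducible given
#' `(seed, patient_id)`: sub-seeds are derived per (scenario, patient,
#' organ).
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer base seed.
#' @param patient_id Patient index within the cohort.
#' @return A tibble with columns `scenario`, `patient_id`, `organ`, `course`
#'   (`"wbi"` or `"boost"`) and `distribution` (list column of
#'   [dose_distribution()] objects).
#' @export
generate_patient <- function(spec, seed, patient_id = 1L) {
  if (!inherits(spec, "scenario_spec")) {
    stop("`spec` must be a scenario_spec", call. = FALSE)
  }
  gen <- spec$generator
  n_vox <- gen$voxel_count
  sib <- identical(spec$boost_type, "sib")
  rows <- purrr::map_dfr(seq_len(nrow(spec$organs)), function(i) {
    org <- spec$organs$organ[i]
    route <- spec$organs$route[i]
    sub <- mix_seed(seed, scenario_index(spec$name), patient_id, i)
    withr::with_seed(sub, {
      # patient-level summed mean-dose target, truncated at zero
      t_total <- -1
      while (t_total <= 0) {
        t_total <- stats::rnorm(1, spec$organs$dmean_mean[i],
                                spec$organs$dmean_sd[i])
      }
      share <- if (sib) 0 else spec$boost_oar_share
      t_wbi <- (1 - share) * t_total
      doses_wbi <- sample_course_doses(
        n_vox, t_wbi, spec$wbi_scheme$total_dose, route, gen, org)
      out <- tibble::tibble(
        scenario = spec$name, patient_id = as.integer(patient_id),
        organ = org, course = "wbi",
        distribution = list(dose_distribution(
          org, doses_wbi, gen$voxel_volume_cm3, spec$wbi_scheme))
      )
      if (!sib) {
        boost_route <- if (identical(spec$boost_type, "brachy"))
          "out_of_field" else route
        doses_boost <- sample_course_doses(
          n_vox, share * t_total, spec$boost_scheme$total_dose,
          boost_route, gen, org)
        out <- dplyr::bind_rows(out, tibble::tibble(
          scenario = spec$name, patient_id = as.integer(patient_id),
          organ = org, course = "boost",
          distribution = list(dose_distribution(
            org, doses_boost, gen$voxel_volume_cm3, spec$boost_scheme))
        ))
      }
      out
    })
  })
  rows
}

#' Generate the full synthetic study dataset
#'
#' Iterates [generate_patient()] over all scenarios of a configuration with
#' the given (or configured) cohort sizes, and optionally writes the dataset
#' to disk as per-course dose-distribution CSV files plus a JSON manifest.
#'
#' @param config A [scenario_config()] list.
#' @param seed Integer base seed.
#' @param sizes Optional named integer vector of cohort sizes overriding the
#'   configured ones.
#' @param out_dir Optional directory to write the dataset into.
#' @return A list with `doses` (tibble as in [generate_patient()], all
#'   patients) and `manifest` (generator name, seed, sizes and a content
#'   hash; identical seed and configuration give an identical hash).
#' @export
generate_cohorts <- function(config = scenario_config(), seed = 1L,
                             sizes = NULL, out_dir = NULL) {
  scen_names <- names(config$scenarios)
  specs <- lapply(scen_names, scenario_spec, config = config)
  names(specs) <- scen_names
  if (is.null(sizes)) {
    sizes <- vapply(specs, `[[`, numeric(1), "cohort_size")
  } else {
    if (is.null(names(sizes)) || !all(scen_names %in% names(sizes))) {
      stop("`sizes` must be named by scenario", call. = FALSE)
    }
    sizes <- sizes[scen_names]
  }
  doses <- purrr::map_dfr(scen_names, function(nm) {
    purrr::map_dfr(seq_len(sizes[[nm]]), function(p) {
      generate_patient(specs[[nm]], seed, p)
    })
  })
  manifest <- list(
    generator = "oarrisk-mixture-v1",
    seed = as.integer(seed),
    cohort_sizes = as.list(stats::setNames(as.integer(sizes), scen_names)),
    n_patients = sum(sizes),
    hash = rlang::hash(lapply(doses$distribution, `[[`, "voxel_doses"))
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    purrr::pwalk(doses, function(scenario, patient_id, organ, course,
                                 distribution) {
      fn <- file.path(out_dir, sprintf("%s_p%02d_%s_%s.csv",
                                       scenario, patient_id, organ, course))
      write_dose_distribution(distribution, fn)
    })
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(doses = doses, manifest = manifest)
}

#' Generate synthetic TLD readings for one scenario and breast size
#'
#' Emulates a phantom measurement session: five chip readings per organ drawn
#' around the configured per-fraction organ dose plus ambient background,
#' with multiplicative log-normal noise (unit mean, default CV 10%), and
#' three background readings around the ambient level. Optionally injects a
#' "barely in-field" outlier chip into the ipsilateral-lung readings.
#'
#' @param spec A [scenario_spec()].
#' @param breast_size `"small"` or `"large"`.
#' @param seed Integer base seed.
#' @param noise_cv Coefficient of variation of the reading noise; default
#'   from the configuration.
#' @param outlier If `TRUE`, one ipsilateral-lung reading is multiplied by
#'   the configured outlier factor.
#' @return A tibble in the [read_tld_readings()] layout (one row per chip,
#'   background rows flagged), with the full-course fraction count in
#'   attribute `n_fractions`.
#' @export
generate_tld_readings <- function(spec, breast_size = c("small", "large"),
                                  seed = 1L, noise_cv = NULL,
                                  outlier = FALSE) {
  breast_size <- match.arg(breast_size)
  gen <- spec$generator
  cv <- noise_cv %||% gen$tld_noise_cv
  targets <- spec$tld[[breast_size]]
  n_frac <- spec$wbi_scheme$n_fractions +
    (if (identical(spec$boost_type, "sib")) 0L else spec$boost_scheme$n_fractions)
  bg <- gen$tld_background_gy
  noise <- function(n) {
    if (cv <= 0) return(rep(1, n))
    s <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)   # unit expectation
  }
  sub <- mix_seed(seed, scenario_index(spec$name),
                  if (breast_size == "small") 1L else 2L)
  withr::with_seed(sub, {
    rows <- purrr::map_dfr(names(targets), function(org) {
      per_fraction <- targets[[org]][1] / n_frac
      r <- (per_fraction + bg) * noise(gen$tld_n_readings)
      if (outlier && org == "lung_ipsi") {
        r[1] <- r[1] * gen$tld_outlier_factor
      }
      tibble::tibble(
        scenario = spec$name, breast_size = breast_size, organ = org,
        tld_id = sprintf("%s_%d", org, seq_along(r)),
        reading_gy = r, is_background = FALSE
      )
    })
    bg_rows <- tibble::tibble(
      scenario = spec$name, breast_size = breast_size, organ = "background",
      tld_id = sprintf("bg_%d", seq_len(gen$tld_n_background)),
      reading_gy = bg * noise(gen$tld_n_background),
      is_background = TRUE
    )
    out <- dplyr::bind_rows(rows, bg_rows)
    attr(out, "n_fractions") <- n_frac
    out
  })
}
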