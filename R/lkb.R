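#' Lyman-Kutcher-Burman parameter set
#'
#' The LKB model is parameterised per complication endpoint by the volume
#' exponent `n` (1 = parallel organ, toward 0 = serial), the slope `m` of the
#' probit dose-response curve, and `D50`, the uniform whole-organ dose giving
#' a 50% complication probability.
#'
#' @param endpoint Endpoint label.
#' @param n_volume Volume exponent, in (0, 1].
#' @param m_slope Slope parameter (> 0).
#' @param d50 D50 in Gy (> 0).
#' @return An object of class `lkb_params`.
#' @export
lkb_params <- function(endpoint, n_volume, m_slope, d50) {
  if (n_volume <= 0 || n_volume > 1) {
    stop("`n_volume` must lie in (0, 1]", call. = FALSE)
  }
  if (m_slope <= 0) stop("`m_slope` must be positive", call. = FALSE)
  if (d50 <= 0) stop("`d50` must be positive", call. = FALSE)
  structure(
    list(endpoint = as.character(endpoint), n_volume = as.numeric(n_volume),
         m_slope = as.numeric(m_slope), d50 = as.numeric(d50)),
    class = "lkb_params"
  )
}

#' Bundled LKB endpoint registry
#'
#' Literature parameter sets for the lung endpoints used throughout the
#' package: symptomatic pneumonitis (n = 1.000, m = 0.35, D50 = 37.6 Gy) and
#' radiation pneumonitis grade >= 2 (n = 0.990, m = 0.37, D50 = 30.8 Gy).
#' The same symptomatic-pneumonitis row is applied to the ipsilateral and
#' the whole lung. A user file in the same YAML layout
#' (`endpoint: {organ, n_volume, m, d50, source}`) can extend or override the
#' registry.
#'
#' @param path Optional YAML file with additional/overriding endpoints.
#' @return A tibble with columns `endpoint`, `organ`, `n_volume`, `m_slope`,
#'   `d50`, `source`.
#' @export
lkb_registry <- function(path = NULL) {
  file <- system.file("extdata", "lkb_params.yaml", package = "oarrisk")
  reg <- lkb_registry_from_yaml(file)
  if (!is.null(path)) {
    user <- lkb_registry_from_yaml(path)
    reg <- dplyr::rows_upsert(reg, user, by = "endpoint")
  }
  reg
}

lkb_registry_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  purrr::map_dfr(names(raw), function(ep) {
    e <- raw[[ep]]
    tibble::tibble(endpoint = ep, organ = e$organ %||% NA_character_,
                   n_volume = e$n_volume, m_slope = e$m, d50 = e$d50,
                   source = e$source %||% NA_character_)
  })
}

lkb_from_registry <- function(endpoint, registry = lkb_registry()) {
  row <- registry[registry$endpoint == endpoint, ]
  if (nrow(row) != 1L) {
    stop(sprintf("endpoint '%s' not found in LKB registry", endpoint),
         call. = FALSE)
  }
  lkb_params(endpoint, row$n_volume, row$m_slope, row$d50)
}

#' Equivalent uniform dose
#'
#' Generalised-mean EUD of a differential DVH,
#' `(sum_i v_i * D_i^(1/n))^n`. For `n = 1` this is exactly the mean dose;
#' as `n` approaches 0 it approaches the maximum dose (serial organ).
#' Zero-dose bins contribute exactly 0 and are skipped.
#'
#' @param x An `oar_dvh`.
#' @param n_volume Volume exponent (> 0).
#' @return EUD in Gy.
#' @examples
#' eud(dvh(c(10, 30), c(0.5, 0.5)), n_volume = 1)     # 20
#' eud(dvh(c(10, 30), c(0.5, 0.5)), n_volume = 0.99)  # 20.026
#' @export
eud <- function(x, n_volume) {
  check_dvh(x)
  if (length(n_volume) != 1L || is.na(n_volume) || n_volume <= 0) {
    stop("`n_volume` must be a single positive exponent", call. = FALSE)
  }
  keep <- x$dose_gy > 0 & x$volume > 0
  if (!any(keep)) return(0)
  if (n_volume == 1) return(sum(x$volume * x$dose_gy))
  # log-sum-exp so small n (serial limit) does not overflow d^(1/n)
  d <- x$dose_gy[keep]
  v <- x$volume[keep]
  a <- log(v) + log(d) / n_volume
  m <- max(a)
  exp(n_volume * (m + log(sum(exp(a - m)))))
}

#' LKB normal-tissue complication probability
#'
#' Probit dose-response: `NTCP = Phi((EUD - D50) / (m * D50))` with `Phi` the
#' standard normal CDF, evaluated in closed form (no quadrature).
#'
#' @param eud_value EUD in Gy (vectorised, each >= 0).
#' @param params An [lkb_params()] object.
#' @return Complication probability in (0, 1).
#' @examples
#' p <- lkb_params("symptomatic pneumonitis", 1, 0.35, 37.6)
#' ntcp(37.6, p)  # 0.5 by construction
#' @export
ntcp <- function(eud_value, params) {
  if (!inherits(params, "lkb_params")) {
    stop("`params` must be an lkb_params object", call. = FALSE)
  }
  if (any(is.na(eud_value)) || any(eud_value < 0)) {
    stop("`eud_value` must be non-negative", call. = FALSE)
  }
  stats::pnorm((eud_value - params$d50) / (params$m_slope * params$d50))
}

#' NTCP directly from a DVH
#'
#' Composition of [eud()] and [ntcp()] using the parameter set's volume
#' exponent.
#'
#' @param x An `oar_dvh`.
#' @param params An [lkb_params()] object.
#' @return Complication probability in (0, 1).
#' @export
ntcp_from_dvh <- function(x, params) {
  ntcp(eud(x, params$n_volume), params)
}
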