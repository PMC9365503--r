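#' Differential dose-volume histogram
#'
#' A DVH is stored as a tibble with one row per dose bin: `bin_lo`/`bin_hi`
#' (half-open interval `[bin_lo, bin_hi)` in Gy), `dose_gy` (the
#' representative bin dose, the bin midpoint) and `volume` (fractional volume
#' in the bin, summing to 1). Test fixtures and textbook examples may use
#' zero-width bins, i.e. point masses at given doses.
#'
#' @param dose_gy Representative bin doses in Gy.
#' @param volume Fractional volumes per bin (must sum to 1 within 1e-9).
#' @param organ Organ label.
#' @param bin_lo,bin_hi Optional bin edges; default zero-width bins at
#'   `dose_gy`.
#' @return A tibble of class `oar_dvh`.
#' @examples
#' dvh(c(10, 30), c(0.5, 0.5), organ = "lung")
#' @export
dvh <- function(dose_gy, volume, organ = "organ",
                bin_lo = dose_gy, bin_hi = dose_gy) {
  if (length(dose_gy) == 0L || length(dose_gy) != length(volume)) {
    stop("`dose_gy` and `volume` must be non-empty and equal length",
         call. = FALSE)
  }
  if (any(volume < 0) || any(dose_gy < 0)) {
    stop("doses and volumes must be non-negative", call. = FALSE)
  }
  if (abs(sum(volume) - 1) > 1e-9) {
    stop("differential DVH volumes must sum to 1", call. = FALSE)
  }
  if (is.unsorted(dose_gy, strictly = TRUE)) {
    stop("`dose_gy` must be strictly ascending", call. = FALSE)
  }
  out <- tibble::tibble(
    bin_lo = as.numeric(bin_lo),
    bin_hi = as.numeric(bin_hi),
    dose_gy = as.numeric(dose_gy),
    volume = as.numeric(volume)
  )
  structure(out, class = c("oar_dvh", class(out)),
            organ = as.character(organ), dose_type = "physical")
}

is_dvh <- function(x) inherits(x, "oar_dvh")

dvh_organ <- function(x) attr(x, "organ")

check_dvh <- function(x) {
  if (!is_dvh(x)) stop("expected an `oar_dvh` object (see dvh())", call. = FALSE)
  invisible(x)
}

#' Bin a voxel dose distribution into a differential DVH
#'
#' Half-open bins `[k*w, (k+1)*w)` of width `w` covering `[0, max dose]`;
#' volume is conserved exactly. The representative dose of each bin is the
#' bin midpoint.
#'
#' @param dist A [dose_distribution()].
#' @param bin_width Bin width in Gy (default 0.1 Gy, fine enough that the
#'   binning error in EUD/NTCP is negligible at clinical doses).
#' @return An `oar_dvh` tibble; empty bins are kept so bins are contiguous.
#' @examples
#' d <- dose_distribution("lung", c(1, 1, 3, 3), scheme = fractionation(25, 2))
#' dvh_from_distribution(d, bin_width = 2)
#' @export
dvh_from_distribution <- function(dist, bin_width = 0.1) {
  if (!is_dose_distribution(dist)) {
    stop("`dist` must be a dose_distribution", call. = FALSE)
  }
  if (length(bin_width) != 1L || is.na(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be a single positive width in Gy", call. = FALSE)
  }
  doses <- dist$voxel_doses
  idx <- floor(doses / bin_width)           # half-open [k*w, (k+1)*w)
  n_bins <- max(idx) + 1L
  counts <- tabulate(idx + 1L, nbins = n_bins)
  lo <- (seq_len(n_bins) - 1L) * bin_width
  # representative bin dose: mean of the voxels in the bin (exact organ mean
  # and exact zero-dose handling); empty bins fall back to the midpoint
  sums <- numeric(n_bins)
  rs <- rowsum(doses, idx)
  sums[as.integer(rownames(rs)) + 1L] <- rs[, 1]
  rep_dose <- ifelse(counts > 0, sums / pmax(counts, 1L), lo + bin_width / 2)
  out <- dvh(
    dose_gy = rep_dose,
    volume = counts / length(doses),
    organ = dist$organ,
    bin_lo = lo,
    bin_hi = lo + bin_width
  )
  attr(out, "dose_type") <- dist$dose_type
  out
}

# volume fraction receiving >= `dose`, linear within real bins, step at
# zero-width bins
volume_at_or_above <- function(x, dose) {
  w <- x$bin_hi - x$bin_lo
  frac <- ifelse(
    w > 0,
    pmin(pmax((x$bin_hi - dose) / w, 0), 1),
    as.numeric(x$dose_gy >= dose)
  )
  sum(x$volume * frac)
}

#' DVH dose metrics
#'
#' Mean dose, `V_x` (percent of the organ volume receiving at least `x` Gy)
#' and `D_y%` (minimum dose received by the hottest `y` percent of the
#' volume, read off the cumulative DVH).
#'
#' @param x An `oar_dvh`.
#' @param v_at Dose thresholds in Gy for `V` metrics (default 20 Gy).
#' @param d_at Volume percentages in (0, 100] for `D` metrics (default 1).
#' @return A one-row tibble with `organ`, `d_mean_gy`, one `v_<x>gy_pct`
#'   column per threshold and one `d_<y>pct_gy` column per percentage.
#' @examples
#' dose_metrics(dvh(c(10, 30), c(0.5, 0.5)))
#' @export
dose_metrics <- function(x, v_at = 20, d_at = 1) {
  check_dvh(x)
  if (length(d_at) && (any(d_at <= 0) || any(d_at > 100))) {
    stop("`d_at` percentages must lie in (0, 100]", call. = FALSE)
  }
  out <- tibble::tibble(
    organ = dvh_organ(x),
    d_mean_gy = sum(x$volume * x$dose_gy)
  )
  for (v in v_at) {
    out[[sprintf("v_%ggy_pct", v)]] <- 100 * volume_at_or_above(x, v)
  }
  for (y in d_at) {
    out[[sprintf("d_%gpct_gy", y)]] <- dose_at_top_volume(x, y)
  }
  out
}

# D_y%: invert the cumulative curve V(d) = y/100
dose_at_top_volume <- function(x, y) {
  if (y <= 0 || y > 100) stop("`y` must lie in (0, 100]", call. = FALSE)
  target <- y / 100
  if (all(x$bin_hi > x$bin_lo)) {
    edges <- sort(unique(c(x$bin_lo, x$bin_hi)))
    v <- vapply(edges, function(e) volume_at_or_above(x, e), numeric(1))
    # v is non-increasing in dose; find d with v(d) = target
    if (target >= v[1]) return(edges[1])
    stats::approx(x = rev(v), y = rev(edges), xout = target,
                  ties = "ordered")$y
  } else {
    ord <- order(x$dose_gy, decreasing = TRUE)
    cum <- cumsum(x$volume[ord])
    k <- which(cum >= target - 1e-12)[1]
    x$dose_gy[ord][k]
  }
}

#' Cumulative form of a DVH
#'
#' @param x An `oar_dvh`.
#' @return A tibble with columns `dose_gy` and `volume_ge`, the fractional
#'   volume receiving at least that dose; starts at `volume_ge = 1` for
#'   dose 0 and is monotone non-increasing.
#' @export
dvh_cumulative <- function(x) {
  check_dvh(x)
  knots <- sort(unique(c(0, x$bin_lo, x$bin_hi, x$dose_gy)))
  tibble::tibble(
    dose_gy = knots,
    volume_ge = vapply(knots, function(d) volume_at_or_above(x, d), numeric(1))
  )
}

#' Plot the cumulative dose-volume histogram
#'
#' @param object An `oar_dvh`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.oar_dvh <- function(object, ...) {
  cum <- dvh_cumulative(object)
  ggplot2::ggplot(cum, ggplot2::aes(x = .data$dose_gy,
                                    y = 100 * .data$volume_ge)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Dose [Gy]", y = "Volume [%]",
                  title = sprintf("Cumulative DVH: %s", dvh_organ(object))) +
    ggplot2::theme_minimal()
}

#' Pool several DVH sources into one organ DVH
#'
#' Combines voxel distributions (e.g. ipsilateral + contralateral lung into
#' the whole lung) by concatenating voxel vectors, weighting each input by
#' its total volume.
#'
#' @param dists List of [dose_distribution()] objects (same voxel volume).
#' @param organ Label for the pooled organ.
#' @return A [dose_distribution()] of the pooled organ.
#' @export
pool_distributions <- function(dists, organ) {
  if (length(dists) == 0L) stop("no distributions to pool", call. = FALSE)
  vv <- unique(vapply(dists, `[[`, numeric(1), "voxel_volume"))
  if (length(vv) != 1L) {
    stop("pooled distributions must share a voxel volume", call. = FALSE)
  }
  types <- unique(vapply(dists, `[[`, character(1), "dose_type"))
  if (length(types) != 1L) {
    stop("pooled distributions must share a dose type", call. = FALSE)
  }
  dose_distribution(organ,
                    unlist(lapply(dists, `[[`, "voxel_doses")),
                    vv, scheme = NULL, dose_type = types)
}
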