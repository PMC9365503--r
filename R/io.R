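#' Read and write dose-distribution files
#'
#' Plain-text CSV interchange format for per-organ voxel dose vectors: header
#' comment lines `# organ=...`, `# voxel_volume_cm3=...` and, for a physical
#' course, `# n_fractions=...` / `# dose_per_fraction=...`, followed by a
#' `dose_gy` column with one voxel dose per row. Doses are written with full
#' double precision, so the round trip is exact.
#'
#' @param x A [dose_distribution()].
#' @param path File path.
#' @return `read_dose_distribution()` returns a [dose_distribution()];
#'   `write_dose_distribution()` returns `path` invisibly.
#' @export
write_dose_distribution <- function(x, path) {
  if (!is_dose_distribution(x)) {
    stop("`x` must be a dose_distribution", call. = FALSE)
  }
  hdr <- c(
    sprintf("# organ=%s", x$organ),
    sprintf("# voxel_volume_cm3=%s", format_full(x$voxel_volume)),
    sprintf("# dose_type=%s", x$dose_type)
  )
  if (!is.null(x$scheme)) {
    hdr <- c(hdr,
             sprintf("# n_fractions=%d", x$scheme$n_fractions),
             sprintf("# dose_per_fraction=%s",
                     format_full(x$scheme$dose_per_fraction)))
  }
  writeLines(c(hdr, "dose_gy", format_full(x$voxel_doses)), path)
  invisible(path)
}

#' @rdname write_dose_distribution
#' @export
read_dose_distribution <- function(path) {
  meta <- read_hash_comments(path)
  # base read.csv: strtod parsing is correctly rounded, so the write/read
  # round trip is bit-exact
  tab <- utils::read.csv(path, comment.char = "#")
  scheme <- NULL
  if (!is.null(meta$n_fractions)) {
    scheme <- fractionation(as.integer(meta$n_fractions),
                            as.numeric(meta$dose_per_fraction))
  }
  dose_distribution(
    organ = meta$organ,
    voxel_doses = tab$dose_gy,
    voxel_volume = as.numeric(meta$voxel_volume_cm3),
    scheme = scheme,
    dose_type = meta$dose_type %||% "physical"
  )
}

#' Read and write DVH files
#'
#' CSV columns `dose_gy_bin_lower,volume_fraction` with comment headers
#' `# organ=...` and `# type=differential|cumulative`. Differential files
#' additionally carry `# bin_upper_last=` (the top edge of the final bin) or
#' `# zero_width=true` for point-mass DVHs. Cumulative input is converted to
#' the internal differential form on read.
#'
#' @param x An `oar_dvh`.
#' @param path File path.
#' @return `read_dvh()` returns an `oar_dvh`; `write_dvh()` returns `path`
#'   invisibly.
#' @export
write_dvh <- function(x, path) {
  check_dvh(x)
  zero_width <- all(x$bin_hi == x$bin_lo)
  hdr <- c(
    sprintf("# organ=%s", dvh_organ(x)),
    "# type=differential",
    if (zero_width) "# zero_width=true"
    else sprintf("# bin_upper_last=%s", format_full(max(x$bin_hi)))
  )
  body <- paste(format_full(x$bin_lo), format_full(x$volume), sep = ",")
  writeLines(c(hdr, "dose_gy_bin_lower,volume_fraction", body), path)
  invisible(path)
}

#' @rdname write_dvh
#' @export
read_dvh <- function(path) {
  meta <- read_hash_comments(path)
  tab <- utils::read.csv(path, comment.char = "#")
  type <- meta$type %||% "differential"
  if (type == "cumulative") {
    # volume_fraction holds V(>= dose); difference to differential bins
    lo <- tab$dose_gy_bin_lower
    vge <- tab$volume_fraction
    if (abs(vge[1] - 1) > 1e-9 || lo[1] != 0) {
      stop("cumulative DVH must start at dose 0 with volume 1", call. = FALSE)
    }
    if (any(diff(vge) > 1e-12)) {
      stop("cumulative DVH must be monotone non-increasing", call. = FALSE)
    }
    vol <- c(-diff(vge), vge[length(vge)])
    hi <- c(lo[-1], lo[length(lo)] + (if (length(lo) > 1)
      diff(lo)[length(lo) - 1] else 1))
    return(dvh(dose_gy = (lo + hi) / 2, volume = vol,
               organ = meta$organ %||% "organ", bin_lo = lo, bin_hi = hi))
  }
  lo <- tab$dose_gy_bin_lower
  if (isTRUE(meta$zero_width == "true")) {
    return(dvh(lo, tab$volume_fraction, organ = meta$organ %||% "organ"))
  }
  hi <- c(lo[-1], as.numeric(meta$bin_upper_last))
  dvh(dose_gy = (lo + hi) / 2, volume = tab$volume_fraction,
      organ = meta$organ %||% "organ", bin_lo = lo, bin_hi = hi)
}

#' Read and write TLD reading files
#'
#' CSV with columns `scenario,breast_size,organ,tld_id,reading_gy,is_background`;
#' one row per TLD chip per measurement session.
#'
#' @param readings A tibble in the column layout above.
#' @param path File path.
#' @return `read_tld_readings()` returns a tibble; `write_tld_readings()`
#'   returns `path` invisibly.
#' @export
write_tld_readings <- function(readings, path) {
  required <- c("scenario", "breast_size", "organ", "tld_id", "reading_gy",
                "is_background")
  if (!all(required %in% names(readings))) {
    stop("TLD readings need columns: ", paste(required, collapse = ", "),
         call. = FALSE)
  }
  readr::write_csv(readings[required], path)
  invisible(path)
}

#' @rdname write_tld_readings
#' @export
read_tld_readings <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    scenario = readr::col_character(),
                    breast_size = readr::col_character(),
                    organ = readr::col_character(),
                    tld_id = readr::col_character(),
                    reading_gy = readr::col_double(),
                    is_background = readr::col_logical()
                  ))
}

# full-precision numeric formatting so CSV round trips are exact
format_full <- function(x) {
  sprintf("%.17g", x)
}

read_hash_comments <- function(path) {
  lines <- readLines(path, n = 50L)
  lines <- lines[startsWith(lines, "# ")]
  kv <- sub("^# ", "", lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  stats::setNames(as.list(vals), keys)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
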