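#' Construct an activity measurement
#'
#' One analyte (a compound id or a mixture label such as `"Ge+P"`) measured
#' in one assay at one total concentration. Supply replicate values when
#' available; the mean and sample standard deviation are computed from
#' them. Printed-table entries that only carry a mean and a "+/-" value are
#' stored summary-only (`replicates` absent, `summary_only = TRUE`) at
#' printed precision, without re-rounding.
#'
#' @param analyte Compound id or mixture label (components joined by `"+"`).
#' @param assay `"FRAP"` or `"ORAC"`.
#' @param concentration_um Total analyte concentration in micromolar.
#' @param replicates Numeric vector of replicate activities (>= 1 value).
#' @param mean,sd Summary values, used only when `replicates` is `NULL`.
#' @param n Replicate count behind a summary-only measurement (default 3,
#'   the study's replication).
#' @param units Unit string; defaults to the assay's canonical units and
#'   must match them.
#' @return A one-row tibble with columns `analyte`, `assay`,
#'   `concentration_um`, `mean`, `sd`, `n`, `units`, `summary_only`, and a
#'   list-column `replicates`.
#' @export
#' @examples
#' activity_measurement("G", "FRAP", 100, replicates = c(491, 494, 497))
activity_measurement <- function(analyte, assay, concentration_um,
                                 replicates = NULL, mean = NULL, sd = NULL,
                                 n = 3L, units = NULL) {
  check_assay(assay)
  if (!is.numeric(concentration_um) || concentration_um < 0) {
    abort("concentration_um must be a non-negative number")
  }
  canonical <- activity_units(assay)
  units <- units %||% canonical
  if (!identical(units, canonical)) {
    abort(paste0(
      "units '", units, "' are inconsistent with the ", assay,
      " assay (expected '", canonical, "')"
    ))
  }
  if (!is.null(replicates)) {
    if (length(replicates) < 1 || !is.numeric(replicates)) {
      abort("replicates must be a non-empty numeric vector")
    }
    m <- base::mean(replicates)
    s <- if (length(replicates) == 1) 0 else stats::sd(replicates)
    n <- length(replicates)
    summary_only <- FALSE
  } else {
    if (is.null(mean)) abort("supply either replicates or a mean")
    m <- mean
    s <- sd %||% NA_real_
    summary_only <- TRUE
  }
  tibble::tibble(
    analyte = analyte, assay = assay, concentration_um = concentration_um,
    mean = m, sd = s, n = as.integer(n), units = units,
    summary_only = summary_only,
    replicates = list(replicates)
  )
}

#' Validate a measurement, recomputing its summaries
#'
#' Recomputes mean and sample SD from the stored replicates (when present)
#' and enforces the unit/assay contract. Summary-only rows pass through
#' with their printed mean/SD untouched.
#'
#' @param m A measurement tibble (one or more rows) in the layout of
#'   [activity_measurement()].
#' @return `m` with `mean` and `sd` recomputed from replicates.
#' @export
validate_measurement <- function(m) {
  check_assay(m$assay)
  if (any(m$concentration_um < 0)) abort("negative concentration")
  expected <- activity_units(m$assay)
  if (any(m$units != expected)) {
    bad <- which(m$units != expected)[1]
    abort(paste0(
      "units '", m$units[bad], "' are inconsistent with the ", m$assay[bad],
      " assay (expected '", expected[bad], "')"
    ))
  }
  for (i in seq_len(nrow(m))) {
    reps <- m$replicates[[i]]
    if (is.null(reps)) {
      if (!isTRUE(m$summary_only[i])) abort("empty replicate list on a non-summary measurement")
      next
    }
    if (length(reps) == 0) abort("empty replicate list")
    m$mean[i] <- base::mean(reps)
    m$sd[i] <- if (length(reps) == 1) 0 else stats::sd(reps)
    m$n[i] <- length(reps)
  }
  if (any(!is.na(m$sd) & m$sd < 0)) abort("sd must be non-negative")
  m
}

#' Read / write long-format replicate measurements
#'
#' The on-disk interchange format is a long CSV with one row per replicate:
#' columns `analyte` (compound id or "+"-joined mixture label), `assay`,
#' `concentration_um`, `replicate_index`, `value`, `units`. The round-trip
#' through [write_measurements()] and [read_measurements()] is lossless at
#' full double precision.
#'
#' @param path File path.
#' @return A tibble in the long replicate layout.
#' @export
read_measurements <- function(path) {
  x <- readr::read_csv(
    path,
    col_types = readr::cols(
      analyte = readr::col_character(),
      assay = readr::col_character(),
      concentration_um = readr::col_double(),
      replicate_index = readr::col_integer(),
      value = readr::col_character(),
      units = readr::col_character()
    )
  )
  # base-R conversion is correctly rounded, so 17-digit values written by
  # write_measurements() come back bit-for-bit
  x$value <- as.numeric(x$value)
  x
}

#' @param x A long replicate tibble as returned by [read_measurements()].
#' @rdname read_measurements
#' @export
write_measurements <- function(x, path) {
  # 17 significant digits guarantee an exact double round trip
  x$value <- sprintf("%.17g", x$value)
  readr::write_csv(x, path)
  invisible(path)
}

#' Collapse replicate rows to per-analyte summaries
#'
#' @param x Long replicate tibble (`analyte`, `assay`, `concentration_um`,
#'   `value`, `units`).
#' @return A tibble with one row per (analyte, assay, concentration):
#'   `mean`, `sd` (sample SD; 0 for a single replicate), `n`, `units`.
#' @export
summarize_measurements <- function(x) {
  check_assay(x$assay)
  x |>
    dplyr::group_by(.data$analyte, .data$assay, .data$concentration_um, .data$units) |>
    dplyr::summarise(
      mean = base::mean(.data$value),
      sd = if (dplyr::n() == 1) 0 else stats::sd(.data$value),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::select(
      "analyte", "assay", "concentration_um", "mean", "sd", "n", "units"
    )
}
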