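#' Fit a calibration standard curve
#'
#' Ordinary least-squares line `response = slope * concentration +
#' intercept` through a ladder of known standards (an Fe2+ ladder for FRAP
#' absorbance, a Trolox ladder for ORAC net AUC). The intercept is free by
#' default - blank-corrected instruments can still carry offsets - and can
#' be forced through the origin.
#'
#' @param concentration_um Known standard concentrations (>= 2 distinct).
#' @param response Instrument responses, same length.
#' @param analyte Label for the calibrated analyte (e.g. `"Fe2+"`,
#'   `"Trolox"`).
#' @param through_origin Force `intercept = 0`.
#' @return An object of class `standard_curve`: list with `slope`,
#'   `intercept`, `r_squared`, `analyte`, `n`, and the fitted points.
#' @export
#' @examples
#' fit_standard_curve(c(0, 50, 100), c(1, 101, 201))
fit_standard_curve <- function(concentration_um, response,
                               analyte = "standard", through_origin = FALSE) {
  if (length(concentration_um) != length(response)) {
    abort("concentration and response must have the same length")
  }
  if (length(unique(concentration_um)) < 2) {
    abort("need >= 2 distinct concentrations to fit a standard curve")
  }
  if (any(!is.finite(response)) || any(!is.finite(concentration_um))) {
    abort("standard-curve points must be finite")
  }
  fit <- if (through_origin) {
    lm(response ~ concentration_um + 0)
  } else {
    lm(response ~ concentration_um)
  }
  fitted_vals <- stats::fitted(fit)
  ss_res <- sum((response - fitted_vals)^2)
  ss_tot <- sum((response - base::mean(response))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(
    list(
      slope = unname(coef(fit)[["concentration_um"]]),
      intercept = if (through_origin) 0 else unname(coef(fit)[["(Intercept)"]]),
      r_squared = r2,
      analyte = analyte,
      n = length(response),
      points = tibble::tibble(
        concentration_um = concentration_um, response = response
      )
    ),
    class = "standard_curve"
  )
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "standard curve (%s, n = %d): response = %.6g * conc + %.6g, r^2 = %.4f\n",
    x$analyte, x$n, x$slope, x$intercept, x$r_squared
  ))
  invisible(x)
}

invert_standard_curve <- function(response, curve) {
  if (!inherits(curve, "standard_curve")) abort("curve must be a standard_curve")
  if (curve$slope == 0) abort("standard curve has zero slope; cannot invert")
  (response - curve$intercept) / curve$slope
}

#' Convert FRAP absorbance to uM Fe2+
#'
#' Inverts the Fe2+ standard curve: `(absorbance - intercept) / slope`.
#'
#' @param absorbance Endpoint absorbance values.
#' @param curve A `standard_curve` fitted on an Fe2+ ladder.
#' @return Equivalent Fe2+ concentrations in uM.
#' @export
frap_to_fe2 <- function(absorbance, curve) {
  invert_standard_curve(absorbance, curve)
}

#' Area under a normalized kinetic fluorescence curve
#'
#' Trapezoidal integral of a fluorescence-decay trace, by default after
#' normalizing to the initial reading (f(0) = 1) so plates with different
#' gains are comparable. For the study-conformant 80-minute window a
#' non-decaying curve integrates to 80.
#'
#' @param time_min Strictly increasing times in minutes, starting at 0.
#' @param fluorescence Non-negative readings, same length.
#' @param normalize Divide by the first reading before integrating
#'   (default `TRUE`).
#' @return Area in (relative fluorescence) x minutes.
#' @export
#' @examples
#' curve_auc(0:80, rep(500, 81)) # 80
curve_auc <- function(time_min, fluorescence, normalize = TRUE) {
  if (length(time_min) < 2) abort("need >= 2 time points")
  if (length(time_min) != length(fluorescence)) {
    abort("time and fluorescence must have the same length")
  }
  if (any(diff(time_min) <= 0)) abort("times must be strictly increasing")
  if (any(fluorescence < 0)) abort("fluorescence must be non-negative")
  if (normalize) {
    if (fluorescence[1] == 0) abort("cannot normalize: f(0) = 0")
    fluorescence <- fluorescence / fluorescence[1]
  }
  pracma::trapz(time_min, fluorescence)
}

#' Net area under the curve
#'
#' The ORAC response variable: sample area minus blank area, both from
#' identically normalized curves over the same window.
#'
#' @param sample_auc,blank_auc Areas from [curve_auc()].
#' @return Net area.
#' @export
net_auc <- function(sample_auc, blank_auc) {
  sample_auc - blank_auc
}

#' Convert a net AUC to uM Trolox Equivalents
#'
#' Inverts the Trolox calibration (net AUC vs Trolox concentration):
#' `(net_area - intercept) / slope`.
#'
#' @param net_area Net areas from [net_auc()].
#' @param curve A `standard_curve` fitted on Trolox-ladder net AUCs.
#' @return Activities in uM TE.
#' @export
orac_te <- function(net_area, curve) {
  invert_standard_curve(net_area, curve)
}

#' Reduce a full ORAC kinetic plate to uM TE
#'
#' Takes a long kinetics table (wells of role `blank`, `trolox_standard`
#' or `sample`), computes each well's normalized AUC, averages the blank
#' area, fits the Trolox calibration on the standards' net AUCs, and
#' converts every sample well's net AUC to Trolox Equivalents.
#'
#' @param kinetics Tibble with columns `well`, `role`, `time_min`,
#'   `fluorescence`, and `trolox_um` (standard wells; `NA` elsewhere).
#'   Sample wells should also carry `analyte` (propagated to the output).
#' @param through_origin Passed to [fit_standard_curve()]; by
#'   construction a blank-relative net AUC is 0 at 0 uM Trolox, so the
#'   default here forces the origin.
#' @return A list with `te` (tibble: `well`, `analyte`, `net_auc`,
#'   `te_um`) and `curve` (the Trolox `standard_curve`).
#' @export
reduce_orac_plate <- function(kinetics, through_origin = TRUE) {
  needed <- c("well", "role", "time_min", "fluorescence")
  missing <- setdiff(needed, names(kinetics))
  if (length(missing) > 0) {
    abort(paste0("kinetics is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  aucs <- kinetics |>
    dplyr::group_by(.data$well, .data$role) |>
    dplyr::arrange(.data$time_min, .by_group = TRUE) |>
    dplyr::summarise(
      auc = curve_auc(.data$time_min, .data$fluorescence),
      trolox_um = if ("trolox_um" %in% names(kinetics)) {
        .data$trolox_um[1]
      } else {
        NA_real_
      },
      analyte = if ("analyte" %in% names(kinetics)) {
        .data$analyte[1]
      } else {
        NA_character_
      },
      .groups = "drop"
    )
  blanks <- aucs$auc[aucs$role == "blank"]
  if (length(blanks) == 0) abort("plate has no blank wells")
  blank_auc <- base::mean(blanks)

  standards <- aucs[aucs$role == "trolox_standard", , drop = FALSE]
  if (nrow(standards) < 2) abort("plate needs >= 2 Trolox standard wells")
  curve <- fit_standard_curve(
    standards$trolox_um, net_auc(standards$auc, blank_auc),
    analyte = "Trolox", through_origin = through_origin
  )

  samples <- aucs[aucs$role == "sample", , drop = FALSE]
  te <- tibble::tibble(
    well = samples$well,
    analyte = samples$analyte,
    net_auc = net_auc(samples$auc, blank_auc),
    te_um = orac_te(net_auc(samples$auc, blank_auc), curve)
  )
  list(te = te, curve = curve)
}
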