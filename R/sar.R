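#' Structure-activity feature vectors of a panel
#'
#' Encodes each compound's computable ring-substituent summaries: hydroxyl
#' count, methoxy count, catechol indicator (adjacent dihydroxy pattern)
#' and a hydroxycinnamic-class indicator (the caffeic ester counts with the
#' hydroxycinnamic set, as in the study design). Positional electronic
#' effects are deliberately not encoded; they are not computable from the
#' declared substituent maps.
#'
#' @param panel A panel tibble from [study_panel()].
#' @return A tibble ordered by `id`: `id`, `n_oh`, `n_och3`,
#'   `has_catechol` (0/1), `is_hydroxycinnamic` (0/1).
#' @export
#' @examples
#' feature_table(study_panel())
feature_table <- function(panel) {
  if (nrow(panel) == 0) {
    return(tibble::tibble(
      id = character(), n_oh = integer(), n_och3 = integer(),
      has_catechol = integer(), is_hydroxycinnamic = integer()
    ))
  }
  panel |>
    dplyr::transmute(
      id = .data$id,
      n_oh = as.integer(.data$n_oh),
      n_och3 = as.integer(.data$n_och3),
      has_catechol = as.integer(.data$has_catechol),
      is_hydroxycinnamic = as.integer(
        .data$compound_class %in% c("hydroxycinnamic", "caffeic_ester")
      )
    ) |>
    dplyr::arrange(.data$id)
}

#' Rank correlation between substituent features and activity
#'
#' Spearman's rho (average ranks for ties) between each feature column and
#' the activity of the matched compounds at one assay/concentration - a
#' descriptive check of whether activity tracks, e.g., hydroxyl count.
#'
#' @param features A [feature_table()] tibble.
#' @param activities Tibble with columns `id` and `activity` (>= 3
#'   compounds after matching by id).
#' @return A tibble with `feature` and `rho`.
#' @export
feature_activity_correlation <- function(features, activities) {
  joined <- dplyr::inner_join(features, activities, by = "id")
  if (nrow(joined) < 3) abort("need >= 3 matched compounds")
  feats <- setdiff(names(features), "id")
  tibble::tibble(
    feature = feats,
    rho = vapply(feats, USE.NAMES = FALSE, FUN.VALUE = numeric(1), function(f) {
      x <- joined[[f]]
      if (stats::var(x) == 0 || stats::var(joined$activity) == 0) {
        return(NA_real_)
      }
      cor(x, joined$activity, method = "spearman")
    })
  )
}

#' Linearity of the concentration-response of one compound
#'
#' Pearson correlation and least-squares slope of activity against
#' concentration. Individual activities are expected to scale linearly
#' with concentration over the assay range; this is the premise behind
#' computing expected additive mixture values at the total concentration.
#' A zero-variance activity vector is reported as `r = 0` with
#' `degenerate = TRUE` (rather than an error) so panel-wide sweeps never
#' abort.
#'
#' @param concentration_um Concentrations (>= 3, non-constant).
#' @param activity Matched activities.
#' @return A list: `r` (Pearson), `slope` (activity per uM), `degenerate`.
#' @export
#' @examples
#' linearity_check(c(100, 500, 1000), c(494, 2478, 5033))
linearity_check <- function(concentration_um, activity) {
  if (length(concentration_um) < 3) abort("need >= 3 concentration points")
  if (length(concentration_um) != length(activity)) {
    abort("concentration and activity must have the same length")
  }
  if (stats::var(concentration_um) == 0) {
    abort("zero variance in concentration")
  }
  slope <- unname(coef(lm(activity ~ concentration_um))[["concentration_um"]])
  if (stats::var(activity) == 0) {
    return(list(r = 0, slope = slope, degenerate = TRUE))
  }
  list(
    r = cor(concentration_um, activity),
    slope = slope,
    degenerate = FALSE
  )
}
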