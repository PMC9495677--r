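#' Interaction-analysis configuration
#'
#' @param additive_band_pct Half-width, in percentage points, of the
#'   no-interaction band around zero difference. Differences with
#'   `|d| <= additive_band_pct` are called additive; above, synergistic;
#'   below, antagonistic. Default 5, the band the study uses.
#' @return A list of class `interaction_config`.
#' @export
interaction_config <- function(additive_band_pct = 5) {
  if (!is.numeric(additive_band_pct) || additive_band_pct < 0) {
    abort("additive_band_pct must be >= 0")
  }
  structure(list(additive_band_pct = additive_band_pct),
            class = "interaction_config")
}

#' Expected additive activity of an equimolar mixture
#'
#' Under additivity and linear dose-response, each component of a
#' k-component equimolar mixture at total concentration C contributes 1/k
#' of the activity it shows alone at C. The expected ("theoretical")
#' mixture activity is therefore the arithmetic mean of the k individual
#' activities measured at the mixture's total concentration.
#'
#' @param individual_means Numeric vector of the k individual mean
#'   activities at the mixture's total concentration.
#' @param k Component count; must equal `length(individual_means)`.
#' @return The expected additive activity (same units as the inputs).
#' @export
#' @examples
#' theoretical_mixture_value(c(282, 294)) # 288
theoretical_mixture_value <- function(individual_means,
                                      k = length(individual_means)) {
  if (k != length(individual_means)) {
    abort("k must equal the number of individual means")
  }
  if (k < 2) abort("a mixture needs at least 2 components")
  if (any(!is.finite(individual_means))) abort("individual means must be finite")
  sum(individual_means) / k
}

#' The difference-(%) interaction index
#'
#' The relative departure of the observed mixture activity from its
#' expected additive value: `100 * experimental / theoretical - 100`.
#' Zero means exact additivity; positive values indicate synergy, negative
#' values antagonism.
#'
#' @param experimental Observed mean activity of the mixture (>= 0).
#' @param theoretical Expected additive activity (> 0), from
#'   [theoretical_mixture_value()].
#' @return The difference in percent (vectorized over its arguments).
#' @export
#' @examples
#' difference_percent(520, 288) # 80.6 -> synergistic
difference_percent <- function(experimental, theoretical) {
  if (any(!is.finite(theoretical)) || any(theoretical <= 0)) {
    abort("theoretical must be finite and > 0 (index undefined otherwise)")
  }
  if (any(experimental < 0)) abort("experimental activity must be >= 0")
  100 * experimental / theoretical - 100
}

#' Classify an interaction from its difference (%)
#'
#' Additive iff `|d|` lies within the band (inclusive); synergistic above,
#' antagonistic below. The inclusive boundary means a difference of exactly
#' +5 with the default band is still "no interaction".
#'
#' @param d Numeric vector of differences in percent.
#' @param config An [interaction_config()].
#' @return Character vector: `"synergistic"`, `"additive"` or `"antagonistic"`.
#' @export
#' @examples
#' classify_interaction(c(81, 4, -58))
classify_interaction <- function(d, config = interaction_config()) {
  if (any(!is.finite(d))) abort("difference must be finite")
  band <- config$additive_band_pct
  dplyr::case_when(
    abs(d) <= band ~ "additive",
    d > band ~ "synergistic",
    TRUE ~ "antagonistic"
  )
}

#' Delta-method SD of the difference (%)
#'
#' First-order propagation of replicate noise into the interaction index,
#' treating the experimental mixture mean and the k individual means as
#' independent. With E the experimental mean, T the theoretical value and
#' standard errors `se^2 = sd^2 / n`:
#' `sd(d) = 100 * (E/T) * sqrt(seE^2/E^2 + sum(se_i^2) / (k^2 T^2))`.
#' The index is a ratio, so the result is invariant under a common
#' rescaling of all means and SDs.
#'
#' @param experimental_mean,experimental_sd,n_exp Mixture mean, replicate
#'   SD and replicate count.
#' @param individual_means,individual_sds,n_ind Component means, SDs and
#'   replicate counts (recycled to length k).
#' @return Approximate standard deviation of the difference, in
#'   percentage points.
#' @export
difference_uncertainty <- function(experimental_mean, experimental_sd, n_exp,
                                   individual_means, individual_sds,
                                   n_ind = n_exp) {
  k <- length(individual_means)
  theoretical <- theoretical_mixture_value(individual_means, k)
  if (any(c(experimental_sd, individual_sds) < 0)) abort("sds must be >= 0")
  n_ind <- rep_len(n_ind, k)
  var_e <- experimental_sd^2 / n_exp
  var_t <- sum(individual_sds^2 / n_ind) / k^2
  if (experimental_mean == 0) {
    # index pinned at -100 up to noise in E alone
    return(100 * sqrt(var_e) / theoretical)
  }
  100 * (experimental_mean / theoretical) *
    sqrt(var_e / experimental_mean^2 + var_t / theoretical^2)
}

#' Round half away from zero
#'
#' The reporting convention for printed interaction tables (2.5 -> 3,
#' -12.5 -> -13), as opposed to R's banker's rounding.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a difference (%) for reporting
#'
#' Printed convention: one decimal when the rounded magnitude is below 10
#' (e.g. `"4.0"`, `"-3.1"`), integer otherwise (e.g. `"81"`); rounding is
#' half away from zero. Underlying values stay at full precision.
#'
#' @param d Numeric vector of differences in percent.
#' @return Character vector of display values.
#' @export
#' @examples
#' format_difference(c(80.56, 3.985, -33.33))
format_difference <- function(d) {
  ifelse(
    abs(round_half_away(d, 1)) < 10,
    sprintf("%.1f", round_half_away(d, 1)),
    sprintf("%d", as.integer(round_half_away(d, 0)))
  )
}

#' Panel-wide interaction analysis
#'
#' Joins every mixture measurement to the individual measurements of its
#' components (same assay, same total concentration), computes the
#' expected additive value, the difference-(%) index, its delta-method SD
#' (where replicate SDs are available), and the classification.
#'
#' @param individuals Summary tibble of single-compound measurements:
#'   columns `analyte`, `assay`, `concentration_um`, `mean`, and optionally
#'   `sd`, `n`. Duplicate rows for one (analyte, assay, concentration) key
#'   are averaged with a warning.
#' @param mixtures Summary tibble of mixture measurements in the same
#'   layout; `analyte` holds a "+"-joined component label in any order.
#' @param config An [interaction_config()].
#' @return A tibble with one row per (mixture, assay, concentration):
#'   `mixture` (canonical label), `k`, `assay`, `concentration_um`,
#'   `experimental`, `theoretical`, `difference_pct`, `difference_sd`,
#'   `classification`, and display strings `theoretical_display`,
#'   `difference_display` under the reporting convention.
#' @export
analyze_panel <- function(individuals, mixtures,
                          config = interaction_config()) {
  if (nrow(mixtures) == 0) {
    return(tibble::tibble(
      mixture = character(), k = integer(), assay = character(),
      concentration_um = numeric(), experimental = numeric(),
      theoretical = numeric(), difference_pct = numeric(),
      difference_sd = numeric(), classification = character(),
      theoretical_display = character(), difference_display = character()
    ))
  }
  if (!"sd" %in% names(individuals)) individuals$sd <- NA_real_
  if (!"n" %in% names(individuals)) individuals$n <- NA_integer_
  if (!"sd" %in% names(mixtures)) mixtures$sd <- NA_real_
  if (!"n" %in% names(mixtures)) mixtures$n <- NA_integer_

  dup <- individuals |>
    dplyr::count(.data$analyte, .data$assay, .data$concentration_um) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    warn(paste0(
      "averaging duplicate individual measurements for: ",
      paste(dup$analyte, dup$assay, dup$concentration_um, sep = "/",
            collapse = "; ")
    ))
    individuals <- individuals |>
      dplyr::group_by(.data$analyte, .data$assay, .data$concentration_um) |>
      dplyr::summarise(
        mean = base::mean(.data$mean),
        sd = base::mean(.data$sd),
        n = as.integer(round(base::mean(.data$n))),
        .groups = "drop"
      )
  }

  rows <- purrr::pmap_dfr(
    list(mixtures$analyte, mixtures$assay, mixtures$concentration_um,
         mixtures$mean, mixtures$sd, mixtures$n),
    function(label, assay, conc, exp_mean, exp_sd, n_exp) {
      comps <- sort(mixture_components(label)[[1]], method = "radix")
      ind <- individuals[individuals$assay == assay &
                           individuals$concentration_um == conc &
                           individuals$analyte %in% comps, , drop = FALSE]
      found <- comps %in% ind$analyte
      if (!all(found)) {
        abort(paste0(
          "missing individual measurement for compound '",
          comps[!found][1], "' in assay ", assay, " at ", conc, " uM"
        ))
      }
      ind <- ind[match(comps, ind$analyte), , drop = FALSE]
      k <- length(comps)
      theo <- theoretical_mixture_value(ind$mean, k)
      d <- difference_percent(exp_mean, theo)
      d_sd <- if (!is.na(exp_sd) && !anyNA(ind$sd) &&
                    !is.na(n_exp) && !anyNA(ind$n)) {
        difference_uncertainty(exp_mean, exp_sd, n_exp, ind$mean, ind$sd, ind$n)
      } else {
        NA_real_
      }
      tibble::tibble(
        mixture = paste(comps, collapse = "+"), k = k, assay = assay,
        concentration_um = conc, experimental = exp_mean, theoretical = theo,
        difference_pct = d, difference_sd = d_sd
      )
    }
  )
  rows |>
    dplyr::mutate(
      classification = classify_interaction(.data$difference_pct, config),
      theoretical_display = sprintf(
        "%d", as.integer(round_half_away(.data$theoretical, 0))
      ),
      difference_display = format_difference(.data$difference_pct)
    )
}

#' Difference-(%) trend of one mixture across concentrations
#'
#' Orders a mixture's interaction results by total concentration and flags
#' whether the difference strictly decreases with concentration, the
#' dilution-dependence pattern seen for several synergistic mixtures.
#'
#' @param results An [analyze_panel()] result filtered to one mixture and
#'   assay, with at least two concentrations.
#' @return A list with `trend` (tibble of `concentration_um`,
#'   `difference_pct`, `classification`, sorted by concentration) and
#'   `monotone_decrease` (logical).
#' @export
concentration_trend <- function(results) {
  if (length(unique(results$mixture)) != 1 ||
        length(unique(results$assay)) != 1) {
    abort("results must cover exactly one mixture in one assay")
  }
  if (nrow(results) < 2) {
    abort("need results at >= 2 concentrations for a trend")
  }
  trend <- results |>
    dplyr::arrange(.data$concentration_um) |>
    dplyr::select("concentration_um", "difference_pct", "classification")
  list(
    trend = trend,
    monotone_decrease = all(diff(trend$difference_pct) < 0)
  )
}
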