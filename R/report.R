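#' Render interaction results as a Markdown table
#'
#' A compact, publication-style layout of an [analyze_panel()] result:
#' one row per mixture with experimental, theoretical and difference
#' columns, synergistic differences emphasized in bold.
#'
#' @param results An [analyze_panel()] tibble.
#' @return Character vector of Markdown lines.
#' @export
#' @examples
#' fx <- load_fixtures()
#' res <- analyze_panel(
#'   fx$individuals,
#'   dplyr::transmute(
#'     dplyr::filter(fx$mixtures, table == 5),
#'     analyte = mixture, assay, concentration_um,
#'     mean = experimental_mean, sd = experimental_sd, n = 3L
#'   )
#' )
#' cat(head(render_interaction_report(res), 8), sep = "\n")
render_interaction_report <- function(results) {
  header <- c(
    "| Mixture | Assay | Conc (uM) | Experimental | Theoretical | Difference (%) | Interaction |",
    "|---|---|---|---|---|---|---|"
  )
  rows <- purrr::pmap_chr(
    list(results$mixture, results$assay, results$concentration_um,
         results$experimental, results$theoretical_display,
         results$difference_display, results$classification),
    function(mix, assay, conc, ex, theo, diff, cls) {
      diff_fmt <- if (cls == "synergistic") paste0("**", diff, "**") else diff
      sprintf(
        "| %s | %s | %g | %g | %s | %s | %s |",
        mix, assay, conc, ex, theo, diff_fmt, cls
      )
    }
  )
  c(header, rows)
}
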