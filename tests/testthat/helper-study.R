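# Shared across test files: the full printed-study analysis, computed once.
study_analysis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- load_fixtures()
      res <- analyze_panel(
        fx$individuals,
        dplyr::transmute(
          fx$mixtures,
          analyte = mixture, assay = assay,
          concentration_um = concentration_um,
          mean = experimental_mean, sd = experimental_sd, n = 3L
        )
      )
      cache <<- list(fixtures = fx, results = res)
    }
    cache
  }
})

# Look up one analyzed mixture row by components (any order), assay, conc.
study_row <- function(components, assay, conc) {
  res <- study_analysis()$results
  out <- res[res$mixture == mixture_label(components) & res$assay == assay &
               res$concentration_um == conc, ]
  stopifnot(nrow(out) == 1)
  out
}
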