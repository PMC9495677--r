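#' Assay measurement units
#'
#' FRAP results are expressed as the concentration of Fe2+ giving the same
#' reduction (uM Fe2+); ORAC results as Trolox Equivalents (uM TE).
#'
#' @param assay Character vector of assay tags, `"FRAP"` or `"ORAC"`.
#' @return Character vector of unit strings.
#' @export
#' @examples
#' activity_units(c("FRAP", "ORAC"))
activity_units <- function(assay) {
  check_assay(assay)
  unname(c(FRAP = "uM Fe2+", ORAC = "uM TE")[assay])
}

check_assay <- function(assay) {
  bad <- setdiff(unique(assay), c("FRAP", "ORAC"))
  if (length(bad) > 0) {
    abort(paste0("unknown assay tag(s): ", paste(bad, collapse = ", ")))
  }
  invisible(assay)
}

#' The ten-compound phenolic-acid study panel
#'
#' Returns the panel of five hydroxybenzoic acids (protocatechuic, gentisic,
#' gallic, vanillic, syringic), four hydroxycinnamic acids (p-coumaric,
#' caffeic, ferulic, sinapic) and rosmarinic acid (a caffeic-acid ester,
#' grouped with the hydroxycinnamic set), with their ring-substituent maps
#' (positions R1-R3) and molecule-level counts of hydroxyl and methoxy
#' groups. `has_catechol` marks an adjacent (ortho) dihydroxy pattern,
#' the structural motif associated with strong radical scavenging.
#' Rosmarinic acid, being an ester of two phenolic rings, carries no single
#' R1-R3 substituent map; only its molecule-level counts are populated.
#'
#' @return A tibble with one row per compound: `id`, `common_name`,
#'   `iupac_name`, `compound_class` (`hydroxybenzoic`, `hydroxycinnamic` or
#'   `caffeic_ester`), `r1`, `r2`, `r3` (each `"OH"`, `"OCH3"`, `"H"` or
#'   `NA`), `n_oh`, `n_och3`, `has_catechol`.
#' @export
#' @examples
#' study_panel()
study_panel <- function() {
  panel <- read_fixture_csv(
    "compounds.csv",
    readr::cols(
      id = readr::col_character(),
      common_name = readr::col_character(),
      iupac_name = readr::col_character(),
      compound_class = readr::col_character(),
      r1 = readr::col_character(),
      r2 = readr::col_character(),
      r3 = readr::col_character(),
      n_oh = readr::col_integer(),
      n_och3 = readr::col_integer(),
      has_catechol = readr::col_logical()
    )
  )
  validate_panel(panel)
}

#' Validate a compound panel
#'
#' Checks the structural invariants a panel must satisfy before it is used
#' downstream: unique ids, at least one hydroxyl per member, non-negative
#' methoxy counts, and (for ring-mapped compounds) agreement between the
#' methoxy count and the substituent map.
#'
#' @param panel A tibble as returned by [study_panel()].
#' @return The panel, invisibly unchanged, for piping.
#' @export
validate_panel <- function(panel) {
  required <- c("id", "compound_class", "n_oh", "n_och3", "has_catechol")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    abort(paste0("panel is missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(panel$id)) {
    abort("panel compound ids must be unique")
  }
  if (any(panel$n_oh < 1)) {
    abort("every panel member must carry at least one hydroxyl group")
  }
  if (any(panel$n_och3 < 0)) {
    abort("methoxy counts must be non-negative")
  }
  ringed <- panel[panel$compound_class != "caffeic_ester", , drop = FALSE]
  if (all(c("r1", "r2", "r3") %in% names(panel)) && nrow(ringed) > 0) {
    map_och3 <- rowSums(ringed[, c("r1", "r2", "r3")] == "OCH3", na.rm = TRUE)
    if (any(map_och3 != ringed$n_och3)) {
      abort("n_och3 must equal the number of OCH3 ring substituents")
    }
  }
  panel
}
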