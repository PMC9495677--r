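read_fixture_csv <- function(name, col_types) {
  path <- system.file("extdata", name, package = "phenolmix")
  if (path == "") {
    # during development (pkgload), fall back to the source tree
    path <- file.path("inst", "extdata", name)
  }
  if (!file.exists(path)) abort(paste0("packaged fixture not found: ", name))
  readr::read_csv(path, col_types = col_types)
}

#' Recorded discrepancies in the printed study tables
#'
#' Internal annotations shipped with the fixtures: cells whose printed
#' values are mutually inconsistent in the source tables. These are
#' surfaced by [reproduce_tables()]; the tables are stored as printed, and
#' nothing is adjudicated.
#'
#' @return A tibble with columns `id`, `scope`, `note`.
#' @export
fixture_notes <- function() {
  tibble::tribble(
    ~id, ~scope, ~note,
    "ferulic-500-theoretical", "table 4, 500 uM theoretical column",
    paste(
      "All 15 ferulic-containing theoretical cells are inconsistent with",
      "the printed individual activities; they reproduce almost exactly if",
      "ferulic's 500 uM FRAP mean (885) is replaced by 8885, indicating a",
      "systematic transcription error. The printed differences are",
      "consistent with the inflated theoreticals. Cells flagged known_typo."
    ),
    "csi-100-theoretical", "table 4, 100 uM, C+Si theoretical",
    paste(
      "Prints 3560 where the individual means give 355.5 (extra digit);",
      "the printed difference (-4.0) is consistent with 356. Flagged",
      "known_typo."
    ),
    "gesy-gsy-orac-text", "table 5 vs running text",
    paste(
      "The text names gentisic + syringic (-24%) as ORAC-antagonistic, but",
      "the table prints Ge+Sy at +236% and G+Sy at -24%. The table is",
      "taken as authoritative; the text discrepancy is recorded, not",
      "adjudicated."
    ),
    "duplicate-1440", "table 3, 1000 uM experimental",
    paste(
      "Ge+V and V+Sy both print 1440 +/- 23 - a possible copy error,",
      "stored as printed."
    ),
    "sinapic-sd-zero", "individual activities, sinapic FRAP 500 uM",
    "Prints 1201 +/- 0; an SD of exactly 0 over triplicates is suspicious but stored as printed."
  )
}

check_fixture_integrity <- function(individuals, mixtures) {
  ok <- nrow(individuals) == 50 &&
    nrow(mixtures) == 208 &&
    sum(mixtures$table == 3) == 78 &&
    sum(mixtures$table == 4) == 78 &&
    sum(mixtures$table == 5) == 26 &&
    sum(mixtures$table == 6) == 26
  if (ok) {
    sentinel_g <- individuals$mean[individuals$compound == "G" &
                                     individuals$assay == "FRAP" &
                                     individuals$concentration_um == 1000]
    sentinel_gesy <- mixtures$experimental_mean[mixtures$table == 5 &
                                                  mixtures$mixture == "Ge+Sy"]
    ok <- length(sentinel_g) == 1 && sentinel_g == 5033 &&
      length(sentinel_gesy) == 1 && sentinel_gesy == 158
  }
  if (!ok) abort("fixture integrity check failed: packaged study tables are corrupted")
  invisible(TRUE)
}

#' Load the packaged study dataset
#'
#' The complete printed dataset of the ten-acid study: the compound panel,
#' the individual activities (FRAP at 100/500/1000 uM, ORAC at 2.5/5 uM,
#' each mean +/- SD over triplicates), and the four mixture tables
#' (experimental mean +/- SD plus the printed theoretical and
#' difference-(%) cells, stored verbatim at printed precision as strings).
#' Fixture rows are summary-only: the replicate values behind the printed
#' means were never published.
#'
#' @return A list of class `fixture_set`: `panel`, `individuals` (summary
#'   measurement tibble), `mixtures` (one row per mixture x concentration
#'   with printed cells and `known_typo` flags), `notes`
#'   ([fixture_notes()]).
#' @export
#' @examples
#' fx <- load_fixtures()
#' dplyr::filter(fx$individuals, analyte == "G", assay == "FRAP")
load_fixtures <- function() {
  panel <- study_panel()
  individuals_raw <- read_fixture_csv(
    "individual_activities.csv",
    readr::cols(
      compound = readr::col_character(),
      assay = readr::col_character(),
      concentration_um = readr::col_double(),
      mean = readr::col_double(),
      sd = readr::col_double()
    )
  )
  mixtures_raw <- read_fixture_csv(
    "mixture_activities.csv",
    readr::cols(
      table = readr::col_integer(),
      assay = readr::col_character(),
      concentration_um = readr::col_double(),
      mixture = readr::col_character(),
      experimental_mean = readr::col_double(),
      experimental_sd = readr::col_double(),
      theoretical_printed = readr::col_character(),
      difference_printed = readr::col_character(),
      known_typo = readr::col_logical()
    )
  )
  check_fixture_integrity(individuals_raw, mixtures_raw)

  individuals <- individuals_raw |>
    dplyr::transmute(
      analyte = .data$compound,
      assay = .data$assay,
      concentration_um = .data$concentration_um,
      mean = .data$mean,
      sd = .data$sd,
      n = 3L,
      units = activity_units(.data$assay),
      summary_only = TRUE
    )
  mixtures <- mixtures_raw |>
    dplyr::mutate(
      mixture_canonical = mixture_label(mixture_components(.data$mixture)),
      k = lengths(mixture_components(.data$mixture)),
      theoretical_printed = normalize_printed(.data$theoretical_printed),
      difference_printed = normalize_printed(.data$difference_printed)
    )
  structure(
    list(
      panel = panel, individuals = individuals, mixtures = mixtures,
      notes = fixture_notes()
    ),
    class = "fixture_set"
  )
}

# canonicalize typographic minus signs and stray whitespace in printed cells
normalize_printed <- function(x) {
  x <- gsub("\u2212", "-", x) # typographic minus -> ASCII hyphen
  gsub("[[:space:]]", "", x)
}

printed_decimals <- function(x) {
  ifelse(grepl("\\.", x), nchar(sub("^[^.]*\\.", "", x)), 0L)
}

#' Recompute the printed interaction tables and compare cell by cell
#'
#' For every mixture row of the packaged tables, recomputes the
#' theoretical value (from the packaged individual activities) and the
#' difference (%) (from the printed experimental mean), rounds each to the
#' precision of the corresponding printed cell (half away from zero), and
#' compares. A cell passes when the gap is at most `tolerance_units` units
#' of the printed final digit - the printed tables were rounded from
#' unrounded raw replicate means, so exact agreement from printed inputs
#' cannot be expected everywhere. Cells flagged `known_typo` in the
#' fixtures (order-of-magnitude inconsistencies in the source) are
#' reported separately from ordinary flagged cells.
#'
#' @param fixtures A [load_fixtures()] result (or a subset of one).
#' @param config An [interaction_config()] (classification band for the
#'   recomputed results).
#' @param tolerance_units Allowed gap in final-digit units (default 1).
#' @return A list of class `table_reproduction`: `cells` (one row per
#'   printed cell: `table`, `assay`, `concentration_um`, `mixture`,
#'   `cell`, `printed`, `recomputed`, `recomputed_display`, `gap_units`,
#'   `status`, `known_typo`), `known_typos` (the subset), and `notes`.
#' @export
#' @examples
#' rep <- reproduce_tables(load_fixtures())
#' dplyr::filter(rep$cells, status == "flagged", !known_typo)
reproduce_tables <- function(fixtures, config = interaction_config(),
                             tolerance_units = 1) {
  mixtures <- fixtures$mixtures
  if (nrow(mixtures) == 0) {
    empty <- tibble::tibble(
      table = integer(), assay = character(), concentration_um = numeric(),
      mixture = character(), cell = character(), printed = numeric(),
      printed_display = character(), recomputed = numeric(),
      recomputed_display = character(), gap_units = numeric(),
      status = character(), known_typo = logical()
    )
    return(structure(
      list(cells = empty, known_typos = empty, notes = fixtures$notes),
      class = "table_reproduction"
    ))
  }
  results <- analyze_panel(
    fixtures$individuals,
    mixtures |>
      dplyr::transmute(
        analyte = .data$mixture, assay = .data$assay,
        concentration_um = .data$concentration_um,
        mean = .data$experimental_mean, sd = .data$experimental_sd, n = 3L
      ),
    config
  )
  joined <- mixtures |>
    dplyr::left_join(
      results |>
        dplyr::select(
          "mixture", "assay", "concentration_um",
          "theoretical", "difference_pct"
        ),
      by = c(mixture_canonical = "mixture", assay = "assay",
             concentration_um = "concentration_um")
    )
  cell_rows <- function(kind, printed_chr, recomputed) {
    dec <- printed_decimals(printed_chr)
    printed <- as.numeric(printed_chr)
    rec_rounded <- round_half_away(recomputed, dec)
    gap <- abs(rec_rounded - printed) * 10^dec
    tibble::tibble(
      table = joined$table, assay = joined$assay,
      concentration_um = joined$concentration_um, mixture = joined$mixture,
      cell = kind, printed = printed, printed_display = printed_chr,
      recomputed = recomputed,
      recomputed_display = sprintf(paste0("%.", dec, "f"), rec_rounded),
      gap_units = gap,
      # small epsilon absorbs binary-representation error in 0.1-unit gaps
      status = ifelse(gap <= tolerance_units + 1e-9, "pass", "flagged"),
      # a typo'd theoretical poisons the printed difference of the same row
      known_typo = joined$known_typo
    )
  }
  cells <- dplyr::bind_rows(
    cell_rows("theoretical", joined$theoretical_printed, joined$theoretical),
    cell_rows("difference", joined$difference_printed, joined$difference_pct)
  ) |>
    dplyr::arrange(.data$table, .data$concentration_um, .data$cell)
  structure(
    list(
      cells = cells,
      known_typos = cells[cells$known_typo, , drop = FALSE],
      notes = fixtures$notes
    ),
    class = "table_reproduction"
  )
}

#' @export
print.table_reproduction <- function(x, ...) {
  n <- nrow(x$cells)
  n_pass <- sum(x$cells$status == "pass")
  n_flag <- sum(x$cells$status == "flagged" & !x$cells$known_typo)
  n_typo <- sum(x$cells$known_typo & x$cells$status == "flagged")
  cat(sprintf(
    "table reproduction: %d cells; %d pass, %d flagged, %d known typos\n",
    n, n_pass, n_flag, n_typo
  ))
  if (n_flag > 0) {
    flagged <- x$cells[x$cells$status == "flagged" & !x$cells$known_typo, ]
    cat("flagged cells (printed vs recomputed):\n")
    for (i in seq_len(nrow(flagged))) {
      cat(sprintf(
        "  table %d %s %g uM %s [%s]: %s vs %s\n",
        flagged$table[i], flagged$assay[i], flagged$concentration_um[i],
        flagged$mixture[i], flagged$cell[i],
        flagged$printed_display[i], flagged$recomputed_display[i]
      ))
    }
  }
  cat(sprintf("recorded source discrepancies: %d (see $notes)\n", nrow(x$notes)))
  invisible(x)
}
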