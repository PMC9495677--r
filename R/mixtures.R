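#' Canonical mixture labels
#'
#' A mixture's identity is its set of components: `"P+Ge"` and `"Ge+P"`
#' name the same equimolar mixture. `mixture_label()` produces the
#' canonical (sorted, "+"-joined) label used for joins and equality;
#' `mixture_components()` splits a label back into its component ids.
#' Sorting uses the locale-independent C collation so labels are stable
#' across systems.
#'
#' @param ids Character vector of component ids, or a list of such vectors.
#' @return `mixture_label()`: character vector of canonical labels;
#'   `mixture_components()`: list of character vectors.
#' @export
#' @examples
#' mixture_label(c("Sy", "P", "Ge"))
#' mixture_components("Ge+P+Sy")
mixture_label <- function(ids) {
  if (!is.list(ids)) ids <- list(ids)
  vapply(ids, function(x) {
    if (anyDuplicated(x)) abort("mixture components must be distinct")
    paste(sort(x, method = "radix"), collapse = "+")
  }, character(1))
}

#' @param label Character vector of "+"-joined labels (any component order).
#' @rdname mixture_label
#' @export
mixture_components <- function(label) {
  strsplit(label, "+", fixed = TRUE)
}

#' Enumerate equimolar k-component mixtures of a panel
#'
#' Generates every k-subset of the panel ids for each k in `k_range`,
#' mirroring a full combinatorial equimolar design (binary through quinary
#' in the study). Output order is deterministic: k ascending, then
#' lexicographic by canonical label.
#'
#' @param panel_ids Character vector of distinct compound ids.
#' @param k_range Integer vector of subset sizes, each in `[2, length(panel_ids)]`.
#' @return A tibble with columns `mixture` (canonical label), `k`, and a
#'   list-column `components`.
#' @export
#' @examples
#' enumerate_equimolar_mixtures(c("P", "Ge", "G", "V", "Sy"), 2:5)
enumerate_equimolar_mixtures <- function(panel_ids, k_range = 2:5) {
  if (anyDuplicated(panel_ids)) abort("panel ids must be distinct")
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2)) abort("mixtures need at least 2 components")
  if (any(k_range > length(panel_ids))) {
    abort("k exceeds the panel size")
  }
  purrr::map_dfr(k_range, function(k) {
    sets <- utils::combn(panel_ids, k, simplify = FALSE)
    labels <- mixture_label(sets)
    ord <- order(labels, method = "radix")
    tibble::tibble(
      mixture = labels[ord],
      k = k,
      components = lapply(sets[ord], function(x) sort(x, method = "radix"))
    )
  })
}
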