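# Published reference totals shipped with the package.

#' Reference index totals for the 14 focal species
#'
#' Per-species totals from a published Andean woody-species survey of 40
#' informants: the freelist citation count and Composite Salience, and
#' the informant count, (participant, category) citation count, distinct
#' category count and Cultural Importance from the semi-structured
#' interviews. Used as a desk-check of the index arithmetic and of the
#' concordance between the two indices.
#'
#' @return A tibble with columns `species`, `salience_n_part`,
#'   `salience_n_cit`, `composite_s`, `ci_n_part`, `ci_n_cit`,
#'   `ci_n_cat`, `ci`.
#' @export
published_index_totals <- function() {
  path <- system.file("extdata", "reference_indices.csv",
                      package = "ethnoindices")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
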