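# Cultural Importance from use-reports: category profiles, use-type
# counts and the CI index (sum over categories of the proportion of
# informants mentioning the category).

#' Use-category profile of one participant for one species
#'
#' Groups the participant's use-reports for the species into the nine
#' use-categories, counting distinct use-types per category (labels are
#' normalized, so restating the same use twice counts once) and deriving
#' the 0/1 mention indicator per category.
#'
#' @param data An `interview_data` object.
#' @param participant_id Single participant id.
#' @param species_code Single species code.
#' @return A 9-row tibble: `use_category`, `n_use_types`, `mentioned`.
#' @export
category_profile <- function(data, participant_id, species_code) {
  stopifnot(inherits(data, "interview_data"))
  check_species_code(data, species_code)
  resolve_participants(data, participant_id)
  u <- data$use_reports
  u <- u[u$participant_id == participant_id &
           u$species_code == species_code, ]
  counts <- table(factor(u$use_category, levels = use_categories()))
  tibble::tibble(
    use_category = use_categories(),
    n_use_types = as.integer(counts),
    mentioned = as.integer(counts > 0)
  )
}

#' Use-type counts for a species, per participant
#'
#' The response variable of the count models: for each participant, the
#' number of distinct use-types reported for the species, per
#' use-category and in total.
#'
#' @param data An `interview_data` object.
#' @param species_code Single species code.
#' @return A tibble with one row per roster participant: `participant_id`,
#'   one integer column per use-category, and `total`.
#' @export
use_type_counts <- function(data, species_code) {
  stopifnot(inherits(data, "interview_data"))
  check_species_code(data, species_code)
  u <- data$use_reports[data$use_reports$species_code == species_code, ]
  grid <- tidyr::expand_grid(participant_id = data$participants$id,
                             use_category = use_categories())
  tab <- dplyr::summarise(
    dplyr::group_by(u, .data$participant_id,
                    use_category = as.character(.data$use_category)),
    n = dplyr::n(), .groups = "drop")
  long <- dplyr::left_join(grid, tab,
                           by = c("participant_id", "use_category"))
  long$n[is.na(long$n)] <- 0L
  wide <- tidyr::pivot_wider(long, names_from = "use_category",
                             values_from = "n")
  wide$total <- as.integer(rowSums(wide[, use_categories()]))
  wide
}

# Per (participant, species): number of distinct categories mentioned.
# Restricted to participants with >= 1 record unless assume_all_asked.
category_mention_counts <- function(data) {
  u <- data$use_reports
  dplyr::summarise(
    dplyr::group_by(u, .data$participant_id, .data$species_code),
    n_categories = dplyr::n_distinct(.data$use_category),
    .groups = "drop")
}

ci_denominator_ids <- function(data, species_code, ids, assume_all_asked) {
  if (assume_all_asked) return(ids)
  seen <- unique(data$use_reports$participant_id[
    data$use_reports$species_code == species_code])
  intersect(ids, seen)
}

#' Cultural Importance of a species
#'
#' CI is the sum over the nine use-categories of the proportion of
#' informants that mentioned the category for the species, equivalently
#' the total number of (participant, category) mention pairs divided by
#' the number of informants. Ranges from 0 (no category mentioned by
#' anyone) to 9 (every category mentioned by every informant).
#'
#' @param data An `interview_data` object.
#' @param species_code Single species code.
#' @param participants Optional participant-id subset (subgroup CI);
#'   `NULL` uses the roster.
#' @param assume_all_asked If `TRUE` the denominator is the full
#'   participant set given; if `FALSE` (default) only participants with at
#'   least one use-report for the species count as informants, matching
#'   surveys where not everyone was interviewed about every species.
#' @return CI in `[0, 9]`.
#' @export
cultural_importance <- function(data, species_code, participants = NULL,
                                assume_all_asked = FALSE) {
  stopifnot(inherits(data, "interview_data"))
  check_species_code(data, species_code)
  ids <- resolve_participants(data, participants)
  denom_ids <- ci_denominator_ids(data, species_code, ids, assume_all_asked)
  if (length(denom_ids) == 0) return(0)
  cm <- category_mention_counts(data)
  cm <- cm[cm$species_code == species_code &
             cm$participant_id %in% denom_ids, ]
  sum(cm$n_categories) / length(denom_ids)
}

#' Cultural Importance table, total and per actor group
#'
#' Per species: the number of informants (`n_part`), the number of
#' (participant, category) mention pairs (`n_cit`), the number of
#' distinct categories cited (`n_cat`), the total CI
#' (`ci = n_cit / n_part`) and, when a grouping factor is given, the mean
#' and standard deviation over subgroup members of the per-participant
#' count of mentioned categories (whose mean is the subgroup CI).
#'
#' @inheritParams cultural_importance
#' @param grouping One of `"none"`, `"sex"`, `"age_class"`,
#'   `"migration_group"`.
#' @return A tibble, one row per species.
#' @export
ci_table <- function(data,
                     grouping = c("none", "sex", "age_class",
                                  "migration_group"),
                     assume_all_asked = FALSE) {
  stopifnot(inherits(data, "interview_data"))
  grouping <- match.arg(grouping)
  roster <- data$participants$id
  cm <- category_mention_counts(data)
  rows <- lapply(data$species$code, function(sp) {
    denom_ids <- ci_denominator_ids(data, sp, roster, assume_all_asked)
    cmi <- cm[cm$species_code == sp & cm$participant_id %in% denom_ids, ]
    n_cit <- sum(cmi$n_categories)
    u <- data$use_reports[data$use_reports$species_code == sp &
                            data$use_reports$participant_id %in% denom_ids, ]
    tibble::tibble(
      species = sp,
      n_part = length(denom_ids),
      n_cit = as.integer(n_cit),
      n_cat = dplyr::n_distinct(as.character(u$use_category)),
      ci = if (length(denom_ids) == 0) 0 else n_cit / length(denom_ids))
  })
  totals <- dplyr::bind_rows(rows)
  if (grouping == "none") return(totals)
  # per-participant category counts (zeros for informants with no record)
  scores <- dplyr::bind_rows(lapply(data$species$code, function(sp) {
    denom_ids <- ci_denominator_ids(data, sp, roster, assume_all_asked)
    if (length(denom_ids) == 0) return(NULL)
    g <- tibble::tibble(participant_id = denom_ids, species_code = sp)
    g <- dplyr::left_join(g, cm, by = c("participant_id", "species_code"))
    g$n_categories[is.na(g$n_categories)] <- 0L
    g
  }))
  groups <- group_summary(scores, data, grouping, "n_categories")
  dplyr::left_join(totals, groups, by = "species")
}
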