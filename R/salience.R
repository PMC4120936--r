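# Freelist salience: per-participant salience and Composite Salience.

#' Per-participant freelist salience of one species
#'
#' For a species at 1-based position `r` in a freelist of length `L`, the
#' salience is its inverse rank divided by the list length,
#' `(L - r + 1) / L`, so the first mention scores 1 and the last `1/L`.
#' A species absent from the list scores 0.
#'
#' @param mentions Character vector of species codes in mention order
#'   (duplicate-free).
#' @param species_code Single species code.
#' @return Salience in `[0, 1]`.
#' @export
#' @examples
#' participant_salience(c("SM", "EG", "BD"), "SM") # 1
#' participant_salience(c("SM", "EG", "BD"), "BD") # 1/3
#' participant_salience(c("SM", "EG", "BD"), "PL") # 0
participant_salience <- function(mentions, species_code) {
  mentions <- as.character(mentions)
  if (anyDuplicated(mentions)) {
    stop("freelist contains duplicate species codes", call. = FALSE)
  }
  L <- length(mentions)
  if (L == 0) return(0)
  r <- match(species_code, mentions)
  if (is.na(r)) return(0)
  (L - r + 1) / L
}

# Salience of every (participant, species) pair as a long tibble.
# Participants without a freelist get salience 0 for every species.
salience_scores <- function(data) {
  stopifnot(inherits(data, "interview_data"))
  grid <- tidyr::expand_grid(participant_id = data$participants$id,
                             species_code = data$species$code)
  fl <- data$freelists
  if (nrow(fl) == 0) {
    grid$salience <- 0
    return(grid)
  }
  lens <- dplyr::summarise(dplyr::group_by(fl, .data$participant_id),
                           L = dplyr::n(), .groups = "drop")
  scored <- dplyr::mutate(dplyr::left_join(fl, lens, by = "participant_id"),
                          salience = (.data$L - .data$rank + 1) / .data$L)
  out <- dplyr::left_join(grid,
                          scored[, c("participant_id", "species_code",
                                     "salience")],
                          by = c("participant_id", "species_code"))
  out$salience[is.na(out$salience)] <- 0
  out
}

#' Composite Salience of a species
#'
#' The mean per-participant salience over a set of informants: the sum of
#' salience scores divided by the number of participants in the set (the
#' full roster by default). Participants with no freelist contribute 0;
#' for subgroups the denominator is the subgroup size. Ranges from 0
#' (never mentioned) to 1 (mentioned first by everyone).
#'
#' @param data An `interview_data` object.
#' @param species_code Single species code.
#' @param participants Optional character vector of participant ids
#'   restricting the denominator to a subgroup; `NULL` uses the roster.
#' @return Composite Salience in `[0, 1]`.
#' @export
composite_salience <- function(data, species_code, participants = NULL) {
  stopifnot(inherits(data, "interview_data"))
  check_species_code(data, species_code)
  ids <- resolve_participants(data, participants)
  scores <- salience_scores(data)
  s <- scores$salience[scores$species_code == species_code &
                         scores$participant_id %in% ids]
  sum(s) / length(ids)
}

#' Composite Salience table, total and per actor group
#'
#' Per species: the number of participants in the denominator, the number
#' of citations (participants mentioning the species anywhere in their
#' freelist), the Composite Salience over all participants and, when a
#' grouping factor is given, the mean and standard deviation of
#' per-participant saliences within each level of the factor. The
#' per-level mean is the subgroup Composite Salience (subgroup-size
#' denominator).
#'
#' @param data An `interview_data` object.
#' @param grouping One of `"none"`, `"sex"`, `"age_class"`,
#'   `"migration_group"`.
#' @return A tibble with one row per species: `species`, `n_part`,
#'   `n_cit`, `composite_s`, then `<level>_mean` / `<level>_sd` columns
#'   for each factor level.
#' @export
salience_table <- function(data,
                           grouping = c("none", "sex", "age_class",
                                        "migration_group")) {
  stopifnot(inherits(data, "interview_data"))
  grouping <- match.arg(grouping)
  scores <- salience_scores(data)
  totals <- dplyr::summarise(
    dplyr::group_by(scores, species = .data$species_code),
    n_part = dplyr::n(),
    n_cit = sum(.data$salience > 0),
    composite_s = mean(.data$salience),
    .groups = "drop")
  totals <- totals[match(data$species$code, totals$species), ]
  if (grouping == "none") return(totals)
  groups <- group_summary(scores, data, grouping, "salience")
  dplyr::left_join(totals, groups, by = "species")
}

# Shared per-group mean +/- sd machinery for both index tables.
# `scores` is long with participant_id, species_code and a value column.
group_summary <- function(scores, data, grouping, value_col) {
  roster <- data$participants[, c("id", grouping)]
  names(roster) <- c("participant_id", "group")
  joined <- dplyr::left_join(scores, roster, by = "participant_id")
  long <- dplyr::summarise(
    dplyr::group_by(joined, species = .data$species_code, .data$group),
    mean = mean(.data[[value_col]]),
    sd = stats::sd(.data[[value_col]]),
    .groups = "drop")
  long$group <- factor(long$group, levels = levels(roster$group))
  wide <- tidyr::pivot_wider(long, names_from = "group",
                             values_from = c("mean", "sd"),
                             names_glue = "{group}_{.value}")
  # order columns level by level: <lvl>_mean, <lvl>_sd
  lv <- levels(data$participants[[grouping]])
  cols <- as.vector(rbind(paste0(lv, "_mean"), paste0(lv, "_sd")))
  wide[, c("species", intersect(cols, names(wide)))]
}
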