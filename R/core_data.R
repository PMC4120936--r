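# Typed records, CSV readers/writers and validators for interview data.

#' The nine use-categories of the interview protocol
#'
#' Semi-structured interviews record plant uses in a closed set of nine
#' categories (construction, environmental use, field use, fodder, food,
#' fuel, medicine, tools, other). All use-reports must carry one of these.
#'
#' @return Character vector of the nine category labels, in canonical order.
#' @export
use_categories <- function() {
  c("construction", "environmental", "field", "fodder", "food",
    "fuel", "medicine", "tools", "other")
}

age_class_levels <- function() c("<20", "20-39", "40-59", ">=60")
migration_group_levels <- function() c("no_young", "no_old", "temp", "perm")
migration_status_levels <- function() c("none", "temporary", "permanent")
sex_levels <- function() c("female", "male")

#' Assign the four survey age classes
#'
#' Bins a continuous age in years into the survey's four classes
#' `<20`, `20-39`, `40-59`, `>=60`. Bins are half-open and
#' lower-inclusive, so boundary ages 20, 40 and 60 fall in the upper class.
#'
#' @param age_years Positive numeric vector of ages in years.
#' @return Factor with levels `<20`, `20-39`, `40-59`, `>=60`.
#' @export
assign_age_class <- function(age_years) {
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    stop("`age_years` must be positive and finite", call. = FALSE)
  }
  cut(age_years, breaks = c(0, 20, 40, 60, Inf), right = FALSE,
      labels = age_class_levels())
}

#' Assign migration actor groups
#'
#' Non-migrants are split by age into `no_young` (under 40) and `no_old`
#' (40 or older); temporary and permanent migrants map to `temp` and
#' `perm` regardless of age (the survey design only contains migrants
#' under 40, but the rule itself does not depend on that).
#'
#' @param age_years Positive numeric vector of ages in years.
#' @param migration_status Character or factor with values `none`,
#'   `temporary`, `permanent`.
#' @return Factor with levels `no_young`, `no_old`, `temp`, `perm`.
#' @export
assign_migration_group <- function(age_years, migration_status) {
  status <- as.character(migration_status)
  bad <- setdiff(unique(status), migration_status_levels())
  if (length(bad) > 0) {
    stop("unknown migration_status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(age_years)) || any(age_years <= 0)) {
    stop("`age_years` must be positive and finite", call. = FALSE)
  }
  grp <- ifelse(status == "temporary", "temp",
         ifelse(status == "permanent", "perm",
         ifelse(age_years < 40, "no_young", "no_old")))
  factor(grp, levels = migration_group_levels())
}

row_error <- function(file, row, msg) {
  stop(sprintf("%s, row %s: %s", file, row, msg), call. = FALSE)
}

need_columns <- function(df, cols, file) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing column(s) %s", file,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
}

check_enum <- function(values, allowed, file, column) {
  bad <- which(!(as.character(values) %in% allowed))
  if (length(bad) > 0) {
    row_error(file, bad[1],
              sprintf("unknown %s value '%s'", column, values[bad[1]]))
  }
}

#' Normalize free-text use-type labels
#'
#' Use-types come from interview transcriptions; labels are case-folded
#' and whitespace-normalized before uniqueness is assessed so that
#' "Stomach ache" and "stomach  ache" count as one use-type.
#'
#' @param x Character vector of raw labels.
#' @return Normalized character vector.
#' @export
normalize_use_type <- function(x) {
  x <- tolower(trimws(x))
  gsub("\\s+", " ", x)
}

validate_participants <- function(df, file = "participants") {
  need_columns(df, c("id", "sex", "age_years", "migration_status"), file)
  df$id <- as.character(df$id)
  if (anyDuplicated(df$id)) {
    row_error(file, which(duplicated(df$id))[1],
              sprintf("duplicate participant id '%s'",
                      df$id[duplicated(df$id)][1]))
  }
  check_enum(df$sex, sex_levels(), file, "sex")
  check_enum(df$migration_status, migration_status_levels(), file,
             "migration_status")
  bad_age <- which(!is.finite(df$age_years) | df$age_years <= 0)
  if (length(bad_age) > 0) row_error(file, bad_age[1], "non-positive age")
  tibble::tibble(
    id = df$id,
    sex = factor(df$sex, levels = sex_levels()),
    age_years = as.numeric(df$age_years),
    migration_status = factor(df$migration_status,
                              levels = migration_status_levels()),
    age_class = assign_age_class(df$age_years),
    migration_group = assign_migration_group(df$age_years,
                                             df$migration_status)
  )
}

validate_species <- function(df, file = "species") {
  need_columns(df, c("code", "scientific_name", "family", "life_form",
                     "origin"), file)
  df$code <- as.character(df$code)
  if (anyDuplicated(df$code)) {
    row_error(file, which(duplicated(df$code))[1],
              sprintf("duplicate species code '%s'",
                      df$code[duplicated(df$code)][1]))
  }
  check_enum(df$life_form, c("tree", "shrub", "subshrub"), file, "life_form")
  check_enum(df$origin, c("native", "native_cultivated", "exotic"), file,
             "origin")
  if (!("vernacular" %in% names(df))) df$vernacular <- ""
  tibble::as_tibble(df[, c("code", "scientific_name", "family", "life_form",
                           "origin", "vernacular")])
}

validate_freelists <- function(df, participants, species,
                               file = "freelists") {
  need_columns(df, c("participant_id", "rank", "species_code"), file)
  df$participant_id <- as.character(df$participant_id)
  df$species_code <- as.character(df$species_code)
  bad <- which(!(df$participant_id %in% participants$id))
  if (length(bad) > 0) {
    row_error(file, bad[1],
              sprintf("unknown participant id '%s'",
                      df$participant_id[bad[1]]))
  }
  bad <- which(!(df$species_code %in% species$code))
  if (length(bad) > 0) {
    row_error(file, bad[1],
              sprintf("unregistered species code '%s'",
                      df$species_code[bad[1]]))
  }
  dup <- which(duplicated(df[, c("participant_id", "species_code")]))
  if (length(dup) > 0) {
    row_error(file, dup[1],
              sprintf("species '%s' listed twice by participant '%s'",
                      df$species_code[dup[1]], df$participant_id[dup[1]]))
  }
  dup_rank <- which(duplicated(df[, c("participant_id", "rank")]))
  if (length(dup_rank) > 0) {
    row_error(file, dup_rank[1],
              sprintf("duplicate rank %s for participant '%s'",
                      df$rank[dup_rank[1]], df$participant_id[dup_rank[1]]))
  }
  # ranks must be 1..L within each participant (one ordered list each)
  out <- dplyr::arrange(tibble::as_tibble(df), .data$participant_id,
                        .data$rank)
  chk <- dplyr::summarise(dplyr::group_by(out, .data$participant_id),
                          ok = all(.data$rank == seq_along(.data$rank)),
                          .groups = "drop")
  if (any(!chk$ok)) {
    stop(sprintf("%s: ranks for participant '%s' are not 1..L", file,
                 chk$participant_id[!chk$ok][1]), call. = FALSE)
  }
  out
}

validate_use_reports <- function(df, participants, species,
                                 file = "use_reports") {
  need_columns(df, c("participant_id", "species_code", "use_category",
                     "use_type"), file)
  df$participant_id <- as.character(df$participant_id)
  df$species_code <- as.character(df$species_code)
  bad <- which(!(df$participant_id %in% participants$id))
  if (length(bad) > 0) {
    row_error(file, bad[1],
              sprintf("unknown participant id '%s'",
                      df$participant_id[bad[1]]))
  }
  bad <- which(!(df$species_code %in% species$code))
  if (length(bad) > 0) {
    row_error(file, bad[1],
              sprintf("unregistered species code '%s'",
                      df$species_code[bad[1]]))
  }
  check_enum(df$use_category, use_categories(), file, "use_category")
  out <- tibble::as_tibble(df)
  out$use_type <- normalize_use_type(out$use_type)
  out$use_category <- factor(out$use_category, levels = use_categories())
  # duplicates after normalization collapse to one report
  dplyr::distinct(out, .data$participant_id, .data$species_code,
                  .data$use_category, .data$use_type)
}

#' Assemble and validate an interview dataset
#'
#' Bundles a participant roster, a species registry, freelists (long
#' format: one row per mention with its 1-based rank) and use-reports into
#' a validated `interview_data` object. All foreign keys are resolved,
#' derived participant fields (`age_class`, `migration_group`) populated,
#' ranks checked to be contiguous from 1 within each participant, and
#' use-type labels normalized and de-duplicated.
#'
#' @param participants Data frame with columns `id`, `sex`, `age_years`,
#'   `migration_status`.
#' @param species Data frame with columns `code`, `scientific_name`,
#'   `family`, `life_form`, `origin` and optional `vernacular`.
#' @param freelists Data frame with columns `participant_id`, `rank`,
#'   `species_code`. May have zero rows.
#' @param use_reports Data frame with columns `participant_id`,
#'   `species_code`, `use_category`, `use_type`. May have zero rows.
#' @return An `interview_data` object (a list of four validated tibbles).
#' @export
interview_data <- function(participants, species, freelists, use_reports) {
  p <- validate_participants(participants)
  s <- validate_species(species)
  f <- validate_freelists(freelists, p, s)
  u <- validate_use_reports(use_reports, p, s)
  structure(list(participants = p, species = s, freelists = f,
                 use_reports = u),
            class = "interview_data")
}

#' @export
print.interview_data <- function(x, ...) {
  cat(sprintf(
    "<interview_data> %d participants, %d species, %d freelist mentions, %d use-reports\n",
    nrow(x$participants), nrow(x$species), nrow(x$freelists),
    nrow(x$use_reports)))
  invisible(x)
}

#' Read an interview dataset from four CSV files
#'
#' Expects UTF-8 comma-separated files with header rows:
#' `participants.csv` (`id,sex,age_years,migration_status`),
#' `species.csv` (`code,scientific_name,family,life_form,origin,vernacular`),
#' `freelists.csv` (`participant_id,rank,species_code`) and
#' `use_reports.csv` (`participant_id,species_code,use_category,use_type`).
#' Validation errors name the offending file and row.
#'
#' @param dir Directory containing the four files, or `NULL` when paths
#'   are given explicitly.
#' @param participants,species,freelists,use_reports Explicit file paths
#'   overriding the directory convention.
#' @return An `interview_data` object.
#' @export
read_interview_data <- function(dir = NULL,
                                participants = file.path(dir, "participants.csv"),
                                species = file.path(dir, "species.csv"),
                                freelists = file.path(dir, "freelists.csv"),
                                use_reports = file.path(dir, "use_reports.csv")) {
  read1 <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  p <- validate_participants(read1(participants), basename(participants))
  s <- validate_species(read1(species), basename(species))
  f <- validate_freelists(read1(freelists), p, s, basename(freelists))
  u <- validate_use_reports(read1(use_reports), p, s, basename(use_reports))
  structure(list(participants = p, species = s, freelists = f,
                 use_reports = u),
            class = "interview_data")
}

#' Write an interview dataset back to four CSV files
#'
#' Inverse of [read_interview_data()]; `read(write(x))` is the identity
#' on validated datasets.
#'
#' @param data An `interview_data` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_interview_data <- function(data, dir) {
  stopifnot(inherits(data, "interview_data"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- data$participants[, c("id", "sex", "age_years", "migration_status")]
  readr::write_csv(p, file.path(dir, "participants.csv"), progress = FALSE)
  readr::write_csv(data$species, file.path(dir, "species.csv"),
                   progress = FALSE)
  readr::write_csv(data$freelists, file.path(dir, "freelists.csv"),
                   progress = FALSE)
  readr::write_csv(data$use_reports, file.path(dir, "use_reports.csv"),
                   progress = FALSE)
  invisible(dir)
}

#' Write an index table to CSV
#'
#' Writes a salience or cultural-importance table (see [salience_table()]
#' and [ci_table()]) as CSV, one row per species. Numeric columns
#' round-trip through [read_index_table()] losslessly to at least six
#' decimals.
#'
#' @param table A tibble as produced by the index-table functions.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_index_table <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_index_table
#' @export
read_index_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

# Participant subset helper: NULL means the full roster.
resolve_participants <- function(data, participants) {
  if (is.null(participants)) return(data$participants$id)
  participants <- as.character(participants)
  if (length(participants) == 0) {
    stop("participant subset is empty", call. = FALSE)
  }
  bad <- setdiff(participants, data$participants$id)
  if (length(bad) > 0) {
    stop("unknown participant id(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  participants
}

check_species_code <- function(data, species_code) {
  if (!(species_code %in% data$species$code)) {
    stop("unregistered species code '", species_code, "'", call. = FALSE)
  }
  species_code
}
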