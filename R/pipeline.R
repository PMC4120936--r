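# Orchestration: simulate / indices / compare / models as composable
# stages writing tidy CSVs plus a reproducibility manifest.

config_fingerprint <- function(config) {
  # stable content hash of the (seed-free) configuration
  rlang::hash(lapply(unclass(config), function(x) {
    if (is.data.frame(x)) as.list(x) else x
  }))
}

write_manifest <- function(out_dir, stage, seed = NULL, config = NULL,
                           extra = list()) {
  manifest <- c(list(
    stage = stage,
    package = "ethnoindices",
    version = as.character(utils::packageVersion("ethnoindices")),
    seed = seed,
    config_hash = if (is.null(config)) NULL else
      config_fingerprint(config)),
    extra)
  jsonlite::write_json(manifest,
                       file.path(out_dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

#' Simulate a dataset to disk
#'
#' Writes the four interview CSVs plus a manifest recording the seed and
#' a configuration hash; reruns with the same seed and configuration
#' produce identical files.
#'
#' @param out_dir Output directory (created if absent).
#' @param config A [generator_config()].
#' @param seed Integer seed.
#' @return The simulated `interview_data`, invisibly.
#' @export
run_simulate <- function(out_dir, config = generator_config(), seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data <- simulate_interviews(config, seed = seed)
  write_interview_data(data, out_dir)
  write_manifest(out_dir, "simulate", seed = seed, config = config)
  invisible(data)
}

as_interview_data <- function(input) {
  if (inherits(input, "interview_data")) return(input)
  read_interview_data(input)
}

#' Compute and write both index tables
#'
#' Writes the Composite Salience and Cultural Importance tables (total
#' plus per-group columns for the requested factor) and a JSON summary
#' holding the Spearman concordance of the two totals.
#'
#' @param input An `interview_data` object or a directory of the four
#'   CSVs.
#' @param out_dir Output directory.
#' @param grouping `"none"`, `"sex"`, `"age_class"` or
#'   `"migration_group"`.
#' @param assume_all_asked Passed to [ci_table()].
#' @return A list with both tables and the concordance, invisibly.
#' @export
run_indices <- function(input, out_dir, grouping = "none",
                        assume_all_asked = FALSE) {
  data <- as_interview_data(input)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sal <- salience_table(data, grouping = grouping)
  ci <- ci_table(data, grouping = grouping,
                 assume_all_asked = assume_all_asked)
  write_index_table(sal, file.path(out_dir, "composite_salience.csv"))
  write_index_table(ci, file.path(out_dir, "cultural_importance.csv"))
  conc <- if (stats::sd(rank(sal$composite_s)) == 0 ||
                stats::sd(rank(ci$ci)) == 0) {
    list(rho = NA_real_, p = NA_real_, n = nrow(sal))
  } else {
    index_concordance(sal$composite_s, ci$ci)
  }
  write_manifest(out_dir, "indices",
                 extra = list(grouping = grouping,
                              spearman_rho = conc$rho,
                              spearman_p = conc$p))
  invisible(list(salience = sal, ci = ci, concordance = conc))
}

#' Run the ANOVA/Tukey and proportion-test screen
#'
#' For both indices and every actor-group factor, writes the tidy ANOVA
#' table (with significance stars), the Tukey pairwise comparisons, and
#' per-category proportion tests for every species.
#'
#' @inheritParams run_indices
#' @param alpha Significance threshold used only for labelling.
#' @param method Proportion-test flavour, see
#'   [category_proportion_test()].
#' @return A list of the three result tibbles, invisibly.
#' @export
run_compare <- function(input, out_dir, alpha = 0.05,
                        method = c("chisq", "exact")) {
  data <- as_interview_data(input)
  method <- match.arg(method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  factors <- c("sex", "age_class", "migration_group")
  anovas <- dplyr::bind_rows(lapply(c("salience", "ci"), function(ix) {
    dplyr::bind_rows(lapply(factors, function(f) {
      compare_groups(data, index = ix, grouping = f)
    }))
  }))
  tukey <- dplyr::bind_rows(lapply(seq_len(nrow(anovas)), function(i) {
    tk <- anovas$tukey[[i]]
    if (is.null(tk)) return(NULL)
    dplyr::mutate(tk, species = anovas$species[i],
                  index = anovas$index[i], factor = anovas$factor[i],
                  .before = 1)
  }))
  props <- dplyr::bind_rows(lapply(data$species$code, function(sp) {
    dplyr::bind_rows(lapply(factors, function(f) {
      dplyr::mutate(proportion_tests(data, sp, grouping = f,
                                     method = method),
                    factor = f, .after = "use_category")
    }))
  }))
  readr::write_csv(dplyr::select(anovas, -"tukey"),
                   file.path(out_dir, "anova_results.csv"),
                   progress = FALSE)
  readr::write_csv(tukey, file.path(out_dir, "tukey_results.csv"),
                   progress = FALSE)
  readr::write_csv(props, file.path(out_dir, "proportion_tests.csv"),
                   progress = FALSE)
  write_manifest(out_dir, "compare", extra = list(alpha = alpha,
                                                  method = method))
  invisible(list(anova = anovas, tukey = tukey, proportions = props))
}

#' Fit and write the count models
#'
#' Fits the per-species (quasi-)Poisson GLMs and the per-category
#' crossed-random-effects mixed models, writing the wide coefficient
#' tables (dropped terms as `"ns"`) and the stepwise drop logs. Model
#' failures for single species or categories are logged and skipped so
#' the rest still report.
#'
#' @inheritParams run_indices
#' @param alpha Stepwise retention threshold.
#' @param dispersion_threshold Quasi refit trigger.
#' @return A list with both model sets, invisibly.
#' @export
run_models <- function(input, out_dir, alpha = 0.05,
                       dispersion_threshold = 1.5) {
  data <- as_interview_data(input)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sm <- species_models(data, dispersion_threshold = dispersion_threshold,
                       alpha = alpha)
  cm <- category_models(data, alpha = alpha)
  readr::write_csv(sm$table, file.path(out_dir, "species_models.csv"),
                   progress = FALSE)
  readr::write_csv(cm$table, file.path(out_dir, "category_models.csv"),
                   progress = FALSE)
  if (!is.null(sm$drop_log)) {
    readr::write_csv(sm$drop_log,
                     file.path(out_dir, "species_drop_log.csv"),
                     progress = FALSE)
  }
  if (!is.null(cm$drop_log)) {
    readr::write_csv(cm$drop_log,
                     file.path(out_dir, "category_drop_log.csv"),
                     progress = FALSE)
  }
  write_manifest(out_dir, "models",
                 extra = list(alpha = alpha,
                              dispersion_threshold = dispersion_threshold,
                              species_failures = as.list(sm$failures),
                              category_failures = as.list(cm$failures)))
  invisible(list(species = sm, categories = cm))
}

#' Run the whole pipeline
#'
#' Simulate (optional), indices, group comparisons and count models in
#' one call.
#'
#' @param out_dir Output directory.
#' @param input Existing dataset (object or directory); when `NULL` a
#'   dataset is simulated first with `config` and `seed`.
#' @param config,seed Passed to [run_simulate()] when simulating.
#' @param grouping Grouping factor for the index tables.
#' @param alpha Significance threshold for comparisons and stepwise.
#' @return A list of all stage results, invisibly.
#' @export
run_all <- function(out_dir, input = NULL, config = generator_config(),
                    seed = 1, grouping = "sex", alpha = 0.05) {
  data <- if (is.null(input)) run_simulate(out_dir, config, seed) else
    as_interview_data(input)
  idx <- run_indices(data, out_dir, grouping = grouping)
  cmp <- run_compare(data, out_dir, alpha = alpha)
  mod <- run_models(data, out_dir, alpha = alpha)
  invisible(list(data = data, indices = idx, compare = cmp,
                 models = mod))
}
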