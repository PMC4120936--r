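# ANCOVA-style Poisson / quasi-Poisson models of use-type counts,
# stepwise-backward simplification by LRT or F tests, and a Poisson
# mixed model with crossed participant x species random intercepts.

#' Per-participant covariates and use-type counts for one species
#'
#' The modelling frame behind the per-species count models: one row per
#' participant with the total number of distinct use-types reported for
#' the species, age in years (continuous), sex, and migration pooled to
#' a binary resident/migrant covariate (temporary and permanent migrants
#' grouped, reflecting their low numbers in the survey design).
#'
#' @param data An `interview_data` object.
#' @param species_code Single species code.
#' @return A tibble: `participant_id`, `count`, `age`, `sex`, `migrant`.
#' @export
species_use_data <- function(data, species_code) {
  stopifnot(inherits(data, "interview_data"))
  check_species_code(data, species_code)
  counts <- use_type_counts(data, species_code)
  tibble::tibble(
    participant_id = data$participants$id,
    count = counts$total[match(data$participants$id,
                               counts$participant_id)],
    age = data$participants$age_years,
    sex = data$participants$sex,
    migrant = factor(ifelse(data$participants$migration_status == "none",
                            "no", "yes"), levels = c("no", "yes")))
}

#' Counts per participant, species and use-category
#'
#' The modelling frame behind the crossed-random-effects mixed models:
#' one row per participant x species x use-category with the number of
#' distinct use-types mentioned (zeros included), plus the participant
#' covariates of [species_use_data()].
#'
#' @param data An `interview_data` object.
#' @return A tibble: `participant_id`, `species_code`, `use_category`,
#'   `count`, `age`, `sex`, `migrant`.
#' @export
category_use_data <- function(data) {
  stopifnot(inherits(data, "interview_data"))
  grid <- tidyr::expand_grid(participant_id = data$participants$id,
                             species_code = data$species$code,
                             use_category = use_categories())
  u <- dplyr::summarise(
    dplyr::group_by(data$use_reports, .data$participant_id,
                    .data$species_code,
                    use_category = as.character(.data$use_category)),
    count = dplyr::n(), .groups = "drop")
  out <- dplyr::left_join(grid, u, by = c("participant_id", "species_code",
                                          "use_category"))
  out$count[is.na(out$count)] <- 0L
  p <- data$participants
  idx <- match(out$participant_id, p$id)
  out$age <- p$age_years[idx]
  out$sex <- p$sex[idx]
  out$migrant <- factor(ifelse(p$migration_status[idx] == "none",
                               "no", "yes"), levels = c("no", "yes"))
  out
}

maximal_formula <- function(two_way = TRUE, random = NULL) {
  fixed <- if (two_way) {
    "age + sex + migrant + age:sex + age:migrant + sex:migrant"
  } else {
    "age + sex + migrant"
  }
  rhs <- if (is.null(random)) fixed else paste(fixed, "+", random)
  stats::as.formula(paste("count ~", rhs))
}

#' Fit a Poisson or quasi-Poisson use-count model
#'
#' Maximum-likelihood log-link GLM of use-type counts on age (years,
#' continuous), sex and the pooled migrant indicator; the maximal model
#' includes all two-way interactions. All-zero responses leave the
#' intercept unidentified on the log scale; such fits are flagged
#' degenerate via `attr(fit, "degenerate")`.
#'
#' @param df Modelling frame from [species_use_data()] (columns `count`,
#'   `age`, `sex`, `migrant`).
#' @param family `"poisson"` or `"quasipoisson"`.
#' @param two_way Include all two-way interactions (the maximal model).
#' @param formula Optional explicit formula overriding `two_way`.
#' @return A fitted `glm` object.
#' @export
fit_use_glm <- function(df, family = c("poisson", "quasipoisson"),
                        two_way = TRUE, formula = NULL) {
  family <- match.arg(family)
  stopifnot(all(c("count", "age", "sex", "migrant") %in% names(df)))
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (is.null(formula)) formula <- maximal_formula(two_way)
  # keep `df` reachable from the formula environment so drop1()/update()
  # can refit after this frame is gone
  environment(formula) <- environment()
  fam <- if (family == "poisson") stats::poisson() else
    stats::quasipoisson()
  fit <- stats::glm(formula, data = df, family = fam)
  attr(fit, "degenerate") <- all(df$count == 0)
  if (!fit$converged) warning("GLM did not converge", call. = FALSE)
  fit
}

#' Overdispersion check for a Poisson GLM
#'
#' The dispersion statistic is the residual deviance divided by the
#' residual degrees of freedom; values well above 1 indicate
#' overdispersion relative to the Poisson variance, in which case the
#' model should be re-fitted with a quasi-Poisson family.
#'
#' @param fit A fitted `glm`.
#' @param threshold Dispersion above which a quasi refit is advised
#'   (default 1.5).
#' @return A list: `dispersion`, `refit_as_quasi`.
#' @export
dispersion_check <- function(fit, threshold = 1.5) {
  rdf <- stats::df.residual(fit)
  if (rdf == 0) stop("zero residual degrees of freedom", call. = FALSE)
  d <- stats::deviance(fit) / rdf
  list(dispersion = d, refit_as_quasi = d > threshold)
}

#' Likelihood-ratio or F test for dropping terms
#'
#' Compares two nested fits of the same response: for (mixed) Poisson
#' models the statistic is twice the log-likelihood difference referred
#' to a chi-square with df equal to the parameter difference; for
#' quasi-Poisson fits an F test on the scaled change in deviance, with
#' denominator df the residual df of the fuller model.
#'
#' @param full,reduced Nested fitted models (`glm` or `glmerMod`).
#' @return A list: `statistic`, `df`, `p`, `test` (`"Chisq"` or `"F"`).
#' @export
drop_term_test <- function(full, reduced) {
  mer <- inherits(full, "merMod")
  n_full <- stats::nobs(full)
  if (n_full != stats::nobs(reduced)) {
    stop("models fitted to different data", call. = FALSE)
  }
  tf <- attr(stats::terms(stats::formula(full)), "term.labels")
  tr <- attr(stats::terms(stats::formula(reduced)), "term.labels")
  if (!all(tr %in% tf)) stop("models are not nested", call. = FALSE)
  if (!mer && stats::family(full)$family == "quasipoisson") {
    df_diff <- stats::df.residual(reduced) - stats::df.residual(full)
    if (df_diff <= 0) return(list(statistic = 0, df = 0L, p = 1,
                                  test = "F"))
    disp <- dispersion_check(full)$dispersion
    f <- (stats::deviance(reduced) - stats::deviance(full)) /
      df_diff / disp
    return(list(statistic = f, df = df_diff, p =
                  stats::pf(f, df_diff, stats::df.residual(full),
                            lower.tail = FALSE),
                test = "F"))
  }
  ll_full <- stats::logLik(full)
  ll_red <- stats::logLik(reduced)
  df_diff <- attr(ll_full, "df") - attr(ll_red, "df")
  if (df_diff <= 0) return(list(statistic = 0, df = 0L, p = 1,
                                test = "Chisq"))
  stat <- max(0, 2 * (as.numeric(ll_full) - as.numeric(ll_red)))
  list(statistic = stat, df = df_diff,
       p = stats::pchisq(stat, df_diff, lower.tail = FALSE),
       test = "Chisq")
}

#' Stepwise-backward model simplification
#'
#' Starting from a maximal model, repeatedly tests every droppable term
#' (respecting marginality: interactions before their main effects) and
#' removes the least significant one as long as its p-value exceeds
#' `alpha`, leaving the minimal adequate model. Poisson (and mixed)
#' models are tested by likelihood-ratio chi-square; quasi-Poisson
#' models by F tests.
#'
#' @param fit A fitted maximal model (`glm` or `glmerMod`).
#' @param alpha Retention threshold (default 0.05).
#' @return A list: `model` (the final fit), `dropped` (tibble logging
#'   each removed term with its statistic, df and p), `retained`
#'   (character vector of final fixed terms).
#' @export
stepwise_backward <- function(fit, alpha = 0.05) {
  quasi <- inherits(fit, "glm") &&
    stats::family(fit)$family == "quasipoisson"
  test <- if (quasi) "F" else "Chisq"
  dropped <- list()
  step <- 0L
  repeat {
    dd <- stats::drop1(fit, test = test)
    dd <- as.data.frame(dd)
    terms_here <- rownames(dd)[rownames(dd) != "<none>"]
    dd <- dd[rownames(dd) != "<none>", , drop = FALSE]
    if (nrow(dd) == 0) break
    pcol <- grep("^Pr", names(dd), value = TRUE)[1]
    scol <- intersect(c("LRT", "F value"), names(dd))[1]
    pv <- dd[[pcol]]
    if (all(is.na(pv))) break
    worst <- which.max(ifelse(is.na(pv), -Inf, pv))
    if (pv[worst] <= alpha) break
    step <- step + 1L
    dropped[[step]] <- tibble::tibble(
      step = step, term = terms_here[worst],
      statistic = dd[[scol]][worst], df = dd[["Df"]][worst],
      p = pv[worst], test = test)
    upd <- stats::update(fit,
                         stats::as.formula(paste(". ~ . -",
                                                 terms_here[worst])),
                         evaluate = FALSE)
    # evaluate where the fitting function stored its data and family
    fit <- eval(upd, environment(stats::formula(fit)))
  }
  retained <- attr(stats::terms(fit), "term.labels")
  list(model = fit,
       dropped = if (length(dropped) > 0) dplyr::bind_rows(dropped) else
         tibble::tibble(step = integer(), term = character(),
                        statistic = numeric(), df = numeric(),
                        p = numeric(), test = character()),
       retained = retained)
}

#' Fit a Poisson mixed model with crossed random intercepts
#'
#' Log-link Poisson mixed model of within-category use-type counts on
#' age, sex and migrant status (maximal model with all two-way
#' interactions), with crossed random intercepts for participants and
#' species to absorb the repeated measurement of both, fitted by Laplace
#' approximation. With a single species level the species intercept is
#' not estimable and the model reduces to a participant-only random
#' intercept.
#'
#' @param df Frame from [category_use_data()], optionally filtered to
#'   one use-category.
#' @param two_way Include all two-way interactions.
#' @param formula Optional explicit fixed-effects right-hand side (a
#'   full formula including random terms).
#' @return A fitted `glmerMod` object.
#' @export
fit_use_glmm <- function(df, two_way = TRUE, formula = NULL) {
  stopifnot(all(c("count", "age", "sex", "migrant",
                  "participant_id") %in% names(df)))
  one_species <- !("species_code" %in% names(df)) ||
    dplyr::n_distinct(df$species_code) < 2
  if (is.null(formula)) {
    random <- if (one_species) "(1 | participant_id)" else
      "(1 | participant_id) + (1 | species_code)"
    formula <- maximal_formula(two_way, random = random)
  }
  environment(formula) <- environment()
  lme4::glmer(formula, data = df, family = stats::poisson(),
              control = lme4::glmerControl(optimizer = "bobyqa",
                                           optCtrl = list(maxfun = 5e4)))
}

#' Random-effect variance components of a mixed model
#'
#' @param fit A fitted `glmerMod`.
#' @return A tibble: `group`, `variance`, `sd`, plus a `boundary`
#'   flag for components estimated at (effectively) zero.
#' @export
glmm_variances <- function(fit) {
  vc <- as.data.frame(lme4::VarCorr(fit))
  tibble::tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor,
                 boundary = vc$vcov < 1e-8)
}

#' Tidy coefficient table of a fitted count model
#'
#' @param fit A fitted `glm` or `glmerMod`.
#' @param dropped Optional drop log from [stepwise_backward()].
#' @return A list of class `model_result`: `coefficients` (term,
#'   estimate, se, statistic, p), `family`, `dispersion` (GLMs),
#'   `random_effects` (mixed models), `dropped`, `converged`,
#'   `degenerate`.
#' @export
model_result <- function(fit, dropped = NULL) {
  mer <- inherits(fit, "merMod")
  co <- if (mer) summary(fit)$coefficients else
    summary(fit)$coefficients
  coefs <- tibble::tibble(
    term = rownames(co), estimate = co[, 1], se = co[, 2],
    statistic = co[, 3], p = co[, ncol(co)])
  res <- list(
    coefficients = coefs,
    family = if (mer) "poisson (mixed)" else stats::family(fit)$family,
    dispersion = if (mer) NA_real_ else
      stats::deviance(fit) / max(1, stats::df.residual(fit)),
    random_effects = if (mer) glmm_variances(fit) else NULL,
    dropped = dropped,
    converged = if (mer) length(fit@optinfo$conv$lme4$messages) == 0 else
      fit$converged,
    degenerate = isTRUE(attr(fit, "degenerate")))
  class(res) <- "model_result"
  res
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> %s%s\n", x$family,
              if (x$degenerate) " (degenerate)" else ""))
  print(as.data.frame(x$coefficients), digits = 4)
  if (!is.na(x$dispersion)) {
    cat(sprintf("dispersion: %.3f\n", x$dispersion))
  }
  if (!is.null(x$random_effects)) {
    print(as.data.frame(x$random_effects), digits = 4)
  }
  invisible(x)
}

#' Per-species minimal adequate count models
#'
#' For every species: fits the maximal Poisson GLM of total use-type
#' counts, checks dispersion, re-fits as quasi-Poisson when the
#' dispersion statistic exceeds the threshold, then simplifies
#' stepwise-backward. Failures for individual species are caught and
#' logged so the remaining species still report.
#'
#' @param data An `interview_data` object.
#' @param dispersion_threshold Quasi refit trigger (default 1.5).
#' @param alpha Stepwise retention threshold.
#' @param two_way Include all two-way interactions in the maximal model.
#' @return A list: `results` (named list of `model_result`), `table`
#'   (wide term x species tibble with `"ns"` for dropped terms),
#'   `drop_log` (tidy tibble of all removals), `failures` (named
#'   character vector of error messages).
#' @export
species_models <- function(data, dispersion_threshold = 1.5, alpha = 0.05,
                           two_way = TRUE) {
  stopifnot(inherits(data, "interview_data"))
  results <- list()
  failures <- character()
  logs <- list()
  for (sp in data$species$code) {
    res <- tryCatch({
      df <- species_use_data(data, sp)
      if (all(df$count == 0)) stop("all counts zero")
      fit <- fit_use_glm(df, "poisson", two_way = two_way)
      if (dispersion_check(fit, dispersion_threshold)$refit_as_quasi) {
        fit <- fit_use_glm(df, "quasipoisson", two_way = two_way)
      }
      st <- stepwise_backward(fit, alpha = alpha)
      model_result(st$model, dropped = st$dropped)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[sp] <- res
      warning(sprintf("species %s: %s", sp, res), call. = FALSE)
    } else {
      results[[sp]] <- res
      if (nrow(res$dropped) > 0) {
        logs[[sp]] <- dplyr::mutate(res$dropped, species = sp,
                                    .before = 1)
      }
    }
  }
  list(results = results,
       table = coef_table_wide(results, two_way = two_way),
       drop_log = if (length(logs) > 0) dplyr::bind_rows(logs) else NULL,
       failures = failures)
}

#' Per-category crossed-random-effects mixed models
#'
#' For every use-category: fits the maximal Poisson mixed model of
#' within-category counts with crossed participant and species random
#' intercepts, then simplifies the fixed effects stepwise-backward by
#' ML likelihood-ratio tests.
#'
#' @inheritParams species_models
#' @return As [species_models()], keyed by use-category.
#' @export
category_models <- function(data, alpha = 0.05, two_way = TRUE) {
  stopifnot(inherits(data, "interview_data"))
  frame <- category_use_data(data)
  results <- list()
  failures <- character()
  logs <- list()
  for (cat in use_categories()) {
    res <- tryCatch({
      df <- frame[frame$use_category == cat, ]
      if (all(df$count == 0)) stop("all counts zero")
      fit <- fit_use_glmm(df, two_way = two_way)
      st <- stepwise_backward(fit, alpha = alpha)
      model_result(st$model, dropped = st$dropped)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failures[cat] <- res
      warning(sprintf("category %s: %s", cat, res), call. = FALSE)
    } else {
      results[[cat]] <- res
      if (nrow(res$dropped) > 0) {
        logs[[cat]] <- dplyr::mutate(res$dropped, use_category = cat,
                                     .before = 1)
      }
    }
  }
  list(results = results,
       table = coef_table_wide(results, two_way = two_way),
       drop_log = if (length(logs) > 0) dplyr::bind_rows(logs) else NULL,
       failures = failures)
}

# Wide coefficient table (rows = terms of the maximal model, columns =
# species or categories, "ns" where a term was dropped).
coef_table_wide <- function(results, two_way = TRUE) {
  terms_all <- c("(Intercept)",
                 attr(stats::terms(maximal_formula(two_way)),
                      "term.labels"))
  cols <- lapply(results, function(r) {
    est <- stats::setNames(rep("ns", length(terms_all)), terms_all)
    co <- r$coefficients
    for (i in seq_len(nrow(co))) {
      # map dummy-coded names (sexmale, migrantyes, age:sexmale...) back
      # to the term they belong to
      base <- gsub("male|yes", "", co$term[i])
      if (base %in% terms_all) {
        est[base] <- sprintf("%.3f%s", co$estimate[i],
                             sub("^ns$", "", significance_stars(co$p[i])))
      }
    }
    est
  })
  out <- tibble::tibble(term = terms_all)
  for (nm in names(cols)) out[[nm]] <- unname(cols[[nm]])
  out
}
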