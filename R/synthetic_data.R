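# Synthetic interview-data generator: a balanced sex x age survey with
# migration confined to the young, Plackett-Luce freelists driven by
# latent species attractiveness, and Poisson use-type counts with
# participant and species random intercepts.

#' Default registry of the 14 focal woody species
#'
#' Andean trees, shrubs and subshrubs selected for agroforestry
#' potential, keyed by short codes used throughout the package.
#'
#' @return A tibble usable as the `species` element of an interview
#'   dataset.
#' @export
default_species_registry <- function() {
  tibble::tribble(
    ~code, ~scientific_name, ~family, ~life_form, ~origin, ~vernacular,
    "BD", "Baccharis dracunculifolia", "Asteraceae", "shrub", "native", "t'ola",
    "BeC", "Berberis commutata", "Berberidaceae", "shrub", "native", "churisik'e",
    "BuC", "Buddleja coriacea", "Buddlejaceae", "tree", "native_cultivated", "kishuara",
    "CB", "Clinopodium bolivianum", "Lamiaceae", "subshrub", "native", "chini munya",
    "EG", "Eucalyptus globulus", "Myrtaceae", "tree", "exotic", "eucalipto",
    "GP", "Gynoxys psilophylla", "Asteraceae", "tree", "native", "k'apa towi",
    "KS", "Kaunia saltensis", "Asteraceae", "shrub", "native", "jaya towi",
    "LG", "Lepechinia graveolens", "Lamiaceae", "shrub", "native", "raqacho",
    "MO", "Minthostachys ovata", "Lamiaceae", "subshrub", "native", "k'oa munya",
    "PS", "Polylepis subtusalbida", "Rosaceae", "tree", "native", "kewinya",
    "PL", "Prosopis laevigata", "Leguminosae", "tree", "native", "thaqo",
    "SP", "Sambucus peruviana", "Caprifoliaceae", "tree", "exotic", "sauco",
    "SM", "Schinus molle", "Anacardiaceae", "tree", "native", "molle",
    "SA", "Senna aymara", "Leguminosae", "shrub", "native", "motocho")
}

default_attractiveness <- function() {
  # log-scale latent importance, ordered to mirror the observed salience
  # ranking of the focal species (a few dominant trees, a long tail)
  c(BD = 1.5, BeC = -4.0, BuC = -1.8, CB = -2.2, EG = 2.2, GP = -2.6,
    KS = -1.4, LG = 0.2, MO = -2.2, PS = -0.9, PL = 1.3, SP = -0.9,
    SM = 1.9, SA = 0.1)
}

default_category_intercepts <- function() {
  c(construction = -0.994, environmental = -0.714, field = -2.356,
    fodder = -0.355, food = -2.881, fuel = -0.765, medicine = -1.853,
    tools = -2.537, other = -2.651)
}

default_category_age_slopes <- function() {
  c(construction = 0, environmental = 0, field = 0, fodder = 0, food = 0,
    fuel = 0, medicine = 0.013, tools = 0.011, other = 0.014)
}

default_category_migration_effects <- function() {
  c(construction = -0.391, environmental = 0, field = 0, fodder = -0.377,
    food = 0, fuel = 0, medicine = 0, tools = 0, other = -0.975)
}

zero_category_vector <- function() {
  stats::setNames(rep(0, 9), use_categories())
}

#' Generator configuration
#'
#' Bundles every knob of the synthetic survey. Defaults emulate the
#' reference design: 5 participants per sex x age-class cell (40 total),
#' 6 temporary and 6 permanent migrants all under 40, the 14-species
#' registry, truncated-Poisson freelist lengths, per-category count
#' intercepts with positive age slopes for medicine/tools/other and
#' migrant deficits for construction/fodder/other, and random intercepts
#' of sd 0.3 (participants) and 0.5 (species).
#'
#' @param n_per_cell Participants per sex x age-class cell.
#' @param age_ranges Named list of `c(lo, hi)` sampling ranges per age
#'   class (ages drawn uniformly within the class).
#' @param n_temporary,n_permanent Numbers of migrants, assigned at
#'   random among participants under 40.
#' @param species Species registry tibble (see
#'   [default_species_registry()]).
#' @param attractiveness Named log-scale latent importance per species,
#'   driving freelist order and content.
#' @param sex_attract,migrant_attract Named per-species additive
#'   attractiveness shifts for male and migrant participants (default
#'   none).
#' @param age_attract Named per-species attractiveness shift per decade
#'   of age above 40 (default none).
#' @param list_length_lambda,list_length_min Truncated-Poisson freelist
#'   length distribution (capped at the registry size).
#' @param category_intercepts,category_age_slopes,category_sex_effects,category_migration_effects
#'   Named per-category log-scale coefficients of the use-type count
#'   model (age in years; sex effect applies to men; migration effect to
#'   migrants).
#' @param sd_participant,sd_species Standard deviations of the normal
#'   random intercepts on the log scale.
#' @param p_asked Probability a participant is interviewed about a
#'   species (1 = everyone asked about everything).
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_per_cell = 5,
                             age_ranges = list("<20" = c(16, 20),
                                               "20-39" = c(20, 40),
                                               "40-59" = c(40, 60),
                                               ">=60" = c(60, 80)),
                             n_temporary = 6,
                             n_permanent = 6,
                             species = default_species_registry(),
                             attractiveness = default_attractiveness(),
                             sex_attract = NULL,
                             migrant_attract = NULL,
                             age_attract = NULL,
                             list_length_lambda = 5,
                             list_length_min = 1,
                             category_intercepts = default_category_intercepts(),
                             category_age_slopes = default_category_age_slopes(),
                             category_sex_effects = zero_category_vector(),
                             category_migration_effects = default_category_migration_effects(),
                             sd_participant = 0.3,
                             sd_species = 0.5,
                             p_asked = 1) {
  zero_species <- stats::setNames(rep(0, nrow(species)), species$code)
  cfg <- list(
    n_per_cell = n_per_cell, age_ranges = age_ranges,
    n_temporary = n_temporary, n_permanent = n_permanent,
    species = species, attractiveness = attractiveness,
    sex_attract = if (is.null(sex_attract)) zero_species else sex_attract,
    migrant_attract = if (is.null(migrant_attract)) zero_species else
      migrant_attract,
    age_attract = if (is.null(age_attract)) zero_species else age_attract,
    list_length_lambda = list_length_lambda,
    list_length_min = list_length_min,
    category_intercepts = category_intercepts,
    category_age_slopes = category_age_slopes,
    category_sex_effects = category_sex_effects,
    category_migration_effects = category_migration_effects,
    sd_participant = sd_participant, sd_species = sd_species,
    p_asked = p_asked)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(cfg$n_per_cell >= 1,
            length(cfg$age_ranges) == 4,
            cfg$sd_participant >= 0, cfg$sd_species >= 0,
            cfg$p_asked >= 0, cfg$p_asked <= 1,
            cfg$list_length_min >= 1,
            cfg$list_length_lambda > 0)
  codes <- cfg$species$code
  for (nm in c("attractiveness", "sex_attract", "migrant_attract",
               "age_attract")) {
    if (!all(codes %in% names(cfg[[nm]]))) {
      stop("`", nm, "` must name every species code", call. = FALSE)
    }
  }
  for (nm in c("category_intercepts", "category_age_slopes",
               "category_sex_effects", "category_migration_effects")) {
    if (!all(use_categories() %in% names(cfg[[nm]]))) {
      stop("`", nm, "` must name all nine use-categories", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Generate a balanced participant roster
#'
#' `n_per_cell` participants per sex x age-class cell, ages uniform
#' within the class range, with the configured numbers of temporary and
#' permanent migrants assigned at random among participants under 40
#' (migration never occurs in the older classes, matching the survey
#' design being emulated).
#'
#' @param config A [generator_config()].
#' @return A raw roster tibble (`id`, `sex`, `age_years`,
#'   `migration_status`) ready for [interview_data()].
#' @export
generate_participants <- function(config = generator_config()) {
  validate_generator_config(config)
  cells <- tidyr::expand_grid(sex = sex_levels(),
                              age_class = names(config$age_ranges))
  rows <- purrr::pmap(cells, function(sex, age_class) {
    rng <- config$age_ranges[[age_class]]
    tibble::tibble(
      sex = sex,
      age_years = stats::runif(config$n_per_cell, rng[1], rng[2]))
  })
  roster <- dplyr::bind_rows(rows)
  roster$id <- sprintf("P%02d", seq_len(nrow(roster)))
  roster$migration_status <- "none"
  young <- which(roster$age_years < 40)
  n_mig <- config$n_temporary + config$n_permanent
  if (n_mig > length(young)) {
    stop("more migrants requested than participants under 40",
         call. = FALSE)
  }
  mig <- sample(young, n_mig)
  roster$migration_status[mig[seq_len(config$n_temporary)]] <- "temporary"
  if (config$n_permanent > 0) {
    roster$migration_status[mig[config$n_temporary +
                                  seq_len(config$n_permanent)]] <- "permanent"
  }
  roster[, c("id", "sex", "age_years", "migration_status")]
}

# Per-participant, per-species attractiveness on the log scale.
participant_attractiveness <- function(roster, config) {
  codes <- config$species$code
  male <- roster$sex == "male"
  migrant <- roster$migration_status != "none"
  dec40 <- (roster$age_years - 40) / 10
  t(vapply(seq_len(nrow(roster)), function(i) {
    config$attractiveness[codes] +
      config$sex_attract[codes] * male[i] +
      config$migrant_attract[codes] * migrant[i] +
      config$age_attract[codes] * dec40[i]
  }, numeric(length(codes))))
}

rtrunc_pois <- function(n, lambda, lo, hi) {
  out <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      k <- stats::rpois(1, lambda)
      if (k >= lo) break
    }
    out[i] <- min(k, hi)
  }
  out
}

#' Generate freelists by Plackett-Luce sequential sampling
#'
#' Each participant's list length is truncated-Poisson; species are then
#' drawn one at a time without replacement with probability proportional
#' to `exp(attractiveness)` among the species not yet listed, so latent
#' importance shows up in both mention frequency and rank.
#'
#' @param roster Output of [generate_participants()].
#' @param config A [generator_config()].
#' @return A long freelist tibble (`participant_id`, `rank`,
#'   `species_code`).
#' @export
generate_freelists <- function(roster, config = generator_config()) {
  validate_generator_config(config)
  codes <- config$species$code
  eta <- participant_attractiveness(roster, config)
  lens <- rtrunc_pois(nrow(roster), config$list_length_lambda,
                      config$list_length_min, length(codes))
  rows <- lapply(seq_len(nrow(roster)), function(i) {
    remaining <- seq_along(codes)
    picked <- integer(0)
    for (r in seq_len(lens[i])) {
      w <- exp(eta[i, remaining])
      j <- if (length(remaining) == 1) remaining else
        sample(remaining, 1, prob = w)
      picked <- c(picked, j)
      remaining <- setdiff(remaining, j)
    }
    tibble::tibble(participant_id = roster$id[i],
                   rank = seq_along(picked),
                   species_code = codes[picked])
  })
  dplyr::bind_rows(rows)
}

#' Generate use-reports from a Poisson count model
#'
#' For every participant x species x use-category cell, a use-type count
#' is drawn Poisson with log-mean
#' `intercept_c + age_slope_c * age + sex_effect_c * male +
#' migration_effect_c * migrant + b_participant + b_species`,
#' the two random intercepts normal with the configured sds. A count of
#' `k` materializes as `k` distinct synthetic use-type labels; the
#' category counts as mentioned whenever its count is positive.
#'
#' @inheritParams generate_freelists
#' @return A use-report tibble (`participant_id`, `species_code`,
#'   `use_category`, `use_type`).
#' @export
generate_use_reports <- function(roster, config = generator_config()) {
  validate_generator_config(config)
  codes <- config$species$code
  b_part <- stats::setNames(
    stats::rnorm(nrow(roster), 0, config$sd_participant), roster$id)
  b_spec <- stats::setNames(
    stats::rnorm(length(codes), 0, config$sd_species), codes)
  grid <- tidyr::expand_grid(participant_id = roster$id,
                             species_code = codes,
                             use_category = use_categories())
  if (config$p_asked < 1) {
    pairs <- tidyr::expand_grid(participant_id = roster$id,
                                species_code = codes)
    pairs$asked <- stats::runif(nrow(pairs)) < config$p_asked
    grid <- dplyr::left_join(grid, pairs,
                             by = c("participant_id", "species_code"))
    grid <- grid[grid$asked, c("participant_id", "species_code",
                               "use_category")]
  }
  idx <- match(grid$participant_id, roster$id)
  age <- roster$age_years[idx]
  male <- roster$sex[idx] == "male"
  migrant <- roster$migration_status[idx] != "none"
  eta <- config$category_intercepts[grid$use_category] +
    config$category_age_slopes[grid$use_category] * age +
    config$category_sex_effects[grid$use_category] * male +
    config$category_migration_effects[grid$use_category] * migrant +
    b_part[grid$participant_id] + b_spec[grid$species_code]
  k <- stats::rpois(nrow(grid), exp(eta))
  keep <- k > 0
  if (!any(keep)) {
    return(tibble::tibble(participant_id = character(),
                          species_code = character(),
                          use_category = character(),
                          use_type = character()))
  }
  out <- grid[rep(which(keep), k[keep]), ]
  out$use_type <- sprintf("%s type %03d", out$use_category,
                          sequence(k[keep]))
  tibble::as_tibble(out)
}

#' Simulate a complete interview dataset
#'
#' Runs the three generator stages under one seed and validates the
#' result through the ordinary data constructor, so simulated datasets
#' satisfy every invariant real data must satisfy.
#'
#' @param config A [generator_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return An `interview_data` object with the config attached as
#'   attribute `"config"`.
#' @export
simulate_interviews <- function(config = generator_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  roster <- generate_participants(config)
  freelists <- generate_freelists(roster, config)
  reports <- generate_use_reports(roster, config)
  out <- interview_data(roster, config$species, freelists, reports)
  attr(out, "config") <- config
  out
}
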