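# Hand-built fixtures with index values worked out by hand.

# Four participants, three species. Known facts:
#   saliences: A: X=1, Y=2/3, Z=1/3; B: Y=1; C: Z=1, X=1/2; D: none
#   Composite S (n=4): X=0.375, Y=5/12, Z=1/3
#   CI for X (record-based denominator {A,B,D}): 4 pairs / 3 = 4/3
#   CI for X (full roster): 4/4 = 1;  CI for Y: 1/1 = 1;  Z: no reports
tiny_participants <- function() {
  tibble::tibble(
    id = c("A", "B", "C", "D"),
    sex = c("female", "male", "female", "male"),
    age_years = c(25, 45, 62, 19),
    migration_status = c("none", "none", "none", "temporary"))
}

tiny_species <- function() {
  tibble::tibble(
    code = c("X", "Y", "Z"),
    scientific_name = c("Xus xus", "Yus yus", "Zus zus"),
    family = c("Xaceae", "Yaceae", "Zaceae"),
    life_form = c("tree", "shrub", "subshrub"),
    origin = c("native", "exotic", "native_cultivated"),
    vernacular = c("ex", "wye", "zed"))
}

tiny_freelists <- function() {
  tibble::tibble(
    participant_id = c("A", "A", "A", "B", "C", "C"),
    rank = c(1L, 2L, 3L, 1L, 1L, 2L),
    species_code = c("X", "Y", "Z", "Y", "Z", "X"))
}

tiny_use_reports <- function() {
  tibble::tibble(
    participant_id = c("A", "A", "A", "A", "B", "B", "D"),
    species_code = c("X", "X", "X", "X", "X", "Y", "X"),
    use_category = c("medicine", "medicine", "medicine", "fodder",
                     "medicine", "fuel", "construction"),
    use_type = c("Stomach ache", "stomach  ache", "influenza",
                 "sheep fodder", "influenza", "firewood", "beams"))
}

tiny_data <- function() {
  interview_data(tiny_participants(), tiny_species(), tiny_freelists(),
                 tiny_use_reports())
}

# Generator configuration with every systematic effect switched off:
# equal attractiveness, flat category intercepts, no covariate effects,
# no random heterogeneity.
null_config <- function(intercept = -0.5, sd_participant = 0,
                        sd_species = 0) {
  reg <- default_species_registry()
  flat_s <- stats::setNames(rep(0, nrow(reg)), reg$code)
  flat_c <- stats::setNames(rep(intercept, 9), use_categories())
  zero_c <- stats::setNames(rep(0, 9), use_categories())
  generator_config(
    attractiveness = flat_s,
    category_intercepts = flat_c,
    category_age_slopes = zero_c,
    category_sex_effects = zero_c,
    category_migration_effects = zero_c,
    sd_participant = sd_participant,
    sd_species = sd_species)
}

# Covariate frame shaped like the survey design, for direct GLM input.
design_covariates <- function(n = 40) {
  tibble::tibble(
    age = stats::runif(n, 16, 80),
    sex = factor(sample(c("female", "male"), n, replace = TRUE),
                 levels = c("female", "male")),
    migrant = factor(ifelse(stats::runif(n) < 0.3, "yes", "no"),
                     levels = c("no", "yes")))
}
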