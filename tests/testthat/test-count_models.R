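test_that("intercept-only Poisson GLM equals the log of the mean", {
  df <- tibble::tibble(count = c(1L, 2L, 3L),
                       age = c(20, 40, 60),
                       sex = factor(c("female", "male", "female"),
                                    levels = c("female", "male")),
                       migrant = factor(c("no", "no", "yes"),
                                        levels = c("no", "yes")))
  fit <- fit_use_glm(df, formula = count ~ 1)
  expect_equal(unname(stats::coef(fit)[1]), log(2), tolerance = 1e-10)
  expect_error(fit_use_glm(dplyr::mutate(df, count = c(-1L, 1L, 2L))),
               "non-negative")
  # all-zero response is flagged degenerate
  fit0 <- suppressWarnings(
    fit_use_glm(dplyr::mutate(df, count = 0L), formula = count ~ 1))
  expect_true(attr(fit0, "degenerate"))
})

test_that("adding a term never increases the deviance", {
  set.seed(61)
  df <- design_covariates(60)
  df$count <- stats::rpois(60, exp(0.5 + 0.01 * df$age))
  forms <- list(count ~ 1, count ~ age, count ~ age + sex,
                count ~ age + sex + migrant,
                count ~ age + sex + migrant + age:sex)
  devs <- vapply(forms, function(f)
    stats::deviance(fit_use_glm(df, formula = f)), numeric(1))
  expect_true(all(diff(devs) <= 1e-10))
})

test_that("dispersion check flags over- but not equi-dispersion", {
  set.seed(67)
  df <- design_covariates(100)
  df$count <- stats::rpois(100, 3)
  fit <- fit_use_glm(df, two_way = FALSE)
  dc <- dispersion_check(fit)
  expect_true(dc$dispersion > 0)
  # saturated model has zero residual df
  dfs <- tibble::tibble(count = c(1L, 3L),
                        age = c(20, 30),
                        sex = factor(c("female", "male"),
                                     levels = c("female", "male")),
                        migrant = factor(c("no", "no"),
                                         levels = c("no", "yes")))
  sat <- fit_use_glm(dfs, formula = count ~ age)
  expect_error(dispersion_check(sat), "zero residual")
})

test_that("drop_term_test behaves on nested and identical fits", {
  set.seed(71)
  df <- design_covariates(80)
  df$count <- stats::rpois(80, 2)
  full <- fit_use_glm(df, two_way = FALSE)
  same <- fit_use_glm(df, two_way = FALSE)
  t0 <- drop_term_test(full, same)
  expect_equal(t0$statistic, 0, tolerance = 1e-8)
  expect_equal(t0$p, 1)
  red <- fit_use_glm(df, formula = count ~ age)
  tt <- drop_term_test(full, red)
  # sex and migrant each contribute one dummy coefficient
  expect_equal(tt$df, 2L)
  expect_true(tt$p > 0 && tt$p <= 1)
  # interaction dummies are counted too
  full2 <- fit_use_glm(df, two_way = TRUE)
  tt2 <- drop_term_test(full2, red)
  expect_equal(tt2$df, 5L)
  other <- fit_use_glm(df[1:40, ], formula = count ~ age)
  expect_error(drop_term_test(full, other), "different data")
  not_nested <- fit_use_glm(df, formula = count ~ sex)
  expect_error(drop_term_test(red, not_nested), "nested")
})

test_that("LRT p-values are uniform under the null", {
  set.seed(73)
  n_rep <- 1000
  pv <- numeric(n_rep)
  df <- design_covariates(60)
  for (i in seq_len(n_rep)) {
    df$count <- stats::rpois(60, 2)
    full <- stats::glm(count ~ age, family = stats::poisson(), data = df)
    red <- stats::glm(count ~ 1, family = stats::poisson(), data = df)
    pv[i] <- drop_term_test(full, red)$p
  }
  ks <- suppressWarnings(stats::ks.test(pv, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("stepwise respects marginality and drops order-independently", {
  set.seed(79)
  df <- design_covariates(300)
  # strong sex:migrant interaction with weak mains
  eta <- 0.6 + 0.1 * (df$sex == "male") - 0.1 * (df$migrant == "yes") +
    1.2 * (df$sex == "male") * (df$migrant == "yes")
  df$count <- stats::rpois(300, exp(eta))
  st <- stepwise_backward(fit_use_glm(df, two_way = TRUE))
  if ("sex:migrant" %in% st$retained) {
    expect_true(all(c("sex", "migrant") %in% st$retained))
  }
  # the same maximal model written with covariates permuted selects the
  # same model (labels canonicalized: migrant:sex == sex:migrant)
  canon <- function(t) vapply(strsplit(t, ":"),
                              function(x) paste(sort(x), collapse = ":"),
                              "")
  f2 <- count ~ migrant + sex + age + sex:migrant + age:migrant + age:sex
  st2 <- stepwise_backward(fit_use_glm(df, formula = f2))
  expect_setequal(canon(st$retained), canon(st2$retained))
  # drop log records statistic, df and p for every removal
  expect_true(all(st$dropped$p > 0.05))
  expect_equal(nrow(st$dropped) + length(st$retained), 6)
})

test_that("a strong effect survives stepwise while noise terms fall", {
  # backward elimination keeps the true effect essentially always; the
  # chance that some null term also survives is bounded by the
  # minimum-p selection effect (simulated expectation ~0.25)
  set.seed(83)
  keep_mig <- 0L
  only_mig <- 0L
  n_rep <- 100
  for (i in seq_len(n_rep)) {
    df <- design_covariates(80)
    df$count <- stats::rpois(80, exp(1.2 - 0.9 * (df$migrant == "yes")))
    st <- stepwise_backward(fit_use_glm(df, two_way = TRUE))
    keep_mig <- keep_mig + ("migrant" %in% st$retained)
    only_mig <- only_mig + ("migrant" %in% st$retained &&
                              !any(c("age", "sex") %in% st$retained))
  }
  expect_gte(keep_mig / n_rep, 0.95)
  expect_gte(only_mig / n_rep, 0.65)
})

test_that("quasi-Poisson stepwise uses F tests", {
  set.seed(89)
  df <- design_covariates(100)
  frailty <- stats::rlnorm(100, 0, 0.8)
  df$count <- stats::rpois(100, 2 * frailty)
  fit <- fit_use_glm(df, "quasipoisson", two_way = TRUE)
  st <- stepwise_backward(fit)
  expect_true(all(st$dropped$test == "F"))
})

test_that("the mixed model collapses to the GLM when variances vanish", {
  set.seed(97)
  cfg <- null_config(intercept = -0.3, sd_participant = 0, sd_species = 0)
  d <- simulate_interviews(cfg, seed = 103)
  frame <- category_use_data(d)
  med <- frame[frame$use_category == "medicine", ]
  gm <- fit_use_glmm(med, two_way = FALSE)
  glm_fit <- stats::glm(count ~ age + sex + migrant, data = med,
                        family = stats::poisson())
  vc <- glmm_variances(gm)
  expect_true(all(vc$variance < 1e-2))
  expect_equal(unname(lme4::fixef(gm)), unname(stats::coef(glm_fit)),
               tolerance = 1e-3)
})

test_that("a single species reduces to one random intercept", {
  d <- simulate_interviews(seed = 107)
  frame <- category_use_data(d)
  one <- frame[frame$use_category == "fodder" &
                 frame$species_code == "BD", ]
  fit <- fit_use_glmm(one, two_way = FALSE)
  vc <- glmm_variances(fit)
  expect_equal(vc$group, "participant_id")
  expect_equal(nrow(vc), 1)
})

test_that("per-species model fitting isolates failures", {
  d <- simulate_interviews(seed = 109)
  # force one species to have no reports at all
  u <- d$use_reports[d$use_reports$species_code != "SM", ]
  d2 <- interview_data(d$participants[, c("id", "sex", "age_years",
                                          "migration_status")],
                       d$species, d$freelists, u)
  sm <- suppressWarnings(species_models(d2, two_way = FALSE))
  expect_true("SM" %in% names(sm$failures))
  expect_equal(length(sm$results), 13)
  expect_true(all(vapply(sm$results, function(r)
    nrow(r$coefficients) >= 1, logical(1))))
  # the wide table carries one column per fitted species plus terms
  expect_equal(ncol(sm$table), 14)
  expect_true(all(c("(Intercept)", "age", "sex", "migrant") %in%
                    sm$table$term))
})
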