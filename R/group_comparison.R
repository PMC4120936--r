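# Intracultural variation: variance-stabilised one-way ANOVA with
# Tukey-Kramer post-hoc comparisons, per-category proportion tests, and
# Spearman concordance of the two indices.

#' Arcsine square-root transform
#'
#' Variance-stabilising transform for proportions: `asin(sqrt(x))`, in
#' radians on `[0, pi/2]`. Index responses are transformed before ANOVA;
#' CI responses are first divided by 9 to land in `[0, 1]`.
#'
#' @param x Numeric vector in `[0, 1]`.
#' @return Transformed values in `[0, pi/2]`.
#' @export
arcsine_sqrt <- function(x) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("`x` must lie in [0, 1]", call. = FALSE)
  }
  asin(sqrt(x))
}

#' Significance stars
#'
#' The usual `*` / `**` / `***` convention at 0.05 / 0.01 / 0.001;
#' `"ns"` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of markers.
#' @export
significance_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", "ns"))))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA of a numeric response on a
#' grouping factor, fitted as a linear model: F is the ratio of the
#' between-group to the within-group mean square with `k - 1` and
#' `n - k` degrees of freedom. Tukey-Kramer pairwise comparisons are
#' attached. Data where both the between- and within-group sums of
#' squares vanish (all responses identical) leave F undefined and are
#' flagged degenerate rather than reported.
#'
#' @param response Numeric vector.
#' @param group Factor (or coercible) with at least two non-empty levels.
#' @return An object of class `anova_result`: a list with `factor_levels`,
#'   `F`, `df`, `p`, `degenerate`, and a `tukey` tibble.
#' @export
one_way_anova <- function(response, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  n <- length(response)
  if (length(group) != n) stop("length mismatch", call. = FALSE)
  if (k < 2) stop("need at least two non-empty groups", call. = FALSE)
  if (any(table(group) == 0)) stop("a level has zero observations",
                                   call. = FALSE)
  if (n <= k) stop("need more observations than groups", call. = FALSE)
  fit <- stats::lm(response ~ group)
  # anova() warns on zero-residual fits; degeneracy is flagged below
  an <- suppressWarnings(stats::anova(fit))
  ssb <- an[["Sum Sq"]][1]
  ssw <- an[["Sum Sq"]][2]
  degenerate <- isTRUE(all.equal(ssb + ssw, 0))
  res <- list(
    factor_levels = levels(group),
    F = if (degenerate) NA_real_ else an[["F value"]][1],
    df = c(an[["Df"]][1], an[["Df"]][2]),
    p = if (degenerate) NA_real_ else an[["Pr(>F)"]][1],
    ms_within = an[["Mean Sq"]][2],
    degenerate = degenerate,
    tukey = if (degenerate) NULL else tukey_hsd(response, group)
  )
  class(res) <- "anova_result"
  res
}

#' @export
print.anova_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<anova_result> degenerate (zero total variance)\n")
  } else {
    cat(sprintf("<anova_result> F(%d,%d) = %.3f, p = %.4g %s\n",
                x$df[1], x$df[2], x$F, x$p, significance_stars(x$p)))
  }
  invisible(x)
}

#' Tukey-Kramer all-pairs comparisons
#'
#' Studentized-range-based pairwise comparisons of group means after a
#' one-way ANOVA, in the Tukey-Kramer form that accommodates unequal
#' group sizes: for groups i, j the statistic is
#' `q = |mean_i - mean_j| / sqrt((MSW / 2) (1/n_i + 1/n_j))`, referred to
#' the studentized range distribution with `k` groups and the ANOVA
#' residual degrees of freedom.
#'
#' @inheritParams one_way_anova
#' @return A tibble with one row per level pair: `pair`, `diff`, `se`,
#'   `q`, `p_adj`.
#' @export
tukey_hsd <- function(response, group) {
  group <- droplevels(as.factor(group))
  k <- nlevels(group)
  if (k < 2) stop("need at least two non-empty groups", call. = FALSE)
  means <- tapply(response, group, mean)
  sizes <- tapply(response, group, length)
  df_den <- length(response) - k
  if (df_den <= 0) stop("need more observations than groups", call. = FALSE)
  msw <- sum(tapply(response, group,
                    function(v) sum((v - mean(v))^2))) / df_den
  pairs <- utils::combn(levels(group), 2)
  out <- apply(pairs, 2, function(pr) {
    d <- means[[pr[2]]] - means[[pr[1]]]
    se <- sqrt(msw / 2 * (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    q <- abs(d) / se
    tibble::tibble(pair = paste(pr[2], "-", pr[1]),
                   diff = d, se = se, q = q,
                   p_adj = stats::ptukey(q, k, df_den, lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

#' Two-sample test of equal use-category mention probability
#'
#' Compares the probability that a use-category is mentioned between two
#' actor groups. The default is the two-sample proportion chi-square test
#' on the pooled 2x2 table with 1 degree of freedom and no continuity
#' correction (the form whose statistic is conventionally reported as a
#' 1-df chi-square); `method = "exact"` gives Fisher's exact two-sided
#' test instead.
#'
#' @param x1,n1 Mentions and group size in the first group.
#' @param x2,n2 Mentions and group size in the second group.
#' @param method `"chisq"` (default) or `"exact"`.
#' @return A list of class `proportion_test`: `x1`, `n1`, `x2`, `n2`,
#'   `statistic` (chi-square, `NA` for exact), `df`, `p`, `method`.
#' @export
category_proportion_test <- function(x1, n1, x2, n2,
                                     method = c("chisq", "exact")) {
  method <- match.arg(method)
  if (n1 < 1 || n2 < 1) stop("group sizes must be >= 1", call. = FALSE)
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) {
    stop("mention counts must satisfy 0 <= x <= n", call. = FALSE)
  }
  if (method == "exact") {
    ft <- stats::fisher.test(matrix(c(x1, n1 - x1, x2, n2 - x2), nrow = 2,
                                    byrow = TRUE))
    res <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                statistic = NA_real_, df = NA_integer_, p = ft$p.value,
                method = "exact")
  } else {
    pbar <- (x1 + x2) / (n1 + n2)
    if (pbar == 0 || pbar == 1) {
      # identical degenerate proportions: no evidence of a difference
      res <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2, statistic = 0,
                  df = 1L, p = 1, method = "chisq")
    } else {
      pt <- suppressWarnings(
        stats::prop.test(c(x1, x2), c(n1, n2), correct = FALSE))
      res <- list(x1 = x1, n1 = n1, x2 = x2, n2 = n2,
                  statistic = unname(pt$statistic), df = 1L,
                  p = pt$p.value, method = "chisq")
    }
  }
  class(res) <- "proportion_test"
  res
}

#' @export
print.proportion_test <- function(x, ...) {
  if (x$method == "chisq") {
    cat(sprintf(
      "<proportion_test> %d/%d vs %d/%d: chi-square(1) = %.3f, p = %.4g\n",
      x$x1, x$n1, x$x2, x$n2, x$statistic, x$p))
  } else {
    cat(sprintf("<proportion_test> %d/%d vs %d/%d: exact p = %.4g\n",
                x$x1, x$n1, x$x2, x$n2, x$p))
  }
  invisible(x)
}

#' Spearman rank correlation
#'
#' Rank correlation with midrank handling of ties and the p-value from
#' the asymptotic t approximation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @return A list: `rho`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0) {
    stop("zero variance in ranks", call. = FALSE)
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

# Per-participant index responses for a species, already on [0,1]:
# salience as-is, CI category count / 9.
index_responses <- function(data, index, species_code) {
  if (index == "salience") {
    sc <- salience_scores(data)
    sc <- sc[sc$species_code == species_code, ]
    tibble::tibble(participant_id = sc$participant_id,
                   value = sc$salience)
  } else {
    cm <- category_mention_counts(data)
    cm <- cm[cm$species_code == species_code, ]
    g <- tibble::tibble(participant_id = data$participants$id)
    g <- dplyr::left_join(g, cm[, c("participant_id", "n_categories")],
                          by = "participant_id")
    g$n_categories[is.na(g$n_categories)] <- 0L
    tibble::tibble(participant_id = g$participant_id,
                   value = g$n_categories / length(use_categories()))
  }
}

#' ANOVA screen of index variation across actor groups
#'
#' For every species, runs a one-way ANOVA of the arcsine-square-root
#' transformed per-participant index (salience, or CI category count
#' rescaled by 9) on one actor-group factor, with Tukey-Kramer post-hoc
#' comparisons. Species with no variation at all (e.g. never cited) are
#' flagged degenerate and carry `NA` statistics.
#'
#' @param data An `interview_data` object.
#' @param index `"salience"` or `"ci"`.
#' @param grouping `"sex"`, `"age_class"` or `"migration_group"`.
#' @return A tibble: `species`, `index`, `factor`, `F`, `df1`, `df2`,
#'   `p`, `signif`, `degenerate`, plus a `tukey` list-column of pairwise
#'   comparison tibbles.
#' @export
compare_groups <- function(data, index = c("salience", "ci"),
                           grouping = c("sex", "age_class",
                                        "migration_group")) {
  stopifnot(inherits(data, "interview_data"))
  index <- match.arg(index)
  grouping <- match.arg(grouping)
  fac <- data$participants[[grouping]]
  names(fac) <- data$participants$id
  rows <- lapply(data$species$code, function(sp) {
    resp <- index_responses(data, index, sp)
    y <- arcsine_sqrt(pmin(1, resp$value))
    g <- fac[resp$participant_id]
    an <- one_way_anova(y, g)
    tibble::tibble(species = sp, index = index, factor = grouping,
                   F = an$F, df1 = an$df[1], df2 = an$df[2], p = an$p,
                   signif = significance_stars(an$p),
                   degenerate = an$degenerate,
                   tukey = list(an$tukey))
  })
  dplyr::bind_rows(rows)
}

#' Per-category proportion tests between actor groups
#'
#' For one species, tests every pair of levels of an actor-group factor
#' and every use-category for a difference in the probability of the
#' category being mentioned.
#'
#' @inheritParams compare_groups
#' @param species_code Single species code.
#' @param method Passed to [category_proportion_test()].
#' @return A tidy tibble: `species`, `use_category`, `group1`, `group2`,
#'   `x1`, `n1`, `x2`, `n2`, `statistic`, `p`, `signif`.
#' @export
proportion_tests <- function(data, species_code,
                             grouping = c("sex", "age_class",
                                          "migration_group"),
                             method = c("chisq", "exact")) {
  stopifnot(inherits(data, "interview_data"))
  grouping <- match.arg(grouping)
  method <- match.arg(method)
  check_species_code(data, species_code)
  roster <- data$participants
  u <- data$use_reports[data$use_reports$species_code == species_code, ]
  lv <- levels(roster[[grouping]])
  pairs <- utils::combn(lv, 2)
  rows <- list()
  for (cat in use_categories()) {
    mentioners <- unique(u$participant_id[as.character(u$use_category) == cat])
    for (j in seq_len(ncol(pairs))) {
      g1 <- roster$id[roster[[grouping]] == pairs[1, j]]
      g2 <- roster$id[roster[[grouping]] == pairs[2, j]]
      if (length(g1) == 0 || length(g2) == 0) next
      tst <- category_proportion_test(sum(g1 %in% mentioners), length(g1),
                                      sum(g2 %in% mentioners), length(g2),
                                      method = method)
      rows[[length(rows) + 1]] <- tibble::tibble(
        species = species_code, use_category = cat,
        group1 = pairs[1, j], group2 = pairs[2, j],
        x1 = tst$x1, n1 = tst$n1, x2 = tst$x2, n2 = tst$n2,
        statistic = tst$statistic, p = tst$p,
        signif = significance_stars(tst$p))
    }
  }
  dplyr::bind_rows(rows)
}

#' Concordance of the two indices
#'
#' Spearman rank correlation between per-species Composite Salience and
#' Cultural Importance totals.
#'
#' @param salience_totals,ci_totals Numeric vectors aligned by species.
#' @return As [spearman_cor()].
#' @export
index_concordance <- function(salience_totals, ci_totals) {
  spearman_cor(salience_totals, ci_totals)
}
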