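---
title: "Quantifying plant knowledge: indices, group comparisons and count models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying plant knowledge: indices, group comparisons and count models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ethnoindices)
```

## The problem

Quantitative ethnobotany asks which plants matter to a community and
whether that valuation varies systematically within the community —
between women and men, across age classes, or between residents and
migrants. `ethnoindices` implements the two complementary instruments
used for woody species in Andean subsistence communities, together with
the statistical machinery needed to detect such *intracultural
variation*:

* **freelisting** captures *active* knowledge: informants name their
  favourite and other important woody species in the order they come to
  mind;
* **semi-structured interviews** capture *passive* knowledge: for a
  fixed set of focal species, informants are asked whether and how they
  use each one within nine closed use-categories (construction,
  environmental, field, fodder, food, fuel, medicine, tools, other),
  every distinct answer being one *use-type*.

## The two indices

**Composite Salience.** For a species at 1-based position $r$ in a
freelist of length $L$, the per-informant salience is the inverse rank
over the list length,

$$ s = \frac{L - r + 1}{L}, $$

so the first mention scores 1, the last $1/L$, and an unlisted species
0. Composite Salience of a species is the mean of $s$ over all $n$
informants, which ranges from 0 (never mentioned) to 1 (mentioned first
by everyone). "Inverse rank" is taken as $L - r + 1$; this is the only
reading for which the documented upper endpoint (all informants, first
position, index 1) is attained.

**Cultural Importance.** Use-reports are grouped per plant and
informant into the nine categories (mentioned: 1, not mentioned: 0) and
the number of distinct use-types per category is recorded. CI of a
species is the sum over categories of the proportion of informants
mentioning the category — equivalently the count of (informant,
category) mention pairs divided by the number of informants — ranging
from 0 to 9.

Two denominators are possible for CI, because not every informant need
be interviewed about every species. By default the denominator is the
number of informants with at least one record for the species; the
`assume_all_asked` flag switches to the full roster (appropriate for
simulated data, where everyone is asked about everything). Informants
with no record for a species are excluded from its subgroup CI rather
than counted as zero-mention informants, since absence of a record is
indistinguishable from not having been asked.

For subgroup indices the denominator is the subgroup size, and the
"mean ± sd" presentation is the mean and standard deviation over
subgroup members of the per-informant quantity (salience, or the count
of mentioned categories); the subgroup mean *is* the subgroup index.
Informants who produced no freelist contribute salience 0 instead of
being dropped, which keeps the denominator fixed at the design size.
One ordered list per informant is stored; where a protocol elicits
"favourites" followed by "other important" species, the two are
concatenated in elicitation order, because salience is defined on a
single ranked list.

## Actor groups

Participants carry sex, continuous age in years, and migration status.
Age is binned into `<20`, `20-39`, `40-59`, `>=60` with half-open,
lower-inclusive bins (boundary ages 20/40/60 go to the upper class, as
the printed labels imply). The migration factor has four levels:
residents under 40 (`no_young`), residents 40 and over (`no_old`),
temporary (`temp`) and permanent (`perm`) migrants; in the emulated
survey design all migrants are under 40, so the factor simultaneously
encodes migration and the age structure of migration.

## Detecting intracultural variation

**ANOVA with a variance-stabilising transform.** Per-informant index
responses are arcsine-square-root transformed before a one-way ANOVA on
each actor-group factor. The transform needs a $[0,1]$ argument;
salience already lives there, while the CI response (the per-informant
count of mentioned categories, 0–9) is first divided by 9. Post-hoc
pairwise comparisons use the Tukey–Kramer studentized-range form, which
accommodates the unbalanced migration groups (8/20/6/6 in the emulated
design). Species with no variation at all (e.g. never cited) leave the
F ratio undefined; they are flagged degenerate and reported with `NA`
rather than dropped silently.

**Per-category proportion tests.** Whether a significant CI difference
traces back to specific categories is tested per category and group
pair with a two-sample test of equal mention probability. The default
is the pooled two-sample proportion chi-square test with 1 df and no
continuity correction — the form under which such results are
conventionally reported as $\chi^2_{(1)}$ statistics — with Fisher's
exact test available behind `method = "exact"`. Degenerate tables
(pooled proportion 0 or 1 with equal observed proportions) are reported
as no-signal ($\chi^2 = 0$, $p = 1$) rather than `NaN`.

**Concordance.** The two indices are compared across species by
Spearman rank correlation (midranks for ties, p-value from the
asymptotic t approximation).

## Count models

The number of distinct use-types an informant knows for a species is a
count, modelled with log-link Poisson GLMs on age (continuous, in
years), sex, and migration pooled to a binary resident/migrant
indicator (temporary and permanent migrants are too few to separate).
Maximal models contain all two-way interactions. Age enters uncentred:
with ages spanning 16–80 the fit is numerically well-conditioned, and
the intercept is then directly comparable to published coefficient
tables that report it on the age-zero scale.

**Overdispersion.** The dispersion statistic is residual deviance over
residual df. When it exceeds a threshold (default 1.5) the model is
re-fitted as a quasi-Poisson, whose standard errors absorb the excess
variance. (The common verbal shorthand "mean > variance" for
overdispersion inverts the actual condition; the implemented rule is
the standard variance-exceeds-mean one, via the dispersion statistic.)
The threshold is configurable because no universal value exists; 1.5 is
far enough above the statistic's null sampling noise at these sample
sizes to avoid spurious refits.

**Stepwise-backward simplification.** From the maximal model, the least
significant droppable term is removed as long as its p-value exceeds
0.05, respecting marginality (interactions leave before their parents),
until the *minimal adequate model* remains. Poisson and mixed models
use likelihood-ratio chi-square tests; quasi-Poisson models use F tests
on the scaled deviance change with denominator df from the fuller
model. Every removal is logged (term, statistic, df, p) so "ns" entries
in the final coefficient table are auditable.

A property worth knowing: per droppable term the procedure operates at
the nominal 5% type-I rate, but the probability that *some* null term
survives is considerably larger (about 25% for a six-term maximal
model), because the last survivor is effectively the minimum of several
p-values, and a surviving interaction forces its main effects to stay.
The test suite encodes the per-term rate, which is the quantity the
procedure actually controls.

**Crossed-random-effects mixed models.** Counts within a use-category
are measured repeatedly per informant (across species) and per species
(across informants). To avoid pseudo-replication, the per-category
models add crossed random intercepts for both factors, fitted as a
Poisson GLMM by Laplace approximation (`lme4::glmer`, bobyqa optimizer,
up to 5·10^4 function evaluations). Fixed effects are simplified by ML
likelihood-ratio tests, the standard choice when testing fixed terms.
Variance components estimated at zero are flagged as boundary fits, not
errors; with a single species the species intercept is not estimable
and the model reduces to a one-factor random intercept.

## The synthetic-data generator

No interview dataset is distributed, so the generator is a first-class
module that produces datasets with the design and statistical structure
the analysis assumes:

* **Roster**: 5 women and 5 men per age class (40 informants), ages
  uniform within class ranges (16–20, 20–40, 40–60, 60–80 years), and
  6 temporary plus 6 permanent migrants assigned at random among the 20
  under-40s — reproducing the 8/20/6/6 migration-group design.
* **Freelists**: list length is truncated Poisson (mean 5, minimum 1,
  capped at the 14-species registry); species are then drawn
  sequentially without replacement with probability proportional to
  `exp(attractiveness)` — a Plackett–Luce scheme, the minimal model
  that makes rank informative about latent importance. Default
  attractiveness values mirror the empirical salience ordering of the
  14 focal species (a few dominant trees, a long tail, one species
  effectively never mentioned). Optional per-species shifts for sex,
  migration and age create controlled group gaps.
* **Use-reports**: for each informant × species × category, a use-type
  count is drawn Poisson with log-mean
  `intercept_c + age_slope_c · age + sex_c · male + migration_c · migrant
  + b_informant + b_species`, the random intercepts normal with sds 0.3
  and 0.5. Default per-category intercepts (−0.35 to −2.88), age slopes
  (0.011–0.014 for medicine, tools and other uses) and migrant deficits
  (−0.38 to −0.98 for construction, fodder and other uses) reproduce
  the magnitudes reported for the emulated survey; a count of *k*
  materializes as *k* distinct synthetic labels ("medicine type 001",
  …) — the real vocabulary of ~85 use-types is emulated in count, not
  content.

Everything funnels through the ordinary validating constructor, so a
generated dataset satisfies every invariant real data must satisfy, and
generation is fully deterministic under a seed.

**What the generator does not emulate.** Freelist content is restricted
to the 14 focal species (real freelists ranged over 33); species
attractiveness and species count intercepts are independent, so the
cross-species correlation between Composite S and CI that real data
show (~0.8) is *not* built in — simulated concordance is weak unless
the user couples the two. Use-type labels carry no semantics, and
interview non-response (`p_asked < 1`) is missing completely at random.
Passing tests therefore demonstrate the correctness of the machinery
under the stated generative model, not the ethnographic realism of any
particular dataset.

## Numerical and design choices

* Ties in Spearman use midranks; zero rank variance is an error, not a
  silent `NA`.
* The arcsine transform rejects inputs outside $[0,1]$ outright.
* Tukey–Kramer p-values come from `ptukey` on
  $q = |\bar y_i - \bar y_j| / \sqrt{(MSW/2)(1/n_i + 1/n_j)}$; the
  implementation is cross-checked in the tests against
  `stats::TukeyHSD` as an independent route.
* ANOVA is fitted through `lm`; the tests verify the F statistic
  against a two-pass sums-of-squares oracle at 1e-10.
* All-zero count responses are flagged degenerate (the log-scale
  intercept diverges) instead of reporting a meaningless fit; in batch
  fitting, per-species or per-category failures are caught, logged and
  skipped so one pathological unit cannot silence the rest.
* Use-type labels are case-folded and whitespace-normalized before
  uniqueness checks, since they originate from transcribed free text.
* Significance is starred at 0.05/0.01/0.001 with no multiple-testing
  correction across species; the screen across 14 species and three
  factors is exploratory by construction.

## Problem sizes used by the test suite

Simulation-backed tests use sizes chosen to make the Monte-Carlo noise
small relative to the asserted bands while keeping the default run
practical: 2000 replicates for null-calibration checks of the ANOVA and
of stepwise retention; 200 replicates for GLM slope/deficit recovery
(n = 500 and n = 40 designs) and for the dispersion classifier
(n = 200 per replicate); 100 replicates of the crossed GLMM recovery
study at 200 informants × 14 species, the size at which the age slope
(0.013) is recovered to ±0.005 and the random-intercept sds to ±50%.

## Known limitations

* The stepwise procedure inherits the usual caveats of significance-
  driven selection: post-selection coefficient estimates are biased
  away from zero and the "minimal adequate model" is not a causal
  claim.
* The Laplace approximation can be crude for Poisson mixed models with
  very small counts; refitting with adaptive quadrature is not
  implemented because the crossed design precludes it in `lme4`.
* Quasi-Poisson standard errors follow R's convention (Pearson-based
  dispersion), while the reported dispersion statistic is
  deviance-based; the two agree closely away from sparse counts.
* Subgroup index tables with empty levels report `NA` rather than
  imputing zeros.
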