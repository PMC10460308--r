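---
title: "Methods: substance-use network analysis with assistnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: substance-use network analysis with assistnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, estimators, numerical choices and
deliberate design decisions behind `assistnet`, and what the package's
synthetic-data experiments do and do not establish about real cohorts.

## The instrument model

The WHO-ASSIST 3.0 asks, per substance category, about frequency of use
in the past 3 months (q2) and five harm domains: urge to use (q3), use
leading to health/social/legal/financial problems (q4), failing to do
what was normally expected (q5, never asked for tobacco), concern
expressed by others (q6) and failed attempts to cut down (q7). The
substance-specific involvement score is the sum of published item
weights (q2: 0/2/3/4/6; q3: 0/3/4/5/6; q4: 0/4/5/6/7; q5: 0/5/6/7/8;
q6/q7: 0 for never, 3 for "yes, but not in the past 3 months", 6 for
"yes, in the past 3 months"). The weights ship as an editable YAML table
(`inst/extdata/assist_weights.yaml`) rather than hard-coded constants so
the instrument configuration is inspectable and replaceable.

Decisions taken where the instrument or reporting conventions leave
room:

* **Missing items.** A substance score with any missing item is missing;
  no partial sums. This is the conservative choice and mirrors
  per-variable missing-data accounting in descriptive tables.
* **3-month harm flags.** For q6/q7 only the "yes, in the past 3 months"
  level counts as a current harm; the "prior" level scores 3 points but
  dichotomises to `FALSE`. q3–q5 are already framed on the past 3
  months, so any non-"never" level counts.
* **Harm without use** is legal (the items permit lifetime-pattern
  answers) and is not suppressed, but it is counted per indicator in the
  QC output.
* **Log transform.** The GGM consumes `log(score + 1)`; the offset
  handles the mass at zero and maps zero involvement to exactly zero.
* **q8 (injection) is not modelled**; it contributes to no downstream
  quantity.
* Both q6 and q7 flags are computed; the zero-order network defaults to
  use + four harms per substance with q7 behind the `include_q7` switch,
  because published harm tables typically report four harm rows.

The four-group classification is hierarchical: ATS use wins over
cannabis (without ATS), which wins over any other substance use, with
"none" for no recent use. A missing ATS or cannabis flag makes the group
missing unless a positive flag higher in the hierarchy overrides it.

## Zero-order network

Each pair of dichotomised indicators is summarised by a 2×2 table on
pairwise-complete rows. The tetrachoric correlation uses the standard
two-step estimator: thresholds fixed at the normal quantiles of the
margins, then a single-parameter likelihood maximisation over the latent
correlation, with bivariate-normal rectangle probabilities from
`mvtnorm`. Numerical choices: a continuity correction of +0.5 on every
cell when any cell is zero (keeps thresholds finite); tables with an
empty margin are flagged as not-a-value rather than estimated; a table
with a vanishing cross-product difference returns exactly 0; the
optimiser works on (−0.9999, 0.9999) with tolerance 1e−8. Edges are
displayed when the two-sided Fisher exact p (point-probability rule, via
`stats::fisher.test`) is below 0.05; the threshold is configurable.

The layout is nonmetric MDS on dissimilarities d = √(2(1−w)) — the
chord distance corresponding to correlation w — alternating Kruskal's
monotone regression (primary tie handling) with the Guttman majorization
transform from a classical-scaling start. A step that would increase
stress-1 is rejected and iteration stops, so the reported stress trace is
non-increasing by construction. The seed only breaks rank-degenerate
starts; the algorithm is otherwise deterministic.

Pairwise-complete estimation (rather than listwise) maximises the
information used per edge; the per-pair sample sizes are returned so
downstream consumers can see the differences.

## Gaussian graphical model

The partial-correlation network is estimated on complete rows of the
log-score matrix in two stages, both scored by the extended BIC
EBIC(γ) = −2ℓ + df·log n + 4γ|E|·log p with df = p + |E|:

1. a 100-point graphical-lasso path, λ log-spaced from
   λmax = max|off-diagonal S| down to λmax/100, each selected graph
   refit without penalty and scored at γ = 0.5 (sparser, safer start);
2. stepwise single-edge additions/removals from the EBIC-best start,
   each candidate refit by zero-constrained maximum likelihood, accepted
   while EBIC(γ = 0, i.e. plain BIC) improves. Ties within 1e−9 prefer
   removal, then lexicographic node order, making the search
   deterministic.

The glasso itself is block coordinate descent with an *off-diagonal-only*
penalty (the fitted covariance keeps diag(S)); its KKT residual is
checked below 1e−6. The constrained MLE is iterative proportional
scaling over vertices and edges with rank-2 Woodbury updates of the
working covariance (refreshed each sweep to stop numerical drift), so at
convergence the fitted covariance equals S on the diagonal and on every
retained edge — the defining property the tests assert. Covariance uses
the maximum-likelihood denominator n for likelihood consistency. The
final model is always an unregularised refit; λ never touches reported
edge weights.

## Centrality

Strength and expected influence are the absolute and signed row sums of
the weight matrix. Closeness and betweenness run on geodesics with edge
length 1/|w| (absent or masked edges have infinite length), using the
standard shortest-path accumulation with equal splitting over tied
geodesics. On disconnected networks closeness sums over reachable nodes
only and the profile is flagged — the convention that avoids infinities
without dropping components. Rankings are descending with lexicographic
tie-breaks; a node top-ranked on at least three of the four indices is
reported as the network's hub.

## Group regression with multiple imputation

Group membership is the analysis stratum: rows whose group cannot be
resolved are dropped before imputation rather than imputed. Covariates
are completed by chained equations — predictive mean matching with k = 5
donors (type-1 matching with a Bayesian parameter draw) for numeric
variables, Bayesian logistic draws for binary, polytomous regression for
categorical — cycled 10 times per chain, m = 20 chains by default (both
configurable; the unit tests use smaller values). The six clinical scale
totals are z-scored within each completed dataset, age enters in years,
and the package's own Newton–Raphson multinomial fitter (score
convergence < 1e−8, step-halving, separation guard at |β|·sd(x) > 15)
produces per-imputation coefficient vectors pooled by Rubin's rules with
Barnard–Rubin degrees of freedom. No multiple-testing adjustment is
applied, matching the exploratory reporting convention the pipeline
follows. m and the implicit all-predictors imputation model are logged
with every run because no published default governs them.

## The synthetic cohort generator

The generator exists so that every stage above is testable without the
study data. One standard-normal latent per substance drives everything:
use is the latent exceeding the prevalence threshold, graded q2
frequency comes from further upper-tail cut-points, and each harm item
thresholds its own latent with loading α = 0.85 on the substance latent
(so harms concentrate in heavy users but keep item noise). Demographics,
diagnosis mix and clinical scale distributions use values a youth
mental-health cohort would show (median age 18, IQR 16–20; 65% female;
~30% LGBTIQA+; PHQ-9/GAD-7 means in the moderate range), fixed once in
`draw_covariates()`.

Two calibration mechanisms matter:

* **Score-scale dependence.** Users specify target *partial*
  correlations of the log involvement scores. The generator converts
  them to a target correlation matrix (standardized precision
  inversion), then solves, per pair, for the latent correlation whose
  implied log-score correlation matches — using the exact conditional
  score distribution given the latent (enumerated over item
  combinations), Gauss–Hermite quadrature and a Hermite-polynomial
  expansion of E[log(1+S)|Z]. Because discretisation attenuates
  correlations (strongly for rare substances such as cocaine at 3.3%
  prevalence), this de-attenuation step is what makes "the true
  tobacco–cannabis partial correlation is 0.48" hold on the scale the
  GGM actually estimates. Targets too large to be attainable on the
  score scale, or jointly inconsistent (non-positive-definite latent
  matrix), are rejected with the offending value.
* **Covariate effects on group membership.** Effects are specified as
  log relative-risk ratios in a multinomial-logit model of the
  four-group classification. Intercepts are calibrated to the
  copula-implied group shares and each participant's latent vector is
  then drawn from the copula *conditional on the assigned group*
  (pool-based matching). Since the marginal group shares equal the
  copula-implied ones, the marginal latent law — and with it every
  correlation calibration — is preserved exactly, while a multinomial
  fit of group on covariates recovers the configured RRRs.

The `paper_like` preset fixes the published marginal prevalences
(tobacco 33%, alcohol 63%, cannabis 27%, ATS 7.6%, cocaine 3.3%, ...),
a dependence structure whose five strongest partial correlations are
tobacco–cannabis 0.48, ATS–hallucinogens 0.30, tobacco–alcohol 0.28,
ATS–cocaine 0.26 and sedatives–opioids 0.21 in that order, moderate
ATS links to every remaining substance (making ATS the hub), small
positive partials elsewhere, published-scale covariate effects, and 5%
missingness. Use-frequency mixes make rare-substance users heavier users
(e.g. ~47% of tobacco users daily), which is both what clinical cohorts
show and what keeps rare-substance scores informative enough for the
dependence targets to be jointly attainable.

Missingness is MCAR. The cell-level mechanism is the basic contract; the
preset uses a block variant in which a participant's whole ASSIST
section goes missing at the configured rate while covariates stay
cell-level, because per-variable missing counts in descriptive tables of
questionnaire studies are block-structured (the same ~4–5% of
participants missing every substance variable), and cell-level
missingness at 5% over ~59 items would leave almost no complete cases
for a complete-case GGM — a regime no questionnaire cohort exhibits.

**What the synthetic experiments show — and don't.** Passing recovery
tests establishes that the estimators are correct and well-calibrated
*under the generator's assumptions*: a Gaussian copula, single-factor
harm structure, MCAR missingness, multinomial covariate effects. Real
cohorts can violate all of these (tail dependence, item-specific
response styles, missingness related to severity, unmodelled site
effects), so the experiments validate the machinery, not the
substantive conclusions one would draw from any particular dataset.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to make
sampling noise small relative to the tolerance being checked: n = 10000
to 20000 draws for threshold/copula fidelity (binomial 99% intervals),
50 tables for the tetrachoric oracle sweep, 50 seeds at n = 2000 for
chain-graph recovery, 20 seeds at n = 1107 for the partial-correlation
recovery study (per-seed sampling error ≈ 0.03, so the 20-seed mean is
accurate to well under the ±0.05 band), and 20 seeds at n = 5000 for the
relative-risk recovery study. Every random quantity derives from an
explicit integer seed; pipeline stages draw independent sub-seeds from
the root seed by hashing, so disabling one stage cannot shift another's
random stream, and re-running a configuration reproduces its outputs
byte for byte.

## Known limitations

* The tetrachoric estimator is the two-step version; full trivariate ML
  would differ in the third decimal at these sample sizes but is not
  implemented.
* The stepwise GGM search is greedy; it can in principle stop at a local
  EBIC optimum, which the chain-recovery and empty-graph suites bound in
  practice but do not exclude.
* The generator does not simulate item-level clinical scales,
  longitudinal follow-up, or site clustering; covariate effects enter
  only through group membership.
* Closeness on disconnected networks uses the reachable-set convention;
  comparing closeness across components of very different sizes is not
  meaningful.
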