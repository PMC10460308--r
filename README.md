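# assistnet

Network analysis of substance use and harms in young people seeking
mental-health care.

Youth presenting to primary mental-health services report far higher
substance use than the general population, and the use and harms of
different substances are heavily intertwined: tobacco with cannabis,
amphetamine-type stimulants (ATS) with cocaine and hallucinogens,
sedatives with opioids. `assistnet` implements, as a tested and reusable
pipeline, the psychometric-network approach to characterising those
patterns from WHO-ASSIST 3.0 screening data:

1. **Involvement scoring** — each of ten substance categories gets a
   summed item-weight risk score from the ASSIST frequency item (q2) and
   five harm items (q3–q7; q5 is never administered for tobacco), with
   use and 3-month harm dichotomisations, polysubstance counts and a
   four-group classification anchored on the high-centrality substances
   (ATS use; cannabis without ATS; other substances only; no recent use).
2. **Zero-order network** — pairwise tetrachoric correlations *r*ₜ
   between all dichotomised use/harm indicators (two-step ML estimator:
   thresholds from the margins, then a 1-D likelihood maximisation in the
   latent correlation), edges displayed when the two-sided Fisher exact
   p < 0.05, embedded by nonmetric multidimensional scaling so shorter
   distances mean stronger associations.
3. **Partial-correlation network** — a Gaussian graphical model of the
   log-transformed involvement scores: a 100-point graphical-lasso path
   scored by the extended BIC seeds an unregularised stepwise edge search
   in which every candidate graph is refit by zero-constrained maximum
   likelihood (iterative proportional scaling); edge weights are the
   partial correlations *r*ₚ = −ω᎐ᵢⱼ/√(ωᵢᵢωⱼⱼ).
4. **Centrality** — strength Σⱼ|wᵢⱼ|, expected influence Σⱼwᵢⱼ, and
   closeness/betweenness on geodesics with edge length 1/|w|, used to
   rank substances and motivate the four-group split.
5. **Group correlates** — multinomial logistic regression (Newton ML,
   reference: no recent use) of group membership on demographics,
   diagnosis and six standardised clinical scale totals, with
   chained-equation multiple imputation (predictive mean matching /
   logistic / polytomous models) and Rubin pooling into adjusted relative
   risk ratios (RRR).

Because the underlying cohort data are not public, the package ships a
**Gaussian-copula synthetic cohort generator** whose defaults reproduce
the published marginal prevalences, dependence structure and covariate
effects; its calibration solves for latent correlations so that the
*score-scale* partial correlations match their targets exactly, which is
what makes the recovery experiments meaningful.

## Worked example

```r
library(assistnet)

cfg <- paper_like_config(n = 1107, seed = 11, missing_rate = 0)
cohort <- generate_cohort(cfg)

scores <- involvement_scores(cohort)
logscores <- scores[, paste0(assist_substances(), "_logscore")]
colnames(logscores) <- assist_substances()

gg <- fit_ggm(logscores)
gg$network$weights["tobacco", "cannabis"]
#> [1] 0.4948349

prof <- centrality_indices(gg$network)
head(prof[order(-prof$strength), c("node", "strength")], 4)
#>       node  strength
#> 5      ats 1.2472020
#> 1  tobacco 1.1317971
#> 3 cannabis 0.7187774
#> 9  opioids 0.6392172
```

The recovered tobacco–cannabis edge (0.49) sits at the generator's
calibrated truth of 0.48, and ATS is the top-strength node — the
network's hub — which is exactly the configuration the four-group
classification is built on.

The full analysis is organised as numbered drivers under `analysis/`
(generate → score/describe → zero-order network → GGM/centrality →
MI-pooled regression), each a thin script over the package functions that
prints what it found and writes its tables under `results/`.

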