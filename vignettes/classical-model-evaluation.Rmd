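---
title: "Scoring, pooling and evaluating multi-panel expert elicitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring, pooling and evaluating multi-panel expert elicitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sejcm)
```

## The model

An elicitation study consists of panels. On each panel, every expert states
three marker quantiles (5%, 50%, 95%) for every item. *Calibration* items
have a known realization and drive performance scoring; *target* items are
the quantities of interest. `sejcm` assumes complete panels — every expert
answers every item — and rejects incomplete ones at load rather than
imputing, since no principled missing-data rule exists for this design.

**Statistical accuracy.** If an expert's probability statements are
accurate, the realizations of the N calibration items fall into the four
interquantile bins with probabilities p = (0.05, 0.45, 0.45, 0.05).
Writing s for the observed bin proportions, the likelihood-ratio statistic
2·N·I(s; p), with I(s; p) = Σᵢ sᵢ ln(sᵢ/pᵢ), is referred to a chi-square
distribution with 3 degrees of freedom; the accuracy score is the upper-tail
p-value. The asymptotic chi-square form (rather than an exact multinomial
test) is the established convention for this scoring rule and keeps scores
comparable with legacy implementations; panels here have N ≥ 10. Bin
membership uses half-open intervals — a realization exactly equal to a
stated quantile counts in the upper bin — an arbitrary but fixed tie rule,
chosen for determinism.

**Informativeness.** Each triple is expanded into the minimally-informative
density consistent with it: masses 0.05/0.45/0.45/0.05, uniform within the
four intervals, on the item's *intrinsic range*. That range is the envelope
of all assessors' outer quantiles and the realization, extended by an
overshoot of k = 10% of the raw span on each side (configurable via
`range_config()`), then clipped to the item's natural bounds so that, e.g.,
a percentage item cannot acquire negative support. Informativeness is the
Shannon relative information of this density against the uniform background
on the range, which reduces to Σᵢ pᵢ ln(pᵢ/rᵢ) with rᵢ the relative interval
widths. It is non-negative, zero only for the background-matching triple,
scale invariant, and "slow": large changes in quantiles move it modestly.
Because all items in the intended application are relative frequencies, the
uniform background is the default; a log scale flag exists on items for
quantities elicited on orders of magnitude. An expert's overall
informativeness is the mean over all items (calibration and target) by
default — the global-weights convention — with a calibration-only option
for sensitivity analysis.

**Combined score and pooling.** The combined score is accuracy ×
informativeness; it is proportional to the expert's weight in the
performance-weighted pool. Three decision makers are built per panel:

- `ew`: equal weights 1/E;
- `pwg`: global weights wₑ ∝ 1{accₑ ≥ α}·accₑ·infₑ;
- `pwi`: item weights wₑᵢ ∝ 1{accₑ ≥ α}·accₑ·infₑᵢ, normalised per item.

The DM's distribution on an item is the weighted mixture of the experts'
densities; its quantiles are obtained by exact inversion of the
piecewise-linear mixture CDF (never Monte Carlo), and the DM is then scored
exactly like an expert, on the *same* intrinsic ranges (the DM does not
extend them), so expert and DM scores share one background.

**Threshold optimisation.** The cut-off α below which experts are
un-weighted is chosen in-sample: candidates are 0 together with the
observed distinct accuracy values (a finer grid cannot change any DM's
support), each candidate DM is scored on the panel's calibration items, and
the candidate maximising the DM's combined score wins; ties resolve to the
smallest α, i.e. the widest support. Only in-sample optimisation is
offered: out-of-sample cross-validation needs disjoint panels and is not
meaningful when panel memberships overlap heavily, as in the motivating
study. `pwg` and `pwi` are optimised separately.

## Evaluation analytics

Cross-panel comparisons use the subset of panels with *distinct* expert
membership (identical-membership panels produce strongly dependent pools);
the first panel in id order represents each membership class.
`pw_vs_ew_summary()` reports the share of panels where the
performance-weighted DM's combined score strictly exceeds the equal-weight
DM's, mean informativeness of experts and both DM types, the count of
panels with low PW accuracy, and the count of experts whose overall
accuracy clears the conventional 5% rejection threshold.

Expert-level overall scores, when raw elicitations are available, pool each
expert's calibration items across all their panels into one set of bin
counts and average informativeness over all their items (the
`"average"` method — per-panel scores averaged — is available as an
alternative, since the pooling rule is a genuine design choice). From a
score table alone only per-panel averaging is possible, and that is what
`expert_scores_from_table()` does.

The association between informativeness and accuracy is summarised by the
Spearman rank correlation (average ranks for ties) with a *one-sided*
permutation p-value for the directional hypothesis of negative association
(seeded, 100,000 permutations by default, with the small-sample +1
correction; a t-approximation is available via `n_perm = 0`). The *running*
rank correlation recomputes rho over experts k..n after ordering by
increasing accuracy (ties broken by id); windows smaller than 3 are
dropped. Attenuation of the negative correlation as k grows shows the least
accurate experts drive it — which is precisely why restricting weight to
statistically accurate experts can recover informativeness without losing
accuracy.

`expected_false_rejections(n, level)` gives the benchmark count
round(n·level) of accurate panels expected below the level by chance if
panels were independent.

## The synthetic generator

`generate_study()` emulates the structure of a large attribution
elicitation: 112 panels of 13 experts, 10–15 calibration variables per
panel (count drawn per panel) plus 10 target questions, all items
proportion-type. Items live on a logit scale — centre μⱼ ~ N(0, 1), sd
σⱼ ~ U(0.4, 1) — and are mapped to percentages in (0, 100), which keeps
triples strictly inside the bounds. The latent truth is drawn from the
item distribution and its mapped value is the realization.

Expert heterogeneity uses a signal model: expert e observes the truth plus
Gaussian noise (sd τ = 1 item-sds), and states the quantiles of the exact
conditional distribution of the truth given their signal, distorted by
their archetype — centre shifted by `bias` item-sds, spread multiplied by
`dispersion`. The calibrated archetype (bias 0, dispersion 1) therefore
states true conditional quantiles, which makes its accuracy p-values
uniform on (0, 1) by construction; dispersion < 1 yields overconfidence
(narrow, informative, statistically inaccurate), dispersion > 1
underconfidence, bias a systematic shift. The default mix — 10% calibrated,
50% overconfident, 10% underconfident, 30% biased — reflects the recurring
field finding that overconfidence dominates and few experts are well
calibrated; it was fixed a priori as the study condition and is converted
to deterministic per-panel counts by largest remainder, so every panel
contains at least one calibrated expert at the default size. A Gaussian
location-scale family is used for analytic control of calibration; any
family would do, the contract being that the calibrated archetype's stated
quantiles are true quantiles of the realization's distribution.

Reproducibility: each panel draws from its own seed substream derived
arithmetically from the global seed, so enlarging a study leaves existing
panels bit-identical.

What the generator does *not* emulate: overlapping panel membership (every
synthetic panel has fresh experts, so distinct-membership selection is
trivial on synthetic data), behavioural interaction between experts, and
item-to-item dependence. Passing tests on synthetic studies therefore
demonstrate the correctness and qualitative behaviour of the scoring and
pooling machinery — dilution of informativeness under equal weights, its
recovery under performance weights, the negative informativeness–accuracy
correlation driven by overconfident experts — not the quantitative values
any particular real elicitation would produce.

## Numerical choices and edge cases

- Degenerate inputs error early and by name: zero-span intrinsic ranges,
  zero-width intervals carrying positive mass (possible when clipping pulls
  a range end onto a stated quantile), empty weight support when α exceeds
  every accuracy.
- Mixture masses are renormalised after accumulation (tolerance 1e-9 on
  input weights; the right-end CDF value is pinned to 1) and quantile
  inversion is exact, verified against bisection to 1e-10.
- Score tables and studies serialise numerics with 17 significant digits,
  so CSV/JSON round-trips are bit-identical.
- Problem sizes in the test-suite simulations (e.g. 200 single-panel
  replicates for recovery properties, a 40-panel study for the cross-panel
  phenomena, 2,000 replicates for p-value uniformity) were chosen as the
  smallest sizes at which the checked properties are stable.

## A small run

```{r example, eval = FALSE}
gen <- generate_study(sim_config(n_panels = 4, seed = 7))
tab <- score_study(gen$study)
pw_vs_ew_summary(tab)

ov <- expert_scores_from_table(tab)
spearman_rho(ov$informativeness, ov$statistical_accuracy)
running_rank_correlation(ov)
```

## Limitations

In-sample DM scores are optimistically biased by construction (the same
calibration items pick α and score the DM); the package mirrors that
deliberately, as the comparison of interest is in-sample PW vs EW. The
chi-square p-value is asymptotic and coarse below N ≈ 10. The distinct-panel
rule treats membership sets, not assessments: two panels with the same
experts but different items still count once. Reported mean EW
informativeness is printed to 3 decimals; published summaries of the
motivating study round the analogous figure to 0.51 in one place and 0.52
in another, a discrepancy attributable to rounding or subset choice that a
3-decimal report avoids.
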