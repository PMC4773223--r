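# sejcm — Classical-Model scoring and pooling for structured expert judgment

When data are sparse or absent — for instance when attributing the burden of
foodborne disease to exposure pathways across world regions — panels of
experts are asked to quantify uncertain quantities as three marker quantiles
(5%, 50%, 95%). The Classical Model turns those judgments into a defensible
pooled estimate by *scoring* each expert on calibration variables from their
field whose true values are known, and *weighting* experts by performance.

`sejcm` implements that machinery and the cross-panel evaluation analytics
around it, for analysts who run or audit multi-panel elicitations:

- **Statistical accuracy** (calibration score): with bins delimited by the
  stated quantiles, the realizations of N calibration variables should fall
  in proportions p = (0.05, 0.45, 0.45, 0.05). The score is the p-value of
  the likelihood-ratio statistic 2·N·I(s; p) referred to χ²(3), where
  s is the empirical bin distribution and I(s; p) = Σ sᵢ ln(sᵢ/pᵢ).
- **Informativeness**: Shannon relative information of the expert's
  minimally-informative density (masses 0.05/0.45/0.45/0.05 between the
  quantiles) against a uniform background on the *intrinsic range* — the
  envelope of all assessors' outer quantiles and the realization, extended
  by a 10% overshoot and clipped to natural bounds.
- **Combined score** = accuracy × informativeness ∝ the expert's weight.
- **Decision makers (DMs)**: equal-weight (`ew`), global performance-weight
  (`pwg`) and item performance-weight (`pwi`) mixtures of the experts'
  densities, with the accuracy cut-off α optimised in-sample (experts below
  α are un-weighted) and the DM scored exactly like an expert via exact
  piecewise-linear CDF inversion.
- **Cross-panel analytics**: distinct-membership panel selection, the
  PW-vs-EW win rate, informativeness dilution under equal weighting, and
  the (running) rank correlation between informativeness and accuracy with
  a seeded permutation p-value.
- **A synthetic study generator** emulating a 112-panel, 13-experts-per-panel
  attribution elicitation with calibrated, overconfident, underconfident and
  biased expert archetypes.

## Worked example

```r
library(sejcm)

gen <- generate_study(sim_config(n_panels = 2, seed = 7))
tab <- score_study(gen$study)          # experts + ew/pwg/pwi rows per panel
subset(tab, panel == "p001" & kind != "expert")
#>    panel assessor kind statistical_accuracy informativeness   combined
#> 14  p001       ew   ew            0.3288980       0.2565015 0.08436282
#> 15  p001      pwg  pwg            0.2027986       0.6262512 0.12700284
#> 16  p001      pwi  pwi            0.2027986       0.6262512 0.12700284
```

The equal-weight DM is statistically acceptable (accuracy 0.33) but diluted
(informativeness 0.26, versus 1.10 for this panel's experts individually);
the performance-weighted DMs more than double the informativeness while
keeping an acceptable accuracy — the core trade-off this package measures.

The full workflow is scripted:

```sh
Rscript analysis/01_simulate.R --seed 1          # results/study.json + truth
Rscript analysis/02_score_and_pool.R             # results/score_table.csv
Rscript analysis/03_panel_analysis.R             # summary + scatter CSVs
```

On the default 112-panel study this prints, among other things, the PW-vs-EW
win percentage, the mean expert/EW/PW informativeness, and an expert-level
Spearman rank correlation between informativeness and accuracy of about
−0.4 with a permutation p-value below 1e-4 — the least accurate
(overconfident) experts drive the negative association, and the running
rank correlation attenuates toward zero as they are excluded.

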