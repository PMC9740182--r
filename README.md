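# hairdyn — recurrence dynamics of hair elemental time series

Laser-ablation ICP-MS scanned along a single hair strand turns one hair into
a month-long elemental time series: >650 sampling points per strand for a
panel of isotope channels, each normalised point-wise to sulfur
(e.g. Zn:S) to cancel hair-matrix density variation. Elemental metabolism is
rhythmically regulated, and the hypothesis behind this workflow is that the
*dynamics* of that regulation — not elemental concentrations — carry an
early, non-invasive diagnostic signature for autism spectrum disorder (ASD),
visible as attenuated periodic dynamics in elements such as zinc, copper and
lithium.

`hairdyn` is an R package plus a scripted analysis that implements the whole
pipeline and exercises it end to end on a synthetic cohort generator whose
statistical structure matches what the analysis assumes:

1. **Simulation** — cohorts of subjects (diagnosis, sex, age, site/batch)
   with per-strand multi-element series: circadian-scale sinusoids on a
   slowly drifting baseline, multiplicative measurement noise, per-site
   batch factors, and case-specific attenuation of the periodic amplitude in
   a configurable element subset.
2. **Feature engineering** — per element, delay embedding with the delay
   `tau` at the first prominent minimum of the average mutual information
   and the dimension `m` from Kennel's false-nearest-neighbour criterion;
   recurrence matrices (RQA) and cross-recurrence matrices for every element
   pair (CRQA) thresholded so every matrix has a fixed 10% recurrence rate;
   12 canonical features per matrix (RR, DET, L, Lmax, DIV, ENTR, LAM, TT,
   Vmax, VENTR, DET/RR, TREND) from exhaustive line-length histograms.
3. **Association scan** — batch correction and z-scoring, one logistic model
   per feature (`diagnosis ~ feature + sex + age_months`),
   Benjamini-Hochberg FDR at 0.05, per-pathway effect summaries.
4. **Diagnostic model** — 80/20 random split (486 subjects split 389/97),
   training-set-only screening of the top-64 features, XGBoost tuned by
   surrogate-assisted search under 5-fold cross-validation, holdout ROC with
   the operating point at Youden's J = sensitivity + specificity − 1, exact
   Clopper-Pearson intervals, and DeLong-type sex-stratified AUC
   comparisons.
5. **QA** — replicate strands sharing a subject's latent dynamics, compared
   feature-wise by symmetric percent difference against the ±10%
   reproducibility bar.

The methods vignette (`vignettes/hair-elemental-dynamics.Rmd`) documents the
model, every tunable parameter, the generator's scope and the numerical
choices.

## Worked example

The numbered scripts under `analysis/` run the study on a 160-subject,
six-element cohort with a 60% case attenuation of Zn/Cu/Li dynamics
(`Rscript analysis/01_simulate_cohort.R`, then `02`…`05`; artifacts land in
`results/`). Output from the run used here:

```
cohort written to results/cohort (160 subjects, 80 cases; 660 points per strand)
engineered 252 features for 160 subjects in 1.0 min
70 of 252 features significant at FDR < 0.05
  pathway n_features n_sig n_sig_pos n_sig_neg        min_q
1      Zn         12     9         5         4 3.524722e-08
2      Li         12     6         4         2 3.524722e-08
3   Zn.Li         12     6         5         1 1.553112e-07
split: 128 train (62 cases) / 32 holdout (18 cases)
tuned booster: CV AUC 0.986 (eta 0.0662, depth 4, 45 rounds)
Holdout evaluation (n = 32 , 18 cases)
  AUC 0.988; Youden J 0.944 at threshold 0.5024
  sensitivity 94.4% (95% CI 72.7-99.9%)
  specificity 100.0% (95% CI 76.8-100.0%)
  accuracy    96.9% (95% CI 83.8-99.9%)
mean fraction of features within +/-10%: 0.918
```

Reading the numbers: the association scan concentrates its discoveries in
the three perturbed pathways and the pairs touching them (enrichment of the
planted signal); the booster separates cases almost perfectly at this effect
size; and replicate strands reproduce ~92% of features within the ±10% QA
band. Equivalent calls are available programmatically — `generate_cohort()`,
`feature_table()`, `associate()`, `split_subjects()`, `screen_features()`,
`tune_and_fit()`, `evaluate_scores()`, `replicate_agreement()` — or in one
shot via `run_pipeline(pipeline_config(...), "out_dir")`.

A minimal session:

```r
library(hairdyn)
coh <- generate_cohort(cohort_config(n_subjects = 40, n_elements = 3,
                                     effect_size = 0.8, seed = 1))
feats <- feature_table(coh$profiles)          # 40 x 72 features
norm  <- batch_correct_and_zscore(feats, coh$subjects$batch)
scan  <- associate(norm, coh$subjects)
head(forest_summary(scan)$summary)
```

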