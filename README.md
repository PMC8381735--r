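# lncPairSig

Prognostic signatures from **immune-related lncRNA pairs** for survival
analysis of tumor cohorts.

Conventional expression signatures weight absolute expression levels, so
they inherit every platform and normalization difference between the
training data and the clinic. `lncPairSig` instead builds signatures from
*within-sample rank comparisons*: for a pair of lncRNAs (A, B) and a
sample *s*, the covariate is the binary indicator

```
C_AB(s) = 1  if expr(A, s) >= expr(B, s),   else 0
```

which is invariant to any positive rescaling of the sample. The risk score
is `RiskScore(s) = Σ_i C_i(s) · W_i`, where the weights `W_i` are
multivariate Cox proportional-hazards coefficients of the selected pairs.

The full pipeline:

1. **Screen** lncRNAs co-expressed with immune genes (Pearson r > 0.4,
   p < 0.001 on log2(FPKM+1)), then keep those differentially expressed
   between tumor and normal (|log2FC| > 1, BH FDR < 0.05, Wilcoxon
   rank-sum).
2. **Encode** all pairs of the surviving lncRNAs as 0/1 indicators and
   drop near-constant pairs (prevalence outside the open interval
   (20%, 80%)).
3. **Select** the signature: univariate Cox screen (Wald p < 0.05),
   LASSO-Cox with repeated cross-validation (deviance-minimizing lambda),
   stepwise AIC refinement (exhaustive best subset for small sets).
4. **Stratify**: 1/3/5-year time-dependent ROC (KM estimator, cumulative
   cases / dynamic controls); the risk cut-off maximizes sensitivity +
   specificity on the 5-year curve.
5. **Evaluate**: Kaplan–Meier + log-rank, chi-square and rank-sum tests
   against clinicopathology, univariate/multivariate Cox independence
   models, Spearman correlation with immune-infiltration tables, per-drug
   IC50 comparisons.

The package contains its own Newton–Raphson Cox partial-likelihood engine
(Efron ties, step-halving, Wald inference) used for every unpenalized fit,
and a seeded synthetic-cohort generator (`simulate_cohort()`) that plants
co-expression, differential expression, pair-driven hazards and correlated
clinical/immune/drug tables, with a full ground-truth record for recovery
testing.

## Worked example

A compact synthetic run (300 tumor + 40 normal samples, 80 lncRNAs, 3
planted prognostic pairs):

```r
library(lncPairSig)
cfg <- pipeline_config(
  sim = sim_config(n_tumor = 300, n_normal = 40, n_lnc = 80, n_imm = 40,
                   n_coexpr = 25, n_de = 18, n_true_pairs = 3, seed = 1),
  n_repeats = 5, seed = 42)
report <- run_pipeline(cfg)
print(report)
#> lncRNA pair signature pipeline report
#>   funnel: 80 lncRNA -> 25 irlncRNA -> 17 DEirlncRNA (14 up / 3 down) -> 47 valid pairs -> 10 univariate -> 10 LASSO -> 5 final
#>   cutoff = -0.2003; groups: high = 88, low = 204
#>   AUC: t365 = 0.663, t1095 = 0.716, t1825 = 0.737
#>   log-rank: chi-square = 41.693, p = 1.07e-10
```

The funnel line is the gene/pair attrition through the pipeline: 80
lncRNAs, 25 passing the immune co-expression screen, 17 differentially
expressed, 47 valid pairs, 10 surviving the univariate Cox screen and the
LASSO, 5 in the final AIC-refined model. The cut-off is a risk-score
value; 88 samples score strictly above it (high risk) and their survival
is sharply worse (log-rank p ≈ 1e-10).

```r
print(report$signature)
#> pair signature: 5 pairs, cutoff = -0.2003
#>              pair     weight
#> 1 LNC0004|LNC0008 -0.3993325
#> 2 LNC0007|LNC0009  0.5368525
#> 3 LNC0008|LNC0011  0.7349595
#> 4 LNC0011|LNC0018 -0.3513408
#> 5 LNC0012|LNC0015 -0.7292747
report$truth$true_pairs
#>     geneA   geneB       beta
#> 1 LNC0007 LNC0009  0.9290304
#> 2 LNC0008 LNC0011  1.1761251
#> 3 LNC0012 LNC0015 -1.1569319
```

All three planted pairs appear in the recovered signature with weights of
the correct sign. The risk score also dominates every ordinally coded
clinical covariate on the 5-year ROC:

```r
head(report$roc_compare)
#>       marker       auc
#> 1 risk_score 0.7374234
#> 2          N 0.6225045
#> 3      stage 0.5899321
#> 4        age 0.5602973
#> 5          T 0.5377090
#> 6          M 0.5376048
```

Real data enter through `pipeline_config(input = list(expression = ...,
group_map = ..., gene_catalog = ..., immune_genes = ..., clinical = ...,
immune_fractions = ..., ic50 = ...))` with TSV/CSV tables; see
`?run_pipeline` and the vignette in `vignettes/pair-signatures.Rmd` for
the file dialects, parameter meanings and design rationale.

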