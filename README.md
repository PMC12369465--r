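# ctgtime

Time-varying association analysis of cardiotocographic (CTG) features.

## The problem

During labor, clinicians monitor the fetal heart rate (FHR) and uterine
pressure (UP) to spot fetuses at risk of acidosis and hypoxic-ischemic
encephalopathy (HIE). Automated CTG classifiers almost universally apply
*time-invariant* rules: a feature is informative or it is not. But labor
is a progression, and a feature's relationship with outcome can itself
change as delivery approaches. `ctgtime` is for biostatisticians and
CTG-methods researchers who want to screen per-epoch CTG features for
exactly that time structure — and to know which features a stationary
classifier would wrongly discard.

## The method

For each feature `F`, outcome class `C ∈ {healthy, acidosis, HIE}` and
time to delivery `TTD` (20-min epochs over the last 12 h of labor, binned
histograms with the Rice-rule bin count), the package estimates

- `NMI_F(F;TTD) = I(F;TTD)/H(F)` — is the feature time varying?
- `NMI_C(C;F) = I(C;F)/H(C)` — the time-invariant (TI) outcome
  association;
- `NMI_C(C;F|TTD) = I(C;F|TTD)/H(C)` — the outcome association when
  accounting for time (TV).

Significance comes from stratified Monte-Carlo permutation nulls
(classes shuffled at the infant level within hospitals; TTD shuffled
within infants), with the literal exceedance p-value
`p = N_MC⁻¹ Σ 1[H0(S) ≥ S]` and one Benjamini–Hochberg family over all
`3·N_feats` tests. The two class tests induce the feature taxonomy:
**type I** (TI only), **type II** (TV only), **type III** (both),
**null** (neither). A model-free complement computes the two-sample
Kolmogorov–Smirnov statistic `d_KS` (healthy vs pathological) pooled and
per epoch, with the argmax of the ECDF difference as the optimal decision
threshold and bootstrap variability for both.

Because labor-ward datasets of this kind are firewalled, the package
ships a seeded synthetic cohort generator (class imbalance, 15 hospitals,
class-dependent labor lengths and epoch availability, feature archetypes
that realise each taxonomy label by construction) plus a raw-trace
simulator with ground-truth event annotations, a rule-based
acceleration/deceleration/contraction detector, and an 88-feature
per-epoch extractor (26 baseline + 28 acceleration + 31 deceleration +
3 contraction features: entropies, spectral band powers, PRSA capacities,
classical fetal-HRV indices, event geometry).

## A worked example

```r
library(ctgtime)

tbl <- generate_feature_table(cohort_spec(seed = 7))   # 450 infants
assoc <- ctg_association(tbl, n_mc = 500, seed = 7)
assoc
#> <ctg_assoc> 11 features, 33 tests (N_MC = 500, alpha = 0.05, n_bins = 20)
#>
#>     null   type_I  type_II type_III
#>        4        3        2        2

dplyr::filter(tidy(assoc), feature == "type_II_01")
#> # A tibble: 3 × 8
#>   feature    kind             statistic n_epochs     p     q reject label
#>   <chr>      <chr>                <dbl>    <int> <dbl> <dbl> <lgl>  <chr>
#> 1 type_II_01 F_vs_TTD           0.0183      6293 0.948 0.994 FALSE  type_II
#> 2 type_II_01 C_vs_F             0.00366     6293 0.362 0.597 FALSE  type_II
#> 3 type_II_01 C_vs_F_given_TTD   0.154       6293 0     0     TRUE   type_II
```

The mirrored `type_II_01` archetype carries outcome information at every
epoch but none after pooling over time: its TI statistic (0.004) is not
significant, while conditioning on TTD lifts the association to 0.154
with `q < 0.05` — the signature of a feature that a time-invariant
classifier would discard. (Its time statistic is also null: the mirrored
profile cancels in the class-pooled feature-time view, and every archetype
of all four kinds is recovered under its designed label here.)

```r
ks <- time_resolved_ks(tbl, "type_III_01")
glance(ks)
#> # A tibble: 1 × 7
#>   feature     d_ks_ti threshold_ti d_ks_tv_max d_ks_tv_mean n_epochs_significant
#>   <chr>         <dbl>        <dbl>       <dbl>        <dbl>                <int>
#> 1 type_III_01   0.181       0.0430       0.472        0.259                   17
#> # ℹ 1 more variable: n_epochs_available <int>
```

For the diverging-trajectory archetype the best per-epoch separability
(`d_KS = 0.47`) is well over twice the pooled value (`0.18`): the optimal
threshold, and its usefulness, move with time. `autoplot()` methods
display both result types; `run_pipeline(pipeline_config(...))` chains
simulate → associate → discriminate → report into a CSV bundle with a
run log and full provenance.

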