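# chronomet

Time-resolved analysis of longitudinal untargeted LC-MS metabolomics
studies with repeated measures: several treatment arms (control `C`,
treated `A`, treated-plus-intervention `AE`), subjects sampled on a
fixed day grid (0, 14, 28, 63, 91 by default), positive and negative
ionization analyzed separately. The package is for analysts who have a
quantified feature table and want the full downstream workflow —
reproducible, testable, and free of external services.

The pipeline:

1. **Preprocess** — keep features with MS2 identification score > 0.5,
   collapse duplicate features to one metabolite by the elementwise
   per-sample maximum, report QC stability (CV over pooled QC
   injections, sample PCA).
2. **Paired screen** — per arm, day 63 vs day 0 on subjects with both
   days: log2FC = mean per-subject log2 ratio, paired t-test on log2
   intensities; two-stage volcano classification (p < 0.05, then
   |log2FC| > 1); exact Venn regions of the changed sets across arms.
3. **Soft clustering** — per arm, metabolite trajectories are
   summarized as per-day medians (log2 scale), z-scored, and clustered
   by fuzzy c-means,

   $$J=\sum_i\sum_k u_{ik}^m\,\lVert x_i-v_k\rVert^2,\qquad
     u_{ik}=\Big[\sum_j (d_{ik}/d_{ij})^{2/(m-1)}\Big]^{-1},\qquad
     v_k=\frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m},$$

   with the cluster number chosen from the minimum-centroid-distance
   (Dmin) curve by an automated elbow rule, and *core* metabolites
   defined by membership > 0.7.
4. **Patterns** — centroids map by Pearson correlation to canonical
   temporal shapes (rise-then-fall, fall-then-rise, monotone up/down,
   late rise); core metabolites shared between two arms are flagged
   when their pattern changes.
5. **Trend classification** — per metabolite and arm, nested linear
   mixed models on log2 intensity with a random subject intercept
   (M0 ⊂ M1: + scaled time t ⊂ M2: + t²), fitted by ML; χ²(1)
   likelihood-ratio tests gate the four-way label `model1_up`,
   `model1_down`, `model2_up`, `model2_down` (linear vs quadratic ×
   sign of the leading coefficient).
6. **Concordance + enrichment** — metabolites trending the same way in
   C and AE and oppositely in A are selected and tested for pathway
   over-representation (one-sided hypergeometric, BH-adjusted) against
   a user-supplied annotation, plus compound-class composition.

A synthetic-study generator plants trajectory archetypes, subject
random intercepts, lognormal noise, duplicate features with MS2 scores
straddling the filter, QC samples and day-63 dropout — with full ground
truth — so every stage is validated end to end without any download.
See `vignettes/chronomet-methods.Rmd` for the models, parameter
defaults and design choices.

## Worked example

```r
library(chronomet)

study <- generate_study(fixture_config("tiny", seed = 1))
sub   <- subset_ion_mode(study$features, study$samples, "POS")
pre   <- preprocess_study(sub$features, sub$samples)
pre$matrix
#> MetaboliteMatrix: 24 metabolites x 91 samples

st <- cluster_stage(pre$matrix, "C", seed = 1)
st$fit
#> ClusterResult: c = 7, m = 2, 24 metabolites, objective 2.4940 (53 iterations)
head(st$core, 3)
#>   metabolite cluster membership
#> 1  M_POS_001       2  0.8969063
#> 2  M_POS_002       2  0.9699776
#> 3  M_POS_003       2  0.9797759

tpl <- archetype_templates(c(0, 14, 28, 63, 91))
head(assign_patterns(st$fit, tpl), 3)
#>   cluster pattern_id   pattern_name correlation
#> 1       1          2 fall_then_rise   0.9994865
#> 2       2          1 rise_then_fall   0.9954509
#> 3       3          2 fall_then_rise   0.7986762

lmm <- lmm_stage(pre$matrix)
subset(lmm$concordance, selected)$metabolite
#> [1] "M_POS_004" "M_POS_009" "M_POS_022" "M_POS_023" "M_POS_024"

ann <- toy_annotation(rownames(pre$matrix$intensity))
head(hypergeom_enrich(subset(lmm$concordance, selected)$metabolite, ann), 1)
#>   pathway_id          pathway_name k K n  N   p_value   q_value
#> 1     path04 vitamin B6 metabolism 1 2 5 24 0.3804348 0.6352343
```

Each core row is a metabolite whose maximal cluster membership exceeds
0.7 — its trajectory is reliably described by that cluster's centroid;
the pattern table names the temporal shape each centroid follows and
how tightly (Pearson r). The concordance list contains the metabolites
whose time trend agrees in C and AE and opposes A — here the generator
planted exactly such metabolites, and the mixed-model screen recovers
them. The enrichment row reads: of the 5 selected metabolites from a
24-metabolite universe, 1 fell in the 2-member pathway (k/K), which is
unremarkable (p = 0.38, hypergeometric upper tail).

The same workflow runs from the shell:

```sh
chronomet simulate --fixture default --seed 5 --out study/
chronomet run-all --features study/features.tsv --samples study/samples.tsv \
    --seed 5 --out results/
```

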