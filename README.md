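# matreg

Tumors remodel their microenvironment through the **matrisome** — the
ensemble of extracellular-matrix and ECM-associated genes: collagens,
glycoproteins, proteoglycans, basement-membrane components, ECM regulators
and secreted factors. `matreg` implements, as a tested and reusable R
pipeline, an end-to-end procedure for charting tumor-type-specific matrisome
gene signatures, the transcription-factor (TF) "modules" that regulate them,
the master-regulator layer above those TFs, and the prognostic and
druggability consequences of module activity. Because the pipeline is meant
to be exercised offline, the package ships a synthetic multi-tumor cohort
generator with *planted, recoverable ground truth* standing in for the
pan-cancer expression compendium, TF-target prior databases, driver tables,
protein-protein interaction (PPI) networks, immunohistochemistry staining
and drug-gene interaction resources the original analysis drew on.

It is written for computational biologists who want either (a) the module
machinery itself — Youden-threshold correlation separation, adaptive-lasso
pruning, multi-model consensus — applied to their own expression matrices
and priors, or (b) a fully self-contained simulation test-bed for regulatory
inference methods.

## The method in brief

1. **Landscape.** Per-tumor gene ranking by mean expression; inter-tumor
   Pearson correlation of mean-expression vectors over the union of top-k
   gene lists, clustered by average linkage on distance 1 − r; tumor-type
   recall from three classifiers (RBF-SVM, neural network, decision tree)
   over repeated random 80/20 splits; chi-square contingency tests with
   Yates continuity correction on 2×2 tables.
2. **Signatures.** A matrisome gene joins a tumor's signature iff it is
   up-regulated (Welch t-test, Benjamini–Hochberg-adjusted P < 0.05) both
   versus matched healthy tissue **and** versus the pooled rest of the
   cohort (same-cluster tumors excluded). Cluster signatures are exact
   intersections of member signatures.
3. **Modules.** A module is one TF→signature-gene interaction in one tumor.
   Candidates are mined from six prior sources and must carry ≥ 2 sources,
   one of them FANTOM5-like (TF presence or TF-binding-site enrichment).
   Pearson correlations are computed in-tumor (r_in) and in the pooled rest
   of the cohort (r_rest), Fisher-transformed (zCor = atanh r); negative
   r_in is discarded; a Youden-index cutpoint over the zCor samples keeps
   modules with zCor_in above the threshold and above zCor_rest; targets
   with > 1 surviving TF are pruned by adaptive lasso ("model 1"); a
   BIC-scored sparse Gaussian network search ("model 2") and lasso
   neighborhood selection ("model 3"), each stabilized over 10 resampled
   folds, confirm the edges; modules present in ≥ 2 of the three models are
   final. Proteins are cross-validated against staining profiles
   (Percentile Positive Staining > 0).
4. **Master regulators.** Cancer drivers pass frequency filters
   (tumor-specific: mutation frequency > 5%; pan-cancer: frequency in the
   tumor above that driver's cross-cohort mean) and must contact > 10% of
   the tumor's module TFs in the PPI network. Shared regulators are
   extracted per cluster with an L2 linear SVM (ROC AUC on held-out
   splits); the regulatory layer is tested for pathway over-representation
   (hypergeometric + BH), flagging pathways carrying ≥ 2 mutated
   cancer-specific masters.
5. **Survival & drugs.** Module activity (mean of TF and target log2
   expression) is mean-dichotomized; Kaplan–Meier/log-rank labels modules
   noxious or favorable; direction consistency across modules sharing a TF
   or target is checked; the whole architecture is mapped to drug-gene
   interactions, partitioned by layer and on-/off-label status.

## Worked example

```r
library(matreg)

sim  <- simulate_study(sim_config(seed = 1))     # 300 genes x 1250 samples
pipe <- run_study_pipeline(sim, seed = 1)        # signatures + modules
fin  <- pipe$modules[pipe$modules$final, ]
t(sapply(pipe$results, function(r) r$counts))
#>     mined post_correlation post_youden model1 final
#> T01    14               10           8      8     8
#> T02    12               10           8      8     8
#> T03    12                9           8      8     8
#> T04    20               14           8      8     8
#> T05    23               13           8      8     8
evaluate_module_recovery(fin, sim$truth)[c("precision", "recall")]
#> $precision [1] 1
#> $recall    [1] 1
```

Reading: mining proposed 14–23 candidate modules per tumor (planted plus
decoy priors); the correlation filter, Youden threshold and adaptive lasso
cut them down to the 8 planted modules per tumor; models 2–3 confirmed all
of them, so the final consensus recovers the planted network exactly
(precision and recall 1 on this seed). In-tumor correlations of final
modules average r ≈ 0.8 against r ≈ 0.06 in the rest of the cohort —
the separation the Youden threshold exploits.

The numbered scripts under `analysis/` run the whole study narrative
(simulation → landscape → signatures → modules → masters → survival/drugs)
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_landscape.R   # ... through 06
```

## Limitations

The synthetic generator controls effect sizes exactly (closed-form planted
correlations, guaranteed filter margins) and does not attempt to mimic
batch effects, sequencing-platform noise, CAGE read counts or
metastatic-specific biology; see the methods vignette
(`vignettes/matrisome-regulation.Rmd`) for what passing tests do and do not
demonstrate about real cohorts.
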