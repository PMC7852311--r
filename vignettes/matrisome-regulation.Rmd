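---
title: "Inferring tumor matrisome regulatory modules: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring tumor matrisome regulatory modules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(matreg)
```

## The problem

Each tumor type expresses its own matrisome program — a characteristic set
of extracellular-matrix genes — and that program is driven by transcription
factors (TFs) which are in turn contacted by mutated cancer drivers.
`matreg` reconstructs this three-layer architecture from a gene × sample
log2-scale expression matrix, sample annotations with matched healthy
tissues and survival follow-up, TF–target prior sources, driver mutation
frequencies, a protein–protein interaction (PPI) network, staining profiles
and a drug–gene interaction table. Every stage is exercised on synthetic
cohorts in which the true signatures, modules, masters and prognostic
effects are planted and therefore recoverable, so the pipeline's operating
characteristics (precision, recall, calibration) can be measured rather
than assumed.

## The module model and its assumptions

A *module* is a directed TF → matrisome-target interaction attributed to
one tumor type. The pipeline treats a pair as a genuine module in tumor
\(T\) when three kinds of evidence agree:

1. **Prior evidence.** The pair occurs in at least two of six prior
   sources, and at least one of them is "functional-genomics-like"
   (FANTOM5-style TF presence, or TF-binding-site enrichment in the
   signature). This is a hard gate: purely text-mined co-occurrence in two
   literature databases is not enough.
2. **Correlation separation.** With \(r_{\mathrm{in}}\) the Pearson
   correlation over \(T\)'s primary samples and \(r_{\mathrm{rest}}\) over
   the pooled primary samples of all other tumors, we require
   \(r_{\mathrm{in}} > 0\) and, after the Fisher transform
   \(z = \operatorname{atanh} r\) (which makes the sampling distribution of
   \(r\) approximately normal), \(z_{\mathrm{in}}\) must exceed both the
   Youden-index cutpoint separating the in-tumor from the rest-of-cohort
   \(z\) sample and \(z_{\mathrm{rest}}\) itself. The underlying assumption
   is tumor-specific rewiring: a regulatory interaction used *by this
   tumor* shows markedly higher co-expression inside it than elsewhere.
3. **Conditional relevance.** Marginal correlation can be inherited from a
   shared upstream factor, so targets claimed by more than one TF are
   regressed on all their candidate TFs with the adaptive lasso and only
   un-shrunk coefficients survive ("model 1"); the surviving edge set is
   then re-estimated by two structurally different methods — a BIC-scored
   sparse Gaussian network search and lasso neighborhood selection — each
   stabilized over 10 resampled folds, and an edge is final only if at
   least two of the three models contain it.

All correlation-based steps assume approximately linear co-expression on
the log2 scale and primary-sample homogeneity within a tumor type; the
pooling of "rest of cohort" assumes no single other tumor dominates the
pooled correlation.

## Stage-by-stage parameters

| Parameter | Default | Units / scale | Why this value |
|---|---|---|---|
| signature `alpha` | 0.05 | BH-adjusted P | conventional FDR level; applied per tumor × comparison family over matrisome genes only, because the matrisome-restricted matrix is built first |
| clustering `k` | 100 | genes/tumor | top-expressed gene list size; the correlation structure is stable for k in 20–100 |
| clustering `cut_height` | 0.5 | 1 − r | tumors join a cluster while their average correlation exceeds 0.5; a deterministic reading of "blocks" in a correlation heatmap |
| classifier splits | 100 (SVM), 10 (NN, tree) | repetitions of random 80/20 | mirrors the reference protocol; standardization statistics come from training folds only to avoid leakage |
| Youden `conf_level` | 0.95 | echo only | recorded for provenance; the cutpoint is a point estimate (see Open decisions) |
| adaptive lasso `gamma` | 1 | weight exponent | standard adaptive-lasso weighting \(w_j = 1/|\hat\beta_j|\); initial fit least squares, ridge when rank-deficient |
| lasso penalty | `lambda.1se` | CV scale | the sparser of the two conventional CV choices; variable selection, not prediction, is the goal |
| models 2–3 folds | 10 × 90% subsamples | — | "10× cross-validation" is under-specified; random subsampling with a 50% stability threshold is the stability-selection reading, both knobs exposed |
| driver filters | > 5% (specific), > own cross-cohort mean (pan-cancer) | mutation frequency | strict inequalities, tested at the exact boundaries |
| PPI coverage | > 10% | fraction of module TFs | strict inequality; coverage = contacted TFs / all module TFs |
| dichotomization | cohort mean | log2 activity | "above the average" is high; ties go low |
| survival P | raw 0.05 | per-module | per-module monovariate tests are reported uncorrected, with BH-adjusted values alongside for transparency |

## What the synthetic generator emulates

`sim_config()` defaults define the reference study conditions: 5 tumor
types × 200 primary samples with 50 matched healthy samples each, 300 genes
(120 matrisome, 60 TFs, 120 others), 12 signature genes per tumor shifted
by +4 log2 units, 8 planted modules per tumor with in-tumor correlation
0.8 against 0.1 elsewhere, 3 decoy prior pairs per true pair, planted
masters at 15% specific mutation frequency wired to half of their tumor's
TFs, a prognostic hazard ratio of 3 and 30% censoring.

Construction choices worth knowing:

* **Baselines.** Per-(gene, tumor) means are drawn once from a shared
  hyper-distribution — gene centers uniform on log2 4–8 plus N(0, 1.5)
  tumor deviations — so tumor types are separable (deviation variance
  exceeds center variance, putting unrelated tumors' mean-vector
  correlation well below the 0.5 cluster cut) without hand-tuned marker
  genes. Matched healthy tissue shares its tumor's baseline means, so with
  a zero planted shift a tumor and its healthy tissue differ only by
  sampling noise — this is what makes the null-calibration tests
  meaningful.
* **Planted correlations.** A module target is built as
  \(\mu + a\,z_{\mathrm{TF}} + \sqrt{1-a^2}\,\varepsilon\) with \(a\) the
  requested correlation, around the *population* mean \(\mu\) (centering on
  the empirical group mean would double the variance of group means and
  bias the null tests — this was measured, not guessed).
* **Structural guarantees.** Every planted module is repaired into ≥ 2
  prior sources including a FANTOM5-like one; every planted master passes
  both frequency filters and is wired to half of its tumor's planted TFs.
  These guarantees hold with probability 1 by construction, so master
  recovery is exact rather than statistical. Decoy drivers are planted to
  fail each filter separately (4% frequency; flat pan-cancer profile;
  passing frequency but no PPI edges).
* **Substreams.** Each generator stage derives its own seed from the master
  seed, so regenerating, say, survival times does not perturb the
  expression matrix.

What it does **not** emulate: batch effects and platform noise, count-level
sequencing models (values are Gaussian on the log2 scale, clamped at 0),
CAGE read counts behind the FANTOM5-like table, metastatic/recurrent
biology, overlapping signatures between tumors (planted signatures are
disjoint), many-to-many module topologies (each planted target has exactly
one planted TF; multi-TF targets arise only through decoy priors), and the
long-tailed degree distribution of real PPI networks. Passing recovery
tests therefore demonstrates that the machinery is correct and calibrated
under its own assumptions — not that real-cohort precision would be
comparable, since real data violate linearity, homogeneity and prior
completeness in ways the generator deliberately does not model.

## Numerical choices and degenerate inputs

* Youden cutpoints are midpoints between consecutive distinct pooled
  z values; sensitivity counts strictly-above, specificity at-or-below.
  Ties in J (including floating-point ties at ~1e-9 resolution) resolve to
  the smallest cutpoint. An all-identical z sample is an error — there is
  no separating cutpoint.
* Identical TF columns in the adaptive lasso are collapsed before fitting,
  keeping the lexicographically first identifier; all other tie-breaks in
  the package are also lexicographic.
* Cross-validation fold assignment inside glmnet calls uses a fixed
  round-robin `foldid`, so penalized fits are deterministic given the data;
  the only randomness in models 2–3 is the explicit, seeded subsampling.
* Constant expression vectors: the correlation filter drops the candidate
  with a message; the landscape correlation errors naming the offending
  tumor; degenerate t-tests (both groups constant) report P = 1.
* `dichotomize()` refuses all-identical activities (one stratum would be
  empty); `km_logrank()` refuses event-free data.
* Gene universes for pathway enrichment default to the expression matrix's
  genes; query genes outside the universe are an error rather than a silent
  drop.

## Open decisions

* *"Youden Index (confidence interval = 0.95)"* — what the interval
  modifies is not stated in the source protocol. Implemented as the
  J-maximizing cutpoint between the two z samples; `conf_level` is echoed in
  the result but does not move the cutpoint.
* *Rest-of-cohort pooling.* The rest comparison pools all other tumors'
  primary samples into one group (for signatures, excluding same-cluster
  tumors), rather than testing per-tumor and combining; "compared vs. the
  same gene in all other tumor types" reads as pooled.
* *Welch t-tests.* Only a "pairwise t-test" is specified; Welch is the safer
  default for the unequal group sizes the design produces.
* *Recall averaging.* Macro-averaging (per-tumor means, then across
  algorithms, unweighted) — whether the reference 95% figure is macro- or
  micro-averaged is unstated.
* *Healthy comparison.* The original design used same-assay matched healthy
  tissue when available and an external healthy compendium otherwise; the
  generator collapses this to a single matched-healthy set per tumor, which
  does not alter the inference contract.
* *Linear SVM knobs.* The reference "epsilon: 0.1, lambda: 0.1" are
  vendor-specific; the contract kept is linear kernel + L2 regularization +
  importance extraction (mean |hyperplane weight|) + repeated 80/20 splits,
  with the cost exposed.
* *Per-sample classification.* The cluster-level SVM classifies samples
  (not tumor-mean profiles).

## Problem sizes used in tests and acceptance

Unit tests run on a reduced cohort (3 tumors × 60 samples, 120 genes) with
the same planted structure; recovery and calibration checks use the full
reference conditions (5 × 200) with 10 replicates for module recovery,
20 replicate-tumor combinations for the signature null, and 500
module-replicate tests for the log-rank null. These sizes give the
acceptance quantities binomial standard errors of a few percent while the
whole suite stays in the tens of seconds on one CPU.

## Limitations

Beyond the generator's idealizations listed above: the consensus restricts
models 2–3 to model-1 pairs, so the pipeline can only remove, never add,
interactions missed by the priors; pooled rest-of-cohort correlations can be
inflated by between-tumor mean structure (ecological correlation), which the
Youden threshold absorbs only when the in-tumor signal is strong; and the
survival screen is monovariate by design — it flags prognostic association,
not independent prognostic value.
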