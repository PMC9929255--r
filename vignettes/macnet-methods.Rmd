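---
title: "macnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{macnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`macnet` implements a complete computational workflow for studying how
circulating factors (for instance, patient serum after acute myocardial
infarction, AMI) reprogram macrophages, and for turning the resulting
transcriptional signature into drug-repurposing candidates. The workflow
is: per-gene differential expression, weighted co-expression modules and
eigengenes, module–trait correlation against clinical outcomes (infarct
size, ejection fraction, end-diastolic volume), a mutual-information
regulatory network restricted to candidate transcription factors,
regulatory-score ranking of candidate driver TFs, connectivity-map style
scoring of perturbation profiles against an up/down signature, triple
feature selection with cross-validated classification, and cross-cohort
validation statistics (hypergeometric list overlap, single-sample gene-set
enrichment).

Every stage is exercised against a synthetic cohort generator with planted
ground truth, so the package's guarantees are stated as recovery
properties rather than as re-derivations of any particular cohort's
numbers.

## The synthetic cohort generator

`generate_cohort()` draws from a linear-Gaussian factor model. Each of the
`k` planted modules has a per-sample latent factor

$$ f_m \sim N(0,1) + \delta_m \, 1[\text{AMI}] + \gamma_m \, 1[\text{Large}], $$

where $\delta_m$ (`group_shift`) models the serum effect and $\gamma_m$
(`subgroup_shift`) the infarct-size subgroup effect, both in factor-SD
units. Module gene $i$ is $\lambda_i f_m + \varepsilon$, with loading
$\lambda_i \sim U(0.4, 0.9)$ and noise SD 0.5; the module's planted TF is
$f_m + \varepsilon$; background genes are pure $N(0,1)$. Everything is
mapped to a plausible log2-expression scale ($6 + 2x$).

This model was chosen because a single mechanism simultaneously induces
co-expression structure (for module recovery), TF–target statistical
dependence (for network recovery), and trait coupling (for module–trait
recovery), each with analytically known strength. Defaults mirror a
realistic discovery cohort: 47 AMI + 20 control samples, the AMI arm split
23 Small / 24 Large, 2,000 genes, five modules of 60–100 genes. Three of
the five modules carry a group shift of 1.0; the remaining two carry
subgroup shifts of +1.5 and −1.5, so the Large-vs-Small contrast yields a
two-sided signature, as adverse-remodeling signatures are in practice.
Clinical traits are coupled to the subgroup-shifted modules at a target
Pearson r of 0.6 with clinically consistent orientation (ejection fraction
tracks the module that is *down* in Large infarcts), then mapped to
familiar units (infarct size ≈ 20 ± 10 %, EF ≈ 50 ± 8 %, EDV ≈ 160 ±
30 mL). The target correlation is calibrated against the empirically
standardized factor, so the planted r is exact in expectation regardless
of the subgroup shift's variance contribution.

Sex is assigned independently of every signal by default (a
`confound_sex` flag exists for sensitivity analyses). The perturbation
database emulates a cell-line compendium: per-drug, per-gene z-score
profiles; planted "reverser" drugs shift signature up-genes by
−`reverser_gain` (default 3) and down-genes by +`reverser_gain` on top of
unit noise; decoys are pure noise.

What the generator deliberately does **not** emulate: count noise and
library-size effects, batch structure, correlated background genes,
nonlinear regulation, and realistic TF cascade depth. Passing recovery
tests therefore demonstrates the pipeline's correctness and statistical
calibration under a well-specified factor model, not its performance on
raw sequencing data.

## Differential expression

Per gene, the package computes a Welch unequal-variance t-test on log2
values, with the log2 fold change defined as contrast-minus-reference mean
difference, Benjamini–Hochberg adjustment across genes, and a fully
deterministic ranking (adjusted p, then raw p, then gene id — the
tie-break matters because downstream feature selection consumes "top
100"). The Welch test is a deliberate, documented stand-in with the same
output contract (log2FC, adjusted p) as a dedicated DE model; no
count-model (negative-binomial) fitting is attempted because the package
operates on normalized log2 matrices.

Group comparisons of functional readouts use the same Welch test or the
Mann–Whitney U test (exact enumeration when the pooled sample size is at
most 12, tie-corrected normal approximation with continuity correction
otherwise). Functional readouts are z-scored per readout with the n−1
denominator; that denominator convention is used everywhere in the
package.

## Co-expression modules

The module pipeline follows the weighted gene co-expression network
canon: unsigned adjacency $a_{ij} = |\mathrm{cor}(x_i, x_j)|^\beta$,
topological overlap

$$ \mathrm{TOM}_{ij} = \frac{\sum_u a_{iu}a_{uj} + a_{ij}}
   {\min(k_i, k_j) + 1 - a_{ij}}, $$

average-linkage clustering of $1 - \mathrm{TOM}$, and module eigengenes
(first principal component of the per-gene standardized member submatrix,
unit norm, sign-oriented to correlate non-negatively with the module's
mean profile).

Three numerical choices deserve justification:

* **Soft power.** The scale-free fitting index is the $R^2$ of a log–log
  regression of binned degree frequency on mean bin degree (10 equal-width
  bins). The chosen power is the smallest candidate whose fit reaches
  `min(target_fit, max_fit − 0.05)` with `target_fit = 0.85`. Anchoring
  the threshold to the fit curve's plateau matters: on noisy curves the
  0.85 line is sometimes first crossed at an extreme power, where the
  sharpened adjacency erodes weakly loaded module genes; simulations show
  module recovery is flat across the plateau and degrades only at its far
  end.
* **Tree cut.** Branches are cut statically at 0.99 × the maximum merge
  height, clusters below `min_size` (30) are returned to the UNASSIGNED
  pool, and modules whose eigengenes correlate above 0.75 are merged
  iteratively (largest pair first). This is a transparent simplification
  of the dynamic hybrid cut; its known weakness — background genes
  attaching to module branches just below the cut — is corrected by a
  **module-membership filter**: assigned genes whose absolute correlation
  with their module eigengene (kME) falls below 0.4 are returned to
  UNASSIGNED and the size filter is re-applied. The 0.4 value sits midway
  between the null kME distribution at these sample sizes (≈0.15 ± 0.12)
  and the weakest expected member kME (≈0.55 at loading 0.4).
* **UNASSIGNED** is a real output category (the catch-all module of
  non-co-expressed genes) but is excluded from eigengene computation and
  trait correlation.

Module–trait association uses Pearson correlation between eigengene and
trait with the Student asymptotic p-value
($t = r\sqrt{n-2}/\sqrt{1-r^2}$), BH-adjusted across modules *within each
trait*: each trait panel is its own testing family, which is what the BH
guarantee is calibrated against in the null tests.

## Regulatory network and driver ranking

Mutual information between two expression profiles is estimated by rank
(copula) transformation followed by equal-frequency binning into
$\max(2, \lfloor n^{1/3} \rfloor)$ bins per axis and the plug-in estimator
$\sum_{ij} p_{ij}\ln(p_{ij}/p_i p_j)$, in nats. This estimator was chosen
over adaptive partitioning because it admits an exact brute-force
contingency oracle, making every MI value in the package independently
checkable.

The network is inferred ARACNe-style: a global MI significance threshold
is calibrated by permutation (null MI values from randomly paired,
permuted genes; an exponential tail is fitted to the upper 5% of the null
and extrapolated to the requested tail probability, default $10^{-7}$ —
far beyond direct counting at any feasible permutation number); each
bootstrap resample keeps TF–gene pairs above the threshold and prunes
indirect edges by the data-processing inequality (edge $ij$ removed when
$w_{ij} < (1-\varepsilon)\min(w_{ik}, w_{jk})$ over triangles, tolerance
$\varepsilon = 0.1$, removals applied simultaneously); consensus edges
need bootstrap support ≥ 0.5 and carry the mean MI over supporting
bootstraps as weight. TF–TF pairs are evaluated in both regulator roles.

Driver ranking restricts the network to targets inside the
trait-associated modules and scores each (TF, module) pair as

$$ \mathrm{RS} = \sum_{t \in \text{targets} \cap \text{module}}
   w(\mathrm{tf}, t)\, |\log_2 \mathrm{FC}(t)|, $$

with fold changes from the Large-vs-Small subgroup contrast. Within each
module the top $\max(1, \lceil 0.01 \cdot \text{module size} \rceil)$ TFs
by RS are selected ("top 1% relative to module size"); ties break by
total edge weight, then TF id.

## Signature and connectivity scoring

The repurposing signature collects genes of the kept modules with adjusted
p < 0.05, split by fold-change sign and ordered by decreasing |log2FC|.
Against each perturbation profile (genes ranked by z-score, descending,
ties by gene id) the classic Kolmogorov–Smirnov tag-set statistic is
computed for the up and down sets:
$a = \max_j (j/t - V_j/N)$, $b = \max_j (V_j/N - (j-1)/t)$, ES $= a$ if
$a > b$ else $-b$. The raw connectivity $c = \mathrm{ES}_{up} -
\mathrm{ES}_{down}$ is zeroed when both enrichments share a sign, and
scores are scaled within the screened database (positive values by the
maximum, negative by the absolute minimum), so the extremes are ±1 by
construction and a score ≤ −0.60 flags a candidate reverser. Scaling is
performed within the input database; if only a cell-line subset is
screened, scores are relative to that subset.

A caveat documented by a test: the KS statistic is antisymmetric under
list reversal only away from $a \approx b$ ties ( |a−b| > 2/N ), where
ES + ES(rev) = −1/N exactly; inside the tie band the strict `a > b`
convention can give both orientations the $-b$ branch.

## Feature selection and classification

Three selectors run at k = 100: sequential mRMR in the
difference (MID) form using the package's MI estimator with the binary
phenotype as a 2-level variable; a maximal-information-coefficient ranking
(equipartition one axis, optimize the other axis's cuts by dynamic
programming, over all grids with at most $n^{0.6}$ cells, normalized by
$\log \min(q, r)$, maximized over both orientations — the standard
approximation to the full characteristic-matrix analysis, with an
exhaustive small-grid mode retained for oracle tests); and the
differential-expression ranking. The intersection of the three top-100
lists is the final discriminative signature, mirroring the
triple-intersection logic used for serum-response signatures.

Classification uses stratified 5-fold cross-validation with 10 repeats
(repeat r seeds its fold assignment with `base_seed + r − 1`). The
built-in classifier is an L2-regularized logistic model trained by
gradient descent on training-fold-standardized features; external
classifiers plug in via a two-function `fit`/`score` contract. Feature
importance is estimated by permutation (held-out AUC drop when one
feature's column is shuffled) — a model-agnostic replacement for
game-theoretic attribution that preserves its role of ranking functional
readouts. Ordination is available as PCA (via SVD) and PLS-DA (NIPALS on
unit-scaled features against the centered 0/1 response, with deflation;
the first component is cross-checked against an independent PLS-DA
implementation in the test suite).

## Validation statistics

Cross-cohort overlap uses the one-sided upper-tail hypergeometric test
(enrichment direction), optionally after an |log2FC| > 0.15 filter when
DE tables are supplied. Single-sample GSEA follows the integrated
running-sum convention: genes ranked per sample, in-set increments
proportional to rank-value$^{0.25}$ (normalized within the set),
out-of-set decrements $1/(N - |S|)$, and the enrichment score is the sum
of the running sum over all positions. A set equal to the whole universe
scores 0 by convention (there are no out-of-set positions to integrate
against). Scores are rank-based and therefore invariant to monotone
transforms of each sample's values; no cross-sample normalization is
applied by default.

## Determinism and problem sizes

Every stochastic procedure takes an explicit seed, and the end-to-end
pipeline (`run_pipeline()`) writes byte-identical outputs when re-run with
the same configuration — this is asserted by a test. The test-suite and
acceptance problem sizes were chosen so a complete run takes a few minutes
on one core: the default 2,000-gene cohort for module/trait/driver/
reverser recovery (bootstraps reduced to 20, MI-null permutations to
10,000), a 500-gene cohort with one 30-gene planted module for
feature-selection recovery, and brute-force oracles capped at the sizes
where exhaustive enumeration is exact (graphs ≤ 12 nodes, lists ≤ 8,
universes ≤ 12).

## Known limitations

* The DE stage is a two-group Welch contrast; no covariate adjustment.
* The static-cut-plus-kME module detector is validated on factor-model
  data; strongly nested or overlapping modules would favor the dynamic
  hybrid cut.
* The MI estimator's equal-frequency binning at $n^{1/3}$ bins is biased
  upward for small n; the network stage absorbs this through its
  permutation-calibrated threshold, but absolute MI values should not be
  compared across sample sizes.
* MIC is the grid approximation, not the full characteristic matrix; its
  independent-variable baseline at n ≈ 200 is ≈ 0.2–0.3, which is why it
  is used only as a ranking.
* Connectivity scores are relative to the screened database because of
  the extreme-based scaling; scores from different databases are not
  comparable.
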