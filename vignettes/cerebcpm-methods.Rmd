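---
title: "Methods: connectome-based predictive modeling with cerebcpm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectome-based predictive modeling with cerebcpm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Connectome-based predictive modeling (CPM) asks whether a continuous
behavioural or physiological measure (the *target*, e.g. body mass index
in kg/m²) can be predicted from a subject's functional connectome, and
which connections carry the prediction. `cerebcpm` implements the
protocol for parcellated connectomes restricted to *connections of
interest* (COI) — here, edges with at least one cerebellar endpoint,
i.e. cerebellocerebral and (optionally) cerebellocerebellar
connections — although the same machinery runs on the whole-brain edge
universe via `build_full_mask()`.

The pipeline is:

1. **Connectivity.** From each subject's timepoints × parcels time
   series, estimate a symmetric parcel × parcel matrix: full Pearson
   correlation (the resting-state default), partial correlation, or
   tangent-space connectivity. Tangent space represents each subject's
   Ledoit–Wolf-regularized covariance $\Sigma_i$ as
   $\log\!\big(G^{-1/2}\,\Sigma_i\,G^{-1/2}\big)$ around the group
   reference $G$, the affine-invariant (Karcher) geometric mean of the
   subject covariances. Matrices are vectorized over the COI mask into
   per-subject edge vectors.
2. **Folds.** Subjects are partitioned uniformly at random into $k$
   folds of near-equal size (default $k = 128$; $k = N$ is
   leave-one-out). Before any model building, every training subject
   sharing a family label with a test subject of the current fold is
   removed, so relatives never predict each other.
3. **Edge selection.** In the training set, every edge is correlated
   with the target after the confounds (gender, age, ethnicity by
   default) are regressed out of both edge and target — a partial
   correlation, with $t = r\sqrt{df/(1-r^2)}$, $df = N_{train}-2-q$.
   Edges with $p \le \alpha$ (default $\alpha = 0.05$) split by sign
   into a *positive* and a *negative* network. The threshold is a
   signal-to-noise filter, not an inference; significance is
   established later by permutation.
4. **Model.** Each training subject is summarized by two network
   strengths — the sums of their edge values over the positive and
   negative masks — and the target is fitted by ordinary least squares
   on $[1, S^+, S^-]$. Held-out subjects are predicted from the same
   masks and coefficients; over all folds every subject is predicted
   exactly once, and the run is scored by the Pearson correlation
   $r_{eval}$ of out-of-fold predictions with observations.
5. **Inference.** `permutation_test_cpm()` re-runs the *entire*
   pipeline (including family exclusion) after shuffling the target,
   and reports $p = \#\{r_{null} \ge r_{obs}\}/m$.
6. **Characterization.** Per-fold selections are aggregated by
   `consensus_network()`; nodes are ranked by weighted degree (the sum
   of incident masked edge weights); predictive networks of related
   measures are compared by mask multiplication with a hypergeometric
   overlap test.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 128 | fold count; a middle ground between few-fold instability and leave-one-out cost. Capped at $N$ with a warning on small samples. |
| `alpha` | 0.05 | two-sided edge-selection threshold. No multiple-testing correction here by design: the threshold selects "meaningful" edges, it does not test them. |
| `exclude_related` | `TRUE` | family-aware exclusion (train side only, keeping out-of-fold coverage intact). |
| `residualize_edges` | `TRUE` | regress confounds out of edges as well as target; the alternative (target only, $df = N-2$) is provided. |
| `freq_threshold` | 1.0 | consensus rule: an edge belongs to the reported network if selected in this fraction of folds. 1.0 is the strictest and most common convention; characterization at 0.5 is also exercised throughout the tests. |
| `weight_mode` | `abs_r` | degree weights; absolute mean $r$ keeps positive and negative networks on one scale. `freq` and `unit` are available. |
| geometric mean `tol`, `max_iter` | 1e-7, 50 | Frobenius norm of the mean log at the fixed point; standard and convergent for well-conditioned covariances. |
| permutation `scope` | `global` | whole-sample target shuffle before the full re-run; `within_fold` restricts shuffling to each test population. |
| permutation `estimator` | `proportion` | plain $b/m$; `add_one` gives the $(b+1)/(m+1)$ variant that cannot return 0. |

Other open choices were resolved as follows, as this package's own
conventions:

* **Indexing is 1-based** for parcels, edges and folds, matching R
  semantics end to end; the canonical edge order is the row-major upper
  triangle, diagonal excluded (`edge_index()`, `edge_pairs()`). Readers
  accept 0-based tables with `zero_based = TRUE`.
* **The parcel count is data-driven** — nothing assumes a particular
  atlas size; COI masks are derived from the `group` column of the
  parcellation table alone.
* **Tangent embedding operates on covariances**, not correlations,
  mirroring the behaviour of the standard tooling; the tangent
  reference is fitted on all supplied subjects by default, with the
  leakage-safe alternative (fit on training folds, reuse on test)
  available by calling `tangent_reference()` on the training subset.
  Condition matrices are embedded per condition and then averaged.
* **Prediction uses the combined two-regressor GLM**; a regressor whose
  mask is empty is dropped (coefficient recorded as 0), and a fold with
  both masks empty falls back to the training-mean prediction and is
  flagged.
* **Overlap significance defaults to the hypergeometric tail** over the
  COI edge universe (the overlap test is not dictated by the protocol,
  so outputs are labelled with the method; a permutation mode is
  provided).

## Numerical choices

* Symmetric eigendecompositions back all matrix functions
  (`sqrt`, `log`, `exp` of SPD matrices); near-zero eigenvalues below
  $10^{-10}\lambda_{max}$ are floored with a warning rather than
  failing.
* Ledoit–Wolf shrinkage uses the closed-form single-target estimator
  with the $1/T$ covariance normalization; the intensity is clipped to
  $[0,1]$, which bounds output eigenvalues below by
  $\alpha\,\mathrm{tr}(S)/P > 0$ on non-constant data.
* Constant edges in a training fold get $r = 0$, $p = 1$ (warned), so
  they can never be selected.
* `top_nodes()` takes `ceiling(fraction * group size)` nodes with ties
  broken by ascending parcel id, making every ranking deterministic.
* Every stochastic step (folds, generator, permutations) draws from an
  explicit seed through an RNG-state-preserving wrapper; permutation
  orders are pre-drawn from the master seed before any replicate runs,
  which is what makes results invariant to the `workers` setting.

## The synthetic generator

`generate_dataset()` emulates the study conditions end to end without
any imaging data. Defaults: 300 subjects, 44 parcels (10 cerebellar /
30 cortical / 4 subcortical, hence 385 COI edges), 200 timepoints,
15 positive and 15 negative planted edges, 60 families of 5.

The latent trait $y_i$ is standard normal with a between-family
variance share `family_trait_icc`. Each subject's covariance is
$\Sigma_i = \Sigma_0 + \beta\, y_i \Delta$, where $\Sigma_0$ has unit
variances and 0.1 background coupling, $\Delta$ is the signed indicator
of the planted COI edges, and $\beta$ = `effect_size` (default 0.1 —
planted edge–target correlations around 0.6, comfortably beyond the
selection threshold at $N = 300$, while keeping $\Sigma_i$ positive
definite without material eigenvalue flooring even for traits several
SDs out; the generator rejects specifications whose flooring would move
eigenvalues by more than 10% of $\lambda_{max}$). Time series are drawn
from $\mathcal N(0, \Sigma_i)$ and edges measured as empirical
covariances, so edge noise shrinks as $T$ grows. The observed target
adds a confound channel (latent score expressed as a binary, a
continuous and a 3-level categorical column) and Gaussian measurement
noise.

`family_edge_sd` (default 0.1) adds a per-family random offset to the
measured COI edge vectors, emulating heritable connectome
idiosyncrasies. This channel matters: with trait clustering alone, a
*global* linear model gains almost nothing from relatives in training,
and removing them would be inconsequential. With both channels active
(`family_trait_icc` > 0), spurious family-level edge–target
associations enter the training fit and genuinely transfer to related
test subjects — exactly the leakage that family-aware exclusion
removes, and the tests demonstrate the resulting drop in $r_{eval}$
when exclusion is switched on.

What the generator does *not* emulate: hemodynamic response,
autocorrelated BOLD noise, scanner artefacts, motion, or site effects.
Signal is planted in covariance space, so correlation- or tangent-kind
pipelines see a somewhat attenuated effect. Passing tests on this
generator therefore validate the statistical machinery and its
contracts, not preprocessing robustness on real acquisitions.

## Expected behaviour of selection at the default threshold

At $\alpha = 0.05$ (two-sided), about 2.5% of non-signal COI edges per
sign pass selection in any given training set. Because training sets of
neighbouring folds overlap heavily at large $k$, these false positives
are *persistent* across folds rather than independent, so a consensus
threshold of 0.5 removes few of them: with 355 null edges, roughly 9
per sign survive alongside the 15 planted ones, which puts the expected
Jaccard against truth near $15/24 \approx 0.63$ with substantial
seed-to-seed spread. This is a property of the protocol's selection
rule, not of the implementation; stricter consensus (the 1.0 default),
smaller $\alpha$, or larger samples all sharpen recovery.

## Problem sizes used by the test suite

Unit tests run on 60–150 subjects with a 14-parcel (46-COI-edge)
parcellation. The end-to-end checks use the default 300-subject/
44-parcel conditions for recovery and leakage (20 seeds each, $k = 32$
for the leakage comparison), and 100 effect-free replicates of 200
subjects with $m = 199$ permutations and $k = 5$ for null calibration —
sizes chosen so the full suite completes in minutes on a single core
while keeping every assertion at study-relevant scale.

## Known limitations

* The generator plants a linear trait effect; nonlinear brain–behaviour
  relations are out of scope, as is any learner beyond the two-strength
  GLM (no ridge/SVR, no nested tuning).
* The permutation test assumes exchangeability of subjects under the
  null; with strong family clustering the global shuffle is slightly
  liberal, which is one more reason the exclusion step matters.
* Tangent embedding requires SPD covariances; on short time series this
  is guaranteed only through the Ledoit–Wolf step, which is why the
  tangent pipeline consumes shrunk covariances rather than raw ones.
* CIFTI/NIfTI ingestion is deliberately not part of the core: the
  package consumes delimited time-series tables, and any imaging-format
  adapter should live outside it.
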