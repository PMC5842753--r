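---
title: "pdcnet: methods and design notes"
author: "pdcnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pdcnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`pdcnet` implements a complete analysis chain for classifying subjects by
their directed functional brain connectivity, estimated from multichannel
source-space time series recorded in short artefact-free epochs:

1. **Synthetic cohorts** of three groups (healthy controls and left/right
   temporal-lobe-epilepsy-like patients) whose region-of-interest (ROI)
   signals follow stable multivariate autoregressive (MVAR) processes with
   group-specific directed couplings.
2. **Directed connectivity** per subject via weighted partial directed
   coherence (wPDC), averaged over epochs and reduced to theta/alpha/beta
   band means.
3. **Feature selection** by random-forest permutation importance with
   significance screening, minimal-subset selection capped at one feature
   per ten subjects, and pairwise feature-interaction effects.
4. **Classification** with balanced random forests: a diagnosis stage
   (patients vs controls) and a lateralization stage (left vs right),
   applied sequentially, evaluated by leave-one-out cross-validation
   (LOOCV) with the full selection pipeline repeated inside every fold.

Because the real clinical recordings behind this design are not publicly
available, the package pairs the analysis chain with a generator whose
ground truth is known exactly: wPDC is defined on MVAR processes, so a
cohort simulated from MVAR networks gives the pipeline a known-answer
surface on which edge recovery, selection behaviour and classification
power can be verified quantitatively.

# The synthetic cohort generator

## Network templates

A template is a stable MVAR process over 14 ROIs (left/right hippocampus,
amygdala, parahippocampus, anterior and posterior cingulate, olfactory
cortex, medial temporal pole). Each region carries a damped AR(2)
oscillator with pole radius 0.75 and a pair-specific centre frequency
spaced between 6 and 11 Hz (so temporal structures peak in theta and
cingulate regions in alpha; a seeded jitter of SD 0.3 Hz individualises the
frequencies). Directed lag-1 couplings of strength 0.25 run from the hub
regions (both hippocampi and both anterior cingulates) to their
contralateral homologue and to the same-side members of the three following
region pairs, so **every region receives inflow** — an earlier two-pair
variant left the temporal pole disconnected, which turned its sender-power
weight into a proxy for the epoch's power normalizer and produced an
artifactual dominant feature column.

The assembled control network is rescaled by 0.95 until its companion
spectral radius is below 0.97 (erroring out after 50 attempts), **before**
any group effect is applied, so the three groups share one global scale.
The planted pathology reduces the outflow couplings of the ipsilateral hubs
by the fraction `effectSize`; the left and right patient templates are
exact mirror images. With `effectSize = 0` all three templates are
identical.

## Subjects and epochs

Each subject draws one jittered copy of its group template (i.i.d. Gaussian
jitter, SD = 10% of the base coupling, on the nonzero coefficients only so
the sparsity pattern is preserved; unstable draws are rejected, up to 25
times) and then simulates 60 independent 1-second epochs at 250 Hz with a
burn-in of 10 x order samples per epoch. Innovations are unit-variance
Gaussian; optional additive observation noise is available but defaults to
zero so the recorded process is exactly MVAR and the connectivity ground
truth stays analytic.

The defaults — 35 controls, 20 + 20 patients, 60 x 1 s epochs at 250 Hz,
`effectSize = 0.8` ("strong") — define the reference study the acceptance
checks run. What the generator deliberately does **not** emulate: volume
conduction and inverse-solution leakage, non-stationarity within epochs,
heterogeneous lesion types, artefacts, and inter-subject variability of the
*topology* (only coupling strengths jitter). Passing tests therefore
demonstrate that the pipeline recovers what it claims on data that satisfy
its model assumptions, not that it would reach the same numbers on clinical
recordings.

# Connectivity estimation

Per epoch, an order-5 MVAR model (20 ms of history at 250 Hz; an
information-criterion policy over orders 1..12 is available) is fitted by
ordinary least squares. From the spectral transfer
`Abar(f) = I - sum_r A_r exp(-i 2 pi f r / fs)` the partial directed
coherence from sender *j* to receiver *i* is

```
PDC(i <- j, f) = |Abar(f)[i, j]| / sqrt(sum_k |Abar(f)[k, j]|^2),
```

the column-normalized (sender-normalized) form, whose squared values sum to
one over each sender column — an identity the test suite checks to 1e-9.
Magnitudes (not squares) enter all downstream averages. Self-connections
are retained: the 588-feature count (14 x 14 x 3) requires the full ordered
grid including the diagonal.

**Weighting.** wPDC multiplies each sender column by the sender's
mean-square amplitude in the epoch, normalized by the maximum channel power
(weights in (0, 1]; a mean-power normalization is available via
`normalize = "mean"`). The weighting is deliberately *network-coupled*:
whichever normalization is used, a power change anywhere moves all weights,
so wPDC features carry network-wide power information on top of the
per-edge coupling. That is physiologically the point of the weighting — and
it is why, on planted-edge validations, the wPDC group contrast is strongly
significant but not monotone in effect size, while the unweighted PDC
contrast grows cleanly with the planted coupling change. The edge-recovery
acceptance check asserts significance on wPDC and monotone growth on the
PDC factor for exactly this reason.

Weighted spectra are averaged arithmetically across the 60 epochs on a 1-Hz
grid from 1 to 30 Hz, then reduced to band means over theta [4, 8), alpha
[8, 12) and beta [12, 30). Band intervals are closed-open so every grid
frequency belongs to exactly one band despite the shared printed endpoints.

# Feature selection

## Permutation importance

A balanced random forest (below) is trained on the full 588-column table.
The importance of a feature is the classical permutation importance: the
drop in per-tree out-of-bag (OOB) accuracy when the feature's column is
permuted, averaged over all trees of the forest, and averaged again over
`nRepeats` independent permutations. Only trees that actually split on the
feature are re-evaluated (a C++ traversal kernel over the fitted trees makes
this cheap), so an unused feature has importance exactly zero in every
repeat.

Two earlier designs were rejected by measurement and are worth recording.
*Forest-level* importance (drop in the majority-vote OOB accuracy) is
insensitive on strongly separable cohorts: trees become stumps, any single
feature appears in a handful of the 1000 trees, and no permutation can flip
a majority — every importance collapses to exactly zero. And testing raw
repeat importances against zero is mis-calibrated: all features share the
realized forest's baseline, so under a shuffled-label null about a third of
noise features were flagged at alpha = 0.05. The shipped significance rule
is the classical importance z-score — mean per-tree drop divided by its
across-tree standard error — which measured a 0.065 type-I rate at nominal
0.05 under the shuffled-label null, with full power on planted features.
Features with non-significant importance are removed before subset
selection.

## Minimal subset

Surviving features are ranked by importance (ties break lexicographically)
and nested prefixes (top-1, top-2, ...) up to the cap of
`floor(n_subjects / 10)` features are scored by balanced-forest OOB error.
All prefix forests share one seed (common random numbers), so error
differences reflect the feature sets rather than bootstrap redraws. The
smallest prefix within one binomial standard error of the best prefix
(floored at one misclassification) is kept and then pruned by backward
elimination: a feature is dropped, least important first, when its removal
keeps the error within the same tolerance. A greedy one-at-a-time forward
rule was rejected because it can never admit the first member of a
jointly-informative pair (each member is useless alone); prefix scoring
keeps such pairs, and the backward pass removes redundant duplicates. The
cap uses the cohort size (75 gives 7, 40 gives 4), matching the
one-feature-per-ten-subjects rule at the study level rather than per fold.

## Interaction effects

The interaction of feature r on feature c is the change in c's permutation
importance when r is removed from the design: a forest is retrained without
access to r (importance is forest-dependent, so removal requires
retraining) and c's importance re-measured, averaged over 20 retraining
replicates. Negative entries mean c's information is only useful while r is
present (joint information); entries near zero mean independence. Removal
is implemented by withholding the column rather than permuting it in place:
a permuted column still competes for splits — with M features only
floor(log2(M)) candidates are drawn per split, so at small M many splits
land on the permuted noise — which systematically dilutes every other
feature's importance and would make even independent features look
negatively interacting. Interaction entries are only interpretable relative
to a design the forest can still fit after the removal; with one or two
features the retrained forest degenerates, so interaction panels should
contain the full selected set, as they do in the pipeline.

# Classification

## Balanced random forests

1000 trees per forest; each tree is grown on a balanced with-replacement
bootstrap drawing the minority-class count from both classes (the bootstrap
vectors are generated in package code and handed to `ranger`, so balance is
exact and seeded); `floor(log2(M))` split candidates per node (9 for 588
features). Prediction is by majority vote; vote ties go to the positive
class (patients for diagnosis, left for lateralization). The fraction of
trees voting for the positive class is the continuous score behind the
reported AUC.

## LOOCV and the sequential system

Each subject is held out once; screening, minimal-subset selection and
forest training all run on the remaining subjects only, and the held-out
subject is predicted by the fold's forest. Per-fold selections are recorded
(they differ slightly across folds, as expected from the procedure's
randomness). The three-class system applies the diagnosis stage first; only
subjects diagnosed as patients reach the lateralization stage. In the
cohort evaluation, patients use their lateralization LOOCV fold and
misdiagnosed controls a full-patient lateralization model, and the
resulting 3 x 3 confusion collapses exactly to the diagnosis stage's 2 x 2
table. Metrics are stored at full precision and rendered as percentages
rounded to one decimal only in the reporting layer.

# Numerical and reproducibility choices

* All randomness derives from one master seed per run; stage and fold seeds
  are drawn from it, so two runs of `runPipeline()` with the same
  configuration are byte-identical, and a cohort can be re-simulated
  exactly from its JSON manifest.
* MVAR fits error on rank-deficient regressors rather than silently
  regularizing; order selection compares criteria on a common sample span.
* Stationarity is validated against the discrete Lyapunov equation of the
  companion form (within 10% at 1e5 samples in the tests).
* All on-disk artifacts are plain text; numeric CSVs are written with 17
  significant digits so round trips are lossless.
* Problem sizes in the test suite: the acceptance checks run the full
  35/20/20 x 60-epoch study across five master seeds with 1000-tree
  forests and 20 screening repeats per fold; unit tests use smaller
  cohorts and forests chosen to keep each property sharp.

# Known limitations

* The wPDC weighting makes single-edge contrasts non-monotone in effect
  size (see above); interpret wPDC features as network-level quantities.
* Permutation importance inherits the known masking behaviour among highly
  redundant features: when several features carry the same information, a
  saturated forest can assign some of them low importance.
* The generator's pathology model (reduced hub outflow, mirrored between
  hemispheres) is a modelling choice; the spatial pattern of real epileptic
  networks is richer.
* Interaction effects are first-order only; higher-order interactions
  would require substantially more subjects to estimate stably.
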