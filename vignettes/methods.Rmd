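---
title: "Searchlight RSA of aloud and silent word reading: models, estimation, and inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight RSA of aloud and silent word reading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(readrsa)
```

`readrsa` implements a complete representational similarity analysis (RSA)
pipeline for single-word reading fMRI experiments in which each word is read
either aloud or silently. This vignette is the package's account of the
science: the models, the estimation procedure, the inferential machinery, the
synthetic-data generator used to validate all of it, and the numerical and
design choices made along the way.

## The experimental design being modelled

The pipeline assumes a design of 30 words (6–10 letters), randomly split
15/15 into an *aloud* and a *silent* reading condition per participant, with
the split re-randomised for every participant. Each participant completes 4
functional runs of 100 volumes at TR = 1.8 s. Every run presents each word
exactly once in a fresh random order, at a fixed stimulus onset asynchrony of
6 s — so a run spans 30 × 6 / 1.8 = 100 volumes exactly. Within a trial the
word itself is visible for 2.5 s, starting 1.5 s into the trial (after a
fixation cross and a task cue); only that 2.5 s window is modelled.

## Five hypothesis models

For a given set of words the package builds five representational
dissimilarity matrices (RDMs), each a symmetric, zero-diagonal matrix of
pairwise dissimilarities. Per-condition models are 15 × 15 (105 unique
pairs); exemplar models over all 30 words are 30 × 30 (435 pairs).

* **Visual** — each word is rasterised to a binary silhouette image and
  entry (i, j) is the correlation distance 1 − *r* between vectorised
  silhouettes. Rendering uses a bitmap fixture font defined in source (an
  original 5 × 7 lowercase glyph set), so silhouettes are bit-identical on
  every platform. The canvas (64 × 11 px by default), letter spacing and
  binarisation threshold are parameters of `render_config()`.
* **Orthographic** — correlation distance between *unconstrained open
  bigram* count vectors: every ordered letter pair at any gap is one bigram
  token, so a word of length L contributes L(L−1)/2 tokens. Counts (rather
  than binary presence) are the default because they preserve
  repeated-letter structure; `counts = FALSE` switches to presence coding.
* **Phonological (acoustic)** — from per-speaker MFCC frame sequences. Each
  word's sequence is cut into `k_segments` (default 10) contiguous
  near-equal-count segments, each segment reduced to its mean frame, and two
  words are compared by the mean Euclidean distance between corresponding
  segment means. Distances are computed strictly within speaker, then
  averaged across speakers. The segmentation count is a free parameter of
  the underlying measure; 10 segments makes the measure length-invariant
  while retaining coarse temporal structure.
* **Semantic** — cosine distance 1 − cos between word embedding vectors.
  Embeddings are user-supplied (or synthetic); any fixed dimensionality
  works.
* **Articulatory** — a feature-weighted phonological edit distance:
  dynamic-programming alignment of phonemic transcriptions where
  substituting phoneme *p* for *q* costs the proportion of binary
  articulatory features on which they differ, insertions/deletions cost 1
  (the maximum substitution cost), and the total is divided by the longer
  transcription's length, bounding results in [0, 1]. Both the indel cost
  and the normaliser are explicit arguments; maximum-length normalisation
  was chosen because it is the convention that keeps the measure a true
  length-normalised distance. A 22-phoneme toy feature table ships with the
  package; any phoneme → binary-feature table can be substituted.

`model_independence_report()` screens a model set for mutual independence:
it vectorises each RDM (lower triangle, row-major — the shared convention
throughout the package), correlates every pair of models, and attaches a
correlation Bayes factor treating the n(n−1)/2 cells as observations.
Treating RDM cells as exchangeable observations overstates the effective
sample size (cells sharing an item are dependent), so these Bayes factors
are screening diagnostics, not calibrated tests — which is exactly how the
report is meant to be used.

### Correlation Bayes factors

`correlation_bf()` offers two priors. The default (`prior = "jzs"`) is the
Jeffreys–Zellner–Siow regression-prior Bayes factor for a correlation — the
"default JZS prior" of common Bayes-factor software — computed by adaptive
quadrature of the g-mixture marginal likelihood in log space. The
alternative (`prior = "uniform-rho"`) places a uniform (stretched-beta,
κ = 1) prior directly on ρ and integrates the exact sampling density of the
Pearson correlation, with the Gauss hypergeometric factor evaluated by a
log-space power series. The two agree on direction but differ numerically
(the JZS form is somewhat more conservative for large n); JZS is the
default because it is what the established Bayes-factor implementations
this package's users will have used for the same screening.

## Single-trial pattern estimation

Trial-level activation patterns are estimated by the least-squares-all
(LSA) approach: one GLM per run containing one regressor per trial, fitted
jointly. Each trial regressor is a boxcar over the 2.5 s word presentation
on a 0.1 s grid, convolved with a gamma HRF parameterised by its mean
("lag", 6 s) and standard deviation ("sigma", 3 s) — i.e. shape 4, scale
1.5, mode at 4.5 s — and sampled at volume acquisition times t = i·TR. The
kernel is normalised to unit sum; peak-normalisation would only rescale all
coefficients by a common factor, which the downstream z-scoring absorbs. An
intercept is always included and discarded along with any nuisance columns
(the interface accepts an arbitrary nuisance matrix; motion estimation
itself is out of scope, as is all preprocessing). An optional per-voxel
linear detrend (`detrend = TRUE`, off by default) stands in for the
high-pass filtering that real data would have received.

Item patterns are the voxelwise mean of each word's four trial
coefficients across runs. Finally the *condition-mean pattern* (the mean
across items at every voxel — the "cocktail blank") is subtracted within
each condition separately, leaving per-voxel means at zero (to 1e−9;
the operation is idempotent). Without this step the large pattern component
common to all words dominates every pairwise correlation.

## Searchlight RSA

For every voxel inside the brain mask, the searchlight collects the item
patterns at all mask voxels within a Euclidean radius of 3 voxel units (123
offsets for an interior voxel), computes the neural RDM (1 − Pearson
between item patterns), vectorises it, z-scores it, and regresses it on the
five z-scored model RDM vectors jointly (plus an intercept, harmless under
z-scoring but protective against numerical drift). The five coefficients —
the searchlight βs — are written at the centre voxel, one 3D map per model
per condition per subject.

Edge handling: spheres are truncated at the mask boundary; spheres with
fewer than `min_voxels` members (default 10) are marked invalid (NA), as
are spheres where any item pattern is constant or the RDM vector has zero
variance. Models are z-scored once per subject and condition (they are
subject- and condition-specific because the word allocation is); the neural
vector is z-scored per sphere. βs are invariant to any common rescaling of
the patterns.

## Group inference

Group analysis stacks one model/condition β map across subjects
(complete-case: a voxel missing in any subject is dropped) and computes
voxelwise JZS Bayes factors:

* **within-condition** maps — right-tailed one-sample Bayes *t*-tests of
  β > 0 (is this information decodable in this condition?), 10 maps (5
  models × 2 conditions);
* **between-condition** maps — two-sided paired Bayes *t*-tests of
  β_aloud ≠ β_silent, 5 maps.

The JZS Bayes factor uses a Cauchy prior with scale √2⁄2 on the
standardised effect size, with the one-sided version obtained by truncating
the prior to the positive half-line; both are computed by adaptive
quadrature of the noncentral-*t* likelihood against the prior. The suite
cross-checks the two-sided form against an independent g-mixture quadrature
and verifies the mixture identity BF_two = (BF_right + BF_left)/2.

All maps are thresholded at BF₁₀ ≥ 3.0 (inclusive — the conventional
"moderate evidence" floor), then each between-condition map is split into
two directional contrast maps by the sign of the group mean difference
d = mean(aloud β) − mean(silent β), and each directional map is masked by
the thresholded within-condition map of its *minuend* condition. The
masking matters: it excludes apparent differences driven entirely by
negative β in the subtrahend condition. Ties (d exactly 0, a measure-zero
event) enter neither map, keeping the two outputs disjoint.

Clusters are connected components of surviving voxels under 26-neighbour
connectivity (the convention of the clustering tool whose behaviour this
reproduces; 6-connectivity is a switch), dropped below 20 voxels, and
reported with extent, mean and max BF₁₀, and a BF-weighted centre of
gravity mapped to mm through the volume affine.

## The synthetic-study generator

`make_dataset()` builds complete studies matching the design above, so the
entire pipeline can be validated without any external data. Per study: one
synthetic lexicon (alternating consonant–vowel strings of 6–10 letters,
one-phoneme-per-letter transcriptions over the bundled inventory, iid
N(0, 1) 50-d embeddings, smoothed-Gaussian-process MFCC sequences for two
synthetic speakers); per subject: a random 15/15 allocation, hypothesis
models built by the stimulus-model code itself, ground-truth item patterns,
and 4 simulated runs (signal = LSA design × patterns, plus Gaussian noise,
optionally AR(1)). A single master seed fans out deterministically to every
subject/run/stage.

**Planting.** A `plant_spec()` asks for a region, a model, a condition, and
a target model–neural correlation ρ. Prototype item coordinates come from
classical MDS of the model RDM, are embedded into the region's voxels by a
random linear map, and are mixed with iid noise patterns; the mixing weight
is calibrated by bisection until the achieved correlation (measured by
recomputing the neural RDM from the generated patterns, averaged over 20
noise replicates) is within ±0.05 of target. The calibration tolerance is
on that 20-replicate mean; any single draw scatters more widely (the
achieved value of the returned draw is recorded in the dataset manifest).
The MDS route cannot reach arbitrarily high ρ — correlation-distance
geometry of finite random embeddings reproduces the model geometry only
approximately — so infeasible targets fail loudly, reporting the ceiling.

**Default conditions.** Study defaults mirror the modelled experiment: 26
subjects, 30 words, 4 × 100 volumes at TR 1.8 s. Validation studies in the
test suite run 12 subjects on a 24 × 24 × 16 voxel volume with an
ellipsoidal mask (~3,500 in-mask voxels) and a spherical planted region of
radius 4.5 voxels (~360 voxels) at ρ = 0.5 — large enough that radius-3
searchlights centred in the region's core lie mostly inside it, small
enough that a full 12-subject study runs in about a minute. BOLD noise
defaults to white Gaussian with sd 0.5 against unit-scale patterns; this
keeps single-trial estimation reliability high (~0.9), deliberately, so
that the planted pattern-level correlation — the quantity the generator
calibrates — survives estimation roughly intact. Real single-trial fMRI is
far noisier; the generator makes no claim to physiological noise realism
(no drift, no physiological cycles, no motion), and passing recovery tests
on it demonstrates correctness of the machinery, not sensitivity on real
data.

## What the validation does and does not show

The test suite verifies, among other things: exact agreement between the
searchlight and an independent brute-force per-voxel loop; agreement of
every numerical engine (LSA, RDM regression, both Bayes-factor families)
with independent oracles (normal equations, fine-grid quadrature by
different formulas) to 1e−6; exhaustive-enumeration checks of the
combinatorial primitives (sphere offsets, open bigrams, edit-distance
alignments); and end-to-end recovery of planted geometry (within-condition
evidence covering ≥ 80% of the planted region, an aloud > silent cluster
overlapping it at Dice ≥ 0.5, off-target models below a 10% suprathreshold
rate).

One caveat is worth stating plainly. Searchlight β fields are spatially
smooth by construction — neighbouring spheres share most of their voxels —
so under a pure null the BF ≥ 3 threshold leaves contiguous *blobs*, not
isolated voxels, and a 20-voxel extent filter does not reduce the
family-wise cluster rate to zero: across replicate null studies roughly a
third still yield one or two small directional-contrast clusters. The
evidence-threshold-plus-extent convention is a descriptive reporting rule,
not a calibrated family-wise error control, and the package reports the
measured null behaviour rather than pretending otherwise. Users wanting
strict false-positive guarantees should treat small clusters near the
extent threshold with caution.

## Problem sizes used in the shipped validation

Unit tests run on toy volumes (≤ 10³ voxels) in seconds. The end-to-end
recovery and null checks use the 12-subject, 24 × 24 × 16 study described
above; one such study takes on the order of a minute, and the full
acceptance computation (one planted study plus ten null replicates) runs in
roughly ten to fifteen minutes on a single CPU.
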