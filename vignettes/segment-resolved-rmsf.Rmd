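---
title: "Segment-resolved fluctuation analysis: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segment-resolved fluctuation analysis: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(segrmsf)
```

## The statistic

For an atom $i$ the conventional root-mean-square fluctuation is

$$\mathrm{RMSF}(i) = \sqrt{\frac{1}{N}\sum_{t=1}^{N}
  \lVert \mathbf{r}_i(t) - \langle \mathbf{r}_i \rangle \rVert^2},$$

the RMS deviation from the atom's own ensemble-average position
$\langle\mathbf{r}_i\rangle$ over all $N$ analyzed frames
(`rmsf_classic()`). It compresses an entire ensemble into one curve and
needs a meaningful per-atom mean, which unordered conformer sets may not
have.

The segment-resolved variant computed by `run_ermsf()` partitions the
analyzed frames into contiguous segments of `skip` frames and, within each
segment $s$ containing $N_s$ frames, measures every deviation against one
**fixed** global reference structure $\mathbf{r}_i^{\mathrm{ref}}$:

$$\mathrm{eRMSF}(i,s) = \sqrt{\frac{1}{N_s}\sum_{j=1}^{N_s}
  \lVert \mathbf{r}_{i,j}^{(s)} - \mathbf{r}_i^{\mathrm{ref}} \rVert^2}.$$

Because the baseline never moves, columns of the resulting
groups × segments matrix are mutually comparable: a flat row means a rigid
atom, a step along a row localizes a conformational change in "ensemble
time", and two ensembles analyzed against comparable references can be
read on one color scale (`shared_color_scale()`).

Two exact identities anchor the implementation and are enforced by tests:

* `skip = 1` collapses each entry to the plain Euclidean distance between
  the atom in that frame and the reference;
* a single segment covering all frames with the mean structure as
  reference reproduces the conventional RMSF to machine precision
  (both denominators are the population $N$, never $N-1$).

## Assumptions

* Frames are conformations of the same molecule with identical atom count
  and ordering (enforced at construction; `read_model_set()` offers
  `name_resid_match` to intersect heterogeneous model sets explicitly).
* Global rigid-body motion is noise, not signal: by default every frame is
  superposed onto the reference before deviations are measured. The fit is
  the unweighted Kabsch least-squares superposition (SVD of the
  cross-covariance with the determinant sign correction, so reflections
  are never returned). Users analyzing pre-aligned ensembles, or model
  sets deliberately placed in a common frame, can pass `align = FALSE`.
* Segment membership follows frame order. For model sets without temporal
  meaning this is load order; it is recorded in the provenance so users
  can order inputs deliberately.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| `skip` | frames per segment (controls resolution of the segment axis) | 1 | maximal resolution; 100 frames with `skip = 10` give 10 segments of 10 |
| `reference` | the fixed baseline $\mathbf{r}^{\mathrm{ref}}$ | frame 1 of the analyzed frames | the natural "first frame" convention; `"mean"` and external structures supported |
| `selection` | analyzed atoms | `"protein"` | the common case; Cα-only (`"name CA"`) is the conventional per-residue representative |
| `group_by` | reporting level | `"residue"` | matches how flexibility is read in practice |
| `align` | remove rigid-body motion | `TRUE` | fluctuation statistics are meaningless under global drift |
| `remainder_policy` | trailing frames when `skip` does not divide the frame count | `keep_partial` | discarding data silently is worse than an uneven final column; the short segment's own $N_s$ normalizes it |
| `start`/`stop`/`step` | frame slicing, 1-based inclusive | all frames | R convention (`seq()`); segmentation counts post-stride frames, i.e. `skip` operates on the analyzed frame list |

All coordinates are Angstrom throughout; XTC input (nanometres by format
convention) is converted on read by the MDAnalysis engine the XTC path
delegates to, and DCD is assumed Angstrom.

## Design choices where the method itself is silent

**Pooling rule.** Residue and region values are the *root of the
unweighted mean of the member atoms' mean squared deviations* — squared
deviations are pooled before the root. The alternative (averaging per-atom
RMSF values) was rejected because it breaks the collapse identity between
the two statistics and no longer has an RMS interpretation.

**Reference for `mean_structure` alignment.** The mean depends on the
alignment and vice versa, so a two-pass scheme is used: align onto frame
1, form the mean, realign onto that mean. Tests verify the scheme is
stable (a further pass changes coordinates by < 1e-6 Å on the scales
exercised).

**Average profile.** Two definitions of the per-residue summary curve are
both legitimate: the arithmetic mean across segment columns
(`mean_of_segments`) and the conventional RMSF over all analyzed frames
pooled with the same rule (`classic_rmsf`). Both are available
(`average_mode`); the default is `classic_rmsf` when the reference is the
mean structure (the two then agree exactly for one segment) and
`mean_of_segments` otherwise.

**Indexing.** All APIs are 1-based with inclusive `start`/`stop`, the host
R convention.

**Degenerate inputs.** Fewer than 3 fit atoms, or a collinear fit set
(rank of the centered coordinate matrix < 2, tested via singular values at
a 1e-10 relative tolerance), raise a degenerate-fit error rather than
returning an arbitrary rotation. A `drop_partial` segmentation that would
produce zero segments errors out. An all-equal matrix gets a degenerate
color-scale guard band of 1e-6 Å so rendering never divides by zero.
Bicubic smoothing of a 1×1 matrix falls back to no interpolation with a
warning.

**Smoothing is presentation-only.** The optional bicubic interpolation of
the heatmap (separable cubic splines, 8× upsampling, overshoot clipped
into the legend range) affects rendering exclusively; every figure is
accompanied by a sidecar TSV holding the raw matrix, and tests assert the
matrix bytes are identical before and after rendering.

## What the synthetic generators emulate — and what they do not

`make_gaussian_ensemble()` adds independent isotropic Gaussian jitter of
per-residue scale $\sigma$ (Å per coordinate) to a fixed reference chain.
Since $E\lVert\Delta\rVert^2 = 3\sigma^2$, the eRMSF of such an ensemble
converges to $\sigma\sqrt{3}$ as segments grow — a sharp quantitative
target the tests check at 2% with $10^4$ frames per segment.
`make_transition_ensemble()` emulates a two-state trajectory: states A and
B separated by a known displacement on a known residue range, switching
after `round(switch_fraction * n_frames)` frames (half-up rounding), with
the true switch frame recorded in the provenance.

These generators validate the *statistic*, which is per-atom: jitter is
uncorrelated across atoms and frames, there is no correlated
(normal-mode-like) motion, no solvent, no force field, and the reference
chain is an idealized zigzag, not a folded protein. Passing tests
therefore demonstrate correctness of the computation and its equivariances
(rigid-motion invariance, permutation invariance within segments,
collapse identities) — they do not demonstrate anything about the
biological realism of fluctuations in real ensembles.

A note on the Gaussian-recovery setup: the recovery test measures
deviations against the noiseless generating reference with alignment off.
Superposing $n$ atoms removes six rigid-body degrees of freedom from
$3n$, deflating the measured fluctuation by a factor of roughly
$\sqrt{1 - 6/(3n)}$ — a property of superposition itself, not an
implementation artifact, and visible in any aligned analysis of small
systems.

## Problem sizes used in the checks

The validation suite runs on deliberately small instances chosen to make
their expected behavior exactly computable: random ensembles of ≤ 10 atoms
and ≤ 30 frames for the oracle comparisons (100 instances), 50 seeds for
rigid-motion invariance, a 60-residue/100-frame two-state ensemble for
transition localization, and a 10-residue chain with two segments of
$10^4$ frames for the $\sigma\sqrt{3}$ recovery. The independent oracles
are plain triple loops written straight from the definitions plus a
quaternion characteristic-polynomial superposition, sharing no code with
the implementation.

## Known limitations

* No mass weighting of fits or fluctuations, and no per-frame weights.
* Covariance/cross-correlation analysis and PCA of fluctuations are out of
  scope; the result object exposes the matrix for downstream tools.
* The model-set path reads PDB only (no mmCIF); trajectory formats are
  PDB, DCD and XTC, the XTC path requiring a `python` interpreter with
  MDAnalysis on the PATH.
* Reconciling model sets that differ in protonation or missing loops is
  the user's decision via `atom_matching`; the package intersects or
  rejects, it never imputes coordinates.
* For unordered model sets the segment axis reflects input order, which is
  only as meaningful as that ordering.
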