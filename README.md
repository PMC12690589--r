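# segrmsf

Segment-resolved, fixed-reference root-mean-square-fluctuation (eRMSF)
analysis of structural ensembles in R.

## The problem

The conventional RMSF of an atom *i*,

```
RMSF(i) = sqrt( (1/N) * Σ_t || r_i(t) − ⟨r_i⟩ ||² )
```

averages the squared deviation from the atom's own mean position ⟨r_i⟩
over all *N* frames of a trajectory. It is a single curve per ensemble: it
tells you *which* regions are flexible, but not *when* fluctuations arise
along a trajectory, and it is ill-defined for ensembles that have no
temporal order at all — conformer sets from structure-prediction models,
multi-model NMR files, or pooled snapshots from different sources.

The segment-resolved eRMSF addresses both limitations. The analyzed frames
are partitioned into contiguous segments of `skip` frames each, and within
every segment *s* each atom's fluctuation is measured against one **fixed
global reference structure** r_iᵣₑᶠ instead of the drifting ensemble mean:

```
eRMSF(i, s) = sqrt( (1/N_s) * Σ_j || r_i,j(s) − r_i_ref ||² )
```

where N_s is the number of frames in segment *s* and r_i,j(s) is atom *i*
in frame *j* of that segment. Because every segment is compared against the
same baseline, the resulting residues × segments matrix is directly
comparable across segments and across ensembles from different sources,
and a conformational transition shows up as a step change along the
segment axis. With `skip = 1` every frame is its own segment (maximal
resolution); with one segment covering all frames and the mean structure
as the reference, eRMSF collapses exactly to the conventional RMSF.

The package is aimed at computational structural biologists comparing
flexibility across molecular-dynamics trajectories, AI-generated conformer
ensembles, and experimental multi-model structures.

## What the package provides

* `structure_ensemble()` — frames × atoms coordinate container with
  per-atom metadata; loaders `read_trajectory_ensemble()` (topology +
  PDB/DCD/XTC trajectories) and `read_model_set()` (sets of PDB files,
  strict or name/resid-matched atom ordering).
* `select_atoms()` — the familiar selection mini-language (`"protein"`,
  `"name CA"`, `"resid 10-50 and not name O"`, ...).
* `kabsch_fit()` / `align_ensemble()` — least-squares superposition
  (SVD with determinant sign correction) removing global rigid-body motion.
* `run_ermsf()` — the full pipeline: slice → align → segment →
  fixed-reference fluctuation → residue/region pooling → average profile.
  Results are tidyverse-friendly: `tidy()`, `glance()`, `autoplot()`
  (heatmap with optional presentation-only bicubic smoothing),
  `plot_profile()`, `shared_color_scale()` for same-scale comparisons.
* Writers: `write_result_table()` (wide/long TSV), `write_ensemble_pdb()`
  (multi-model PDB), `write_bfactor_pdb()` (structure colored by
  fluctuation through the temperature-factor column).
* Seeded synthetic generators (`make_reference_peptide()`,
  `make_gaussian_ensemble()`, `make_transition_ensemble()`) producing
  ensembles with known fluctuation structure, used throughout the tests.
* A command-line front end: `ermsf_cli()` plus the launcher script
  installed at `system.file("scripts", "segrmsf", package = "segrmsf")`,
  with `run` and `fixtures` subcommands.

## Worked example: localizing a conformational transition

A synthetic 60-residue ensemble in which residues 30–45 jump by 8 Å after
40% of the 100 frames (noise 0.3 Å), analyzed with `skip = 10`:

```r
library(segrmsf)

ref <- make_reference_peptide(60)
ens <- make_transition_ensemble(ref, displaced_residues = 30:45,
                                displacement = 8, switch_fraction = 0.4,
                                noise_sigma = 0.3, n_frames = 100, seed = 7)
res <- run_ermsf(ens, selection = "name CA", reference = 1, skip = 10)
res
#> <ermsf_result> 60 residue group(s) x 10 segment(s)
#>   frames analyzed: 100 (skip = 10), selection: 'name CA' (60 atoms)
#>   reference: frame_index (frame 1), alignment: on
#>   eRMSF range: [0.4, 6.505] Angstrom; average profile mode: mean_of_segments

round(colMeans(res$matrix[res$groups$resid %in% 30:45, ]), 2)
#>  segment_1  segment_2  segment_3  segment_4  segment_5  segment_6  segment_7
#>       0.71       0.72       0.77       0.72       5.88       5.92       5.85
#>  segment_8  segment_9 segment_10
#>       5.88       5.90       5.90
```

The displaced region's mean eRMSF stays near the noise floor (~0.7 Å,
segments 1–4, frames 1–40) and jumps in segment 5 — exactly the segment
containing the true switch frame (41) — remaining elevated thereafter. The
post-switch level (~5.9 Å) is below the raw 8 Å displacement because the
global superposition of each frame onto the reference absorbs part of a
sub-region displacement into the rigid-body fit. A conventional RMSF curve
would show *that* residues 30–45 are mobile, but not *when* the change
happens.

Visual and file outputs:

```r
autoplot(res, interpolation = "bicubic")        # residues x segments heatmap
plot_profile(res)                               # average per-residue profile
write_result_table(res, "ermsf.tsv")
write_bfactor_pdb(ens, bfactor_values(res, ens), "colored.pdb")
```

Or from a shell:

```sh
segrmsf run --topology top.pdb --trajectory traj.dcd --select "name CA" \
  --skip 10 --table ermsf.tsv --heatmap map.png --profile profile.png
```

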