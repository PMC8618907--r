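---
title: "Methods: cavity scanning, boron probes, pose filtering and folding analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cavity scanning, boron probes, pose filtering and folding analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bdascan)
library(dplyr)
```

## The problem

Boron Neutron Capture Therapy needs carriers that place many ¹⁰B atoms
selectively in tumour cells. Replacing selected aromatic residues of a
therapeutic antibody with a boronated analogue (4-borono-L-phenylalanine-like;
the `BPA` residue, a tyrosine whose OH is replaced by B(OH)₂) turns the
antibody itself into the carrier — provided the substitution neither unfolds
the protein nor touches the antigen-binding interface. `bdascan` screens a
structure for substitutable Phe, Tyr, Trp and His residues and evaluates the
substitution's structural consequences.

The screen rests on a geometric idea: truncate every residue of one type to
Gly (and, separately, Ala), leaving vacated side-chain volumes ("cavities"),
then ask whether a small boronic-acid fragment probe docks back *into* the
cavity, *re-occupying* it with the boron pointing the way the native
side-chain terminus pointed. A residue whose cavity accepts a well-oriented,
clash-free, well-scored probe is a boronation candidate.

## Cavity scanning

`protected_residues()` excludes the binding interface by a heavy-atom
distance criterion: any scan-protein residue with a heavy atom within
`cutoff` (default **8.0 Å**) of any receptor heavy atom is protected. The
interface of an antibody–antigen complex is usually drawn as a box around
the CDR loops; a distance rule generalises that box to arbitrary complexes
and is reproducible. Explicit residue lists are accepted wherever an
exclusion set is taken, for users who prefer a published epitope definition.

`truncate_residue()` keeps exactly {N, CA, C, O} for the Gly target and
additionally CB (at its original position) for Ala. No rebuilding or
minimisation follows: the probes are docked into the raw vacated volume, so
the cavity geometry is exactly the native side-chain's. Mutations of one
residue type are applied simultaneously in one structure
(`build_cavity_scan`), giving the classical eight scan structures (4 types ×
Gly/Ala); scanning one residue at a time is available by passing an
exclusion set containing everything else.

## Boron chemistry

Docking engines in common use do not parameterise boron, so each probe's
boron is **typed as carbon** in the exported PDBQT while the true element is
kept in the probe metadata and flagged in a `REMARK`. Probe geometry is
ideal: aromatic rings at 1.39 Å, a flat cyclopentane template at 1.54 Å
(the ring pucker is irrelevant at the resolution of a rigid fragment dock),
and the boronic group placed from `boron_geometry()`:

| parameter | default | meaning |
|---|---|---|
| `b_c_length` | 1.56 Å | B–C(aryl) bond |
| `b_o_length` | 1.36 Å | B–O bond |
| `o_h_length` | 0.96 Å | O–H bond |
| `c_b_o_angle`, `o_b_o_angle` | 120° | sp² boron, planar |

These are standard experimental arylboronic-acid values; every one is
overridable so the package can track any preferred literature set, and
construction is exact — built bonds match the configuration to numerical
precision rather than being fitted. The boronic acid is modelled neutral and
trigonal (the anionic tetrahedral boronate form becomes relevant only well
above physiological pH).

Partial charges are shipped as editable CSV tables
(`inst/extdata/*.csv`) computed once with the Gasteiger method, with
non-polar hydrogens merged into their parent carbons (united-atom docking
convention). Charge models from dedicated tools can be substituted by
passing a different table.

`build_bpa()` performs the substitution on a native tyrosine: OH (and HH) is
removed, B is placed along the CZ→OH direction, and the two oxygens are laid
in the aromatic ring plane at the configured angles. The operation is local
by construction — every retained atom has exactly zero displacement — so a
boronated structure differs from the native only at the boronic group.
`export_residue_template()` writes the residue record as JSON, as
prepin-like text with N/C link atoms marked for chain continuation, or as
frcmod-like bond/angle stubs covering the three bond classes a standard
force field lacks (C–B, B–O, boronic O–H).

## Docking

`dock()` is a contract with three engines. The external adapter shells out
to any AutoDock-Vina-compatible binary with the conventional flags
(`--center_*`, `--size_*`, `--energy_range 4`, `num_modes` 20 by default, a
fixed seed logged for best-effort reproducibility) after stripping waters
and ions from the receptor. The *replay* engine re-reads saved multi-model
PDBQT poses, so a published docking run can be re-filtered exactly.

The *built-in* engine exists so the whole pipeline can be exercised and
tested without an external binary. It is deliberately simple and fully
specified: exhaustive rigid placement on a cubic lattice crossed with a
fixed deterministic rotation set, scored as −1 per receptor heavy atom in a
3.0–4.5 Å contact shell of any probe heavy atom and +10 per atom closer
than 2.5 Å. Ties break by lattice order; there is no randomness. It is a
test scaffold with a brute-force oracle (every emitted pose is re-scored
independently in the tests), not a physics engine, and its scores are
"contact scores", not kcal/mol.

## Pose filtering

Each pose is judged on four criteria (`evaluate_and_rank`):

* **Cavity assignment** — the pose heavy-atom centroid must lie within
  `r_cavity` (default **5.0 Å**) of a vacated side-chain centroid;
* **Reference-carbon distance** — distance between the native attachment
  carbon (CZ for Phe/Tyr) and the probe ipso carbon C1, at most `d_max`
  (default **2.0 Å**);
* **Directionality** — the angle between the residue vector (default
  CB→CZ; CG→CZ selectable, as both conventions appear in practice) and the
  probe's ring→boron vector, at most `theta_max` (default **60°**). A pose
  at 180° occupies the cavity backwards, pointing boron at the backbone;
  such poses are rejected with reason `"directionality"`;
* **Clashes** — no (probe, receptor) heavy-atom pair closer than
  `overlap_factor` (default **0.6**) times the sum of van der Waals radii.

The numeric thresholds are package defaults chosen to accept only poses
that genuinely re-occupy the vacated volume with the boron oriented like
the native terminus; all four are configuration-exposed. The verdict is a
pure function of the measured quantities, so permuting input poses changes
nothing, and tightening any threshold can only convert accepts to rejects —
both properties are tested. Per-residue-type vector mappings cover
Trp (CB→CZ2) and His (CB→ the NE2/CE1 midpoint, approximating the outward
imidazole direction). Note that a site can carry both a geometric rejection
(e.g. opposite directionality) and a favourable affinity; the report keeps
the verdict and the reasons side by side and leaves reconciliation to the
analyst.

## Folding analytics

The trajectory module implements the wild-type-versus-mutant comparison from
scratch on multi-model PDB or XYZ input:

* `kabsch()` — least-squares superposition via SVD with reflection
  correction; tested against a brute-force rotation-grid oracle
  (coarse-to-fine Euler sweep ending at 2° — valid as an upper bound since
  Kabsch is optimal) and against an independent implementation.
* `rmsd_series()` / `rmsf()` — the RMSF superposes frames on the iterated
  mean structure (two passes) so rigid-body drift does not inflate
  fluctuations. On i.i.d. Gaussian-noise trajectories both recover the
  closed form σ√3; the tests assert this within 5% at the sizes where the
  estimator variance supports it (≥500 atoms for per-frame RMSD, ≥500
  frames for RMSF).
* `find_hbonds()` — geometric detection at donor–acceptor ≤ **3.0 Å** and
  D–H···A ≥ **135°** (common MD-analysis defaults; boronic O–H donates,
  its oxygens accept). A heavy-atom mode for hydrogen-free trajectories
  uses the distance cutoff plus an opening-angle check at the donor and
  reports each unordered pair once.
* `hbond_conservation()` — partner residues of the mutated site with
  ≥10% frame occupancy, compared as sets; conservation is the retained
  fraction of wild-type partners.
* `cluster_trajectory()` — GROMOS-style leader clustering on pairwise
  Kabsch RMSD (default cutoff **1.5 Å** on CA atoms), chosen because it is
  deterministic, has a one-line brute-force oracle (exhaustive neighbour
  counting), and reports medoid representatives and populations directly
  comparable to standard MD-package cluster output.

`compare_trajectories()` assembles the report; `glance()` reduces it to one
row (mean/σ RMSD per series, Δ, mean hydrogen-bond counts, top-cluster
populations, representative-pair RMSD, site conservation).

## Synthetic data: what it does and does not show

The generators produce *geometric* fixtures, not physical ones: ideal
backbones (helix φ/ψ −57/−47, extended −139/135), template side chains, no
energies, no solvent. Their value is exact ground truth: the noise model
makes σ√3 the true RMSF; the two-state generator knows every frame label;
the hydrogen-bond fixture knows every planted triad (d = 2.8 Å, angle 170°,
decoys ≥6 Å away), making precision/recall exactly assessable.

Two-state frames are allocated to states in exact proportion to the
requested populations, with a seeded permutation setting their order. With
Bernoulli sampling at 200 frames the sampling noise alone (sd ≈ 0.032)
would exceed the ±0.02 recovery band, so exact allocation is what makes the
cluster-recovery test a test of the clustering rather than of the sampler.

Passing these tests shows the analytics and the pipeline plumbing are
correct; it does not show that real antibody trajectories are well described
— anisotropic correlated motion, solvent effects and force-field limitations
are outside what synthetic fixtures can probe. Conversely, the full-scale
figures for a real Fab (tens of cavities per residue type, docking scores in
the −6…−4 kcal/mol range, ~100 ns MD with hundreds of hydrogen bonds) need
the real PDB entries, an external docking engine and an MD package, which
the package deliberately treats as user-supplied inputs.

## Numerical and design notes

* Sizes used by the shipped tests and acceptance script: 200–500-atom
  peptides, 25–500 frames, 200-frame clustering — chosen so every check
  runs deterministically in seconds at desk scale.
* Altloc policy: highest occupancy wins, ties by altloc letter; downstream
  geometry then sees a single conformer.
* Hydrogens present in input files are kept, but all geometric selections
  default to heavy atoms; protonation is the job of external preparation
  tools.
* Residue numbering follows the input file verbatim (author numbering); no
  renumbering is ever applied, so sites are addressable as `"chain:resnum"`.
* Solvent stripping removes HOH/WAT and single-atom residues only; unknown
  polymer residues pass through untouched.
* Collinear point sets and sub-3-point selections are rejected by
  `kabsch()` rather than silently regularised; zero-length reference
  vectors in the pose filter are errors, not 0° angles.
* Leader-clustering ties (equal neighbour counts) resolve to the lowest
  frame index, making cluster output byte-stable across runs.
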