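# bdascan

Identify antibody residues that can carry boron for Boron Neutron Capture
Therapy (BNCT) without disturbing folding or target binding.

BNCT kills cells that have accumulated ¹⁰B when the boron captures a thermal
neutron; the therapeutic problem is getting enough boron selectively into
tumour cells. One route is a *boron delivery antibody*: a therapeutic
monoclonal antibody (e.g. an anti-EGFR Fab) in which selected aromatic
residues are replaced by a boronated analogue such as 4-borono-L-phenylalanine
(here the non-standard residue **BPA** — a tyrosine whose hydroxyl is replaced
by B(OH)₂). The question `bdascan` answers is: *which* Phe/Tyr/Trp/His
residues tolerate that substitution?

The package implements the full in-silico screening pipeline:

1. **Cavity scanning** (`build_cavity_scan`) — every Phe/Tyr/Trp/His outside a
   protected binding interface (`protected_residues`) is truncated to Gly and,
   separately, to Ala (`truncate_residue`), producing eight scan structures
   whose vacated side-chain volumes are docking cavities.
2. **Fragment probes** (`build_probe`) — phenylboronic acid, *p*-toluene
   boronic acid and cyclopentylboronic acid built from ideal geometry with
   literature boron bond parameters (`boron_geometry`); the boron is typed as
   carbon for docking (`export_probe_pdbqt`), since docking engines do not
   parameterise boron.
3. **Docking** (`dock`) — a common engine contract with an external
   AutoDock-Vina-compatible adapter, a deterministic built-in grid-scan
   engine for desk-scale testing, and a replay engine over saved poses
   (`parse_vina_pdbqt`).
4. **Pose filtering** (`evaluate_and_rank`) — each pose is assigned to its
   nearest cavity, measured for reference-carbon distance and for the
   *directionality angle* between the native side-chain vector (CB→CZ) and
   the probe's ring→boron vector, and checked for steric clashes; accepted
   poses yield per-site champions.
5. **Boronation** (`build_bpa`, `export_residue_template`) — candidate
   tyrosines are rebuilt as BPA with exact configured geometry, and residue
   templates (JSON / prepin-like / frcmod-like) are exported for MD
   parameterisation.
6. **Folding evaluation** (`compare_trajectories`) — wild-type vs mutant MD
   trajectories (multi-model PDB or XYZ) are compared with Kabsch-superposed
   RMSD series, per-residue RMSF, geometric hydrogen-bond detection and
   conservation, and GROMOS-style leader clustering with population
   reporting.

Synthetic generators (`make_structure`, `make_noisy_trajectory`,
`make_two_state_trajectory`, `make_hbond_fixture`) produce structures and
trajectories with known ground truth, so every stage is testable offline.

All user-facing functions take a data frame (an "atom table") first and
return tibbles, so steps chain with the pipe; report objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(bdascan)
library(dplyr)

# a synthetic peptide with two scannable tyrosines
pep  <- make_structure("GAYAGAYAG")
scan <- build_cavity_scan(pep, "TYR", "GLY")
scan
#> <bda_cavity_scan> TYR -> GLY: 2 sites

probe <- build_probe("phenylboronic_acid")
probe
#> <bda_probe> phenylboronic_acid: 9 heavy atoms, ligand vector C4->B

cen   <- as.numeric(scan$sites[1, c("centroid_x", "centroid_y", "centroid_z")])
poses <- dock(scan$structure, probe, grid_box(cen, c(8, 8, 8)),
              engine = "builtin")
ideal <- superpose_probe_on_residue(probe, filter(pep, resnum == 3))
poses <- bind_rows(poses,
                   tibble::tibble(probe_name = probe$name, mode_rank = 99L,
                                  affinity = -5.6, coords = list(ideal)))

ev <- evaluate_and_rank(poses, scan$sites, scan$structure, pep, probe)
glance(ev)
#> # A tibble: 1 × 5
#>   n_poses n_accepted n_sites_hit n_champions best_affinity
#>     <int>      <int>       <int>       <int>         <dbl>
#> 1      21          1           1           1          -5.6
```

The ideal re-occupying pose is accepted (distance ≈ 0 Å to the native CZ,
directionality angle ≈ 0°, no clashes) and becomes the site champion at
−5.6 kcal/mol; the exhaustive grid-scan poses of the toy engine fill the
cavity but sit too far from the reference carbon and are rejected with their
reasons recorded. The accepted site can then be boronated:

```r
bpa <- build_bpa(filter(pep, resnum == 3))
unique(bpa$resname)
#> [1] "BPA"
```

A thin command-line wrapper over these functions is installed at
`system.file("scripts", "bdascan", package = "bdascan")` with subcommands
`io-strip`, `scan`, `build-bpa`, `dock`, `filter-poses`, `analyze-md` and
`fixtures`.

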