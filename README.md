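# dynsite

Dynamic active-site mapping from conformational ensembles, developed
around the type-3 dicopper centre of human tyrosinase (Tyr).

Tyrosinase oxidises four chemically distinct melanogenic intermediates —
L-tyrosine, L-DOPA, DHICA, and DHI — at a single CuA/CuB active site, and
missense variants at its substrate-interacting residues cause
oculocutaneous albinism type 1. Understanding both facts requires
*dynamic* descriptors over conformational ensembles rather than a single
structure. `dynsite` is the analysis toolkit for that kind of study,
aimed at structural bioinformaticians working with multi-MODEL PDB
ensembles, docked ligand poses, and variant tables.

## What it computes

Per-residue descriptors over an ensemble (all on Kabsch-superposed
frames, Cα fit):

- **per-residue RMSD** — heavy-atom deviation from the reference at 1 ns
  analysis ticks, with per-interval series and time averages;
- **RMSF** — `RMSF_i = sqrt(⟨|r_i(t) − ⟨r_i⟩|²⟩)`;
- **DCCM** — `C_ij = ⟨Δr_i·Δr_j⟩ / sqrt(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)`, with a
  documented per-residue coupling-score reduction (mean correlation to a
  partner set, excluding self);
- **contacts** — heavy-atom pairs within 5.0 Å excluding covalent
  neighbours;
- **SASA** — Shrake–Rupley quadrature, 1.4 Å probe, deterministic
  golden-spiral layout, plus a side-chain **exposure ratio** against
  embedded random-coil (Gly-X-Gly) reference areas;
- **secondary structure** — Kabsch–Sander-style H-bond energies
  (`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond at
  `E < −0.5`) assigning {H, G, E, T, C}, with state fractions over the
  ensemble.

Ligand-facing operations: hydrogen-bond / hydrophobic / π-stacking
detection with the study's relaxed geometric criteria, docking-pose
validity against the dicopper site (oxygen within 4.0 Å of CuA/CuB *and*
oriented toward the site), greedy energy-ranked pose clustering at 5.0 Å
RMSD, bound-state classification over trajectories, and interaction-set
algebra splitting residues into **universal**, **substrate-specific**,
and shared groups.

Mutation-impact analytics: Δ-metrics with stabilization labels
(RMSD/RMSF/SASA up = destabilising; contacts/DCCM down = destabilising),
per-variant perturbation summaries, pooled-variance Student's t-tests on
per-interval RMSD, UMS/foldability normalisations, conservation tallies,
and a **group disruption score**: sign-adjusted relative changes averaged
across metrics → variants → residues → groups, reported as the ratio of
an anchoring region (K334, E345, F347) to the 374–386 gating loop.

Synthetic-data generators with exact ground truth (correlated Gaussian
ensembles, ideal helices/sheets, a toy dicopper site, bound/escaping
ligand trajectories, variant panels) make every stage testable without
external trajectories; curated machine-readable reference sets for the
tyrosinase active site (the 23-residue interaction list, the universal
triad H367/F347/S375, per-substrate specific residues, the ClinVar
missense list) ship with the package.

## Worked example

```r
library(dynsite)

refs <- tyr_reference_sets()
cls <- classify_universal_specific(
  interaction_map_from_sets(tyr_substrate_sets("full")))
length(cls$union)        # 23  residues in the interaction set
cls$universal            # "F347" "H367" "S375"  (the universal triad)
cls$specific$DHICA       # "R196"  (electrostatic recruitment of the
                         #          carboxylated substrate)

# disruption scoring on a 25-variant synthetic panel with 10% noise
panel <- gen_variant_panel(variant_panel_spec(
  refs$interacting_residues, refs$groups,
  c(anchoring_334_347 = 0.34, gating_374_386 = 0.20),
  noise_cv = 0.10, n_variants = 25, seed = 1))
disruption_score(panel$deltas, refs$groups)
#> <DisruptionReport: 25 variants; group scores anchoring_334_347=0.3384,
#>  gating_374_386=0.2; ratio 1.69>

# DCCM recovery of a prescribed correlation block
helix <- gen_ideal_structure("alpha_helix", 30)
sds <- rep(0.05, 30); sds[10:17] <- 0.4
ens <- gen_gaussian_ensemble(helix, fluctuation_spec(
  sds, blocks = list(list(residues = 10:17, rho = 0.8)),
  n_frames = 1500, seed = 1))
anchors <- selection_spec(resseq = setdiff(1:30, 10:17), atoms = "CA",
                          hetero = FALSE)
C <- dccm(ens, fit_selection = anchors)$matrix
mean(C[10:17, 10:17][upper.tri(diag(8))])
#> 0.799   (prescribed 0.8)
```

The disruption ratio of 1.69 is the panel's recovered anchoring/gating
susceptibility contrast (1.7 by construction before noise); the DCCM
block mean shows the estimator recovering the generator's prescribed
correlation. `run_metrics()`, `run_map()`, `run_delta()`,
`run_disrupt()`, and `run_simulate()` chain these stages and write
TSV/JSON reports whose headers embed every cutoff, stride, and seed
used; a thin command-line wrapper ships in `inst/cli/dynsite.R`.

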