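---
title: "Dynamic active-site mapping: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic active-site mapping: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynsite)
```

## The problem this package addresses

Human tyrosinase (Tyr) is the copper-dependent enzyme that initiates
melanin biosynthesis, oxidising a series of chemically distinct
intermediates — L-tyrosine, L-DOPA, DHICA, and DHI — at a single type-3
dicopper site (CuA/CuB, each coordinated by three histidines). How one
active site accommodates substrates that differ in charge, polarity, and
redox character, and how disease-associated missense variants (the cause
of oculocutaneous albinism type 1) disturb that accommodation, are
questions about *dynamics*: loop flexibility, correlated motions, contact
networks, and solvent exposure over conformational ensembles, not about a
single static structure.

`dynsite` implements the analysis layer for this kind of study as a
reusable toolkit: per-residue structural and dynamic descriptors over
conformational ensembles, geometric detection of ligand–protein
interactions around a dicopper centre, docking-pose triage, interaction-set
algebra separating *universal* from *substrate-specific* recognition
residues, and mutation-impact analytics culminating in a group-level
disruption score. Because trajectory data of this kind are rarely
deposited, the package ships first-class synthetic-ensemble generators
with known ground truth, so every stage is testable end to end.

The package deliberately does **not** perform homology modelling,
glycosylation, docking searches, quantum optimisation of the copper
cluster, or force-field dynamics; it consumes structures, ensembles,
poses, and precomputed stability scores (UMS, foldability) and analyses
them.

## Data model and the frame-time convention

A `Structure` is an ordered atom table; residues are grouped by
`(chain, author residue number, insertion code)` in atom order, and all
reporting uses author numbering so labels match the literature (H180 …
H390). An `Ensemble` couples a reference topology (t = 0) with coordinate
frames at strictly increasing times in ns.

Saved snapshots begin at `t = stride`: the t = 0 reference is the
topology, not a frame. A 20 ns run saved every 0.25 ns therefore carries
**80 frames** (0.25 … 20 ns); counting the reference gives the
alternative "81 snapshots" bookkeeping sometimes seen for the same
protocol, which is why the package fixes the convention explicitly rather
than leaving it implicit. Analysis-frame sampling places ticks at
multiples of the analysis stride (default 1 ns) and maps each tick to the
nearest saved frame, ties resolved toward the earlier frame; 20 ns at
0.25 ns stride analysed at 1 ns yields exactly 20 analysis frames.

PDB reading and writing are delegated to `bio3d` behind this surface;
alternate locations keep the highest-occupancy conformer (ties by altloc
letter), giving a deterministic single-conformer model. Coordinates are
Angstrom throughout.

## Per-residue descriptors

All metrics operate on globally superposed frames (closed-form Kabsch SVD
superposition on Calpha atoms), which makes every descriptor invariant
under rigid transforms of any frame.

**Per-residue RMSD.** At each analysis frame the system is superposed on
the reference using Calpha atoms, then each residue's *heavy-atom* RMSD
to the reference is computed; the per-interval series and its time
average are both reported. Heavy atoms (rather than Calpha only) are used
for the deviation because side-chain remodelling is exactly the signal of
interest in loop-gating regions; the alignment, by contrast, should not
be dragged by it.

**RMSF.** `RMSF_i = sqrt(mean_t |r_i(t) − <r_i>|²)` on superposed frames,
averaged over the residue's selected atoms. For isotropic per-coordinate
Gaussian displacement of standard deviation σ the expected RMSF is
σ·√3, which the generator-based tests recover within 5% at 2000 frames.

**DCCM.** `C_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)` over one atom
per residue (Calpha by default). The matrix is symmetric with unit
diagonal and entries in [−1, 1]. Residues with zero variance get `NA`
off-diagonals — never 0, because 0 would falsely assert "uncorrelated".

*Superposition fit set.* Both RMSF and DCCM accept a `fit_selection`.
Fitting on all Calpha atoms is the default, but when a large fraction of
the system moves coherently, the least-squares fit absorbs part of that
collective motion and aliases it into apparent anti-correlation — a
well-known artefact of DCCM analysis. The estimator-recovery checks in
the test suite therefore superpose on the quasi-rigid anchor residues of
the generated ensembles, which is the design a practitioner would choose
when a stable core is known. With that design the two-block generator
(ρ = 0.8 intra-block, 0 inter-block) is recovered within ±0.05 at 5000
frames.

*Per-residue DCCM score.* Published figures often show one DCCM value per
residue without defining the reduction. The package's documented
reduction is the mean correlation of the residue to a partner set
(typically the active-site interaction set), excluding self; averaging
over all residues is available by passing the full residue list.

**Contacts.** Heavy-atom pairs (a, b) with a in the residue, b outside
it, within 5.0 Å (inclusive), excluding covalent neighbours — the
peptide C–N link between adjacent residues and any inter-residue pair
below 1.7 Å. Counting is atom-pair-based; partner-residue counting is
available via `mode = "partners"` because the upstream convention behind
published contact numbers is ambiguous.

**SASA.** Shrake–Rupley quadrature with a 1.4 Å probe on a deterministic
golden-spiral layout of 960 points per atom (4000-point settings agree
with the two-sphere spherical-cap closed form within 0.05%). The embedded
van der Waals radii are C 1.7, N 1.55, O 1.52, S 1.8, Cu 1.4 Å;
hydrogens are ignored by default (heavy-atom model).

**Exposure ratio.** Side-chain SASA divided by a per-residue-type
random-coil reference area, ×100, unclamped (a clamped display variant
exists). The reference areas are computed by the package itself from
extended Gly-X-Gly tripeptides built with its idealised geometry and
cached per (probe, quadrature) setting. They are therefore *synthetic*
reference areas, self-consistent with the package's SASA engine: an
isolated extended side chain evaluates to ~100% by construction. Glycine
uses its Calpha as the side-chain proxy.

**Secondary structure.** A Kabsch–Sander-style assignment on backbone
hydrogen bonds: `E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)`
kcal/mol, bond when `E < −0.5`. Two consecutive n-turns at offset 4 give
α-helix (H), at offset 3 a 3₁₀-helix (G); bridge patterns give strand
(E); isolated turns T; else coil (C); priority H > G > E > T > C. Amide
hydrogens are inferred geometrically (1.01 Å along the direction opposed
to the bisector of N→C(prev) and N→CA) when absent, enabling assignment
on heavy-atom-only files. Residues with missing backbone atoms are
labelled C and recorded in a warnings attribute. This is deliberately not
a full DSSP reimplementation: π-helices, bends, and chirality classes are
out of scope, and the five states match the ensemble-fraction reporting
the analyses need.

## Ligand interactions and pose triage

**Hydrogen bonds.** The upstream protocol specifies only a relaxation
("0.4 Å tolerance, 20° angle cutoff") of unstated baselines. The package
documents its baselines — donor–acceptor distance 3.0 Å, D–H–A angle
140° — relaxed to 3.4 Å / 120° by those tolerances; both are
configurable. Boundaries are inclusive wherever the protocol prints ≤/≥.
When a donor hydrogen is neither present nor inferable (side-chain donors
in heavy-atom files), the distance criterion alone applies — standard
practice for heavy-atom structures and recorded per bond by the `angle`
field being `NA`.

**Hydrophobic contacts** are apolar–apolar (C/S) pairs within 5.0 Å;
each residue is reported once per frame with its minimum distance.
**π-stacking** uses ring centroids within 5.0 Å and inter-plane angles:
≤ 30° parallel, 60–90° T-shaped (plane angles folded to [0, 90]).

**Ligand chemistry** comes from embedded idealised templates for the four
melanogenic substrates (codes `LTY`, `LDO`, `DHC`, `DHI`): planar ring
systems with annotated aromatic rings, hydroxyl/carbonyl oxygens, donors
and acceptors. No general-purpose chemical perception is attempted;
unknown ligands fall back to an element heuristic.

**Pose validity** mirrors the catalytic-geometry rule: some
hydroxyl/carbonyl oxygen within 4.0 Å (inclusive) of CuA or CuB, *and*
oriented toward the site — the ring-centroid→oxygen vector must have
positive projection onto the centroid→copper-midpoint vector.
**Clustering** is greedy and energy-ranked: the best-energy unassigned
pose seeds a cluster and absorbs poses within 5.0 Å ligand heavy-atom
RMSD (no re-superposition; the receptor frame is common), matching
docking practice.

**Bound-state classification** over an ensemble requires the criterion to
hold at *every* analysis frame. The protocol's "≤ 4.0 Å deviation" is
ambiguous between an O–Cu distance and a positional deviation of the
ligand; both are implemented, the O–Cu distance reading is the default,
and the criterion used is recorded in every report. On single-frame
ensembles the classifier and the pose validator agree by construction.

**Interaction maps.** A residue enters a substrate's set when it has
qualifying records in more than `min_persistence` of the analysis frames.
The default is 0 (any frame) because the mapped interaction sets include
residues engaged only transiently; persistence fractions are always
reported so stricter thresholds are reproducible. Copper-coordinating
histidines can be force-included by an explicit allow-list (H211 and H390
in the curated tyrosinase sets, which are part of the catalytic
architecture without binding substrates directly). Universal residues are
those engaged by all substrates, specific residues by exactly one, and
the remainder carry their substrate-combination signature; the three
classes partition the union exactly.

## Mutation-impact analytics

**Δ-metrics** are per-residue differences (system B − A) for RMSD, RMSF,
SASA, contacts, and the DCCM score; missing metrics propagate as `NA`,
never zero. The sign convention for stabilisation follows the structural
reading: increases in RMSD/RMSF/SASA destabilise; decreases in contacts
and DCCM destabilise (loss of packing and of coupling). A neutral band of
1% of the wild-type value (absolute 1e-9 when the wild-type value is 0)
prevents floating-point dust from being labelled as signal.

**Disruption score.** The cross-metric average needs commensuration,
since the metrics carry different units. Each Δ is sign-adjusted so
positive means destabilising, then divided by the wild-type magnitude of
that metric for that residue (relative change); when a wild-type value is
0 the fallback is a z-score across the residue universe. The resulting
dimensionless magnitudes are averaged across metrics per residue per
variant, then across variants per residue, then across residues per
group; the ratio of the two group scores is reported. This scheme is
scale-invariant (scaling all magnitudes by a positive constant leaves the
ratio unchanged) and order-invariant, both property-tested. The default
groups are the curated anchoring region (K334, E345, F347; residues
334–347) and gating loop (M374, S375, Q376, V377, G379, S380, F386;
residues 374–386).

**Significance testing** uses the pooled-variance two-sample Student's t
(the named test of the upstream protocol; Welch's form is available
behind a flag) on per-interval RMSD series, with conventional stars
(p < 0.05 `*`, < 0.01 `**`, < 0.001 `***`). Zero pooled variance with
equal means returns t = 0, p = 1; with unequal means the infinite-t case
is flagged rather than hidden. UMS values in [0, 1] normalise to percent;
foldability is expressed against a reference maximum of 19. Conservation
classes are per-ungapped-reference-position: identical across all rows →
conserved across distant species; else identical across the
vertebrate-tagged rows → vertebrate-conserved; else not conserved; gaps
and ambiguity codes break identity (conservative calls).

## What the generators emulate — and what they do not

`gen_gaussian_ensemble` draws correlated multivariate-normal Calpha
displacements (per-coordinate standard deviations, block correlation
structure validated as positive semidefinite), with side-chain atoms
following their residue's Calpha rigidly. This is the simplest model for
which RMSF and DCCM ground truth are exact, which is the point: estimator
recovery can be checked against prescribed values. It is *not* molecular
dynamics — there is no force field, no water, no kinetics, and no
anharmonicity.

`gen_ideal_structure` builds backbone geometry from canonical internal
coordinates (α: φ = −57°, ψ = −47°; 3₁₀: −49°/−26°; strand:
−139°/135°) with standard peptide bond lengths and angles (verified to
0.02 Å), optionally with simplified idealised side chains (real PDB atom
names, standard bond lengths, extended placements; not rotamer-accurate).
The antiparallel-sheet builder places the partner strand by a
deterministic grid search over rigid offsets maximising the inter-strand
backbone hydrogen-bond count — a placement optimisation, not a
simulation.

`gen_toy_active_site` arranges two coppers 3.5 Å apart with three
histidine-like residues each (coordinating nitrogen at 2.1 Å) and a
bridging O₂ placeholder, numbered after the tyrosinase coordinating
histidines. `gen_ligand_trajectory` docks a substrate template with its
qualifying oxygen 3.2 Å from CuA, collinear with the Cu–Cu axis, so that
escape-mode drift produces an *exactly* linear O–Cu distance and the
4.0 Å crossing has a closed form. Bound-mode jitter displacements are
Gaussian with the requested standard deviation but resampled to stay
within twice that value, so the generator's "bound" label is guaranteed
true for jitter ≤ 0.4 Å — a generator's mode labels must be ground
truth, or classifier accuracy cannot be scored against them.

`gen_variant_panel` moves mutant metric values away from wild-type
baselines in the destabilising direction by `effect_size ×
lognormal(CV)` relative magnitudes (lognormal keeps magnitudes positive,
mean 1). With group effect sizes 0.34 and 0.20 and no noise the
disruption-score ratio is 1.7 exactly by construction; with CV = 10%
across 25 variants the recovered ratio stays within [1.5, 1.9] in ≥95 of
100 seeds. Passing these tests demonstrates that the *analysis chain*
recovers prescribed effects; it says nothing about whether real
trajectories would show those effects.

All generators are bit-reproducible given a seed, and every generated
file embeds its seed and parameters (header comments or a JSON sidecar).

## Numerical choices and degenerate inputs

- Kabsch superposition rejects fewer than 3 fit points or collinear fit
  sets (second singular value below 1e-8) rather than returning an
  ill-conditioned rotation.
- Quadrature defaults: 960 points per atom for routine SASA, 4000 where
  closed-form agreement is being measured; the golden-spiral layout is
  deterministic, so SASA values are exactly reproducible.
- Analysis tie-breaks: ticks equidistant between two saved frames take
  the earlier frame.
- Problem sizes used by the test and acceptance runs — 5000 frames for
  DCCM recovery, 2000 for RMSF, 40-residue helices, 20 trajectories per
  bound/escape mode, 100 seeds for the noisy disruption panel — were
  chosen to put estimator standard errors comfortably inside the stated
  tolerances while keeping a full run in the minutes range on one CPU.
- Single-frame ensembles: RMSF and DCCM are undefined and error
  explicitly (`dynsite_undefined_fluctuation_error`) rather than
  returning zeros.

## Known limitations

- The secondary-structure assigner is a five-state simplification of
  DSSP; π-helix, bend, and bridge-chirality classes are not assigned.
- Side-chain geometry in generated structures is idealised; exposure
  reference areas are self-consistent with the package's SASA engine but
  are not the GetArea reference values, so absolute exposure percentages
  from other software will differ systematically.
- Ligand chemistry is template-based for the four melanogenic substrates;
  arbitrary ligands receive only an element-level fallback.
- Periodic-boundary imaging is assumed already resolved; ensembles must
  be whole and imaged.
- No multiple-testing correction is applied to per-residue t-tests,
  matching the upstream protocol's reporting.
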