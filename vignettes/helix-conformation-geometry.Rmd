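---
title: "Geometry of closed and open helix conformations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of closed and open helix conformations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(helixstates)
```

This vignette is the package's own account of its methods: the geometric
model behind each measurement, the thresholds and conventions with their
defaults and reasons, what the synthetic generator does and does not
emulate, and the numerical choices made where the design was genuinely
open.

## The scientific setting

Membrane receptors of the adiponectin-receptor family crystallise in a
*closed* and an *open* state that differ mainly in one mobile unit: helix
IV, intracellular loop 2 (ICL2) and helix V. Helix V is usefully divided
into an N-terminal stretch (NT), two middle stretches (M1, M2) and a
C-terminal stretch (CT); the conformational switch is concentrated in M2,
which trades the α-helical i→i+4 hydrogen-bond ladder for a 3₁₀-helical
i→i+3 ladder, bends, and stretches. Everything this package measures —
hydrogen-bond geometry, helical class, bend, advance, superposition
displacement, altloc occupancies — exists to make that switch quantitative
and reproducible on any structure, deposited or synthetic.

## Hydrogen-bond model

X-ray models at typical membrane-protein resolution have no experimental
hydrogens, so amide hydrogens are always rebuilt and never read: H sits
1.00 Å from N, in the C(i−1)–N–Cα plane, opposite the bisector of the
N→C(i−1) and N→Cα unit vectors. Proline (no amide hydrogen), chain starts
and chain breaks (C(i−1)⋯N(i) ≥ 2 Å) get none.

A CO(i)⋯HN(j) candidate at helical offset j−i ∈ {3, 4} is scored by two
numbers and judged by two thresholds (`geometry_config()`):

| parameter | default | meaning |
|---|---|---|
| `hbond_max_ON` | 3.5 Å | maximal O⋯N distance (applied to the 1-decimal rounded value) |
| `hbond_min_angle` | 130° | minimal O⋯H–N angle at the hydrogen (180° = linear) |
| `weak_band` | 3.2–3.5 Å | rounded distances flagged as weak bonds |
| `NH_length` | 1.00 Å | rebuilt N–H bond length |
| `contact_cutoff` | 4.0 Å | heavy-atom residue-contact cutoff (inclusive) |
| `coordination_cutoff` | 2.6 Å | metal coordination cutoff |

Two conventions deserve emphasis. First, the angle is measured **at the
hydrogen**: rejected candidates in real structures sit at 102–125°, values
that only make sense in the at-H convention (an at-N angle could never be
that small for a near-contact pair). Second, the distance threshold is
applied to the rounded value because published hydrogen-bond tables quote
one decimal and count 3.5 Å pairs as bonds; `round_distances = FALSE`
switches to the raw value.

In an ideal α-helix the i+4 candidate bonds (2.90 Å, 163°) and the i+3
candidate is rejected purely by angle (3.09 Å but 107°); in an ideal
3₁₀-helix the i+3 candidate bonds (2.70 Å, 171°) and the i+4 candidate is
far (4.77 Å). The discrimination between the two helical classes therefore
hinges on the 130° angle criterion, not on distance.

Classification follows participation: a residue appearing (as acceptor or
donor) only in offset-4 bonds is `alpha`, only in offset-3 bonds
`three10`; when both occur, the bond with the shorter O⋯N distance decides
(ties go to `alpha`, the more common geometry — the mixed case has no
published convention); no bonds at all gives `turn_or_none`.

## Dihedrals, axes, bend, advance

Dihedrals are IUPAC-signed (the sign convention is pinned to
`bio3d::torsion.xyz` in the test suite); ω of residue i refers to the
peptide bond preceding i. Chain breaks yield `NA`, never errors.

The helix axis over a residue range is estimated by *quadruplet-midpoint
smoothing*: running averages of four consecutive Cα positions nearly
cancel the helical wobble, and a total-least-squares line is fitted
through them. On short segments the midpoints still trace a faint helix
(~0.1 of the Cα radius), which biases the fitted direction by over a
degree on a 10-residue segment; a second averaging pass over the midpoints
cancels this residual and brings segment axes of an ideal helix parallel
to within ~0.6°. The axis is oriented along the range as given (a reversed
range gives the antiparallel axis), and with exactly four Cα atoms the
line is fitted to the raw positions. Since no published axis convention
exists for the bend and tilt angles quoted in structure papers (~18°,
~20°), figure-derived angles are treated as reproducible only to a few
degrees; the generator cross-check (below) recovers constructed kinks to
better than 0.5°.

The *advance* is defined as the straight-line Cα(i)→Cα(i+span) distance,
not an axial projection — the simplest definition consistent with the
standard benchmark of 10.5 Å over 7 α-helical residues. It is not monotone
in span below one turn (span 2 → 3 genuinely dips, 5.39 → 5.04 Å, because
residue i+3 returns above residue i); from span 3 on the axial rise
dominates and monotonicity holds.

## Superposition and displacement

`kabsch_fit()` minimises RMSD over proper rotations via SVD with the
determinant correction; reflections are excluded by construction, and
collinear point sets are rejected rather than silently fitted. Chains are
paired by author residue number over residues modeled in both. Because the
published displacement values ("~11 Å", "13.5 Å", "3.6 Å") depend on the
fit frame and no frame is stated, `atom_displacement()` defaults to
fitting on all common Cα **excluding** the mobile region (residues
250–288 in the default region scheme): displacements of the moving unit
are then measured in the frame of the static body. Whole-chain RMSDs use
all common Cα; the residue-set ambiguity of published values is absorbed
by a ±0.05 Å comparison tolerance, not by tuning the pairing.

## Dual-conformer models

`split_conformers()` turns an altloc-bearing model into complete
single-conformer structures: blank-altloc atoms are shared, each output
takes exactly one label, occupancies of formerly-labelled atoms are reset
to 1, and a residue modeled only under other labels is an error (silently
dropping it would corrupt RMSDs downstream). Which label is which physical
state is *not* assumed — depositions do not guarantee a convention — but
resolved at run time by `compare_dual_model()`, which assigns each split
conformer to its nearest reference by whole-chain CA RMSD; the assignment
is invariant under reference ordering. `conformer_occupancies()` reports
per-label mean occupancies over a range to 2 decimals, matching the
precision at which mixtures (e.g. 44:56) are published.

## The synthetic generator

`make_ideal_helix()` builds N, Cα, C, O by sequential internal-coordinate
placement (NeRF): each atom is placed from the previous three by a bond
length, bond angle and torsion. Bond lengths and the angles at C and N are
standard library values (N–Cα 1.458, Cα–C 1.525, C–N 1.329, C=O 1.231 Å;
Cα–C–N 116.2°, C–N–Cα 121.7°, Cα–C–O 120.8°); the carbonyl oxygen lies in
the peptide plane trans to the next nitrogen.

The angle at Cα deserves its own paragraph, because it is the one place
where two "standard" choices disagree measurably. With the modern
refinement-library value N–Cα–C = 111.2°, an exact (φ, ψ) = (−57°, −47°)
helix has a rise of 1.575 Å per residue and a 7-residue advance of
10.95 Å — not the canonical 1.5 Å and 10.5 Å of the textbook α-helix. The
canonical values are a consequence of the classical construction, which
used a tetrahedral carbon; with N–Cα–C = 109.5° the same dihedrals give a
1.52 Å rise and a 10.55 Å advance (10.5 at one decimal), while leaving
every hydrogen-bond verdict unchanged. Since the generator's stated
purpose is to make the standard α-helix — and its 10.5 Å advance — *emerge*
from the construction rather than be painted on, the builder uses the
tetrahedral angle at Cα. This is a deliberate, documented choice, not a
fitted parameter: it was made by computing the τ-dependence of the rise
once, before any test asserted the value.

Determinism and noise: `set.seed(seed)` is applied on every build; zero
noise is exact (dihedrals round-trip to 10⁻³°, verified against `bio3d`),
and `noise_sigma` adds independent Gaussian noise of that σ to every
coordinate. Kinked helices rotate everything C-terminal of the kink
residue (plus that residue's carbonyl group, so no bond stretches) about
an axis through its Cα perpendicular to the pre-kink helix axis — because
the axis is perpendicular, the inter-axis angle equals the requested kink
exactly, making the construction a calibration-free ground truth for bend
estimators. Dual-conformer files displace the B copy perpendicular to the
helix axis; metal-site toys place nitrogens on exact tetrahedral
directions.

What the generator does **not** emulate, and what passing tests therefore
do not show: real side chains (poly-Ala only; contacts on synthetic models
are backbone-level), sequence-dependent dihedral variation along a helix,
correlated coordinate error (crystallographic error is neither isotropic
nor independent), solvent and lipids, and crystal packing. Tests on
generated helices validate the *geometry pipeline*; conclusions about a
real receptor still require the deposited entries, which the analysis
functions accept unchanged.

## Noise margins of the classification

The discrimination margin is asymmetric. An ideal 3₁₀-helix is far from
every decision boundary (its offset-3 bond is 2.70 Å / 171°, its offset-4
candidate 4.8 Å away), and noisy realizations classify essentially
perfectly. The ideal α-helix, however, holds its offset-3 rejection by the
angle margin alone (107° against the 130° threshold, with the rejected
candidate's distance *shorter* than the accepted bond's); at σ = 0.1 Å
per coordinate the rebuilt-hydrogen angle jitters by several degrees and
occasionally crosses the threshold, whereupon the shorter-distance
tie-break mislabels the residue `three10`. At that noise level a small
percentage of α-helix residues misclassify — an intrinsic property of the
published criteria under coordinate noise, reproduced and quantified by
the acceptance suite rather than hidden by loosening a threshold. Below
σ ≈ 0.06 Å the misclassification rate is negligible.

## Region scheme and open conventions

The default region scheme (`region_scheme()`) resolves one documented
inconsistency in the published partition of helix V: the NT range is
quoted both as 264–276 and as ending at 267. The package defaults to the
non-overlapping partition NT 264–267 / M1 268–272 / M2 273–280 /
CT 281–288, which tiles helix V exactly and matches the interaction
narrative (NT tied to helices III/VI in the closed form, M1 to helices
III/IV in the open form); every range is user-overridable.

## Orchestration and problem sizes

`analyze()` runs the full pipeline per chain and across chains and emits a
JSON report (`write_analysis_report()`; layout in
`inst/extdata/report-schema.json`). Its conformational-state call uses the
offset-3 bond count over the M2 acceptors as a proxy: ≥ 3 bonds is
closed-like, ≤ 1 open-like — the same count that separates the closed
molecules (4 and 3 bonds) from the open one (1 bond) in the deposited
reference structures. Stage failures are recorded in place and do not
abort the report; two runs on the same input differ only in the
provenance timestamp.

The test suite exercises helices of 10–30 residues, 5-atom superposition
toys against a rotation-grid brute force, and 1000-seed noise ensembles —
sizes chosen so the geometry is fully exposed while the whole suite runs
in about a minute.

## Known limitations

* Secondary-structure assignment is pattern-based (distance + angle); no
  DSSP energy function, no bifurcated bonds, no side-chain donors or
  acceptors.
* The helix-axis method is one defensible choice among several; published
  bend/tilt angles from other software agree only to a few degrees.
* Sequence is bookkeeping in the generator: proline is honoured by the
  hydrogen builder, but φ/ψ preferences are not enforced.
* mmCIF support covers the `atom_site` category (coordinates, altlocs,
  occupancies), not reflections, assemblies or symmetry.
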