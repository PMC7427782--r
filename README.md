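# helixstates

Geometric analysis of closed and open transmembrane-helix conformations in
crystallographic receptor structures.

## The problem

The human adiponectin receptor AdipoR1 crystallises with its seven
transmembrane helices in two conformational states. The states differ almost
entirely in one mobile unit — helix IV, intracellular loop 2 (ICL2) and
helix V — and the switch is legible in plain backbone geometry:

* In the **closed** form the middle (M2) stretch of helix V
  (Gly273–Val280) abandons the α-helical i→i+4 hydrogen-bond ladder for a
  3₁₀-helical i→i+3 ladder held by a few weak bonds, and the helix bends
  inward; in the **open** form the same stretch is nearly straight and the
  3₁₀ bonding all but vanishes.
* Between the forms, the cytoplasmic ends of helices IV and V shift by
  ~3.6 and ~11 Å and ICL2 is repositioned by up to 13.5 Å.
* The wild-type crystal is not one state but a refined **44:56 mixture** of
  both, deposited as an alternate-location (altloc) dual-conformer model.

`helixstates` implements every measurement in that chain of reasoning as a
reusable, testable R package, for structural biologists who want to apply
the same diagnostics to their own multi-state models.

## What it computes

* **Main-chain hydrogen-bond geometry** (`build_amide_hydrogens`,
  `scan_helical_hbonds`, `count_bonds`): amide hydrogens are rebuilt from
  heavy atoms (X-ray models carry none), and every CO(i)⋯HN(i+3) and
  CO(i)⋯HN(i+4) candidate is scored by the O⋯N distance *d* and the
  O⋯H–N angle θ at the hydrogen. A bond requires *d* ≤ 3.5 Å (on the
  1-decimal rounded value) and θ ≥ 130°; bonds with *d* in 3.2–3.5 Å are
  flagged weak. Proline donors never bond.
* **Helical classification** (`classify_helix`): per residue,
  participation in i→i+4 bonds only ⇒ `alpha`, i→i+3 only ⇒ `three10`,
  both ⇒ the shorter-distance bond decides, neither ⇒ `turn_or_none`.
* **Backbone dihedrals, helix axes, bend and advance**
  (`backbone_dihedrals`, `helix_axis`, `interaxis_angle`,
  `helical_advance`): IUPAC (φ, ψ, ω); axes by quadruplet-midpoint
  smoothing plus a total-least-squares line; the *advance* is the
  straight-line Cα(i)→Cα(i+span) distance (10.5 Å over 7 residues in the
  standard α-helix, 14 Å in an ideal 3₁₀-helix).
* **Superposition and displacement** (`kabsch_fit`, `chain_rmsd`,
  `atom_displacement`, `region_superpose_deviation`): SVD-based Kabsch
  fits restricted to proper rotations (reflections are never fitted), CA
  pairing by author residue number, and displacement measured after a fit
  on the static body (mobile region excluded).
* **Dual-conformer handling** (`split_conformers`,
  `conformer_occupancies`, `compare_dual_model`): lossless altloc
  splitting into complete single-conformer models, occupancy bookkeeping,
  and run-time assignment of each conformer to its nearest reference state.
* **Contacts and metal sites** (`residue_contacts`,
  `coordination_sphere`): minimal heavy-atom distances per residue pair and
  metal coordination spheres (e.g. the receptor's His₃-coordinated zinc).
* **Synthetic ground truth** (`make_ideal_helix`, `make_kinked_helix`,
  `make_dual_conformer_file`, `make_metal_site`): ideal α/3₁₀ backbones
  from internal coordinates, helices kinked by a known angle, altloc files
  with known occupancies and displacements — so every stage is testable
  without downloading a single structure.
* **Orchestration** (`analyze`, `write_analysis_report`): one call runs
  hydrogens → bond scan → classification → dihedrals/axes/advance →
  RMSD/displacements → coordination and emits a JSON report (schema in
  `inst/extdata/report-schema.json`).

Structures are read and written in PDB and mmCIF (via `read_structure` /
`write_structure`, with altlocs and occupancies preserved; parsing is
delegated to `bio3d`).

## Worked example

```r
library(helixstates)

helix <- make_ideal_helix(helix_spec(12))          # ideal alpha, 12 residues
ch <- get_chain(helix)
helical_advance(ch, 3, 7)
#> [1] 10.5

scan_helical_hbonds(ch, 4:6)[, c("i","j","offset","d_ON","angle_OHN","is_bond")]
#>   i  j offset d_ON angle_OHN is_bond
#> 1 4  7      3 3.09       107   FALSE
#> 2 4  8      4 2.90       163    TRUE
#> 3 5  8      3 3.09       107   FALSE
#> 4 5  9      4 2.90       163    TRUE
#> 5 6  9      3 3.09       107   FALSE
#> 6 6 10      4 2.90       163    TRUE
```

The i+4 partners bond (2.90 Å, 163°); the i+3 candidates are rejected by
the at-hydrogen angle (107° < 130°) — the same criterion that terminates
the 3₁₀ stretch of AdipoR1 helix V at Gly273. The 3₁₀ geometry flips both
verdicts and stretches the helix:

```r
m2 <- make_ideal_helix(helix_spec(12, phi = -49, psi = -26))
helical_advance(get_chain(m2), 3, 7)
#> [1] 14
classify_helix(get_chain(m2), 5:8)$label
#> [1] "three10" "three10" "three10" "three10"
```

Bend recovery and dual-conformer round trip:

```r
kk <- make_kinked_helix(helix_spec(20, kink_residue = 10, kink_angle = 18))
interaxis_angle(helix_axis(get_chain(kk), 1:10),
                helix_axis(get_chain(kk), 11:20))
#> [1] 17.6

du <- make_dual_conformer_file(helix_spec(20), 8:14, displacement = 11,
                               occupancies = c(0.44, 0.56))
conformer_occupancies(du, 8:14)
#>    A    B
#> 0.44 0.56
sp <- split_conformers(du)
compare_dual_model(du, references = list(closed = sp$A, open = sp$B))$assignment
#>        A        B
#> "closed"   "open"
```

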