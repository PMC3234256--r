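---
title: "Catalytic site prediction by spatial and electrostatic congruence"
author: "clasp developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catalytic site prediction by spatial and electrostatic congruence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

Enzymatic function is carried by a small number of catalytic residues whose
side chains adopt a tight, recurrent three-dimensional arrangement — the
Ser–His–Asp triad of serine proteases, or the Ser70/Lys73/Ser130/Lys234
constellation of class A β-lactamases. `clasp` detects candidate catalytic
sites in a query structure in two stages:

1. **Spatial congruence.** An ordered *motif* of 3–5 sites is taken from a
   reference structure. Each site names a *stereochemical group* (the residue
   types allowed to fill it, e.g. Lys-like = {Lys, Arg, His}) and a single
   *reactive atom* per residue type (Ser OG, Lys NZ, His NE2, …). All residue
   tuples of the query whose types satisfy the groups and whose pairwise
   reactive-atom distances lie within a cutoff and within a per-pair
   tolerance of the motif's reference distances are enumerated exhaustively.
2. **Electrostatic congruence.** For each spatial match, the electrostatic
   potential difference (PD) between every residue pair, in units of kT/e,
   is compared with the reference motif's PDs. Within an enzyme family these
   PDs fall in a narrow band, so candidates whose PDs deviate strongly are
   penalized — this is what prunes geometric look-alikes (the classic
   example being a calcium-binding lysozyme whose four residues match a
   β-lactamase motif to within 1 Å yet deviate by up to 229 kT/e in PD).

The combined score of a match is

$$S = w_d \sum_{i<j} \frac{|d^q_{ij} - d^r_{ij}|}{d^r_{ij}}
    + w_p \sum_{i<j} \frac{|P^q_{ij} - P^r_{ij}|}
                          {\max(|P^r_{ij}|,\, P_\mathrm{floor})},$$

with two refinements on the PD sum: a pair contributes nothing when both
$|P^q|$ and $|P^r|$ lie inside an ignore band $\varepsilon_0$ around zero
(near-zero PDs carry no signal, e.g. the charge-neutral Ser70/Ser130 pair),
and the denominator is floored at $P_\mathrm{floor}$ so that small reference
PDs constrain loosely rather than infinitely. Distance deviations are
normalized by the reference distance: a 1 Å deviation over a 4 Å pair counts
twice as much as over an 8 Å pair. Lower scores are better; probing a motif
in its own reference structure gives exactly $S = 0$.

The literature behind this method reports score *orderings* (which motif
ranks first in a scan, which structures outrank others), not a closed-form
score, so absolute published score values are not comparable across
implementations; orderings and the zero self-score are. All ranking
behaviour in this package is therefore asserted on orderings.

Pair bookkeeping uses one fixed convention throughout: pairs are ordered
lexicographically (i, j) with i < j over motif site index, and each PD is
$\phi(\text{site } i) - \phi(\text{site } j)$. Permuting the input site
order permutes the reference vectors consistently, so downstream scores do
not depend on how the user lists the residues.

## The electrostatic model

Potentials come from a finite-difference solution of the variable-dielectric
Poisson equation — the zero-ionic-strength limit of the linearized
Poisson–Boltzmann equation — on a cubic lattice:

* charges and radii are assigned statically per (residue type, atom name)
  from a PARSE-inspired heavy-atom table (the Ser OG atom always carries
  −0.49 e);
* the node dielectric is the solute value (2.0) inside the union of atom
  spheres inflated by the solvent-probe radius (1.4 Å) and the solvent value
  (78) elsewhere, with harmonic averaging of the dielectric on cell faces;
* point charges are spread to the eight surrounding nodes with trilinear
  weights;
* the Dirichlet boundary is the analytic Coulomb superposition in pure
  solvent (single-level, no focusing) — adequate at fixture scale and fully
  deterministic;
* the interior is solved by red–black successive over-relaxation with
  ω = 1.9 to a relative residual of 1e−6 (iteration cap 20,000), in
  compiled code;
* potentials are reported in kT/e at 298 K; the conversion constant
  $e^2/(4\pi\varepsilon_0 k T)$ is computed from CODATA physical constants,
  not hard-coded.

Individual node potentials are grid-sensitive; potential *differences*
evaluated on the same grid are the robust observable, which is why the
score consumes PDs only. The package validates the solver against an
analytic oracle: a +1 e monopole in a uniform dielectric reproduces
$\phi = C q/(\varepsilon r)$ to better than 5% everywhere beyond five grid
spacings from the charge, a symmetric dipole's midplane potential vanishes,
the solution is linear in the charges, and PDs are invariant to a constant
boundary offset and stable (< 5%) under halving of the grid spacing.

### Grid parameters

| parameter | default | units | rationale |
|---|---|---|---|
| spacing h | auto in [0.4, 0.6] | Å | finest spacing on a 0.05 Å ladder whose node count fits `maxNodes`; mirrors common PQR-pipeline behaviour. The stated selection rule is interpreted as *finest-that-fits* since coarser spacings always fit once any does. |
| solute ε | 2.0 | — | standard protein-interior continuum value |
| solvent ε | 78 | — | water at 298 K |
| probe radius | 1.4 | Å | water probe used to inflate atom spheres |
| temperature | 298 | K | enters only the kT/e unit |
| ionic strength | 0 | mol/L | pure Poisson regime; the parameter is accepted for interface compatibility but no Debye screening is applied |
| padding | 10 | Å | distance from the molecular extent to the Dirichlet boundary |

An out-of-process backend contract (`externalGrid`) delegates charge
assignment and the solve to the standard PDB2PQR/APBS pipeline when those
executables are on the PATH, as the fidelity reference for real proteins;
the wrapper reports a typed unavailability error otherwise and the internal
solver remains fully usable.

### The charge table

The internal pipeline operates on heavy atoms only: hydrogen partial
charges are folded into neighbouring heavy atoms so that every residue sums
exactly to its formal charge at pH 7 (Asp/Glu −1, Lys/Arg +1, His 0).
Plain folding would cancel the canonical charge on reactive hydroxyl
oxygens (OG −0.49 with HG +0.49), so the table instead keeps the canonical
charge on the reactive polar atom and places the hydrogen compensation on
the adjacent carbon (Ser CB +0.49). This keeps the assignment static and
deterministic without a protonation engine; the external backend adds
hydrogens itself. Metal ions (Zn, Mg, Mn, Ca) are retained with formal +2
charge and tabulated radii, with a flag to exclude them. Termini are not
special-cased (OXT carries 0), which keeps fixture peptides exactly
integer-charged.

## Search parameters

| parameter | default | units | rationale |
|---|---|---|---|
| cutoff | 15 | Å | upper bound on any pairwise distance in a match; exceeds the largest reference distance of the 4-residue β-lactamase motif |
| tol τ_d | 1.5 | Å | per-pair deviation tolerance; the published worked examples involve deviations up to 1 Å |
| w_d, w_p | 1, 1 | — | equal weighting by default; w_p = 0 gives the pure 3D-congruence baseline |
| ε₀ | 25 | kT/e | both-near-zero ignore band, comfortably above the ~±22 kT/e charge-neutral pair values seen in family tables |
| P_floor | 50 | kT/e | denominator floor; below this magnitude a reference PD no longer tightens the constraint |

Design choices where the procedure was genuinely open:

* a residue may not occupy two sites of one match (injective assignment);
* candidates are drawn from a single chain at a time — composite
  multi-subunit sites are out of scope by construction;
* ties in the best-match selection break by smaller distance term, then by
  residue identifiers, making every report deterministic;
* motifs with no congruent match are reported as *no match*, never as a
  sentinel score, so library rankings sort over actual matches only;
* the ROC sweep uses inclusive thresholds (score ≤ t ⇒ predicted positive)
  and trapezoidal area over the operating points.

The pruned depth-first search orders sites by ascending candidate count and
extends a partial tuple only while every new pairwise distance stays within
the cutoff and tolerance; this is exact, and the test suite asserts
set-equality against a brute-force Cartesian oracle on 100+ randomized
small fixtures per run.

## Synthetic fixtures: what they emulate and what they do not

All tests and the acceptance script run offline on generated data:

* **Toy structures** are single-chain PDB files with alanine-like backbones
  and grafted side chains placed so each planted residue's reactive atom
  sits exactly at its target coordinate. Published pairwise-distance tables
  (e.g. the trypsin triad 3.3/7.8/5.5 Å, the alkaline-phosphatase site
  4.6/7.7/3.2 Å) are embedded into 3D coordinates by classical
  multidimensional scaling, so printed geometry drives real pipeline runs.
  Decoy residues are scattered beyond the search cutoff. Generators are
  pure functions of (spec, seed) and re-parse losslessly.
* **Charge fixtures** (monopole, dipole, seeded random clouds) are the
  solver's oracle inputs.
* **Labelled score sets** emulate the family-discrimination task: positives
  carry geometry near the reference and PDs drawn tightly around a family
  profile whose default means (±100–250 kT/e) and spreads (10–25 kT/e)
  mirror published β-lactamase family statistics; negatives carry
  comparable geometry with PDs from a broad uniform distribution. On 20
  seeded sets of 5 positives + 45 negatives, enabling the PD term reduces
  the decoy fraction scoring below the worst true positive from roughly
  40% to under 1% and lifts sensitivity at 10% FPR from ~45% to ~100% —
  the direction, though not the magnitude, of the published large-scale
  contrasts.

What passing these tests does **not** show: real active sites sit in clefts
where dielectric-boundary discretization error is largest; real decoys are
not uniform in PD space; and full-protein potentials require thousands of
atoms and finer grids than fixture-scale solves. Reproducing published
per-structure PD values (e.g. the 2G2U S70/K73 value of −201.7 kT/e)
requires the actual crystal structures and remains open in this build: the
pipeline accepts locally supplied PDB files and the corresponding test is
left failing, rather than weakened, when the files are absent.

## Degenerate inputs and numerical corner cases

* Zero total charge yields an identically zero potential; the relative
  residual uses a guarded denominator.
* Distance embeddings verify their reconstruction and refuse non-Euclidean
  inputs (triangle-inequality violations).
* Alternate locations resolve to the highest occupancy (ties by altloc
  letter); only the first model is read; waters are dropped; insertion
  codes are preserved verbatim and matching is by (chain, number, icode).
* `assignParameters` under the strict policy names every unparameterized
  residue; the skip policy drops them with a count.
* Generated fixtures abort if any two atoms fall within 1 Å.
* Confusion metrics flag 0/0 as undefined rather than returning 0.

## Problem sizes

The shipped test-and-acceptance configuration uses fixture solves on grids
of roughly 40–90 nodes per axis (h = 0.5–0.8 Å, padding 8–10 Å), 100
randomized search-oracle cases, and 20 × 50-item score sets; the full suite
completes in well under a minute of compute on one core, and
`scripts/acceptance.R` in a similar time. These sizes are the package's
chosen validation scale: large enough for every qualitative claim asserted,
small enough to run anywhere.

## Known limitations

* Distance-based matching cannot distinguish mirror images; reflection
  invariance is asserted in the tests as a documented property, not fixed.
* Single polypeptide chains only; composite active sites across subunits
  are not handled.
* The linearized, zero-ionic-strength regime only; no nonlinear PB, no
  solvation energies or forces.
* Absolute CLASP scores are implementation-specific; only orderings and
  the zero self-score transfer.
* No pKa-coupled protonation prediction; the static charge model is a
  deliberate simplification.
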