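---
title: "Fingerprinting p53-DNA interfaces: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fingerprinting p53-DNA interfaces: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p53dyn)
```

## The scientific setting

p53 response elements (REs) are 20-bp sites of two palindromic 10-bp half
sites; each half site is read by a dimer of p53 core domains, one monomer
per 5-bp quarter site (Q1–Q4).  On the reference strand a half site
follows the degenerate consensus Pu-Pu-Pu-C-W-W-G-Py-Py-Py (W = A/T).
Functional REs deviate from this consensus at a handful of positions, and
those deviations re-pattern the direct interface contacts:

* **Lys120** approaches the major groove over quarter-site positions 1–3.
  Which base it bonds depends on identity: G offers two acceptors (O6 and
  N7, supporting a *three-centered* hydrogen bond), A offers N7, T offers
  O4, and C none.  In a Watson–Crick A·T pair the two acceptors (purine
  N7, thymine O4) sit 6–7 Å apart — too far for one amine to bridge, so
  only a two-centered bond forms.
* **Arg280** holds the G base paired with the absolutely conserved C at
  position 4 (the "G4′" contact), through the NH1–O6 / NH2–N7 pairs.
* **Arg248** engages the minor-groove backbone at positions 4–5.
* A salt-bridge chain **A: DNA–Arg280, B: Arg280–Glu281, C:
  Glu281–Arg273, D: Arg273–DNA** buttresses the specific interface.

`p53dyn` turns a conformational ensemble of such a complex into
quantitative descriptors of all of the above, plus coarser readouts of
how the interface re-patterning propagates: side-chain RMSD series,
per-residue RMSF, an organizational angle/dihedral tying the domain's
orientation to its quarter site, DNA bend angles, and normalized dynamic
cross-correlation maps.

## Contact model

A hydrogen bond or salt bridge is defined purely by heavy-atom geometry:
a contact exists in a frame when the minimum distance over all configured
donor–acceptor atom pairs is within the cutoff (default **3.5 Å**).
Occupancy over a frame window is the percentage of frames with the
contact formed.  Choices worth stating:

* **No angular criterion.**  The distance-only definition is the one the
  occupancy tables this package mirrors were computed with.  Nothing in
  the code path assumes hydrogen positions, so the criterion also works
  for heavy-atom-only models.
* **Boundary rule.**  A distance exactly equal to the cutoff counts as
  bonded (`<=`).  Published descriptions are ambiguous between "less
  than" and "cutoff of"; `occupancy(boundary = "<")` selects the strict
  rule, and for continuous distance distributions the difference has
  measure zero.
* **Aggregation.**  Equivalent guanidinium nitrogens are aggregated by
  the min-pair rule; the named per-pair series (NH1–O6, NH2–N7) and
  their per-frame average are emitted alongside, since published distance
  plots report both conventions.
* **DNA backbone atoms** for salt bridges and Arg248 default to the
  phosphate oxygens `O1P`/`O2P`; the mapping configuration can widen or
  narrow the set per contact.

## Windows

Occupancy statistics default to the **tail two-thirds** of the ensemble
and fluctuation analyses (RMSF, the organizational descriptor, average
structures) to the **tail sixth**.  These fractions mirror the common MD
practice of discarding the settling portion of a production run — for a
30-ns trajectory they correspond to the last 20 ns and the final 5 ns
respectively.  All windows are resolved in frame counts (`resolve_window`);
time stamps are optional metadata.  A fraction `f` of `n` frames resolves
to the last `n - ceil((1-f) n)` frames, with a 1e-9 tolerance so that
thirds and sixths of round frame counts are not shifted by floating-point
representation.

## Position labels and strand bookkeeping

Within one quarter site, positions 1–5 live on the *local* strand (the
strand whose 5′→3′ reading gives Pu-Pu-Pu-C-W) and primed labels name the
paired bases on the opposite strand.  For Q1/Q3 the local strand is the
global reference strand; for Q2/Q4 it is the complementary chain, which
is why published tables print the primed columns 5′…1′ for those
quarters.  `contact_partner` resolves any label to the physical chain and
base; position **0** — used by the organizational descriptor — is the
base pair immediately 5′-adjacent to local position 1, implemented as a
configurable offset (`position0_offset`) because flanking caps could
arguably shift the register by one.

## Geometry descriptors

* **Superposition** is the standard Kabsch SVD solution with the
  determinant correction, optional weights, and an error on degenerate
  (collinear / < 3 point) input.  RMSD series superpose each frame on a
  fit selection (typically the monomer Cα set) before measuring a named
  side chain, so the series reports internal rearrangement rather than
  diffusion.
* **RMSF** defaults to deviations about the *windowed mean* structure
  after per-frame superposition — the standard fluctuation definition.
  Because some published fluctuation plots are instead computed against
  the initial structure, `rmsf_profile(reference = "initial")` retains
  that mode; the two differ by the drift of the mean, and neither mode is
  guessed silently.
* **Organizational angle/dihedral**: angle Cα(Ser269)–Cα(Gly112)–C3′(pos
  0), dihedral adding C3′(pos 4′); degrees; the dihedral follows the
  IUPAC sign convention (verified against two independent
  implementations).  Values are reported per frame, as window means, and
  as evaluated on the window-average structure — the latter is the
  convention used when such descriptors are tabulated for time-averaged
  structures, and the two can differ for broad distributions, so both are
  emitted.
* **Average structures** superpose each window frame on the first window
  frame before averaging (or on nothing, for ensembles already in a
  common frame).

## DNA model and bend metric

`ideal_bdna` builds a straight B-form duplex from the standard base-pair
reference-frame geometries (planar idealized bases) with rise 3.38 Å and
twist 36°/bp.  Backbone atoms (`C3'`, `P`, `O1P`, `O2P`) are *schematic*:
placed at B-DNA-like radii so selections and phosphate contacts resolve,
not a full sugar-phosphate model.  Base-pair frames are recovered by
least-squares fitting each base's standard geometry to its observed ring
atoms and averaging the two (complementary frame flipped), which
reproduces the construction twist to well under 0.5°.

The **bend angle** is deliberately simple: principal axes are fitted to
the base-pair origins of the first and last `ceil(n/3)` pairs (both
oriented 5′→3′), and the bend is the angle between them.  This is *not*
the curvilinear-axis algorithm used by dedicated DNA-geometry programs,
and its absolute values are not comparable to published curvilinear
bends; it is transparent, rigid-motion invariant, and accurate for
ensemble-relative comparisons, which the tests quantify by planting kinks
of 10–45° and recovering them within 2°.  Terminal-segment length is
configurable (`terminal_bp`); near-degenerate axis fits are reported as
angle 0 with a flag rather than a spurious number.

## Covariance maps

The "covariance map" is implemented as the normalized dynamic
cross-correlation of Cα displacement vectors,
`C_ij = <Δr_i·Δr_j> / sqrt(<|Δr_i|²><|Δr_j|²>)`, displacements taken
about the windowed mean after superposition on the same fit selection as
the RMSF (a documented coupling).  This is the standard reading of
red/purple ± correlation maps; the raw block-traced covariance is
available behind `normalized = FALSE`.  A zero-variance atom yields an
`NA` row/column — undefined, not zero.  Symmetry and the unit diagonal
hold to 1e-12 and are asserted in the tests.

## The synthetic generator: what it emulates, and what not

The original ensembles for this system were 30-ns explicit-solvent MD
trajectories of ~110,000-atom systems and are not deposited, so the
package ships a generator whose output has the same *statistical* shape
as the published readouts and a recorded ground truth:

* per-contact Bernoulli bonding at stated probabilities, with bonded
  distances ~ Normal(2.9, 0.15) Å truncated above 2.4 Å and unbonded
  distances ~ Normal(5.5, 0.5) Å truncated above cutoff + 0.2 Å — the
  3.5 Å rule then misclassifies a draw with probability below 1e-3,
  a leakage rate the tests bound at 0.1%;
* isotropic Gaussian positional jitter (default σ = 0.3 Å per
  coordinate, the scale implied by ordinary crystallographic B-factors);
* a planted DNA bend applied as a rigid rotation of the second half-site
  unit (DNA plus its monomer) about an axis through the half-site
  midpoint (default 15°, mid-range of published half-site bends);
* one planted anti-correlated Cα pair (residues 120 and 180 of the first
  monomer, amplitude 2 Å — large-loop scale), emulating the
  negative coupling between the L1-loop region and the dimerization
  surface that correlation maps of this system show;
* a coupled-disruption scenario in which the Lys120 and Arg280 contacts
  break together with a stated coupling probability.

Mechanically, each contact owns one mobile atom group (a base, a
carboxylate, a guanidinium tip, or a phosphate group) that is translated
along the donor–acceptor direction so the controlled distance equals the
draw; unbonded frames leave the group at rest unless rest geometry is
within cutoff + 0.2 Å, in which case it is pushed outward.  The defaults
describe a consensus-conforming quarter site: Lys120 bonded mainly at the
central position (p = 0.9), Arg280 holding G4′ (p = 0.9), a partially
formed salt-bridge chain (A 0.9, B 0.6, C 0.5, D 0.4), and a dynamic
Arg248 (0.8/0.3).

The template is a *contact rig*, not a physical model: pseudo-protein
monomers are minimal atom sets, moved groups follow schematic straight
lines, and no force field, sterics or solvent exists.  Passing the
recovery tests therefore establishes that the *analysis pipeline*
measures what was planted — occupancies to within binomial error, bends
to within 2°, fluctuation amplitudes to within 5%, correlations with the
planted sign and magnitude — on data of realistic statistical shape.  It
does **not** establish anything about real p53 trajectories, force-field
quality, or the published trajectory-derived table values, which would
require re-running the MD.

## Problem sizes

The validation suite generates ensembles of 663 atoms with 2000 frames
for occupancy/correlation recovery (binomial standard error ~1.1 points
at p = 0.5), 5000 frames of a 4-atom fixture for the RMSF closed form,
150-frame ensembles per planted kink, and ≤ 20-frame fixtures for exact
brute-force oracle equality.  These sizes keep the full suite around a
minute while leaving every tolerance dominated by statistics, not by
compute budget.

## Numerical choices

* Distances accumulate squared terms via `rowSums` (long-double
  accumulation), matching a naive frame-by-frame oracle bit for bit.
* `acos` arguments are clamped to [−1, 1]; dihedrals use the
  atan2 formulation, stable near 0/180°.
* Kabsch raises an error (rather than returning a reflection) when the
  covariance matrix is rank-deficient.
* Random number use is a single `set.seed`-driven stream per generated
  ensemble; identical seeds give bit-identical bundles on disk, which the
  determinism tests assert via checksums.

## Known limitations

* The bend metric is segment-based, not curvilinear; absolute bends of
  strongly writhed DNA will differ from Curves-style values.
* Water-mediated and energetic analyses are out of scope; contacts are
  geometric only.
* The synthetic monomers carry only the analysed atoms, so analyses that
  assume complete residues (e.g. full-backbone fitting) must select what
  exists; mapping files make the selection explicit.
* Multi-model PDB is the only trajectory container; binary trajectory
  formats are intentionally unsupported to keep the artifact
  self-contained and text-diffable.
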