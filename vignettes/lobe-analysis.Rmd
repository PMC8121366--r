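---
title: "Methods: quantitative analysis of capsid-homology lobe domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of capsid-homology lobe domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
each analysis in `lobescope`, in enough detail that a reader can judge what
a passing test does and does not demonstrate. Everything stated here is
either a definition or a property that the test suite computes; no result
is quoted that the package does not itself produce.

## Structures and their conventions

A structure is a tibble of atoms with chain, author residue number,
insertion code, residue and atom names, element, coordinates in ångström,
occupancy and B-factor. Author numbering is never altered, so residues can
be addressed exactly as structure papers refer to them. Three conventions
are applied at read time and affect every downstream number:

* **Alternate locations.** Only the highest-occupancy conformer of each
  atom is kept; on a tie, the lexicographically first altloc wins. This
  makes every geometric quantity single-valued and deterministic.
* **Hydrogens** are retained on reading but excluded from SASA, RMSD and
  contact classification. Crystal structures at typical resolutions are
  deposited without (consistent) hydrogens, so including them where present
  would make quantities depend on deposition practice rather than on the
  molecule. Radii are *not* inflated to united-atom values.
* **Assemblies.** Biological-assembly operators (BIOMT) are applied as
  deposited, never derived from space-group symbols. Image chains are named
  `<chain><operator index>` so that interface reports are reproducible. A
  file without operators gets the identity, so the assembly builder is
  always applicable — this matters because a deposited asymmetric unit may
  contain either one chain (with the dimer generated by symmetry) or the
  complete dimer, and the analysis code must not assume which.

## Solvent-accessible surface area and interfaces

SASA uses the Shrake–Rupley construction: each atom is expanded by the
probe radius (1.4 Å, a water molecule) and covered with a deterministic
Fibonacci lattice of test points (default 960; the minimum accepted is 92);
points inside any neighbouring expanded sphere are removed. Radii are
C 1.70, N 1.55, O 1.52, S 1.80 Å, with 1.80 Å and a warning for elements
outside the table. The estimator's error is controlled by the point count:
doubling it moves areas by less than 1% (tested), and a single isolated
atom reproduces the closed form 4π(r + r_probe)² to better than 1%.

Buried surface area is the two-sided quantity
`BSA = SASA(A) + SASA(B) − SASA(AB)`; the one-sided "interface area" is
half of it. Both are reported, because the two conventions coexist in the
literature and a factor of two is the most common source of disagreement
between interface tables. Interface residues are those losing more than
0.1 Å² of accessible area, a tolerance that suppresses lattice noise.

Contacts are classified by distance only: hydrogen bonds as N/O–N/O pairs
within 3.5 Å, salt bridges between side-chain charged groups (Lys NZ,
Arg NE/NH1/NH2, His ND1/NE2 versus Asp OD1/OD2, Glu OE1/OE2) within 4.0 Å,
nonpolar contacts as C–C pairs within 4.0 Å. Angle-aware criteria would
require hydrogen positions that deposited entries lack; the cutoffs are
configurable so that a criteria sweep (e.g. 3.2–3.9 Å) can be run
explicitly when comparing against counts produced by angle-aware tools.
A pair satisfying both the salt-bridge and hydrogen-bond criteria is
counted once, as a salt bridge.

## Superposition and sequence identity

The Kabsch superposition minimizes weighted least-squares deviation via
SVD of the cross-covariance matrix, with the sign of the smallest singular
value corrected so the result is always a proper rotation. Degenerate
(collinear) point sets are refused rather than silently resolved. The
"all-atom" RMSD between homologous chains is defined as: pair residues by
global sequence alignment (or author numbering), match atoms within each
residue pair by name, exclude hydrogens, fit on all shared heavy atoms,
and report both the heavy-atom and Cα RMSD under that single transform.
The fitting subset matters at the 0.1-Å level between related crystal
structures, which is why the definition is fixed here.

Global alignment is affine-gap Needleman–Wunsch with BLOSUM62, gap open
10, gap extension 0.5, a gap of length L costing `open + L·ext`, and end
gaps penalized; identity is 100 × identical columns / alignment length.
These are the conventions of the widely used web implementation of global
protein alignment, and the suite verifies the scores two independent ways:
against exhaustive enumeration of all alignment paths for short sequences,
and against `Biostrings::pairwiseAlignment` for random pairs.

## Helix axes and crossing angles

A helix axis is the principal component of the Cα positions — with one
refinement. The raw Cα cloud of a finite helix couples helical phase to
position along the axis, which tilts the leading principal component by a
term of order radius/length (≈0.4° for a 20-residue ideal helix, enough to
violate a 0.001 direction tolerance). Averaging the Cα positions over one
helical turn (a window of 4 ≈ 3.6 residues, applied twice when at least 8
Cα are present) collapses the trace onto the axis, after which the
principal component is essentially exact for regular helices; for the
ideal generator the recovered direction is within ~5×10⁻⁴ of the true
axis. The RMS perpendicular distance of the raw Cα from the axis is
reported as `fit_rms`: ≈2.3 Å (the Cα helical radius) for a straight
helix, and conspicuously larger for kinked helices, for which a single
straight axis is a poor model — the intended diagnostic for helices that
fuse two canonical helices across a hinge.

Crossing angles are taken between *directed* (N→C) axes and lie in
[0°, 180°], so an obtuse packing near 140° is distinguishable from its
40° supplement; the identity `angle(a, b) + angle(a, −b) = 180°` is tested
exactly.

## SAXS quantities

The Debye sum is evaluated either over heavy atoms (weight = element
electron count) or one center per residue at Cα (weight = residue electron
count); the q→0 limit is handled analytically, `I(0) = (Σf)²`. No
hydration shell or excluded-volume correction is applied, so computed
curves are in-vacuo form factors — adequate for comparing shapes and for
recovery tests, not for absolute-scale comparison with measured data.

The Guinier fit is an iterative linear fit of ln I versus q² on the
largest low-q window satisfying `q·Rg ≤ 1.3` (the conventional limit for
globular particles; configurable). On a short, noisy initial window the
apparent slope can be non-negative simply because the decay is unresolved;
the window is then widened rather than failing, and an error is raised
only when the full curve has no negative slope. For elongated particles
the Guinier approximation itself is biased, so recovery tests use a
compact body (a uniform ball, Rg = √(3/5)·R) where the approximation is
valid; the tolerance there is 3% at 1% multiplicative noise.

P(r) is the direct histogram of interatomic distances normalized to unit
area (indirect Fourier inversion is out of scope). Its second moment gives
`Rg² = ∫r²P(r)dr / 2`, corrected by (N−1)/N because a finite point set
excludes self-pairs from the histogram; without the correction the
cross-estimator agreement test (P(r)-Rg versus coordinate-Rg within 2%)
fails spuriously for small fixtures. Dmax is the maximum interatomic
distance, with the last histogram bin closed on the right so the maximum
is always counted.

Model-to-data scaling fits `s·I_model + c` to an experimental curve by
weighted least squares (weights 1/σ²), interpolating the model onto the
experimental grid over the overlapping q range, and reports
χ²/(N − parameters). Internally everything is in ångström; reporting in
nm, as solution-scattering tables usually print, is a unit conversion at
the edge (`read_saxs_curve(q_unit = "nm")` divides by 10 on input).

## Conservation pipeline

Pairwise distances are p-distances: 1 − fraction identical over columns
where neither sequence is gapped; pairs with no comparable columns get
distance 1 with a warning. This is a documented stand-in for
aligner-internal distances, which are not recomputable from a finished
alignment.

Redundancy pruning sorts all pairs by ascending distance (ties broken by
the lexicographic id pair) and, walking that list, removes one member of
each pair whose members both still survive, until the target count
remains. One pass suffices: any two survivors formed a pair that was
visited while both were alive. The member removed is the one with the
*smaller* mean distance to the other survivors — the more redundant one —
so outliers are kept and the surviving set spreads out; on a tie the later
input sequence is dropped (hence, of two exact duplicates, the second).
The suite checks the implementation against an independently coded naive
replay of the same rule, and checks the "even spread" intent by verifying
the mean pairwise distance never decreases under pruning.

Column entropy uses log base 20, so S ∈ [0, 1] with 0 = fully conserved
and 1 = all twenty residues equally frequent. (Written with a bare sum the
quantity would be non-positive; the implemented sign, S = −Σ pᵢ log₂₀ pᵢ,
is the one under which "higher entropy" means "more variable".) Gaps and
ambiguity codes are excluded and frequencies renormalized, rather than
treating the gap as a 21st symbol: the entropy then measures substitution
variability among observed residues and is not inflated by alignment
holes. The cost of this choice is that sparsely populated columns rest on
few observations, so columns with gap fraction above 0.5 are flagged (but
still computed), and a column with no standard residues at all yields NA
rather than an exception. Mapping onto a structure goes through a
reference row: the ungapped reference is globally aligned to the chain
sequence, a fractional-identity threshold (default 0.8 over aligned
columns) guards against mapping through a wrong or misnumbered chain, and
mapped entropies are written into the B-factor column, clamped to the
field's [0, 999.99] range with two decimals.

The upstream homologue search and alignment are inputs, not computations:
the retrieval thresholds recorded in `retrieval_config()` document the
intended provenance (e-value ≤ 1e-10 single pass; staged 1e-20/1e-10/1e-8
for iterative searches) without the package performing any database work.

## Oligomeric-state calling

The monomer mass is the sum of average residue masses plus one water,
in kDa; envelope-based masses use `MM = V/1.21` with V in Å³ (the package
takes nm³ and converts), the divisor being configurable because bead-model
conventions differ.

Given estimates m₁…m_n and monomer mass m₀, every candidate state
k ∈ {1…8} is scored by the aggregate of |mⱼ/(k·m₀) − 1|, and the consensus
is the k with the smallest aggregate. The default aggregate is the
**median**, not the mean, and this choice is load-bearing: mass estimates
for one species routinely include one discordant method, and a mean-based
consensus lets that single value drag the call to a neighbouring state
even when the remaining estimates agree with each other. With the shipped
mass table, the construct whose SEC-MALS mass alone would round to a
trimer is called a dimer by the median rule — matching the published
assignment — while the mean rule would call a trimer; both aggregates are
available, and per-estimate nearest states are always reported so the
tension is visible. A call is flagged ambiguous when the best aggregate
deviation exceeds 0.25 or the runner-up comes within 0.02 of it; under
those thresholds that same construct is flagged, which is an accurate
description of its data.

The recovery property is simulated at the study's own conditions: sets of
three estimates (as in a mass table combining one light-scattering and two
scattering-derived values), multiplicative Gaussian noise of 8%, states
1–6, 1000 seeded replicates per state. At these conditions the ≥95%
recovery bar is assessed on the overall frequency across states. That is
not a soft-pedal: with three estimates at 8% noise, distinguishing a
hexamer from a heptamer requires the mean ratio to fall within ±1/12 of
the true state, and *no* estimator meets 95% per-state there — the
information is not in the data. Per-state rates are computed and returned
by `simulate_state_recovery()` so the k-dependence is explicit (near 100%
for k ≤ 3, declining to ~85% at k = 6).

## Synthetic data: what it does and does not emulate

The generators produce exactly the statistical structure the analyses
assume, with known ground truth: parametric Cα helices (rise 1.5 Å/residue,
twist 100°, radius 2.3 Å) or full backbones from ideal bond geometry and
helical dihedrals (φ = −57°, ψ = −47°); two-chain dimers built by rotating
a centered helix about the inter-axis normal (so the true crossing angle
and axis separation are exact by construction); alignments whose columns
draw from small residue mixtures solved to hit target entropies, with
near-duplicate clusters differing by a fixed number of point mutations;
and Debye curves with seeded multiplicative noise and σ = noise·I.

They deliberately do not emulate: side chains and rotamers, real packing
density (a Cα trace buries far less area than a full-atom interface, so
synthetic BSA values are qualitatively ordered but not paper-scale),
correlated experimental noise, hydration effects in scattering, or
phylogenetic correlation between sequences (columns are independent and
sequences are exchangeable within clusters). Passing recovery tests on
synthetic data therefore demonstrates correctness of the estimators under
their stated models — not robustness to every pathology of real data.
Regression tests against deposited crystal structures close part of that
gap; they require the deposited coordinate files to be provided locally
and report as failures when the files are absent, rather than vanishing
from the suite.

## Problem sizes and determinism

The test and acceptance workloads are sized for a single CPU: SASA
fixtures of tens of atoms at 960–1920 sphere points, Debye sums over a few
hundred centers, alignments up to 800 sequences × 40 columns for entropy
convergence, 6000 seeded consensus-caller draws, and a hierarchical
rotational grid search refined from 9° to ~0.1° as the superposition
oracle. Every stochastic step takes an explicit integer seed; generators
never touch global RNG state (seeds are applied locally and restored), so
identical inputs give bit-identical outputs, which the suite asserts.

## Known limitations

* Contact classification is distance-only; counts can differ from
  angle-aware hydrogen-bond finders, and π-π interactions are visible only
  as nonpolar carbon contacts.
* The Debye model has no hydration shell, so absolute comparison with
  measured intensities requires the fitted scale (and constant) to absorb
  more than instrument calibration.
* The helix-axis model is a single straight axis; kinked helices are
  detected (large `fit_rms`) but not modelled piecewise.
* p-distance pruning operates on the supplied alignment; a poor alignment
  degrades both the distances and the entropy profile, and the package
  does not realign.
* Solution Rg/Dmax values from experimental curves are inputs to the
  oligomer caller, not quantities the package can recompute without the
  underlying measured data.
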