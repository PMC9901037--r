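---
title: "Methods: quantifying N-terminal groove flexibility in peptide-MHC I complexes"
author: "GrooveFlex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying N-terminal groove flexibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GrooveFlex)
```

# Scope and data model

GrooveFlex measures the geometry of peptide binding at the N-terminus of
the MHC class I groove from two kinds of input: static crystal structures
(PDB/mmCIF) and multi-frame coordinate trajectories (multi-model PDB).
Four S4 containers carry the data: `StructureModel` (atom table plus
per-chain sequence records), `Trajectory` (frames x atoms x 3 with a
topology), `AngleSeries` (a time-stamped angle trace with an explicit
wrap state), and `InteractionSeries` (per-frame distance and orientation
between two residues). Author residue numbering is authoritative
throughout: the groove residues of interest are addressed as Ile52,
Tyr59, Asn63, Cys76, Trp167 exactly as deposited, and nothing is
renumbered.

# Structure stage

**Reading and alternate locations.** Parsing goes through `bio3d`.
Alternate conformers are resolved to the highest-occupancy copy, ties
broken by altloc identifier order — a convention, since occupancy ties
carry no physical preference. Waters and common buffer components are
dropped.

**Unmodeled regions.** A residue counts as modeled when any of its atoms
has coordinates; missing-density detection therefore reports
whole-residue disorder only, not side-chain disorder. Gaps are maximal
runs of residue numbers absent from the coordinate record, found from
numbering gaps between consecutive modeled residues and, when a sequence
record exists, from record residues never modeled (which also catches
terminal disorder). PDB sequence records carry no residue numbers, so
author numbering is assumed to start at `seqStart` (default 1, the MHC I
heavy-chain convention); if the modeled residues fall outside that
numbering the record is dropped for that chain with a warning rather
than guessed. Crystallographic practice declares a residue invisible
below a density threshold (about 1 sigma); coordinates-absent is the
faithful proxy available downstream of refinement, and the distinction
is deliberately not modeled.

**Peptide position map.** The disulfide-trapped design anchors the
peptide's P7 cysteine to heavy-chain Cys76. P7 is located as the peptide
cysteine whose S-gamma lies within 2.5 A of the Cys76 S-gamma (a standard
disulfide bond length plus margin), P1 is six chain positions N-terminal
to it, and residues before P1 are labeled P-1, P-2, ... If no partner is
found the mapping errors instructing manual specification
(`peptidePositionMap()`), rather than guessing a register.

**Superposition and displacements.** `kabschSuperpose()` is the
closed-form SVD solution with the determinant correction that excludes
reflections; collinear point sets are rejected. Inter-structure
comparisons fit on heavy-chain C-alpha atoms of residues 1–180 (the
alpha1/alpha2 domain, the conventional peptide-MHC reference frame),
restricted to residues modeled in *both* structures; the fit set is
configurable and no outlier trimming is applied. Displacements are
reported to 0.01 A. The superposition set used for published
peptide-MHC comparisons is rarely stated; the alpha1/alpha2 C-alpha
frame is this package's fixed, documented choice.

**Contacts.** Hydrogen bonds use donor-acceptor distance <= 3.5 A, plus
a donor-H-acceptor angle >= 120 degrees only when explicit hydrogens are
present (crystal structures usually lack them, so the distance criterion
alone applies there). Hydrophobic contacts are carbon-carbon pairs
within 4.5 A, deduplicated per residue pair keeping the minimum
distance. Donor/acceptor typing comes from a fixed dictionary over the
20 standard residues; non-standard residues are skipped with a warning.
All cutoffs are arguments of `contactCriteria()`.

# Trajectory stage

**RMSF.** Frames are superposed on a reference before fluctuations are
measured; the default reference is the two-pass mean structure (fit to
frame 1, recompute the mean, refit), which is more stable than a
first-frame reference for short trajectories. RMSF of atom i is
`sqrt(mean_t |x_i(t) - <x_i>|^2)` — note the mean over frames, not the
n-1 estimator — and per-residue values average the residue's C-alpha
atoms by default (all heavy atoms by flag). Because the fit atoms are
themselves fluctuating, the rigid fit absorbs a small part of the
apparent motion; with the ~180-residue fit sets used here the bias is
below one percent, and the test suite quantifies it against the
`sigma * sqrt(3)` closed form of the harmonic generator at 2000 frames.

**Ring geometry.** Ring centers are unweighted means of the six ring
atoms (at least five required). Ring normals are best-fit plane normals
(SVD), with the sign fixed by the right-hand rule over the ordered atom
cycle (Newell polygon normal), so the orientation is reproducible under
rigid motion. Normal-normal angles are reported unfolded in [0, 180]
degrees — stacking peaks near 110 or 150 degrees would fold to 70/30 and
lose their identity otherwise. Folding to the stacking deviation
`s = min(theta, 180 - theta)` happens only inside `classifyPiPi()`:
s >= 60 degrees is T-shaped, s <= 30 parallel-like, else intermediate,
with half-a-bin grace at the thresholds so a peak sitting exactly on a
boundary (a 150-degree ring angle is exactly s = 30) takes the boundary
class instead of flipping on quantization noise. The deposited-structure
convention for resolving the +/- sign of a ring normal is not published;
this package's orientation rule is stated above and applied uniformly.

**Interaction definitions.** Four atom-pair rules, selected by the P1
residue type: Phe P1 vs Tyr59 uses ring-center to ring-center (plus the
normal-normal angle); Ala P1 vs Tyr59 uses C-beta to ring center; Phe P1
vs Ile52 uses ring center to C-delta; Ala P1 vs Ile52 uses C-beta to
C-delta. Other P1 types error explicitly — extending to Trp would need a
two-ring convention that is out of scope.

**CH-pi.** The criterion is distance <= 6.0 A (ring center to C-delta)
and C-H-X angle >= 120 degrees, X the ring center — numeric values in
the range of the standard literature criterion, configurable. A methyl
C-delta carries three hydrogens and the convention here is the
ring-facing one (largest angle). When hydrogens are absent (crystal
structures) ideal tetrahedral hydrogens are constructed on the carbon
(1.09 A, tetrahedral angle, arbitrary azimuth); the azimuth freedom
means constructed angles are approximate to a few degrees, which the
distance-dominated criterion tolerates.

**Distributions.** Probability distributions are density-normalized
histograms, 0.25 A bins for distances and 5 degree bins for angles, with
the peak reported as the center of the maximal bin (ties toward the
lowest value) and width as FWHM of the binned density. Histograms rather
than kernel estimates keep the peak location assumption-free; the
published distributions' smoothing method is unstated, so the bin widths
are this package's documented choice.

# Rotation stage

The dihedral omega over Cys76:CA, P7:CA, P1:CA, P1:N (standard IUPAC
sign) reports whether the peptide terminal amino group points up
(~ -100 degrees) or down (~ +100 degrees) in the A pocket. Raw wrapped
traces are unwrapped by requiring frame-to-frame changes below 180
degrees, adding or subtracting 360 otherwise; an exact 180-degree jump
is broken toward no adjustment and logged. Smoothing is a centered
10-ns moving average over the unwrapped trace (smoothing wrapped angles
across the branch cut is refused), with truncated windows at the edges
rather than dropped samples. Event detection requires a dwell of at
least 1 ns in the start band (-100 +/- 45 degrees) before the trace
enters the end band (+100 +/- 45 degrees, modulo 360 — so an unwrapped
excursion to -260 degrees counts as reaching +100); the dwell rejects
single-frame noise, and the detector re-arms after each event so
multiple rotations are countable. Band centers/widths and the dwell are
arguments.

# Melting temperatures

Replicates are averaged pointwise, the curve smoothed by an 11-point
centered moving average (about 1 degree C on the 0.1-degree grids used
here), the first derivative taken by central differences and smoothed
with the same window (differentiation amplifies residual noise), and Tm
read at the derivative minimum — as printed for fluorescence curves that
decrease through the transition; dye-based melts that peak in +dF/dT use
`extremum = "maximum"`. The extremum is refined by the half-depth
centroid of its peak: for a symmetric transition the centroid is
unbiased and averages noise over the whole peak, which is what makes a
single noisy curve (1 percent of amplitude) recoverable to 0.3 degrees
where a three-point parabola is not. Flat or linear curves and
transitions centered at the grid boundary are rejected with explicit
errors; multi-transition curves report the global extremum and list all
interior local extrema.

# The synthetic-data module

Each generator is a pure function of its parameters and seed (byte
identical on rerun, caller's RNG untouched) and returns its ground truth
alongside the data:

- `makeHarmonicTrajectory()`: rigid helical C-alpha scaffold, residue i
  displaced i.i.d. isotropic Gaussian with per-coordinate sigma_i, so
  expected RMSF is sigma_i * sqrt(3). Default conditions used by the
  acceptance runs: 180 residues with sigma 0.5 A in residues 41–62
  against 0.1 A elsewhere, 2000 frames at 20 ps — the flexible-region
  contrast and sampling interval of the equilibrium ensembles being
  emulated.
- `makeRingPair()`: two hexagonal PHE/TYR-like rings at programmed
  center distance and normal angle, per-atom Gaussian jitter.
- `makeRotationTrace()`: piecewise-sigmoidal level schedule (10-ns
  transitions), Gaussian noise (15–20 degrees, thermal scale), wrapped
  into (-180, 180].
- `makeGappedStructure()`: poly-alanine helical backbone with listed
  ranges omitted from coordinates but present in the sequence record.
- `makeMeltCurve()`: descending logistic over 25–95 C on a 0.1 C grid
  (inflection = programmed Tm, width 3 C), noise proportional to
  amplitude.

What these emulate is the *statistical structure* the analyses consume —
fluctuation amplitudes, stacking geometry, state transitions, missing
density, sigmoidal unfolding. What they do not emulate: real force-field
dynamics, anharmonicity and correlated motion, real MHC folds, asymmetric
or multi-step melts. Passing tests therefore demonstrate that the
estimators recover known ground truth under realistic noise, not that
any particular biological system behaves this way.

# Problem sizes and determinism

The test-suite and acceptance runs use 2000-frame ensembles for
closed-form RMSF and distribution recovery, 300-ns rotation traces at
20 ps sampling, 100 seeded rotation traces for event-count recovery, and
701-point melt curves — sizes at which the stochastic tolerances (5
percent on RMSF, one bin on peaks, 0.3 C on noisy Tm) are comfortably
resolved on a single CPU in seconds. All randomness flows from explicit
seeds; reports rerun byte-identical.

# Known limitations

- Missing-density detection cannot see side-chain-only disorder or use
  density levels; it is a coordinate-record analysis.
- SEQRES-to-author-numbering alignment is by declared offset, not by
  sequence alignment; structures with exotic numbering keep numeric-gap
  detection only.
- CH-pi hydrogen construction is ideal-geometry, not force-field
  specific.
- P1 residue types other than Phe/Ala are rejected, not approximated.
- The pipeline consumes trajectories; it does not run or resume MD, and
  replica-exchange bookkeeping is upstream of all inputs.
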