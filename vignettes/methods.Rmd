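---
title: "Methods: longitudinal connectome remodeling with connremod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal connectome remodeling with connremod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis model

connremod analyzes cohorts of subjects scanned at three timepoints — t0
before surgery, t1 and t2 after — and asks, per connection, per region and
per network, whether connectivity changed in the early (t0–t1) or late
(t1–t2) interval. Its connectivity measure is the connection weight (CW):
tractography streamlines filtered by a microstructure-informed convex model
each carry a signal contribution; a streamline's weight is

    w = contribution × length / mean length of its bundle,

where a *bundle* is the set of streamlines joining one unordered pair of
gray-matter labels, and the CW of a connection is the sum of its bundle's
streamline weights. Two exact identities follow and serve as test oracles:
aggregation is linear in contributions at fixed bundle mean length, and a
bundle of n streamlines with equal contributions c has CW = n·c regardless
of its length distribution.

Surgical cohorts need extra bookkeeping, which this package treats as
contracts rather than conventions:

- **Timepoint-invariant parcellation.** The two postoperative cavity masks
  are merged (voxel-wise union, capturing cavity remodeling) and label
  portions under the merged mask are excluded identically at every
  timepoint; `apply_filter_to_timepoints()` *verifies* that the retained
  label sets agree and raises an error otherwise, because a divergence
  means a registration/mapping bug upstream.
- **Per-subject masks.** Masks are never pooled across subjects; each
  resection is tailored, and pooling would discard peri-resection tissue
  in subjects with small resections.
- **Side-flipping.** Left-focus subjects are mirrored through the
  homotopic label pairing (L### ↔ R###; midline labels fixed) so the
  surgical hemisphere occupies a common index block. The operation is an
  involution and preserves the entry multiset — both are asserted in the
  tests.
- **Group prevalence threshold.** A connection is removed everywhere if
  its CW is zero in ≥ 10 % of subjects at t0 (an edge zero in exactly 1 of
  10 subjects is removed — the boundary is inclusive).

## Graph-theoretic conventions

The underlying study names its measures but not their weighted variants,
so the following conventions were chosen, all standard in the
connectivity-toolbox tradition, and all validated against brute-force
enumeration oracles (simple-path enumeration, triangle enumeration,
all-pairs shortest paths) on ≥ 500 random graphs of ≤ 6 nodes to 1e-9:

- **Lengths.** Path-based measures traverse lengths = 1/weight; absent
  edges are unreachable (infinite length).
- **Betweenness.** Weighted Brandes with fractional splitting of tied
  shortest paths, normalized by (n−1)(n−2)/2.
- **Clustering.** Onnela geometric-mean form on weights normalized by the
  graph maximum; degree < 2 scores 0. This makes clustering invariant to
  global weight rescaling.
- **Local efficiency.** Global efficiency of the neighbor-induced subgraph
  with inherited weights (the simpler Latora–Marchiori style rather than
  harmonic variants); < 2 neighbors scores 0.
- **Characteristic path length.** Mean over *connected* ordered pairs,
  with a warning when the graph is disconnected (masked clinical networks
  can fragment). Global efficiency needs no convention (unreachable pairs
  contribute 0).
- **Small-worldness.** σ = (C/⟨C_null⟩)/(L/⟨L_null⟩) with C the mean
  Onnela clustering and L the CPL; the null ensemble is 100
  Maslov–Sneppen degree-preserving rewirings (10 attempts per edge) with
  the original weight multiset randomly reassigned to the rewired edges.
  All parameters and the seed are explicit; a complete equal-weight graph
  yields σ = 1 exactly because the ensemble equals the graph.

## Permutation inference

All tests are paired t-tests (t = mean(d)/(sd(d)/√n), sample sd) with a
sign-flip permutation null: flipping a subject's difference sign is
equivalent to exchanging its two observations. Tests are two-sided; each
edge/node/measure draws its permutations from an RNG substream derived
from (seed, unit id), so results do not depend on evaluation order.

Two p-value conventions are supported:

- `add_one = TRUE` (default): p = (1 + hits)/(1 + n_perm). Guarantees
  p > 0, appropriate for downstream FDR machinery.
- `add_one = FALSE`: the plain permutation-distribution proportion
  hits/n_perm, which is what the classical description — comparing the
  observed t against the null distribution built from the permutations —
  computes.

The distinction matters at n = 10. The exhaustive sign-flip distribution
has 2^10 = 1024 patterns, so the smallest attainable two-sided p is
2/1024 ≈ 0.00195 (the identity and its negation always tie the observed
statistic). Consequences worth understanding before interpreting results:

- With sampled permutations and add-one, p ≤ 0.001 requires zero sampled
  hits, an event with probability ≈ 3×10⁻⁴ even for an infinitely strong
  effect; a p ≤ 0.001 threshold under this convention is close to
  unattainable by design, and Benjamini–Hochberg rejection at q ≤ 0.05
  needs more edges at the floor than sampling typically produces.
- `exhaustive = TRUE` enumerates all 1024 patterns at the same cost as
  1000 samples, yields the exact floor, and makes BH recovery behave as
  the effect sizes deserve. It is the recommended mode for n ≤ 12.

Degenerate samples have explicit conventions rather than silent NaNs: an
all-zero difference vector gives (t = 0, p = 1); a zero-variance nonzero
difference gives t = ±Inf with the null evaluated under the same
convention (only all-same-sign patterns tie), with a warning.

The early-vs-late interval analysis computes per-subject |CW_t1 − CW_t0|
and |CW_t2 − CW_t1| per supported edge (i < j only), tests them as a
paired sample (the paired test requires per-subject quantities; the
cohort-averaged magnitudes are also reported for plotting), and flags
which interval dominates. The lateralization analysis classifies every
supported edge by hemisphere (both endpoints surgical side → ipsilateral;
both contralateral → contralateral; mixed → commissural; any midline
endpoint → unclassified and excluded), takes the direction of every
retained edge — significant or not — as the sign of the cohort-mean paired
difference, and runs a chi-square test of independence (no continuity
correction) on the 2×2 hemisphere-by-direction table plus a goodness-of-fit
test of the increase counts against a 50/50 split. Expected counts below 5
warn but do not fail.

## The synthetic generator: what it emulates and what it does not

No public data accompany the study design, so `generate_cohort()` builds a
self-contained cohort with the statistical structure the analysis assumes:

- **Parcellation.** `regions_per_hemisphere` (default 20; 124 reproduces
  the full-scale dimensionality) contiguous voxel blocks per hemisphere
  plus `n_midline` basal labels (brainstem analogue) on a 24³ grid, with
  the 6 most central blocks per hemisphere tagged insular. Homotopic
  pairs share block geometry mirrored in x.
- **Baseline.** Log-normal CW (log-mean 0, log-sd 0.5) on a cohort-level
  support; `frac_structural_zeros` (default 0.15) of edges are absent.
  Structural zeros are drawn *once per cohort*, not per subject: they
  model shared anatomy, and independent per-subject zeros at 15 % would
  empty the 10 %-prevalence support almost entirely at n = 10.
- **Planted effects.** Defined once in canonical (right-focus)
  orientation so cohort-level paired tests can recover them after
  side-flipping: decreases (factor 0.6) on ipsilateral edges (70 % of the
  planted set), increases (factor 1.5) on contralateral and
  peri-resection edges, where peri-resection labels are those 6-adjacent
  to the canonical insular block but not inside it. Early effects apply
  between t0 and t1, late effects between t1 and t2, both before
  multiplicative log-normal noise (log-sd 0.15 per transition). A factor
  of exactly 1 is no effect and never enters the ground truth.
- **Effect-size calibration.** The study reports no effect sizes, so the
  defaults are free parameters chosen once so that recovery is neither
  trivial nor hopeless: with these values planted edges reach the
  exhaustive permutation floor while unplanted edges stay calibrated, as
  the acceptance suite measures. They are the package's choices, not
  estimates from the study.
- **Focus sides.** Exactly round(frac_left_focus·n) subjects are
  left-focus (default 4 of 10, matching the emulated cohort), with the
  assignment order randomized; an i.i.d. draw would make the flip count
  itself random and was rejected for test stability.
- **Masks.** Two overlapping, non-identical random boxes around the
  focus-side insular centroid per subject, clipped to the focus half,
  allowed to nibble one voxel into neighboring labels so partial label
  exclusion is exercised.
- **Streamlines.** Each supported connection becomes a bundle of 3
  records with random lengths, equal contributions (so aggregation
  rebuilds the target matrix exactly by the n·c identity) and endpoint
  voxels sampled inside the endpoint labels.
- **Determinism.** Every random draw derives from the master seed through
  named substreams (one per subject, per mask, per analysis unit), so a
  cohort is bit-identical under reruns and stable under changes to
  n_subjects.

The generator does **not** emulate: diffusion signal, fODFs or tractogram
geometry (endpoints are bookkeeping only); registration (all mappings are
identity in synthetic voxel space); spatially correlated noise between
neighboring edges; subject-level covariates influencing connectivity.
A green recovery test therefore establishes that the *pipeline* detects
multiplicative CW changes of the documented size under log-normal noise —
not that any particular biological effect is detectable in real data.

## Numerical and design choices

- Partially resected labels are retained while ≥ `min_retained_voxels`
  (default 1) voxels survive, with the excluded fraction reported; the
  source methodology excludes "portions" of labels without stating a
  drop rule, so the permissive default preserves peri-resection labels
  and stricter policies can be layered on.
- Bundle mean lengths are computed after removing zero-contribution
  streamlines (`drop_zero_before_mean = TRUE`); the upstream convention
  is unstated, so the alternative is one flag away.
- Matrices keep the full P×P grid with masked entries zeroed (plus the
  boolean support mask) instead of deleting rows, so label indexing is
  stable across stages.
- Tie comparisons in permutation counting use a relative 1e-12 tolerance;
  exact ±identity ties are exact in floating point because sign flips
  commute with the arithmetic.
- Reported summary statistics round half away from zero to one decimal;
  the packaged clinical table's age column yields 32.8 ± 8.6 by
  computation, which the emulated report prints as "32 ± 8" — the
  computed values are reported and the discrepancy documented rather than
  forced.
- NIfTI-1 volumes are read/written by a minimal built-in implementation
  (uncompressed .nii, identity affine, int32/float64), since no NIfTI
  package is assumed; the writer is validated against an independent
  reader in the test suite.

## Limitations

- At n = 10 the permutation resolution bounds every p at 2/1024; FDR
  behavior across thousands of edges is dominated by this floor, and the
  package deliberately exposes both p conventions and the exhaustive mode
  so users can see the discreteness instead of being surprised by it.
- Realized false-discovery proportions on a single cohort fluctuate
  around the BH-controlled expectation; single-seed FDP values above the
  nominal q are possible and expected.
- The lateralization chi-squares treat edges as independent observations,
  as in the emulated analysis; edges sharing a node are not independent,
  so those statistics are descriptive rather than strictly inferential.
- Small-worldness requires a connected graph and ≥ 4 nodes; the global
  comparison reports NA for scopes where the null ensemble is undefined.
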