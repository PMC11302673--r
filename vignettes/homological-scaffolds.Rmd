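---
title: "Persistence homological scaffolds and aperiodic spectral dynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Persistence homological scaffolds and aperiodic spectral dynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(homscaffold)
```

## The question the package addresses

Functional connectomes — matrices of Pearson correlations `r` between
regional brain signals — carry structure beyond pairwise coupling: cycles of
regions whose mutual correlations form closed loops that are not filled in by
stronger chords.  Persistent homology quantifies such loops.  This package
implements a bimodal analysis that (i) summarises each region's participation
in the connectome's persistent 1-cycles as a *persistence centrality* (PC)
and (ii) asks whether task-evoked changes in PC covary, region by region,
with task-evoked changes in the *aperiodic* (1/f-like) part of
electrophysiological power spectra, particularly in the theta-alpha
(4–12 Hz) range.

## Topology chain

**Pseudo-distance.**  Each retained correlation is mapped to
`omega = 1 - r`; pairs with `r <= 0` are excluded outright, i.e. they are
absent from every complex in the filtration rather than being given distance
1.  Treating `r = 0` as absent is a deliberate choice: a zero correlation
carries no coupling evidence, and giving it `omega = 1` would create spurious
ties with the exclusion boundary.

**Flag filtration.**  The Vietoris–Rips (flag) complex is built to dimension
2: all vertices at birth 0, retained edges at their `omega`, and every
triangle whose three edges are retained, born at the maximum of its edge
births.  Simplices are ordered by (birth, dimension, lexicographic index) —
a deterministic tie-break that makes barcodes invariant to relabelling up to
the same permutation.  Only H1 is analysed, so tetrahedra are never needed:
a triangle can kill a 1-cycle but a tetrahedron cannot.

**Barcode.**  H1 persistence pairs over Z/2 are computed by column reduction
of the triangle boundary matrix, compressed to creator edges (edges whose
insertion closes a cycle, found by union–find).  Each pair gives an interval
`[b, d)` with persistence `pi = d - b`.  Zero-persistence pairs — the
"apparent" pairs that dominate flag filtrations, where a triangle is born at
the same value as its maximal edge — are discarded: they contribute nothing
to scaffold weights.  Creator edges never killed (possible because
negative-correlation exclusion can leave cliques unfilled) are reported as
infinite intervals, counted, and excluded from scaffolds.

**Volume-optimal cycles.**  A barcode interval does not come with a canonical
cycle; the package follows the volume-optimal formulation: among 2-chains
`tau` of triangles present at the death time that contain the death triangle
and whose mod-2 boundary lies in the birth-time complex, find one minimising
the number of triangles.  The boundary of the optimum is the reported
persistent cycle — the tightest wrapper of the hole.  Working over Z/2 makes
cycles plain edge sets and the optimisation a 0/1 problem.

The solver exploits three exact reductions before optimising: (i) by the
flag property a triangle born at or before `b` has no constrained edge and
can only add volume, so candidates are triangles born in `(b, d]`; (ii) only
the death triangle's connected component of the constrained-edge incidence
graph matters; (iii) unit propagation (a constrained edge covered by exactly
one remaining candidate forces that candidate).  The residual GF(2) affine
system is then solved exactly: by Gray-code enumeration over its kernel when
that is small, and otherwise by an iterative-deepening search that grows the
chain from the forced set, always branching over the triangles covering a
currently odd-parity edge, with the admissible bound `ceil(violated / 3)`
(each triangle flips at most three constrained edges).  The first depth at
which a solution appears is the exact optimum.  A real-valued l1 linear
programming relaxation (the classic approach to this problem) is kept as a
fallback for instances the search declines; its solution is accepted only
when it is integral, its support is feasible over Z/2 and its support size
matches the LP objective — which certifies optimality.  In the simulated
studies shipped with the package the exact combinatorial paths handle
essentially every instance; the LP is a safety net, not the workhorse.
`brute_force_optimal_cycle()` (exhaustive enumeration, capped at 20
candidate triangles) is retained as an independent oracle and is compared
against the solver in the test suite.

**Scaffold and PC.**  The persistence homological scaffold weights each edge
by the summed persistence of every optimal cycle through it,
`w_ij = sum over cycles g containing (i,j) of pi_g`.  Scaffolds are averaged
across subjects per condition, and `PC(i) = sum_j w_ij / sum_{j,k} w_jk`.
The denominator is read as the ordered-pair sum (each undirected edge counted
twice): only this reading makes PC a probability-like vector with
`sum_i PC(i) = 1`, and it matches the identical construction of degree
centrality `DC(i) = sum_j r_ij / sum_{j,k} r_jk`.  PC is computed on the
group-averaged scaffold (the pipeline's default, following the processing
order of the source analysis); a per-subject route is available through
`topology_from_fc()` for variance estimates.  For DC the sums run over the
retained positive entries — the graph actually analysed topologically; a
flag (`include_negative`) restores raw signed sums.

## Spectral chain

**Welch.**  One-sided PSDs from 2-second Hann windows with 1-second hops
(50% overlap), density-normalised so the spectrum integrates to the signal
variance.  The "1-second overlap" of the reference pipeline is read as 50%
of the 2-s window.

**IRASA.**  For each resampling factor `h` (default `seq(1.1, 1.9, 0.05)`,
the method's published default), the signal is resampled by `h` and `1/h`
(Fourier resampling), the Welch spectra of the pair are geometrically
averaged — scale-free `1/f^chi` spectra are fixed points of this operation,
while narrowband peaks are displaced and suppressed — and the aperiodic
spectrum is the median across factors.  The periodic spectrum is
`total - aperiodic`, exactly, so additivity is bit-exact; it may be negative
pointwise.  Spectra are estimated over 1–120 Hz (truncated at Nyquist with a
warning if `fs < 240` Hz) and analysed over 1–90 Hz.  Resampled lengths are
rounded to 5-smooth FFT sizes; this perturbs each factor by well under 1%,
and since the up/down pair is kept reciprocal the fixed-point property of
power laws is preserved.

**Band power ratios.**  `BPR(region, band)` is the trapezoidal integral of
the chosen component (aperiodic by default) over the band divided by the
integral of *total* power over the full 1–90 Hz analysis band.  The
full-band total denominator makes band ratios comparable across regions and
conditions and bounds a partition's ratios by 1; an aperiodic-only
denominator is available (`denominator = "aperiodic_fullband"`), and setting
`component = "periodic"` reproduces the periodic-control analysis.  Band
schemes: canonical (delta 2–4, theta 4–8, alpha 8–12, beta 12–25, gamma
25–90 Hz) and 32 log-spaced bands over 2–90 Hz; the headline theta-alpha
band is 4–12 Hz, the union of theta and alpha.

## Statistics

Task-minus-rest differences (Delta PC, Delta DC, Delta BPR) are compared by
cosine similarity per frequency band.  The band-wise |cosine| curves for PC
and DC are compared with a cluster-based sign-flip permutation paired t-test:
per band, a paired t across task conditions; clusters are maximal contiguous
runs of bands with `|t|` above the two-sided threshold at `p = 0.05` (the
cluster-forming threshold is a free parameter; 0.05 is the conventional
default); cluster mass is the sum of t in the run; the null flips the sign
of whole condition-level difference vectors.  With `n <= 12` paired
conditions all `2^n` flips are enumerated — at the design's eight task
conditions the attainable two-sided p-values are multiples of 1/256 with
minimum 2/256 = 0.0078125 — otherwise a seeded Monte Carlo sample is used
with the observed flip included.  Each cluster is tested against the
max-cluster-mass null (familywise control, standard cluster-permutation
practice).  Kendall's tau-b (via `stats::cor.test`) relates resting PC to
each Delta PC; Mann–Whitney U (exact Wilcoxon distribution without ties for
`n*m <= 400`; exact midrank enumeration with ties when `C(n+m, n) <= 2e5`;
tie-corrected normal approximation beyond) serves distributional
comparisons.  Angular differences are `acos` of cosines; within-kind angle
distributions across conditions are computed as all pairwise angles, an
interpretation choice where the source is not fully explicit.

## Synthetic data: what it emulates, and what it does not

The generator produces paired datasets with the statistical structure the
analysis assumes:

* **BOLD-like** series are multivariate Gaussian draws whose correlation
  matrix plants rings: consecutive regions on a ring correlate strongly,
  chords weakly, so the empirical connectome contains an H1 feature whose
  optimal cycle is the ring.  A requested ring structure is projected to the
  nearest positive semi-definite correlation matrix (eigenvalue clipping and
  diagonal rescaling) — necessary because a circulant with nearest-neighbour
  correlation above 0.5 and near-zero chords is not a valid correlation
  matrix; the projection preserves the ring-above-chord ordering that the
  topology consumes.  No hemodynamic convolution is applied: the topology
  chain consumes only Pearson correlations, so realism beyond the
  correlation structure would be untestable decoration.
* **Task modulation** changes within-ring correlations between rest and
  task (one ring strengthens, one weakens by default), planting a PC change
  of known sign `m_i` per region.  A *degree confound* — a block of regions
  whose mutual correlations rise uniformly under task — moves DC strongly
  while contributing no persistent cycle (cliques fill immediately in a flag
  complex) and no spectral coupling.  This dissociates Delta DC from
  Delta PC, emulating the empirical observation that degree changes are
  task-specific while cycle-participation changes are not; without it,
  planted rings would move both centralities identically and the PC-vs-DC
  contrast would be undefined.  The magnitude of task-evoked connectivity
  change is a free parameter of the generator (the source analysis does not
  state one).
* **MEG-like** series are sums of three independently generated components
  per region: spectrally shaped Gaussian noise with target PSD proportional
  to `f^-chi` (exact power law in expectation, enabling tight
  exponent-recovery tolerances), Gaussian-profile narrowband oscillators
  (identical across conditions, so the periodic component carries no planted
  effect and the periodic-control analysis comes out null), and a white
  noise floor (sd 0.001 in shaped-amplitude units, small enough not to bias
  slopes up to 90 Hz at `chi = 3`).  Under task, each modulated region's
  exponent is offset by `-delta_chi * coupling_strength * m_i`.  The sign is
  analytic, not conventional: with BPR defined against full-band total
  power, a *smaller* chi concentrates relatively more aperiodic power in
  4–12 Hz (a steeper slope moves mass below 4 Hz), so decreasing chi raises
  theta-alpha BPR.  `coupling_strength = 1` plants the covariation;
  `coupling_strength = 0` is the null study used for type-I control.
* **Seeding.**  One master seed; every (subject, condition, component)
  stream derives its own seed from it, so regenerating any subset is
  bit-reproducible and subjects are independent.

What passing tests on these data do *not* show: robustness to hemodynamic
filtering, source-leakage correlations between regions in the spectral
modality (regions are spectrally independent here), non-Gaussian or
non-stationary signals, and atlas geometry.  Results on real recordings
depend on those factors; the synthetic study validates the machinery, not
the neuroscience.

## Default study conditions and problem sizes

The default `synthetic_study_config()` mirrors a small simultaneous-cohort
design: 10 subjects, 30 regions, one resting plus eight task conditions
(four motor, four working-memory), 400 BOLD samples, and 12 s of MEG-like
signal at 250 Hz (the minimum supporting stable 2-s Welch segments, chosen
to keep a full multi-seed study affordable on a single CPU; the spectral
validation studies use 60 s at 500 Hz where estimator tolerance matters).
The study-level IRASA uses `hset = seq(1.1, 1.9, 0.2)` — five factors
instead of seventeen — a variance/compute trade-off adequate for band-
integrated ratios; `irasa()` itself defaults to the published factor set.
The planted rings use within-ring correlations 0.35/0.65 (rest/task,
reversed for the second ring) with chords at 0.1, and the degree confound
block moves 0.15 to 0.45.  At these sizes a full nine-condition study runs
in roughly 20 s, and the twenty-seed planted plus twenty-seed null
validation in the test suite completes within its budget.

## Numerical choices and degenerate inputs

* Exact equality of birth and death (`b = d`) discards a pair; no epsilon is
  involved because births are copied, not recomputed.
* Perturbing all `omega` by less than half the minimum gap between distinct
  values provably preserves every pairing's identity; the test suite checks
  this.
* Constant regional series and NaNs are rejected with the region named;
  all-nonpositive connectomes make DC undefined and raise; all-zero
  scaffolds make PC undefined and raise.
* Zero Delta BPR vectors (possible in a null band) contribute cosine 0
  rather than an error inside `compare_modalities()`.
* `t` statistics with zero variance across conditions are mapped to 0 in
  the cluster test; the permutation comparison uses a relative tolerance so
  the observed flip always counts (the exact-test minimum p is attained, not
  undercut).
* Infinite H1 intervals are counted and logged by the pipeline
  (`counts$infinite_dropped`) and excluded from scaffolds.

## Known limitations

* H2 and higher homology are out of scope (max dimension 2); no cohomology,
  no approximate Rips schemes.
* The volume-optimal search is exact but worst-case exponential; the
  iterative-deepening fallback carries a node budget and the package raises
  a diagnostic error rather than silently returning a suboptimal chain if
  every strategy declines (not observed in the shipped study sizes).
* Scaffold variants that count cycles instead of summing persistence, edge
  thresholding of scaffolds, and spectral peak-model fitting are
  deliberately not implemented.
* The pipeline ingests plain matrices (TSV) only — no neuroimaging
  containers.
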