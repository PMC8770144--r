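---
title: "Processing sparse serial still diffraction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing sparse serial still diffraction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smsfx)
```

## The problem

Serial femtosecond crystallography of small-molecule and hybrid materials
delivers a stream of still snapshots: each XFEL pulse hits one randomly
oriented microcrystal, and the crystal is destroyed before it can be
rotated. Two features separate this regime from both macromolecular serial
work and conventional single-crystal diffraction:

* **Sparsity.** Small unit cells put few reciprocal-lattice points near the
  Ewald sphere, so a typical hit frame carries only a handful (about 3–10)
  of reflections. Fourier-based autoindexing, which needs dozens of spots
  with visible periodicity, does not apply.
* **No shared orientation.** Every frame needs its own orientation matrix,
  and the unit cell is initially unknown.

`smsfx` implements the processing chain for this regime: a virtual powder
diffractogram aggregated over all shots for unit-cell determination,
figure-of-merit and indexing-rate ranking of candidate cells, per-frame
indexing by a maximum-clique consistency search, and merging with two-step
reference scaling, indexing-ambiguity resolution and systematic-absence
statistics. A seeded forward simulator generates still datasets with known
ground truth so that every stage is testable without beamtime.

## Lattice arithmetic

All downstream stages consume the direct metric tensor $G$ built from the
six cell parameters ($G_{ij} = \mathbf{a}_i\cdot\mathbf{a}_j$), its inverse
$G^*$, and the Busing–Levy $B$ matrix with $B^\top B = G^*$. Volumes are
$\sqrt{\det G}$; $d$ spacings are $1/\sqrt{h^\top G^* h}$; a change of basis
with row matrix $P$ maps $G \to P G P^\top$. Angles are degrees at every
interface and radians internally.

**Metric pseudosymmetry.** An integer matrix $M$ with $\det M = \pm 1$
acting on Miller indices is a *pseudosymmetry (indexing-ambiguity) operator*
when it leaves the metric nearly invariant,
$\lVert M G M^\top - G\rVert_F / \lVert G\rVert_F \le \mathrm{tol}$,
without being a Laue operation. Such operators map the lattice almost onto
itself in an inequivalent setting: individual stills can index either way,
and a naive merge then looks pseudo-merohedrally twinned.
`find_pseudosymmetry_ops()` scans integer matrices (entries bounded by 2 by
default, configurable) with a per-row quadratic-form prefilter, and returns
one representative per left coset of the Laue group. The default tolerance
is 0.5 % relative Frobenius norm: larger than cell-parameter noise, smaller
than genuine symmetry breaks (a monoclinic $\beta - 90^\circ \approx 5^\circ$
corresponds to percent-level metric deviations). For the bundled monoclinic
C test lattice (5.938, 7.325, 29.202 Å, $\beta = 95.44^\circ$) the search
returns the operator $(-1\,0\,0 / 0\,{-1}\,0 / 1\,0\,1)$, whose metric
deviation is 0.48 % — which is why the default tolerance sits at 0.5 % and
why analyses of this lattice in the package use 1 %.

The canonical asymmetric-unit representative of an orbit is its
lexicographic maximum (comparing $h$, then $k$, then $l$), a fixed,
documented convention; Friedel inversion is always part of the Laue group
used for merging.

## The forward simulator

The simulator is the package's source of test data and defines the
conditions every property test runs under. It emulates: one crystal per hit
frame with a uniform random orientation (quaternion sampling); a top-hat
within-shot spectrum of fractional width 0.3 % (the natural XFEL SASE
bandwidth) around a per-shot central energy jittered by a Gaussian
(default fractional $\sigma$ = 0.1 %), with the central energy treated as
the measured per-shot value; mosaic crystals; lognormal per-frame scale
variation ($\sigma$ = 0.3); sub-pixel centroid noise (0.1 px);
multiplicative lognormal intensity noise (10 %); and blank frames
(hit fraction 0.9 — a desk-scale convenience; real serial hit rates are far
lower, which affects only how many frames must be simulated, not the
per-frame physics).

A reflection with lab reciprocal vector $\mathbf{x}$ ($q = |\mathbf{x}|$)
diffracts at wavenumber $w_B = q^2 / (-2 x_z)$ (beam along $+z$). It is
emitted when the *excitation distance* — its distance to the Ewald sphere of
the nearest in-band wavenumber — is within $q\,\eta/2$, where $\eta$ is the
mosaic full width (default 0.3°, typical of micron-scale crystals; this
default also calibrates the median spots-per-hit of the bundled monoclinic
configuration into the observed 3–10 band). The *effective recorded
wavelength* of a spot is the truncated-Gaussian mean of the in-band
wavenumbers weighted by the mosaic rocking curve: a spot integrates photons
across the whole band, it is not pinned to the band edge nearest its Bragg
condition. (Hard clamping would bias every harvested $d$ by half the
bandwidth and make histogram peaks bimodal.) The reciprocal point is then
projected onto that Ewald sphere before the detector projection, so still
geometry is exact: with zero bandwidth the harvested $d$ of every spot
equals a lattice $d$ to $10^{-6}$.

Partiality is a Gaussian in the angular offset from the exact Bragg
condition at the central wavelength, with width set by the mosaic half-angle
plus the bandwidth-equivalent angle $\sin\theta\cdot\Delta E/E/2$; a
reflection exactly on the sphere records the full $|F|^2$. Recorded
intensity is frame scale × partiality × $|F|^2$ × noise.

The toy structure supplying $|F|^2$ uses three independent point scatterers
weighted like Ag/Se/C, expanded through a twofold axis and the C-centring
translation. The expansion matters: it makes $|F|^2$ exactly invariant
under the $2/m$ Laue group used for merging and makes the centring absences
exact. Without it, merging would pool genuinely inequivalent intensities
and no merging statistic could reach high fidelity.

**What the simulator does not model:** SASE spectral spikes (the top-hat
band is a smooth surrogate), detector panel gaps and tilts, background and
pixel-level profiles, multi-crystal hits, radiation damage, and
detector-geometry error (the geometry is taken as known). Tests passing on
this simulator therefore demonstrate the correctness and calibration of the
*algorithms* under controlled still-diffraction physics, not robustness to
every instrumental pathology of real beamtime data.

## Virtual powder synthesis

Each spot is converted to a $d$ spacing using its own shot's measured
wavelength — this single step removes the shot-to-shot energy jitter that
would otherwise smear the aggregate. The $d$ values are histogrammed over
$q = 1/d$ (2000 uniform bins by default over the data range; uniform-in-$q$
keeps resolution-independent sharpening), giving a sharpened powder
diffractogram assembled from thousands of sub-pixel spot observations.
Peak picking automates the hand-selection of strong lines: local maxima
above 5× the median bin count, parabolic sub-bin refinement, top 20 by
height. Counts (not intensity) weighting is the default; weighting is a
flag. A Cu Kα $2\theta$ export supports overlay with laboratory PXRD.

## Candidate-cell scoring

Two figures of merit and one empirical test rank candidate cells:

* **de Wolff $M_{20}$** (with $Q = 1/d^2$):
  $M_{20} = Q_{20} / (2\,\langle|\Delta Q|\rangle\, N_{20})$, where
  $\langle|\Delta Q|\rangle$ is the mean distance of the first 20 observed
  lines to the nearest calculated line and $N_{20}$ counts distinct
  calculated lines out to $Q_{20}$. Perfect fits are capped at $10^4$ to
  keep rankings finite.
* **$M^*$**: the intensity-weighted total $d$-mismatch of the whole
  pattern divided by $M_{20}$,
  $M^* = \sum I \,\Delta d \,/\, M_{20}$, lower is better. $\Delta d$ is
  unsigned and computed on the $d$ axis; $I$ is per-bin counts (the sum
  runs over pattern points, not picked peaks).
* **Indexing rate**: the fraction of hit frames the sparse indexer solves
  with the candidate. The correct cell combines the top indexing rate with
  a low $M^*$; on simulated data it out-indexes axis-swapped, 3 %-stretched
  and half-volume distractors by well over the 1.5× margin used in the
  acceptance suite.

The built-in candidate generator is deliberately naive (a full
powder-indexing engine is external prior art): axis hypotheses are small
integer multiples of the picked peak $d$ values — sparse still statistics
essentially never sample the axis fundamentals directly, because the
single-digit-degree scattering angles involved have tiny Ewald-crossing
probability — combined per Bravais class inside a volume window, scored by
mean $|\Delta Q|$ times a de Wolff-style line-count penalty (without the
penalty, any over-dense large cell explains every peak), and refined by
*assignment least squares*: $Q(hkl)$ is linear in the reciprocal metric
coefficients, so alternating nearest-line assignment with an analytic fit
converges over a ~1–2 % basin, far wider than direct minimisation of the
line mismatch (whose basin is narrower than any practical grid). The
generator recovers a synthetic orthorhombic (6, 8, 10 Å) cell to 0.1 %;
its known limitation is that an axis whose length appears among no small
multiple of a picked peak cannot be proposed, which is why hand-supplied
candidate lists are first-class inputs and pass through verbatim.

## Sparse-frame indexing

Per frame: (1) every spot collects all lattice reflections (centring
allowed, full sphere) whose $d$ matches within 0.5 % relative; (2) nodes of
distinct spots are connected when the measured inter-spot reciprocal
distance $\lVert \mathbf{s}_i - \mathbf{s}_j \rVert$ agrees with the
metric-computed $|B(h_i - h_j)|$ within 0.0015 Å⁻¹ (both defaults bracketed
by the 0.3 % bandwidth plus centroid noise; measured $\mathbf{s}$ vectors
are taken on the per-shot nominal-wavelength sphere, the residual radial
scale error being absorbed by the pair tolerance); (3) an exact
branch-and-bound maximum-clique search (greedy-colouring bound, compiled)
finds the largest mutually consistent assignment set, breaking size ties by
the smaller summed mismatch, deterministically.

**Enantiomorph handling.** Pairwise distances are blind to a global Friedel
flip: the maximum clique is equally often the improper image of the real
assignment, which no proper rotation can fit. Both the clique assignment
and its global flip are therefore fit by orthogonal Procrustes against the
$B$-matrix vectors, and the proper-rotation fit wins. Omitting this step
halves the indexing rate — the failure mode is silent and size-independent.

After the clique fit, unassigned spots whose back-computed fractional
indices deviate from integers by less than 0.1 on every axis (the tight
small-molecule cutoff; 0.3 is the macromolecular default) join the
solution; the orientation is re-refined on all assigned spots with the cell
fixed (never refined), extension spots that degrade the fit are shed worst
first, and the solution is accepted if the rms reciprocal residual is below
0.003 Å⁻¹ (twice the pair tolerance — the residual floor is set by the
mosaic projection displacement $\approx q\eta/2$ plus the band's radial
scale error). Degenerate (collinear) cliques are rejected; a minimum of
3 non-collinear spots fixes a rotation.

For a pseudosymmetric lattice a fraction of frames indexes in the
twin-related setting. This is expected and unavoidable at the single-frame
level — the two settings differ by less than the tolerances — and it is
resolved at the merge stage. A twin-setting solution also carries the
operator's intrinsic metric strain (~0.4° for the bundled lattice) in its
fitted orientation; orientation-recovery comparisons in the tests are
therefore made modulo the full operator set, with the strain absorbed into
the equivalent target rotation.

## Merging

Observations carry both the raw (as-indexed) indices and their
asymmetric-unit reduction. Merging is two-step: first symmetry-equivalent
observations are averaged plainly; that set (or an external reference, such
as model intensities) then serves as a scaling reference, each frame
receiving a single multiplicative scale
$k = \sum I_\mathrm{obs} I_\mathrm{ref} / \sum I_\mathrm{ref}^2$ over its
reference-common reflections (minimum 3, frames below are dropped and
logged), and the scaled observations are re-merged. Iterating with a later
reference is a caller loop. No per-frame B factor or anisotropy is
modelled. Uncertainties are standard errors of the mean; reflections
measured once receive a flagged sentinel sigma of 50 % of $|I|$ (the SEM is
undefined and the error model is deliberately plain; a hook for weighting
variants exists). On synthetic data the SEM is consistent with half-dataset
splits within a factor 1.5, and end-to-end merged intensities correlate
with ground-truth $|F|^2$ at $r \ge 0.99$ once multiplicity reaches the
tens.

**Resolution cutoff.** Shells are equal-volume in $1/d^3$ (10 by default);
the chosen $d_\mathrm{min}$ is the most generous cutoff whose outer shell
has mean multiplicity inside 10–15, with a warning and nearest-achievable
fallback when no shell qualifies.

**Indexing-ambiguity resolution.** Each frame is scored under every
operator's remapping against the reference. The score is the negative
dispersion of $\log(I/I_\mathrm{ref})$ over common reflections: under the
correct setting this ratio is the frame scale times a bounded partiality,
under a wrong setting it inherits the full dynamic range of the
intensities. Plain Pearson correlation was considered and rejected: it is
degenerate at the 2–3 common reflections typical of sparse stills (with
two points it is exactly ±1). Ties resolve to the identity; frames with
fewer than two common reflections under every operator are left unchanged
and flagged — with one reflection the setting is undecidable in principle.
Frames consisting only of operator-invariant reflections (for the bundled
lattice, $h = 0$: one sixth of observations) are consistent under either
setting and count as resolved regardless of the operator chosen. A
deliberate 50/50 scramble of indexed synthetic frames is restored to a
single convention for ≥ 95 % of frames; in the noise-off limit with an
exact reference, restoration is complete.

**Systematic absences.** Reflection classes defined by a predicate on raw
indices (lattice-centring violations, glide classes) are tabulated with
counts and mean $I/\sigma$; a class with no observations, or mean
$I/\sigma$ below 2, is reported absent. The simulator emits no
centring-forbidden reflections, so injected violations are detectable
against a truly empty class.

## Problem sizes and numerical choices

The test and acceptance suites run, by design, at desk scale: 200–500
frames for calibration and ranking checks, 5000 frames (≈ 40× multiplicity)
for merging fidelity, 20 000 frames in the exact-Ewald (zero-mosaicity)
limit for orientation recovery — that limit emits well under one spot per
frame, which is the honest price of an exact-geometry test. Seeds fix every
stream end to end; the simulator restores the caller's RNG state.

Other fixed choices: $M_{20}$ ceiling $10^4$; calculated powder lines
merged at $10^{-5}$ relative; clique ties broken by summed pair mismatch;
assignment-node cap 350 per frame (worst $d$-mismatch hypotheses dropped
first); HKLF4 export errors on field overflow rather than silently
clipping (the pipeline's export stage rescales into range when needed).

## Known limitations

* The candidate generator is a stand-in, not a powder-indexing engine:
  axis lengths must appear among small multiples of picked peaks, and
  triclinic search is out of scope.
* Orientation recovery of twin-setting frames is limited by the
  pseudosymmetry operator's intrinsic metric strain; only the merge-stage
  resolution, not the indexer, can assign the global convention.
* Single-panel, gap-free detector geometry, taken as exact.
* Anomalous signal is a non-goal (Friedel pairs merge); no structure
  solution or refinement.
* One crystal per shot; multi-lattice frames are not indexed.
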