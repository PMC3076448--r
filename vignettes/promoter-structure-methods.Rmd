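---
title: "Methods: sequence-encoded DNA structure and AFM single-molecule analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence-encoded DNA structure and AFM single-molecule analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, conventions and numerical choices behind
`curvafm`, in the order the analysis runs: coordinates and sequence
handling, the helix-axis trajectory and the phasing-pitch supercoil scan,
duplex stability, the AFM image chain, and the synthetic generators that
provide ground truth.

## Promoter coordinates

Positions are counted relative to the transcription start site, +1, with
no position 0: a fragment spanning −869..+421 contains exactly
869 + 421 = 1290 bases. This is the only convention under which that
printed span closes, and all public functions speak it; internal arrays
are 0-based offsets (`promoter_to_offset()` / `offset_to_promoter()` form
a bijection, and −1/+1 are adjacent). Passing position 0 is an error, not
a silent shift.

A/T tracts are defined as *maximal runs of A/T* (IUPAC W) of at least 5 bp
by default. The threshold is a design choice: the verbal description of
the PRRII element (three tracts separated by 6 and 7 bp, the longest
19 bp) constrains but does not fix it, and a 5 bp floor with strict W-runs
reproduces that three-tract architecture while ignoring the scattered
2–4 bp runs any random sequence contains. IUPAC ambiguity codes are
rejected outright because both the wedge-angle and the nearest-neighbor
tables downstream are defined only over ACGT.

## Helix-axis trajectory

The double-helix axis is built step by step from a dinucleotide table
giving roll, tilt and twist (degrees) for each of the 16 steps, with a
fixed rise of 0.34 nm per step. The table ships as an editable TSV
(`inst/extdata/wedge_steps.tsv`) derived from the classical wedge-angle
set: each step's deflection is a wedge magnitude and direction, stored
pre-decomposed as roll = wedge·cos(direction), tilt = wedge·sin(direction).
Its mean twist corresponds to a helical repeat of ≈10.61 bp/turn.

**Rotation convention.** Per step the local frame is rotated by

  R = R_z(twist/2) · W · R_z(twist/2),

where W is a *single* rotation by the wedge angle √(roll² + tilt²) about
the in-plane axis with rotation vector tilt·x̂ + roll·ŷ, and the next
point lies 0.34 nm along the direction bisecting the incoming and
outgoing helix axes. Applying tilt, roll and twist as three sequential
rotations with the translation along the pre-step axis — the more obvious
construction — is *not* exactly symmetric under reverse complementation:
the non-commutativity terms leave a rigid-motion residual of order 0.1 nm
over a few hundred base pairs. The mid-step convention adopted here makes
the trajectory of the reverse complement superimpose on the reversed
trajectory to numerical precision (RMSD < 1e−6 nm in the tests) whenever
the table obeys complement symmetry, while keeping consecutive points
spaced exactly one rise apart. The group-theoretic reason: conjugation by
a 180° rotation about the local x-axis maps the inverse step rotation
onto the step rotation of the complementary dinucleotide, but only when
the wedge acts as one rotation sandwiched between half-twists.

**Phasing-pitch override.** The supercoil scan rescales all 16 twist
values by the single factor (360/pitch)/mean(native twist), preserving
the sequence-dependent twist modulation; at the native repeat the factor
is exactly 1, which gives a clean regression test. The alternative —
replacing every twist by 360/pitch — flattens the modulation and shifts
peak pitches by a fraction of a base pair; either convention is
defensible, so the one with the exact identity was chosen. Overrides are
accepted in 4..20 bp/turn.

The 0.36 nm/bp figure is deliberately *not* used in the trajectory: it is
the image-calibration constant for converting AFM contour lengths to base
pairs, kept global and not configurable per molecule.

## Ends ratio, curvature map, supercoil calls

The Ends ratio of a window is contour length over chord length: exactly 1
for a straight segment, π/2 for a semicircle, and arbitrarily large as a
window closes on itself. Defaults are a 150 bp window at a 1 bp step;
values are reported at window centers with no edge padding (no curvature
is fabricated at molecule ends), and windows that do not fit yield an
empty profile with a warning. Theoretical trajectories are measured with
the 3D chord; AFM traces with the 2D chord on the surface. The statistic
is invariant under rigid motions and uniform scaling, which the tests
assert directly.

The curvature map evaluates the profile over a pitch grid of 5–15 bp/turn
at 0.5 bp steps — finer than integer steps so a peak near 7.5 bp/turn is
resolvable at all.

**Supercoil calling.** A call requires a 2D local maximum of the map that
(i) lies at least 1.5 bp/turn away from the canonical 10.5 bp/turn row,
(ii) reaches an absolute Ends ratio of 2, (iii) exceeds the same-center
value in the canonical row by a factor of 2, and (iv) stands at least
0.05 above its row's median. The amplitude floor deserves a note: random
sequences carry substantial intrinsic curvature, and a null study over
seeded random 976 bp fragments (see the control test) shows map maxima
routinely in the 1.3–2.2 range across all pitches. A floor just above 1
would therefore fire on essentially every molecule; the floor of 2
combined with the canonical-contrast requirement keeps the false-call
rate on random controls at the few-percent level while phased-tract
signals (amplitudes 3–18 in the tests) pass with a wide margin. Two
suppression rules keep one physical structure from being reported twice:
a weaker same-handed maximum within half a window of an accepted call is
the same structure leaking into neighboring pitch rows, and a weaker
maximum at *half* an accepted pitch in the same region is the phasing
harmonic (tracts recurring every second turn also phase-align there — a
genuine planar signal, but not a second supercoil; the doubled pitch is
not suppressed because tracts then alternate helical faces and cancel).
Handedness is purely the phasing rule: peak pitch below canonical ⇒
left-handed (negative), above ⇒ right-handed (positive).

The curvature apex is the center of the profile's global maximum, ties
broken toward the 3′ end so that a flat profile has a well-defined,
documented answer.

## Duplex stability

Stability profiles use the unified Watson–Crick nearest-neighbor set (10
unique stacked pairs expanded to all 16 dinucleotides by complement
symmetry; `inst/extdata/nn_unified.tsv`), evaluated at 25 °C from ΔH and
ΔS (ΔG = ΔH − T·ΔS) rather than read from a 37 °C table, because 25 °C /
1 M NaCl / pH 7 is the stated analysis condition and 1 M NaCl is exactly
the table's reference state, so no salt correction is applied. The window
statistic is the *mean* step ΔG (kcal/mol per step), which keeps windows
of different lengths comparable; a window-sum variant is available via
`statistic = "sum"` since a stability plot's units are ambiguous without
axis labels. Initiation terms are tabulated but not applied inside
sliding windows — they belong to whole-duplex formation, not to a window
of an intact duplex. Strand symmetry (the profile of the reverse
complement is the mirrored profile) holds to 1e−12 and is asserted over
whole sequences.

## AFM image chain

The pipeline is: per-line second-order polynomial flattening (background
mask iterated to convergence; a fully masked line falls back to a
whole-line fit) → light Gaussian blur (σ = 1 px) for geometric stability
→ threshold → morphological closing and small-hole filling → connected
components → Guo–Hall thinning → spur pruning → path tracing → sub-pixel
refinement → end placement → height read-out.

Numerical choices that matter, and why:

* **Height threshold 0.5 nm** sits between the noise SD (~0.3 nm) and the
  double-helix height (0.8–1.2 nm). The *mask* is cut at 0.6× that value
  on the blurred field: blurring lowers ridge crests to ~0.67 of nominal,
  and because blurred noise is spatially correlated, threshold dips come
  in multi-pixel patches that would sever the ridge if the margin were
  less than several blurred-noise SDs.
* **Guo–Hall thinning** rather than the simpler two-pass scheme: the
  latter leaves two-pixel diagonal staircases that read as junction
  chains and make paths untraceable at ~45° orientations.
* **Small-hole filling (≤ 25 px)** before thinning: an enclosed noise
  dropout thins to a ring, which has no endpoints to trace from. Large
  enclosed regions are genuine loop interiors and are kept.
* **Spur pruning with end-of-path protection.** Branches of ≤ 6 px ending
  at a junction are noise spurs — except when the junction terminates the
  main path, where a spur right at a molecule end splits the true tail
  into a *second* short branch. Junction pixels cluster at thick nodes,
  so candidates are grouped by junction cluster; if the cluster has at
  most one long continuation, the longest short branch is the tail and is
  kept. Continuations are counted as 8-connected *groups* of neighbor
  pixels, since a thinning triangle otherwise counts one path twice.
* **Crossing traversal.** At junctions the trace continues in the
  direction of minimal turning angle, and every pixel-to-pixel edge is
  used at most once, so both passes of a self-crossing are traversed.
* **Sub-pixel refinement** moves each path point to the height-weighted
  centroid along the local perpendicular; without it, contour lengths at
  2 nm/px are quantized.
* **End placement at 0.75× crest.** A blurred ridge end decays smoothly;
  on noiseless renders the field directly over the true molecule end
  measures ≈ 0.8 of the interior crest, and 0.75 trades a fraction of a
  pixel of systematic overshoot for robustness to noise dips. Ends are
  first trimmed back above that level, then extended out to it along the
  end tangent.

With these choices the rod-length invariant (error < 5% on straight test
molecules of 100–350 nm at arbitrary orientation, noise SD 0.3 nm) holds
with a median error well under 1%.

**Orientation** resamples the measured height profile to the model length
and takes the Pearson correlation against the sequence-derived signal
(smoothed local twist, standardized) in both orientations. The winner
must beat the loser by 0.1 in correlation; otherwise the molecule stays
unoriented and is excluded from positioning statistics. Molecules whose
measured length differs from the model by more than 15% are refused with
a reason rather than force-fitted.

**Positioning.** The dyad formula `Lc = L − (L₊+L₋)`, `dyad = L₊ + Lc/2`
is applied with arms measured from the trace as the contour outside the
particle region (height ≥ 1.8 nm, i.e. above the helix and below particle
tops); because the particle is symmetric around the wrapped segment, the
radius it hides cancels out of the dyad estimate. Proteins are the most
prominent local maximum of the (7 bp-smoothed) height profile at least
0.4 nm above the profile median. Loops are found as the closest pair of
contour-distant (≥ 50 bp) passages within 4 nm; the reported middle point
is the *contour* midpoint of the enclosed segment, with the geometric
apex available via `midpoint = "apex"` since published "middle points"
could be read either way.

## Synthetic generators

The generators define the study conditions rather than adapt to them:
molecules are 2D-equilibrated worm-like chains (Gaussian tangent
increments of variance segment/persistence, the convention under which
tangent correlations decay as exp(−s/2Lp); persistence 50 nm), ridges
render at the 0.8–1.2 nm double-helix height with ~2 nm Gaussian
cross-section, self-crossings add and clip at 1.6 nm to match the
observed summit range without modelling tip physics, noise is additive
Gaussian with SD 0.3 nm, and tip broadening is an optional Gaussian blur.
The bundled promoter-like construct spans −869..+421 and embeds, on a
seeded random background: the PRRII three-tract cluster (19, 8 and 9 bp
W-runs separated by 6 and 7 bp of G/C), a 7.5 bp-phased A-tract cassette
flanking it (encoding the left-handed superhelix), a 13.5 bp-phased
cassette upstream (the right-handed one), a 10.5 bp-phased cassette
around the TSS (canonical planar curvature), and the TACTTAAA TATA box at
−48. It is a synthetic stand-in assembled from the verbal description of
the real element, not the real sequence — analyses that need the actual
promoter accept any FASTA via `read_fasta()`.

What the generators do *not* emulate — tip-sample mechanics, scanner
drift and creep, molecule–surface electrostatics, sequence-dependent
flexibility — bounds what passing tests show: they validate the
measurement chain on idealized but noisy images, not the microscope.

## Problem sizes and runtime choices

The test suite uses 976–1290 bp sequences for sequence-side checks, 100
random-window oracle comparisons per statistic, 40 seeded random controls
for call specificity, 300 chains for worm-like-chain recovery, and
8–12 rendered images per mapping check; the acceptance checks scale the
image studies to ~100 rendered molecules and 1000 chains. These sizes
keep every statistical assertion comfortably powered (medians over ≥ 20
successful mappings, binomial margins of several SDs) while the whole
suite stays fast enough to run on every change.

## Known limitations

* Per-line flattening cannot preserve a molecule lying *along* a scan
  line over more than half its width — a known artifact of the method
  itself, not of this implementation.
* The skeleton tracer resolves plain crossings; molecules with multiple
  interleaved crossings or contour-length self-overlap (plectonemes) are
  beyond it and surface as length mismatches at orientation.
* Loop detection assumes one dominant loop; two loops sharing a crossing
  region return only the closest-passage pair.
* The trajectory model is rigid: no thermal fluctuations, no elastic
  relaxation, no writhe bookkeeping. Its supercoil calls are statements
  about sequence-encoded *intrinsic* geometry, not about the topology of
  a constrained molecule.
* The wedge-angle and nearest-neighbor tables are point estimates;
  swapping in alternative tables (both ship as TSV) shifts peak pitches
  and ΔG levels by small amounts, and peak positions near 7.5 bp/turn are
  convention-dependent at the ±0.5 bp level.
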