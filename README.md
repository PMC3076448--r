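# curvafm

Structural analysis of promoter DNA from sequence and from AFM images:
intrinsic curvature and sequence-encoded supercoiling, duplex stability,
and single-molecule positioning of nucleosomes, bound proteins and loops.

## The problem

Transcription initiation depends on physical properties written into the
promoter sequence: intrinsically curved regions, superhelical structures
formed by phased A/T-tracts, and regions of low duplex stability where the
double helix melts first. Atomic force microscopy (AFM) of single promoter
molecules can reveal these structures directly — supercoil crossings stand
out as height summits, bound factors as bumps on the DNA ridge, and
nucleosomes as large particles with two free DNA arms — but turning raw
height images into base-pair positions requires a chain of quantitative
steps. `curvafm` implements both sides:

**From sequence.** The helix axis is reconstructed base pair by base pair
from a dinucleotide wedge-angle table (roll, tilt, twist per step; rise
0.34 nm). Curvature is measured with the *Ends ratio*,

```
Ends ratio = (contour length of window) / (end-to-end distance of window)
```

computed in a 150 bp sliding window at 1 bp steps. A superhelix phased at
a period different from the canonical ~10.5 bp/turn repeat is nearly
invisible as planar curvature — so the twist of the model is uniformly
rescaled over a *phasing pitch* grid (5–15 bp/turn). At the pitch matching
the phasing period the superhelix flattens into a plane and the Ends ratio
peaks: a peak below 10.5 bp/turn is a left-handed (negative) supercoil, a
peak above is right-handed (positive). Duplex stability is the mean
nearest-neighbor free energy ΔG (unified Watson–Crick parameters, 25 °C,
1 M NaCl) over the same windows.

**From images.** Height rasters are line-flattened, thresholded, thinned
to one-pixel skeletons, traced through crossings by direction continuity,
refined to sub-pixel accuracy, and converted to base pairs at 0.36 nm/bp.
Molecules are oriented by correlating their height profile with the
sequence-derived twist modulation. Positions are then read off in bp:
nucleosome dyads via `Lc = L − (L₊ + L₋)` and `dyad = L₊ + Lc/2`, bound
proteins as the most prominent height maximum, loops via the self-crossing
of the trace, and time-lapse series via the migration of the curvature
apex.

A seeded synthetic module generates phased-A/T-tract sequences and
AFM-like images of 2D-equilibrated worm-like chains (persistence length
50 nm, helix height 0.8–1.2 nm, crossing summits capped at 1.6 nm, noise
SD 0.3 nm), so every stage runs against known ground truth with no
external data.

## Worked example

The numbered scripts under `analysis/` run the full study on the packaged
synthetic promoter construct (1290 bp on the skip-zero promoter axis
−869..+421, with PRRI, PRRII, TATA and TSS annotated). For example:

```sh
Rscript analysis/01_sequence_structure.R
```

prints

```
Promoter-like construct: 1290 bp spanning -869..+421
PRRII carries 3 A/T tracts (longest 19 bp), separated by 6 and 7 bp
canonical-pitch curvature apex at 13 bp (Ends ratio 2.45)
left-handed supercoil: centers -196..-154, peak pitch 7.5 bp/turn, amplitude 4.74
right-handed supercoil: centers -265..-219, peak pitch 13.5 bp/turn, amplitude 3.58
control fragment (976 bp random): 0 supercoil call(s)
```

— the pitch scan finds the left-handed superhelix encoded by the
7.5 bp-phased tract cassette upstream of PRRII and the weaker right-handed
one upstream of it, places the canonical-pitch curvature apex just
downstream of the TSS, and stays silent on a random control fragment.
`analysis/03_afm_positioning.R` closes the loop on the image side:

```
dyads: 29/30 mapped, median error 1.5 bp
loops: 18/20 detected, median length 254 bp (92 nm), summits 1.49-2.32 nm
```

Each script writes its tables (profiles, maps, calls, histograms) as TSV
under `results/`.

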