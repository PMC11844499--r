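---
title: "Decoding optical pooled screens: models, parameters and design choices"
author: "opscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding optical pooled screens: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opscreen)
```

# The problem

In an optical pooled CRISPR screen (OPS), a lentiviral sgRNA library is
delivered to cells at low multiplicity of infection, so almost every
transduced cell carries one perturbation. The perturbation's identity is read
*in situ*: a 12-nt barcode at the start of each cell's expressed sgRNA is
amplified into a bright rolling-circle amplicon ("rollony") and sequenced by
twelve cycles of four-colour sequencing-by-synthesis (SBS) chemistry under a
microscope. Each cycle produces a five-channel image per field of view (FOV):
DAPI plus one channel per nucleotide (G, T, A, C). A separate acquisition at
higher magnification measures an image phenotype per cell — here the
integrated intensity of telomeric native-FISH (nFISH) spots, a proxy for
Alternative Lengthening of Telomeres (ALT) activity, or the mean
immunofluorescence of a stained protein. The analysis problem is to decode a
barcode for every cell from the ISS images, quantify the phenotype for the
same physical cells imaged at a different magnification, join the two
datasets, and test each sgRNA's phenotype distribution against control cells.

`opscreen` implements this pipeline end to end together with a synthetic
screen generator that plants full ground truth (cell positions and shapes,
spot positions and barcodes, per-cycle stage jitter, per-cell phenotype
values), so every stage is verifiable at desk scale.

# Pipeline model, stage by stage

## Registration

Stage drift between cycles is modelled as a rigid translation (no rotation or
scaling). Each cycle's DAPI image is registered onto cycle 1 by phase
correlation: the normalized cross-power spectrum's inverse-transform peak
gives the integer shift; with `upsample > 1` the peak is refined on a local
grid of spacing `1/upsample` pixels by an upsampled discrete Fourier
transform. Both images are low-pass filtered (Gaussian, default sigma 1.5 px)
before whitening: nuclei are smooth objects, so the upper half of the
spectrum carries almost pure noise phase which would otherwise swamp the
correlation peak. Smoothing commutes with translation and therefore does not
bias the estimate. Shifts are applied with the integer part as a zero-filled
translation and any fractional remainder spectrally (no interpolation
smoothing); pixels that left the frame in any cycle are masked from spot
detection. A cycle whose estimated shift exceeds `max_shift` (50 px) is
flagged failed; since a full-length read then cannot exist, spots on such a
FOV are dropped rather than called short.

## Spot detection from cross-cycle variance

A true ISS spot changes colour between cycles; static structures do not. For
each SBS channel we compute the per-pixel *population* standard deviation
across cycles (denominator fixed at the number of cycles, stated once here),
then average the four per-channel SD maps. Spots are local maxima of this SD
image. The local-maximum footprint is fixed at 3x3 — deliberately decoupled
from the `min_distance_px` separation parameter (default 2 px), which is
enforced afterwards by greedy selection in order of decreasing value (ties on
plateaus resolve to the smallest (row, col)). Coupling the footprint to the
separation radius suppresses the dimmer member of spot pairs separated by
2–3 px even when a genuine intensity dip exists between them, and measurably
caps recall at high spot density. The detection threshold is robust by
default: `median + k_mad * MAD` of the SD image (`k_mad = 5`); a constant
image yields no spots.

## The 12-cycle consistency filter

Only spots consistently present in *every* cycle are decoded. A spot passes a
cycle when the maximum over the four SBS channels of its windowed peak
intensity strictly exceeds that cycle's background plus `k_sigma` (default 3)
robust noise scales, with background and scale taken as the per-frame median
and normal-consistent MAD. Cycles that failed registration are excluded from
the denominator, but their presence makes the spot ineligible for a
full-length call.

## Intensity extraction and median crosstalk correction

Per spot, cycle and channel we take the *mean* over a square aperture of side
`2*aperture_px + 1` (default 3x3), after subtracting the per-frame median
(the cycle's background in that channel). The mean, not the max, is the
default statistic: the maximum of a window adds a positive bias common to all
channels, and a channel-common additive bias is exactly what a multiplicative
correction matrix turns into channel-specific distortion. With the unbiased
mean, correction never performs worse than raw calling in our tests; `"max"`
remains available.

The correction matrix is estimated per cycle by a two-pass scheme: spots are
provisionally classed by the argmax of their raw four-vector; column *j* of
the matrix is the channel-wise median of the vectors in class *j*, scaled to
unit maximum. The corrected vector is the matrix inverse applied to the raw
vector. If any base class holds fewer than `min_spots_per_base` (5) spots, or
the matrix is ill-conditioned, a degraded mode is used instead — a diagonal
matrix of per-channel global medians — and flagged. The degraded mode only
normalizes per-channel gain; it cannot remove crosstalk, which is why the
default codebook is base-balanced (below).

## Base calling and quality

The called base per cycle is the channel with the highest corrected intensity
(pre-clamping); ties break in the fixed channel order G, T, A, C and are
flagged. Cycle quality is `1 - second/first` on the clamped non-negative
intensities, 0 when the top intensity is 0; spot quality is the minimum cycle
quality — the weakest link of the read. This margin-based definition makes
quality thresholding monotone in practice: raising the threshold never
degrades accuracy beyond counting noise.

## Genotyping

Reads overlapping a cell *body* (watershed-grown from the nucleus over the
median of the four SBS channels of cycle 1; configurable to all cycles — the
choice of cycle is an open imaging question, and cycle 1 has the strongest
signal) are aggregated per cell after an optional quality floor and
truncation to `read_length` bases. The top two barcodes by count are
recorded; count ties break lexicographically and flag the cell ambiguous. The
top barcode maps to the codebook by exact prefix lookup (Levenshtein distance
0); an optional `max_distance > 0` extension maps to the unique entry within
that edit distance. Truncation that makes two codebook prefixes collide is an
error, never a silent merge. Cells whose top barcode is unmapped are retained
in the table but excluded from statistics.

## Phenotype quantification

Two modes. Mean-IF: the mean pixel intensity per labelled region. nFISH: a
grayscale white top-hat (image minus its opening with a square window of
half-width `tophat_radius_px = 5`) performs the background subtraction
implicitly; local maxima above `k_sigma = 5` robust noise scales, inside a
nucleus, are spots; each spot's integrated value is the sum of the top-hat
image over its connected above-threshold region dilated by 2 px (the
dilation recovers the sub-threshold tails of the spot profile — without it
about a fifth of a Gaussian spot's mass is missed). Telomeric signal is
nuclear, so quantification uses nucleus masks while genotyping uses cell
bodies; the nucleus/cell label correspondence (the watershed preserves seed
labels) is the join key.

## Cross-magnification matching

Cells are placed in a global coordinate system from their FOV's stage
coordinates: the stage coordinate refers to the FOV centre, pixel
coordinates are (row, col) with origin top-left, and y grows with the row
index (configurable at the simulator level; some stages invert y). A
systematic offset between the ISS and phenotype acquisitions is estimated as
the componentwise *median* displacement over mutual-nearest-neighbour pairs
within a 30 um gate — median, not mean, so a minority of wrong pairings
cannot corrupt it; an image-correlation alternative would need pixel data and
is noted as an extension. After applying the offset, candidates are nearest
neighbours within `gate_um` (15), assigned greedily one-to-one by increasing
residual, and accepted only if all four morphological features agree to
within `morph_threshold = 0.10` relative difference:
`|f_iss - f_ph| / max(f_iss, f_ph, eps)`. We read the 10% matching threshold
as per-feature rather than as an aggregate score; per-feature is the
stricter and more interpretable reading.

Morphology must therefore be *scale-stable* in micrometre units:

* area = pixel count x pixel size squared;
* perimeter = Crofton four-direction boundary estimator x pixel size
  (estimators differ by several percent, so the same one is used
  everywhere);
* eccentricity from the second central moments;
* solidity = pixel count over the number of lattice points inside the convex
  hull of the pixel centres. This estimator is exactly 1 for digitally
  convex regions at *any* resolution; the more common pixel-corner hull area
  puts a resolution-dependent bias of several percent into solidity, which a
  10% cross-magnification threshold cannot tolerate.

## Screen statistics

Each non-control sgRNA's per-cell phenotype values are tested against the
pooled control cells (non-targeting and safe-targeting guides pooled by
default, configurable) with a two-sided Mann–Whitney U test:
`U = sum [x_i > y_j] + 1/2 [x_i = y_j]`. When `n_x * n_y <= 64` the p-value
is computed by full enumeration of all label arrangements (ties exact);
larger samples use the normal approximation with tie correction and
continuity correction, which matches `wilcox.test` to machine precision on
tie-free data. At the 8-vs-8 switchover the two branches agree to about
0.011 in the worst case. Bonferroni correction multiplies by the number of
sgRNAs actually tested. The `min_cells = 3000` rule is a reporting flag
(`low_n`), not a filter, so small runs still produce complete tables. Fold
change is the ratio of means versus pooled controls. ECDF tables support the
standard per-guide distribution plots.

# The synthetic screen generator

The generator is first-class, tested code; its defaults define the reference
study conditions used throughout the test suite.

* **Geometry.** Cells on a jittered grid; nuclei are rotated ellipses with
  semi-major axis 4–6 um and axis ratio 1.2–1.8 (adherent cancer-line nuclei
  are visibly elongated; the lower bound stays away from circularity because
  a *relative* eccentricity comparison is uninformative at eccentricity ~ 0);
  cell bodies are the nuclei expanded by 2.5 um. Pixel sizes 0.65 / 0.325 /
  0.1625 um at 10X / 20X / 40X are configuration defaults, not claims about
  any particular instrument.
* **Barcodes.** The default codebook holds 14 sgRNAs — three each against
  FANCM, DDX39A and BLM, three non-targeting and two safe-targeting controls
  — with fixed 12-nt barcodes at minimum pairwise Hamming distance 6 and
  *base balance*: every base appears at least three times at every position.
  Base balance is standard SBS panel colour-balance design, and it is what
  keeps every base class populated when the correction matrix is estimated
  per cycle; an unbalanced panel (a base absent at one position) forces the
  degraded diagonal mode on every run.
* **ISS forward model.** One sgRNA per cell (the low-MOI idealization; a
  doublet rate can be configured to exercise the dominant-barcode logic);
  spot count per cell ~ Poisson(2.5). In cycle *c* the on-channel signal is
  `signal_amplitude * decay^(c-1)` (1000, 0.97 — a steady but manageable
  per-cycle loss) mixed through a column-stochastic crosstalk matrix
  (diagonal 0.8, off-diagonals 0.2/3); background is `100 + 10*(c-1)`;
  spots are Gaussian with sigma 1.0 px at 10X (a ~1 um rollony rendered at
  ~1.5 um FWHM); nuclei and cytoplasm are blurred by a *physical* 0.5 um
  optical blur so the same cell renders consistently at every magnification
  (a pixel-unit blur would make segmented morphology resolution-dependent
  and break cross-magnification matching). Each cycle's frame is cropped
  from a padded canvas at an integer jitter offset (at most `jitter_px_max`
  = 5 px, recorded in the ground truth), then additive Gaussian noise
  (sd 50; an optional Poisson term exists) is applied. Noise is additive
  Gaussian by default because SD-based detection depends mainly on the
  temporal variance structure, not the noise family.
* **Phenotype model.** Per-cell integrated nFISH intensity is log-normal
  with control mean 1144 A.U. and log-sd 0.8, multiplied by a per-gene
  effect: 2.90 for FANCM, 0.80 for BLM, 1.0 for DDX39A. The effect sizes are
  anchored to the printed per-cell intensity means of the positive and
  negative ALT regulators they emulate (3316/1144 and 911/1144). Spots per
  nucleus ~ 1 + Poisson(3), intensity split by normalized exponentials,
  rendered as Gaussians of 0.25 um sigma on a background of 10 with noise
  sd 2.
* **Determinism.** All randomness flows from `seed`; identical seeds give
  bit-identical screens.

What the generator does *not* emulate: optical PSF physics beyond a Gaussian,
realistic rollony morphology, autofluorescence spectra, chromatic or
nonrigid distortion, phasing/prephasing chemistry errors, segmentation-model
failure modes on crowded or apoptotic cells. Passing tests therefore show
that the pipeline's logic is correct under its stated model — not that any
particular accuracy will be achieved on real microscope data.

# Problem sizes and numerical choices

The test suite and the acceptance script run screens of 1–4 FOVs of
200–350 px with 25–120 cells per FOV (hundreds of cells, several hundred
spots), plus direct phenotype draws at 3,000 cells per sgRNA for the
statistical checks and 500 replicates at 50-vs-50 for null calibration —
sizes chosen so a full verification runs on a laptop in minutes while keeping
every estimate's sampling error well inside the tolerances being checked.
Degenerate inputs are defined, not exceptional: zero-cell configurations
produce empty outputs; a blank DAPI image produces an empty labelling; a
constant image cannot be registered (error) and yields no spots; empty read
sets give zero summaries with a flag; regions under 3 px are flagged
degenerate with eccentricity 0. Ties are total orders everywhere (channel
order for bases, lexicographic for barcodes, smallest (row, col) for
plateaus), so identical inputs give identical outputs.

# Known limitations

* Rigid translation only; rotation, scaling and chromatic shifts are out of
  scope.
* The classical nuclei segmenter (smooth + Otsu + distance-transform
  watershed) is the default for determinism; a pretrained deep-learning
  segmenter can be plugged in behind the same contract but is neither
  bundled nor required.
* The Mann–Whitney enumeration branch is exponential in sample size and is
  bounded by `exact_bound = 64` pairwise comparisons by design.
* The nFISH spot operators are a stated stand-in (top-hat scheme); the
  upstream experimental literature does not pin down a reference
  implementation.
* Greedy one-to-one matching is order-dependent by residual; a global
  assignment (Hungarian) would differ only in pathological near-tie
  configurations.
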