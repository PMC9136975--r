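---
title: "Edible fluorescent matrix codes: models, synthesis, and decoding"
author: "silkcode"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edible fluorescent matrix codes: models, synthesis, and decoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkcode)
```

## The problem

Counterfeit medicines are a major public-health hazard, and most
anticounterfeit measures protect the *package*, not the individual dose.
One proposed on-dose measure is an edible taggant: a thin silk-fibroin
film carrying an n×n matrix code written in three fluorescent silk inks
(eCFP, eGFP, mKate2). Each square unit of the grid holds exactly one of
four levels — empty, cyan, green, or red — so a single physical code is
read as three binary images through three excitation/emission filter
sets. This package implements the complete digital side of that system
in silico:

1. **code_model** — the quaternary matrix-code data model and its key
   encodings;
2. **synthgen** — a synthetic fluorescence-image generator reproducing
   the unit-patch data-augmentation scheme with fabrication
   imperfections;
3. **cnn_decoder** — a 2D convolutional network that maps a
   single-channel raster to its binary channel key, trained end-to-end
   inside the package;
4. **baseline_decoder** — a classical grid-segmentation/threshold
   reader, used both as a fallback and as the generator's consistency
   oracle;
5. **keycrypt** — digitized-key serialization, cryptographic hashing,
   and registry-based authentication;
6. a benchmarking harness for bit-error-ratio (BER) studies and
   intensity-degradation sweeps.

## Keys and capacity

A code with grid side $n$ yields one binary **channel key** $K_b$ of
$n^2$ bits per fluorescence channel (bit $i = 1$ iff cell $i$, scanned
row-major from the top-left, holds that channel's ink). The three
channel keys concatenate in the fixed order (eCFP, eGFP, mKate2) into
the **digitized key** of $3n^2$ bits — 147 bits for 7×7, 75 for 5×5,
243 for 9×9. The encoding capacity of a key of size $s$ at bit-level
$c$ is $c^s$; the nominal capacity of a 7×7 code is $2^{147} \approx
1.78\times10^{44}$. Because the three inks are mutually exclusive per
cell, the physically realizable code space is $4^{n^2}$, which is
strictly smaller; both are computed exactly with the package's
arbitrary-precision integer helper (`capacity()`), never in floating
point.

The digitized key can be reconstructed as a **quaternary key** (digit =
symbol level, 0–3) and a **double binary key** (each quaternary digit
as two bits, most-significant first). The mapping NONE=0, ECFP=1,
EGFP=2, MKATE2=3 and the row-major scan order are package conventions,
declared here and serialized with every key; they are deliberate,
documented choices where the physical system fixes no canonical order.

## The synthetic image generator

The reference augmentation scheme crops square units (101×101 px) from
fluorescence photographs of real fabricated codes and tiles them into
7×7 composites of 692×648 px (width × height). `silkcode` replaces the
photographic crops with a parametric imperfection model:

* a filled unit is a centred square (nominal half-side 0.8 of the patch
  half-side) whose boundary is displaced by a smooth random angular
  profile (**edge roughness**, relative amplitude 0.15 by default);
* its fill intensity is drawn from `fill_intensity_range` (default
  0.65–0.85 above background) and modulated by a smooth low-frequency
  field (casting inhomogeneity);
* the patch is blurred by a Gaussian point spread (`blur_sigma`) and
  summed with the mean background (0.08) plus white Gaussian noise
  (sd 0.02);
* an empty unit is background plus noise only.

A **patch library** (200 filled + 200 empty patches by default,
mirroring the reference pool of 200 real crops) is drawn once per seed;
composition places a randomly drawn patch at each grid cell with ±
`jitter_px` placement jitter. All outputs are pure functions of
(config, seed).

Two geometry profiles are built in. The `"full"` profile reproduces the
reference geometry (648×692 canvas; 101-px library patches resized to a
~70-px active cell area; margins 10 px; jitter ±3 px). Note that
7×101 = 707 px exceeds the stated canvas, so the original units cannot
have been tiled at full size; the package therefore derives the cell
pitch from the canvas ((canvas − 2·margin)/n) and centres the active
area per cell. The `"desk"` profile is a 96×96 miniature (9-px active
units, 2-px margins, ±1 px jitter) with identical generative structure,
used for CPU-scale training studies; the spatial signal-to-noise ratio
of both profiles is comparable, but absolute resolution is not, which
is why decoder architectures are scaled alongside (below).

What the generator does *not* emulate: perspective or rotation errors
(the reference imaging rig is registered), inter-channel spectral
bleed-through (disjoint filter sets; an optional crosstalk hook exists
in the config for robustness studies), and the optics of the
micrograting invisibility layer. Passing tests on synthetic data
therefore demonstrate decoder correctness *under the stated
imperfection model*, not performance on photographs.

**Degradation.** Fluorescence loss (photobleaching, heat) is modelled
by scaling the foreground-above-background amplitude by an
`intensity_fraction` ∈ [0,1], either exactly at render time
(`config$intensity_fraction`, used by the sweeps) or approximately on
finished rasters (`degrade_intensity()`, which masks foreground pixels
at 3σ above background so that background statistics stay untouched).

## The CNN decoder

The full-scale architecture follows the reference recipe exactly: for a
648×692 input, three convolutional layers (16 filters 32×32 stride 2;
32 filters 16×16 stride 1; 64 filters 8×8 stride 1), each followed by
batch normalization, ReLU, and overlapping max-pooling (windows
32×32/16×16/8×8, strides 2), then a 400-node fully connected layer
(batch norm + ReLU) and a linear n²-node output; mean-squared-error
loss against the 0/1 target key; ADAM with initial learning rate
2×10⁻⁴, mini-batches of 100, at most 15 epochs. Where the recipe is
silent the package makes these documented choices: "same" zero padding
for convolutions, "valid" pooling, binarization of the linear outputs
at 0.5, seeded He initialization, no early stopping, and a single
decoder applied to all three channels (the task is channel-agnostic
blob detection). Each input image is shifted by its median before the
first convolution — codes are mostly background, so the median tracks
the background level, making decoding invariant to global intensity
offsets and letting the zero padding blend into the background.

The engine itself (im2col gathers, GEMM convolutions, fused
overlapping max-pool with argmax tracking, batch-norm statistics, ADAM)
is implemented in R with C++ inner kernels; gradients are verified
against finite differences in the test suite. The heavily overlapping
pooling windows are evaluated as a disjoint stride-block maximum
followed by a small stride-1 window maximum, which avoids materializing
the full window×position gather.

### The desk-scale profile

Training the full-scale network is a GPU-scale job (tens of millions of
parameters on 648×692 inputs). For CPU-bound runs the package defines a
reduced profile that preserves the *relative* geometry of the reference
architecture rather than its absolute numbers. Two ratios matter:

* **kernel to cell pitch** — full scale: 32-px kernels on a 92.6-px
  pitch (≈0.35); desk scale: 4-px kernels on a 13.1-px pitch (≈0.3),
  with layer kernels 4/2/2 and pooling windows 4/2/2;
* **output-grid resolution per cell** — full scale ≈5.8 final spatial
  units per code cell; pooling strides 2/1/1 at desk scale give a
  21×21 final grid, i.e. 3 units per cell. Keeping all three pooling
  strides at 2 (the literal full-scale rule) collapses the desk output
  grid to 4×4 — under one unit per 7×7 cell — and measurably degrades
  decoding at the image borders; this is a resolution artifact of
  miniaturization, not a property of the reference architecture, which
  is why the desk profile relaxes the later pooling strides.

The desk learning rate is raised to 3×10⁻³: the reference rate 2×10⁻⁴
is tied to its ≈1,400-step schedule at full scale, and the desk run
must reach comparable optimization progress in fewer steps. (At a
fixed 15-epoch cap, desk-scale validation BER improves by an order of
magnitude between learning rates 10⁻³ and 3×10⁻³.)

## The classical baseline reader

`grid_cell_stats()` averages each cell's interior window (default: the
central 50% of the cell pitch, which stays clear of edge roughness and
jitter), and `threshold_decode()` binarizes the n² means either at a
fixed threshold (default: midpoint between the background level and the
weakest filled intensity) or at the Otsu two-class separation point,
which makes the decode invariant to affine intensity rescaling. Ties
resolve to 0 — for authentication a failed match is always preferable
to a false accept. On noiseless renders this reader recovers the truth
key exactly; that property is the package's generator/decoder
consistency oracle and is enforced in the test suite.

## Hashing and authentication

A digitized key is serialized as an ASCII bit string with the explicit
header `n=<n>;order=ECFP,EGFP,MKATE2;` — the byte convention is not
fixed by the physical system, and the ASCII form avoids endianness and
padding ambiguity at the cost of digests that differ from any packed-
byte convention. The serialization accepts *raw* decoder output
(including keys that violate per-cell exclusivity) so that anything a
decoder produces can be hashed. Digests (MD5 → 128-bit hashed key;
SHA-256/SHA-512 as stronger alternatives — MD5 is retained for
interoperability but is cryptographically broken, and SHA-256 is the
package default) index a JSON registry of product records (dosage
strength, dose frequency, expiration, manufacturing details).
Verification is exact digest equality only; tolerance to bit errors is
the decoder's job, never the registry's.

## Study sizes and numerical choices

The package's evaluation studies run at these sizes, chosen as the
desk-scale counterpart of the reference protocol (9,494 training and
50,000 validation images at full resolution):

* **decoder correctness**: 200 noiseless 7×7 images for the baseline
  reader (exact recovery); a 500-image easy-noise set that the CNN
  must fit to zero bit errors within the 15-epoch cap — with only 500
  images the batch size drops to 10 so that the epoch cap still allows
  enough optimizer steps;
* **headline BER benchmark**: 5,000 training and 5,000 disjoint
  validation images at moderate (default) noise, single channel per
  image, with the per-image channel cycling through the three inks.
  (With the full 9,494-image training set of the reference protocol
  the desk validation BER reaches zero; 5,000 keeps the benchmark
  inside a CPU-hour-scale budget while staying below the reference
  error rate.)
* **degradation sweeps**: intensity fractions 1.0/0.9/0.75/0.5/0.25
  with paired seeds (identical codes, patch draws, and noise at every
  fraction), echoing the observation that bit errors remain negligible
  while fluorescence intensity stays above ~75%.

Numerical details: batch-norm ε = 10⁻⁵ with running-statistic momentum
0.9 for inference; exact big-integer capacity arithmetic in base-10⁴
limbs; Otsu's threshold searched exhaustively over the n² cell means;
decoding ties break to 0; degenerate all-equal statistics under Otsu
decode to all-zeros with a warning.

## Known limitations

* No transfer to photographs of physical codes is claimed anywhere;
  the generator's imperfection model is parametric, not photographic.
* The CNN profiles assume registered, axis-aligned codes (no
  localization or perspective search), as does the baseline reader.
* MD5 is supported for compatibility with the reference description
  but should not protect new registries.
* The full-scale training recipe is provided and geometry-checked but
  is not exercised by the test suite; its documented results are from
  the desk profile.
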