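---
title: "Methods: color depth MIP matching in colordepth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: color depth MIP matching in colordepth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the models, parameter choices and numerical
conventions behind `colordepth`, and what the synthetic benchmarks do and do
not establish.

## The matching model

All data live in one *alignment space*: a voxel grid with a physical voxel
size in µm and an x midline. The package assumes registration has already
happened; the space is metadata that makes pixel coordinates comparable
across samples and modalities.

A **color depth MIP (CDM)** collapses a 3D stack along z. For each xy
column we keep the maximum-intensity voxel; the pixel's hue encodes that
voxel's slice through a blue→red ramp and its brightness scales linearly
with the voxel's intensity. Two CDM pixels "match" when both are foreground
and their decoded depths differ by at most a slice tolerance, so 2D pixel
overlap approximates 3D proximity. The kernel score of an image pair is the
maximum matched-pixel count over all translations in a small search square
(and optionally over the mirrored target), which absorbs residual
registration error.

The **shape re-score** addresses the kernel's main failure mode: a wrong EM
neuron can overlap an LM pattern heavily while leaving whole EM branches
unexplained. Every EM foreground pixel is classified once: an *xy penalty*
if no LM foreground lies within `xy_radius_um`, a *z penalty* if LM support
exists in xy but the nearest such depth differs by more than
`z_mismatch_um`, otherwise a *positive match*. The final score is
`positive / max(negative, 1)`. The rule is deliberately one-directional:
extra LM signal is expected (driver lines label several neurons at once)
and never penalized, while unexplained EM signal is evidence against the
match.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `xy_shift_px` | 2 | px | translation search radius of the kernel |
| `z_slice_tolerance` | 2 | slices | max decoded-depth difference for a pixel match |
| `pixel_intensity_threshold` | 32 | 8-bit units | foreground cutoff for search pixels |
| `xy_radius_um` | 12 | µm | shape-score xy support radius |
| `z_mismatch_um` | 40 | µm | shape-score depth mismatch bound |
| `max_lines` | 300 | lines | cap on distinct driver lines per EM target |
| `line_kernel_length_um` | 10 | µm | DSLT oriented-kernel length |
| `local_offset` | 20 | 8-bit units | DSLT margin over the local mean |
| `min_directions_hit` | 9 of 13 | – | DSLT directional vote threshold |
| `min_voxels` | 100 | voxels | junk filter: smallest kept component |
| `radius_um` (rasterization) | 2 | µm | EM tube radius |

The 12 µm / 40 µm / 300-line constants are the method's published operating
points and both shape bounds are treated as inclusive (a pixel exactly at
the radius is still supported). The kernel tolerances (`xy_shift_px`,
`z_slice_tolerance`, threshold 32/255) are open parameters of the original
search plugin that are not printed anywhere; the defaults here were fixed
once as the smallest values that absorb the ±1-voxel quantization jitter the
pipeline itself introduces (rasterization rounds to voxel centres, depth
decode rounds intensity scaling), and were not revisited afterwards.

The foreground test uses the HSV *value* channel (max of R,G,B) rather than
photometric luma: pure blue — the anterior end of the depth ramp — has luma
≈ 29, which a luma cutoff of 32 would silently erase. Value-channel
brightness treats all depths equally.

## Numerical conventions

- **Coordinates.** Voxel indices are 0-based; a physical coordinate `c`
  maps to voxel `floor(c / voxel_size)` and back to the voxel centre
  `(i + 0.5) * voxel_size`, so round trips move points by at most half a
  voxel per axis. Volumes are stored `[y][x][z]` in R's column-major arrays;
  CDMs are `[y][x]` with origin top-left; the mirror axis is x.
- **Depth LUT.** The ramp walks the exact integer path from blue (hue 240°)
  to red (hue 0°) through 8-bit RGB space — 4 segments × 255 unit steps + 1
  = 1021 distinct colors — and samples `n_slices` evenly spaced positions.
  Distinctness (hence exact decodability) holds by construction; requests
  beyond 1021 slices are refused. The LUT is an explicit object passed
  through every API so a dataset can be reproduced with the table that
  encoded it.
- **Decode under intensity scaling.** Encoding scales a LUT color by
  `intensity / max_intensity` with rounding; decode normalizes the
  brightest channel back to 255 and accepts the nearest LUT color within an
  RGB guard distance of 8 (the worst-case rounding perturbation is a few
  units per channel). Colors farther than the guard from every LUT entry
  are decode errors, black is background.
- **Tie-breaks, all deterministic.** MIP ties go to the shallower slice;
  kernel ties to the smaller shift magnitude, then original over flipped;
  ranking ties to lexicographic ids; connected components are ordered by
  size then lexicographic minimum coordinate.
- **Zero-penalty scores.** `positive / max(negative, 1)` keeps penalty-free
  matches finite while preserving order.
- **Mirror geometry.** Reflection maps column `x` to
  `round(2 * midline_vox − 1 − x)`; with the default centre midline this is
  an exact involution (verified by test). Combining keeps the brighter
  pixel on overlap, mimicking MIP semantics.
- **DSLT.** Out-of-bounds kernel samples are excluded from the local mean
  (counts are per-voxel), which makes the mask invariant to adding a
  constant to the whole volume. Connectivity is fixed at 26-neighbourhood
  so one-voxel diagonal contacts keep thin neurites connected.
- **Determinism under parallelism.** The precompute partitions the pair
  list into fixed batches, maps workers over batches, and concatenates
  results in batch order, so output is bit-identical for any worker count
  or batch size. A failed batch is retried once, then surfaced with its id.

## Design decisions taken where the design was open

- **DSLT details.** The referenced segmentation algorithm is not specified
  in the source material, so this package implements the stated idea —
  oriented local thresholding — with the 13 symmetric axes of the
  26-neighbourhood as directions and all parameters exposed. Defaults were
  chosen so the planted-neuron fixture segments cleanly (noise sd 5 over
  background 10 against tube intensity 255 leaves generous margin).
- **Junk filter.** The original relies on manually chosen Fiji shape
  descriptor thresholds; here the descriptor is (voxel count, bounding-box
  extents, elongation) with documented, overridable defaults.
- **Pixel-match rule.** The original plugin's hue-window comparison is not
  printed; matching via decoded-depth difference ≤ `z_slice_tolerance` is
  equivalent in intent and exactly testable against an oracle.
- **Rerank-then-cap.** All pairs are scored, then shape-reranked, then
  grouped and capped at 300 lines, so the cap operates on the final
  ordering rather than on the pre-rerank one.
- **GUIDs.** Synthetic data cannot carry institutional identifiers, so
  GUIDs are content-derived hashes of (modality, image id, variant) —
  stable across regeneration, unique across variants.
- **Schemas.** The served document types are named but not field-specified
  upstream; the JSON schemas shipped in `inst/extdata/schemas/` (and copied
  into every bucket version) are authored as part of this package, and the
  validator implements the subset of JSON Schema they use.
- **H5J volumes** are out of scope: the codec is undocumented in the source
  material; TIFF stacks are the supported volume format.

## The synthetic generator

`generate_dataset()` emulates the study conditions end to end: `n_em`
tube-like neurons (smooth correlated random walks, spline-interpolated,
radius 2 µm) in a 256 × 128 × 64 voxel space at 1 µm isotropic — chosen so
the 12 µm / 40 µm constants equal 12 px / 40 slices — with a quarter of
neurons crossing the midline (their LM expression includes the mirrored
twin; their EM CDMs get combined-mirror variants). Driver lines express 1–3
EM neurons, one per channel (emulating stochastic multi-color labeling),
with a 0.3 probability of an extra distractor neuron absent from the EM
library sharing a channel. Channels add constant haze (10) and Gaussian
noise (sd 5), clipped to 8 bits. Ground truth maps every segmented voxel
set to the neurons whose rasterized signal it overlaps (>10% of the set's
voxels); voxel sets attributable only to distractors have no correct answer
and are excluded from recovery statistics.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: registration error beyond the kernel's ±2 px
search, non-Gaussian imaging artifacts (occlusion, tissue autofluorescence,
anisotropic PSF), realistic arbor complexity (synthetic neurons are
unbranched tubes), intensity variation along a neuron, and the sheer
density of real MCFO samples. The benchmarks certify the *implementation* —
kernels equal their oracles, invariants hold, the pipeline is deterministic
— not field performance of the method.

## Problem sizes

The test suite checks kernels against brute-force oracles at small sizes
(volumes ≤ 14³ over 50 seeds for DSLT, 32 × 32 CDM pairs over 100 seeds for
the search kernel, 48² spaces for shape penalties), and runs the full
recovery experiment at 50 EM neurons × 20 driver lines (seed 7, one
sample/line), which yields ≈ 45–50 LM voxel sets and ≈ 3,600–3,800 pair
evaluations. `scripts/acceptance.R` repeats that experiment at the
caller-supplied seed. Recovery is ≥ 90% by design threshold; both tested
seeds reach 100%.

## Known limitations

- The rerank pass is O(|EM pixels| × disc area) per pair in interpreted R;
  at production scale (10⁴ × 10⁵ images) this would need the compiled
  kernel path of the original system, not this package.
- `xy_support_distance` uses an exact Euclidean distance transform only for
  xy-isotropic voxel sizes (the common case for registered templates);
  anisotropic grids fall back to a direct exact computation.
- The bucket layout models the *published* artifact; no HTTP serving, GUI,
  or alignment service is included, and PPPM-style result documents are
  representable in the data model but never computed.
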