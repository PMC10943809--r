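# colordepth

Cross-modal neuron morphology matching with color depth MIPs, in R.

Connectome reconstructions from electron microscopy (EM) describe single
neurons as skeletons; genetic driver lines characterized by light microscopy
(LM) express reporters in small sets of neurons per sample. Finding the same
neuron across the two modalities — e.g. hunting driver lines that target a
neuron of interest from a connectome — requires comparing 3D morphologies at
scale. `colordepth` implements the computational core of that workflow for
images registered to a shared alignment space:

- **Color depth MIP (CDM) encoding.** A 3D stack is collapsed to a 2D RGB
  image: a pixel is present iff its xy column contains signal, and its color
  encodes the z slice of the brightest voxel through a blue (anterior) → red
  (posterior) hue ramp. 3D shape comparison then reduces to 2D pixel overlap.
- **Skeleton rasterization.** EM skeletons (SWC) are drawn as tubes of
  controlled radius before encoding, so EM and LM CDMs are comparable.
- **DSLT segmentation.** LM channels containing several neurons plus
  background haze are split into per-neuron voxel sets by direction-selective
  local thresholding: a voxel is foreground if it beats the mean intensity
  along an oriented line kernel by an offset in enough of 13 3D directions.
  Small "junk" components are filtered by shape descriptors; each surviving
  voxel set becomes its own searchable CDM.
- **The search kernel.** Two pixels match when both are foreground and their
  decoded depths differ by at most `z_slice_tolerance` slices; a pair score
  is the maximum matched-pixel count over xy translations (±`xy_shift_px`)
  and, optionally, the mirrored target. Neurons crossing the brain midline
  additionally get a *combined-mirror* CDM variant, and the better of
  original/combined is kept per pair (the flip-max rule) — bilateral LM
  expression then matches single-hemisphere EM neurons.
- **Shape re-scoring.** Search results are re-sorted by a uni-directional
  penalty score: every EM foreground pixel with no LM support within
  ±12 µm in xy counts one penalty; xy-supported pixels whose nearest LM
  depth differs by more than 40 µm count one penalty; the final score is

  ```
  shape score = positive / max(negative, 1)
            positive = # matched EM pixels
            negative = # xy penalties + # z penalties
  ```

  LM-only pixels are never penalized, because LM samples legitimately
  contain extra neurons — but EM branches missing from the LM pattern are
  evidence against the match.
- **Precompute and publish.** An all-vs-all EM×LM pass (deterministically
  sharded across workers) records matches in both directions, groups EM→LM
  results by driver line, caps them at 300 lines, and writes a versioned
  static JSON tree (`current.txt`, `config.json`, `schemas/`,
  `metadata/by_body|by_line|cdsresults/`) with denormalized image metadata,
  content-derived GUIDs and constant interpolation — a file-system mirror of
  a static match-serving API.
- **Synthetic data.** `generate_dataset()` builds toy EM/LM datasets
  (tube-like neurons, bilateral cells, multi-neuron channels with haze and
  Gaussian noise) with ground-truth correspondence, so the whole pipeline is
  testable without any downloads.

## Worked example

```r
library(colordepth)

space <- toy_space()                      # 256 x 128 x 64 voxels, 1 um
lut   <- build_depth_lut(space$shape_xyz[3])

# a synthetic dataset with known ground truth
ds <- generate_dataset(n_em = 6, n_lines = 3, seed = 7)
ds
#> <synthetic_dataset> 9 EM images (6 neurons), 11 LM voxel-set images, 3 lines

# search one segmented LM voxel set against the EM library
res <- search_library(ds$lm_lib$cdm[[1]], ds$em_lib$cdm, search_params(), ds$lut)
head(res, 2)
#>   target_id target_variant matched_pixels    dx    dy used_flip normalized_score rank
#> 1 body_002  original                  508     0     0 FALSE                1        1
#> 2 body_006  combined                   16     0     0 FALSE                0.0315   2
```

508 of the voxel set's 508 foreground pixels land on `body_002` pixels
within the depth tolerance at zero shift (`normalized_score = 1`), so the
set is a clean recovery of that neuron; the runner-up overlaps only 3% of it.

```r
# full precompute with flip-max, shape re-ranking and both directions
tabs <- precompute_all(ds$em_lib, ds$lm_lib, search_params(), shape_params(), ds$lut)
tabs
#> <match_tables> 99 pair evaluations, 6 EM targets, 11 LM images, shape-reranked

# publish as a versioned JSON bucket and read a document back
write_bucket_layout(tabs, ds$em_lib, ds$lm_lib, "bucket", "v1.0.0")
doc <- lookup_doc("bucket", "cdsresults", make_guid("LM", ds$lm_lib$image_id[1]))
doc$results[[1]]$image$publishedName   #> "body_002"
```

`autoplot()` renders any CDM with its midline guide; `plot_matches()` bar-plots
a ranked match table; `tidy()`/`glance()` turn `match_tables` into tibbles.

A command-line wrapper over the same functions is installed at
`system.file("cli", "colordepth", package = "colordepth")` with subcommands
`encode`, `search`, `precompute` and `simulate`.

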