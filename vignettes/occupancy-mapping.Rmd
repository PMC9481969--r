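---
title: "Occupancy mapping and similarity analysis of 3D expression domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Occupancy mapping and similarity analysis of 3D expression domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wntscape)
```

## The model

The package operates on a *catalogue*: a set of binary expression
domains, one per gene (or reporter) per developmental stage, all
registered to one reference embryo so that they share a voxel grid,
together with an embryo foreground mask and optionally an anatomy label
volume. Everything downstream is set algebra over these masks.

Three assumptions are built in and worth stating explicitly:

1. **Inputs are already binary.** Converting a continuously variable
   signal into expressed/not-detected is a thresholding judgement made
   upstream; the package binarizes input volumes by the fixed rule
   `value > 0` and does nothing subtler. Derived territories obtained by
   subtracting many mapped domains (unique-gene maps in particular)
   inherit the accumulated noise of each gene's binarization, so their
   boundaries should be read as approximate.
2. **Domains are co-registered.** All masks must live on compatible
   grids (equal shape and voxel size); the registration itself is out of
   scope and assumed done.
3. **Domains lie inside the embryo.** Statistics are computed over the
   full grid, not restricted to the foreground, on the expectation that
   mapped domains are inside the embryo by construction. Where the
   foreground matters (zero-expression territories, combination counts)
   the embryo mask enters the definition explicitly.

### Occupancy and regions of high occupancy

The occupancy of a voxel is the number of family members whose domain
contains it. Summing binary masks gives the occupancy image, and the
identity `sum(occupancy) == sum(per-gene volumes)` is checked in the
test suite as a conservation law.

A region of high occupancy (ROHO) is a connected component of the
thresholded occupancy image. Published defaults for the Wnt/Fzd system
are wired into `roho_threshold()`: five or more Wnts at E9.5 and E11.5,
four or more at E10.5, four or more Fzds at every stage, with occupancy
peaks at Wnt ≥ 7 and Fzd ≥ 6. Three parameters of the componentization
were never published and are therefore package decisions:

- **Connectivity** defaults to 26 (vertex adjacency). ROHOs are treated
  as visually contiguous territories across serial sections; 26 is the
  most inclusive standard choice, and 6/18 are available.
- **Minimum region size** defaults to 5 voxels, suppressing single-voxel
  components that binarization noise can create. Set `min_voxels = 1` to
  disable.
- **Label order** is decreasing voxel count, ties broken by the
  lexicographically smallest bounding-box origin. The published regions
  were numbered anatomically by hand; a deterministic rule replaces
  that, and anatomical naming is left to the user.

The *gene set* of a region follows the intersect-any-voxel rule: a gene
belongs if its domain meets the region in at least one voxel. This is
deliberately permissive — a single shared voxel suffices — because that
is how the published gene sets were defined.

### Similarity

Pattern similarity uses the Jaccard index,
`JI = |A ∩ B| / |A ∪ B|`. Two conventions:

- **JI of two empty domains is 0**, not NaN. Undetected genes
  (zero-volume domains are legal) would otherwise poison whole tables.
- **Row/column normalisation**: the row-normalised intersection table
  divides by the row (test) pattern volume, the column-normalised table
  by the column (target) volume; empty rows/columns give 0. Exported
  CSVs carry the per-gene total volumes in a comment header so absolute
  voxel counts can always be recovered.

Similarity networks threshold the JI table. The published analysis
showed "the 15 genes with most similar patterns" per stage without
stating the selection rule; the package operationalises it as the k-th
order statistic of the per-gene best-partner similarity
`s(g) = max_j JI(g, j)`. This is deterministic, reproducible, and the
largest threshold at which at least k genes keep an edge; ties retain
all tied genes and the achieved count is reported. Other plausible rules
(mean JI, degree at a fixed threshold) would select slightly different
node sets, so reproductions of the published network topology are
approximate by construction.

## The synthetic embryo generator

`generate_catalog()` exists so that every pipeline stage can be tested
against planted ground truth with no external data. It emulates the
*statistical structure* the analysis assumes, not embryo anatomy:

- an ellipsoidal foreground (20–60% of the grid; real embryos are not
  ellipsoids, but connectivity and volume fractions are what matter
  here);
- K localized hotspots, each expressed by `genes_per_hotspot` members of
  each family — the phenomenon the occupancy machinery is built to
  detect;
- per-gene private spheres, providing unique territory;
- optional independent per-voxel flip noise (`speckle_rate`), a
  stand-in for binarization noise — the real mapping error field is
  unknown and not modelled;
- paralogue pairs assembled from three disjoint voxel sets of exact
  sizes, so the target `JI = core / (core + pa + pb)` holds to machine
  precision (the member voxels are scattered, not blob-shaped; only the
  set sizes matter for JI);
- a reporter domain as a dilated union of chosen hotspots, mimicking a
  pathway read-out that sits within and around regions of high family
  occupancy.

Defaults state the catalogue scale of the system that motivated the
package: 19 Wnt-like + 10 Fzd-like genes on a 32×48×32 grid of 10 µm
voxels (a realistic reconstruction resolution), 4 hotspots of radius 3
voxels shared by 5 genes, 2 private spheres of radius 2 per gene,
speckle 0.

Under `strict_recovery` (default) every planted sphere is pairwise
disjoint and inside the foreground, and the separation inequality
`min_separation > 2 × (hotspot_radius + private_radius)` is enforced.
This guarantees: planted per-gene volumes equal measured volumes;
occupancy at a hotspot equals the number of genes planted there; and
thresholding at `t = genes_per_hotspot` returns exactly K components
whose gene sets equal the planted ones. Placement is rejection sampling
with a budget of 1000 tries per sphere; exhaustion is an error that
reports how many hotspots were placed, never a silent degradation.

**What a green recovery test establishes** — that the occupancy,
componentization and gene-set machinery is correct on data satisfying
the generator's assumptions (disjoint spherical territories, no noise).
It does not establish robustness to registration error, anisotropic
structures, or thresholding artefacts in real mapped data; the small
speckle-robustness check probes only mild independent noise.

## Numerical choices

- All set statistics are integer voxel counts; ratios (JI, fractions)
  are exact integer divisions in double precision, so tests compare them
  exactly rather than with tolerances.
- Physical volumes are `count × prod(voxel_size_um)`; anisotropic voxels
  are supported, and generation ignores anisotropy (spheres are balls in
  voxel units — documented, since hotspot shape does not affect any
  statistic the package reports).
- CSV exports print 17 significant digits so read-back reproduces the
  in-memory values bit-for-bit.
- Degenerate inputs are defined, not errors, where a meaning exists:
  empty domains (volume 0, JI per the convention above), empty hotspot
  subsets (empty reporter), structures with zero voxels (fraction 0 plus
  a warning). Statistics with no meaningful value on empty input —
  coverage of an empty domain, profile of an empty query — raise classed
  errors.
- Determinism: one RNG stream per generated catalogue, seeded once, with
  genes processed in label order; the pipeline given the same
  configuration reproduces every artefact byte-for-byte (timestamps
  appear only in `summary.json`).

## Configuration and formats

Volumes travel as NIfTI-1 (`.nii`/`.nii.gz`; uint8/int16/int32/float32/
float64, both endiannesses on read). The deposited Woolz format of the
original archives is not parsed — convert to NIfTI first — and TIFF is
not supported in this build because no TIFF codec is available in the
target environment. Run and phantom configurations serialise as JSON
(not YAML, for the same availability reason). The catalogue manifest is
a CSV with columns `label,family,stage,file`, with reserved family
values `embryo` and `anatomy`; axis order is `(plane, row, column)` and
is recorded in the manifest header so external viewers can reorient.

## Known limitations

- No automated matching of detected regions to any hand-curated regional
  inventory, and no anatomical naming.
- `genes_per_hotspot` accepts an integer, a vector recycled across
  hotspots, or `"all"`; fully general per-hotspot-per-family gene lists
  are not configurable.
- The generator's noise model (independent flips) is a stand-in; it
  makes no claim about spatially correlated mapping error in real data.
- Whether published pairwise statistics were computed on full grids or
  foreground-masked grids is immaterial when all domains lie inside the
  foreground, which the package assumes; stray voxels outside the
  foreground in converted data would shift results slightly.
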