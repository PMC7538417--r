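---
title: "Methods: spherical-extrusion reconstruction of rod-shaped cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spherical-extrusion reconstruction of rod-shaped cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The reconstruction model

Fission yeast and similar rod-shaped cells are, to a good approximation,
radially symmetric about the curved axis running along their length. That
single assumption lets a full 3D cell be reconstructed from one 2D
segmentation at the cell's midplane:

1. The **Euclidean distance map** of the binary midplane ROI assigns every
   interior pixel its distance to the nearest ROI edge; along the medial
   axis this value is the local cell radius.
2. The **topological skeleton** (thinning of the ROI to a one-pixel curve
   equidistant from the boundaries) traces that medial axis, following the
   cell whether it is straight, bent or curved.
3. A **sphere** is centred at every skeleton point with the local
   distance-map radius. At an optical section a distance `dz` from the
   midplane, a sphere of radius `R` contributes a circular cross-section of
   radius `r = sqrt(R^2 - dz^2)`; the union of all coplanar circles is the
   cell's 2D ROI in that section, and the per-section ROIs stacked over Z
   are the 3D reconstruction.

Volumes are sums of per-section ROI areas times the voxel geometry
(`area * pixel_size^2 * z_spacing`). Surfaces use the staircase formula
`S = sum(P_i * Z) + 2 * A`: the section perimeters times the spacing cover
all faces orthogonal to the imaging plane, and twice the midplane area
covers the faces parallel to it. For comparison the package also computes
the field's idealized references from the midplane ROI alone: a
cylinder-with-hemispheres rod (`V = h*pi*r^2 + (4/3)*pi*r^3`,
`S = 2*h*pi*r + 4*pi*r^2`, with `r = W/2`, `h = L - W`) from either
Feret-caliper or area-preserving-ellipse length/width, and for nuclei a
prolate ellipsoid (`V = (4/3)*pi*a*b^2`) with the Knud Thomsen surface
approximation (exponent `P = 1.6075`). We use the prolate arrangement of
the Thomsen formula, `4*pi*((2*a^P*b^P + b^(2P))/3)^(1/P)`, which is the
one consistent with the prolate volume: it reduces exactly to `4*pi*a^2`
at `a = b` and stays within about 1.2% of the closed-form prolate surface
at biological axis ratios.

## Segmentation front ends

**Whole-cell (brightfield).** Cells in a flat layer are surrounded, in
defocused brightfield sections, by a dark boundary band whose width grows
with distance from the focal plane and vanishes at focus. The pipeline
finds the focus as the minimum-intensity-standard-deviation section,
enhances every section below the focus (Gaussian blur then unsharp mask),
Otsu-binarizes each, and averages the binaries: boundary bands become
valleys of the resulting grayscale map. A second Otsu threshold isolates
the bands; bright components not connected to the image border are
candidate cell interiors, each enlarged by the band half-width (median of
the band's distance-transform ridge) since the band straddles the true
outline symmetrically. Optional steps follow the same order as the
original protocol: watershed splitting of touching cells limited by a
separator length, gap/notch smoothing below a user area threshold, an
optional solidity filter (off by default - genuinely curved cells have low
solidity), and periphery exclusion. Externally produced 2D label masks
(e.g. from a CNN segmenter) can replace this entire chain and run through
the same post-processing; that import path defaults to watershed splitting
with a 20 px separator.

**Nuclei (fluorescence).** Each section is enhanced (blur sigma 1 px,
unsharp radius 2 px, weight 0.6 - values chosen as sensible defaults, all
exposed in the configuration), thresholded by Otsu, smoothed by blurring
the binary and remasking at 0.5, and converted to regions. Components with
circularity `4*pi*A/P^2` below 0.6 are discarded (they are typically
crescents left where a weak nucleolar signal escaped the threshold);
survivors are optionally dilated (default 0.1 um) and regularized to their
area-, centroid- and orientation-preserving fitted ellipse. Regions are
then linked across sections by nearest centroid (greedy, nearest pair
first, ties to the larger area) within 2.0 um; chains may bridge up to 2
missing sections, after which only the largest contiguous run survives.
Chains are discarded if any centroid strays more than 3.0 um from the
chain mean, if fewer than 5 sections remain, or if the largest-area
section (the nuclear midplane) sits at the top or bottom of the run - the
signature of a truncated nucleus. One detail is deliberate: per-section
Otsu thresholds are floored at the stack-global Otsu threshold. Otsu
assumes a bimodal histogram; on sections that contain no nucleus it
happily splits camera noise in half, and the resulting speckle can chain
across sections and pass every geometric filter. The global floor is the
standard remedy and leaves genuinely bimodal sections untouched.

## Numerical choices in the extrusion core

Three half-pixel-scale conventions matter at the accuracy level the
package targets (a 40 px wide cell changes volume by ~5% per half pixel
of radius):

* **Edge offset.** The distance transform measures distance to the
  nearest *background pixel centre*, half a pixel beyond the ROI edge.
  Profile radii therefore use `distance - 0.5`.
* **Sub-pixel ridge refinement.** Thinning snaps the skeleton to pixel
  centres, but for rods of even pixel width the medial axis runs between
  pixel rows, and on tilted rods skeleton pixels sit up to ~0.7 px off
  axis with correspondingly smaller distance values. The distance function
  falls off with unit slope on both sides of the axis, so sampling it one
  pixel to each side along the local skeleton normal gives a tent profile
  whose apex `(d+ - d-)/2` is the sub-pixel axis position; the point moves
  there and its radius grows by the distance moved. Disk centres keep
  these sub-pixel coordinates during extrusion (a `round_centres` switch
  restores the integer-ROI behaviour of systems that cannot represent
  sub-pixel circles, at the cost of quantizing rods to odd pixel widths).
* **Midplane-area calibration.** The reconstruction's defining contract
  is that the union of the coplanar midplane circles reproduces the
  midplane ROI. A single additive radius offset per cell is fitted by
  bisection so the rasterized midplane union matches the ROI's pixel area;
  this removes the residual alignment-dependent bias of the discrete
  distance transform.

Thinning itself is Zhang-Suen with two standard repairs: a guard that
keeps one pixel when parallel deletion would erase a final 2x2 core, and
a sequential cleanup that removes staircase-corner pixels whose
neighbourhood is a single connected group. Spur pruning (on by default)
removes terminal branches shorter than the local radius - smooth inputs
rarely branch, but rasterization noise seeds short spurs. Because thinning
stops roughly one local radius short of the medial-axis endpoints, each
endpoint is extended along the distance ridge (forward cone, largest
non-increasing distance, at most one radius of steps); the extension
points carry decreasing radii and naturally rebuild the hemispherical end
caps. Any point's sphere is contained in the union of maximal balls, so
extra skeleton points can never inflate the reconstruction.

Disk rasterization includes a pixel when its centre lies inside the
radius, boundary inclusive. This approximates the majority-volume voxel
rule to within half a voxel, keeps the operation separable per section,
and makes the reconstruction exactly equal to a brute-force
union-of-spheres voxelizer with the same conventions (an equality the test
suite asserts voxel for voxel). Anisotropy is handled by converting
section offsets into pixel units, `dz_px = sections * z_spacing /
pixel_size`; radii always live in XY pixel units. A direct consequence,
verified in the tests: rescaling the axial distance correction changes an
extruded cell's voxel count but not its volume in cubic micrometres, while
a stacked (nuclear) ROI keeps its voxel count and scales its volume -
the two 3D strategies respond to axial calibration in opposite ways.

## Calibration

Dark noise is subtracted everywhere (negative results clamp to zero -
counts are non-negative); flat-field images are dark-subtracted,
normalized to mean 1, and divided out; a per-channel integer section shift
corrects axial chromatic aberration, with all channels cropped to their
common Z overlap; and the nominal section spacing is multiplied by the
axial distance factor (e.g. 0.1 um x 0.65 = 0.065 um) before any
extrusion or volume computation. The package applies given calibration
values; estimating them from bead stacks is manual upstream work. A single
2D flat-field image is applied to every optical section.

## What the synthetic scenes do and do not test

The generator renders phantoms at the acquisition geometry of a typical
widefield fission yeast dataset (0.1071 um pixels, 72 sections at a
corrected 0.065 um spacing, 768 x 768 px fields) with one integer seed
driving all randomness. Cells are straight, bent or tapered capsules
(width 3.6-4.2 um; lengths 8-13 um for the wild-type preset, 5-7 and
16-22 um for the short and long size-mutant presets, 40-80 degree arcs
for the bent preset), placed without overlap in a flat layer at the focus
plane. Each nucleus is a prolate ellipsoid (axis ratio 1.1) sized to
exactly 12.5% of its cell's analytic volume, with a central nucleolar
sphere at 75% of the nuclear intensity - dim enough to be a visible
structure, bright enough to stay above a background/foreground threshold,
which is the regime the segmentation is designed for (a much dimmer
nucleolus reproduces the known crescent failure mode that the circularity
filter exists to catch). The brightfield render is a geometric band model
- a dark ring of width `slope * |k - focus|` around the analytic outline
plus Gaussian noise - not an optics simulation: there is no PSF, no
shading, no texture inside cells. It exercises every operator the
segmentation chain uses (focus finding, band growth, band-halfwidth
recovery, splitting, smoothing) but passing it says nothing about
deconvolution quality or low-SNR behaviour on real microscopes. For the
same reason the scene-processing configuration sets the nuclear dilation
to zero: the 0.1 um default compensates PSF-driven under-segmentation on
real data, and with a PSF-free render it would only bias nuclear volumes
upward by ~15%.

On these scenes the package's own validation (the test suite and
`scripts/acceptance.R`) measures: extruded sphere and capsule volumes
against closed forms (64^3- and 160^2 x 81-voxel problems), bend
invariance at 60 and 120 degrees, exact agreement with the brute-force
voxelizer, staircase-surface equality with an independently traced
per-section oracle, detection rate and median volume error on a 20-cell
wild-type scene, recovery of the generated N/C ratio, and the solidity
contrast between bent and straight populations (8-cell scenes). Problem
sizes were chosen so the whole suite stays comfortable on a single CPU;
they are stated here so results are read at the scale they were computed.

## Known limitations

Radial symmetry is the load-bearing assumption: flattened or lobed cells
will be reconstructed as locally round tubes. One focus plane is assumed
per field (cells in a monolayer); per-cell focus is out of scope, as are
time-series linking and sub-voxel (mesh) surfaces - reconstructions are
full-voxel by design. The watershed separator criterion matches the
contract of the original tool (cut short necks, preserve long contacts)
rather than any specific implementation bit-for-bit. Nuclear volumes from
stacked thresholded sections lose a few percent at the polar caps where
cross-sections approach the pixel scale; the aspect-ratio filter flags
the pathological cases rather than correcting the bias.
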