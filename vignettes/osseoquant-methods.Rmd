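---
title: "Voxel-conserving quantification of bone-to-implant contact: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-conserving quantification of bone-to-implant contact}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osseoquant)
```

## The measurement problem

Osseointegration of an implant is conventionally quantified as
*bone-to-implant contact* (BIC): the fraction of the implant surface in
direct apposition with mineralized bone. Classical histomorphometry measures
it on one stained thin section per specimen — a destructive preparation that
reduces a three-dimensional interface to a single plane whose choice is
partly arbitrary. Micro-computed tomography images the entire interface
nondestructively, but metallic implants surround themselves with bright
halation and beam-hardening artifacts, and any surface estimate on a voxel
grid carries a systematic staircase ("aliasing") area inflation.

`osseoquant` implements a 3D measure designed so that the staircase bias
cancels. On a segmented label volume (background/marrow = 0, bone = 1,
implant = 2, excluded = 3) it builds the *voxel-conserving* surface — the
exact set of axis-aligned unit faces between materials, with no smoothing
whatsoever — and reports:

* **pBIC** (possible contact): the area of lateral-shell faces between
  implant and bone *or* marrow — every face a bone voxel could occupy;
* **eBIC** (effective contact): the subset of those faces actually adjacent
  to bone;
* **pVA** = 100 · eBIC / pBIC.

A curved surface digitized on a voxel grid is over-measured by a
geometry-dependent factor — a right circular cylinder's lateral voxel-face
area tends to 4/π ≈ 1.27 times the true area as resolution grows. Because
eBIC and pBIC are measured on the *same* voxelization of the *same* shell,
that factor appears in numerator and denominator and cancels in pVA. This is
the core reason the pipeline must avoid mesh smoothing or decimation: any
smoothing would break the exact cancellation. The package verifies both
halves of the argument: the cylinder ratio is reproduced within [1.24, 1.31],
while pVA on one phantom changes by well under 2 percentage points when the
voxel size is halved.

End caps are not part of the measure: contact is only meaningful on the
lateral (conical) shell, so z-oriented faces within one voxel of the
implant's extreme slices are dropped. A cone's staircase lateral surface
legitimately contains z-faces at intermediate heights; detection therefore
keys on the extreme slices, not on face orientation alone.

## Processing chain

The quantification chain mirrors a µCT workstation workflow:

1. **Box resampling** (`resample_box2`): disjoint 2×2×2 block means, halving
   resolution and reducing data eightfold. Besides memory, this is the main
   noise-reduction step (noise SD drops by √8) and thins partial-volume
   films relative to the voxel. Odd trailing rows are dropped — the simplest
   contract consistent with the factor-8 reduction on even dimensions.
2. **Unsharp masking** (`unsharp_mask`): slice-wise
   `out = in + g (in − boxmean(in))`, 5×5 kernel, sharpness 0.6 by default.
   The gain convention `g = s/(1−s)` is used because the originating
   software's formula is unpublished; `gain = "plain"` (`g = s`) is
   available. Output is clipped to the input range. "5×" kernels are read as
   5×5; a 5-voxel *radius* is the other possible reading.
3. **Threshold detection** (`detect_thresholds`): two thresholds maximizing
   the three-class between-class variance over a 256-bin histogram
   (multi-level Otsu). On plateau ties (spike histograms) the plateau
   midpoint is returned. A voxel exactly at a threshold goes to the lower
   class.
4. **Interface cleanup** (`clean_interface`): see below.
5. **Exclusion** (`exclude_outside_bone`): shell regions outside the bone
   (proud implant seating) are relabelled `excluded` by a cutting plane;
   faces against excluded voxels leave the pBIC denominator entirely, which
   is the correction that keeps pVA comparable across specimens with
   different analysable shell fractions.
6. **3D measure** (`compute_bic3d`) and the **virtual 2D arm**
   (`extract_section`, `compute_bic2d`, `section_sweep`).

### Why the default chain does not unsharp-mask

Unsharp masking is implemented and tested, but the default quantification
configurations do not apply it. With a realistic point-spread blur, the
5×5/0.6 sharpening produces an undershoot on the dark side of the
bone–implant edge strong enough to push genuinely apposed bone below the
bone threshold: on sector phantoms this destroys 6–10 percentage points of
true contact at contact fractions ≥ 0.5. In the original interactive
workflow sharpening aided *visual* segmentation, a role that does not exist
in this fully automated chain. Users reproducing an interactive protocol can
re-enable it through the `preprocess` block of a pipeline config.

### Interface cleanup: bounded geodesic opening

Metal halation plus blur deposits a thin film of bone-valued voxels against
the implant shell even where there is no bone — the classic "noise layer
around the implant" that plagues µCT BIC studies and, untreated, drives pVA
towards 100%. `clean_interface` removes it in two moves, confined to a
3-voxel collar around the implant so bulk bone is untouched:

1. **Bounded geodesic opening** of the bone mask: Euclidean-ball erosion
   (radius 1 by default) followed by `radius + 1` unit geodesic dilations
   *inside the original bone mask*. The distinction this draws is physical:
   bone truly apposed to the shell has bulk bone (an eroded core) directly
   behind it and is regrown; the halo film has marrow behind it, hence no
   core to grow back from, and stays removed. A plain ball opening fails
   both ways at once — it permanently eats single-voxel bone wedged in
   concave staircase notches (measured 2.6 pp of true contact on a perfect
   full-contact phantom) — while unrestricted morphological reconstruction
   re-adds the entire film through its lateral connection to real bone. The
   bounded variant restores notch bone (at most a notch away from the core)
   and leaves films removed.
2. **Island removal**: 26-connected bone components smaller than
   `min_island` voxels (default 27 ≈ a 3×3×3 speckle) become marrow.

The implant label is never modified; face adjacency is 6-connected
(a geometric necessity for faces), island detection 26-connected.

### Automatic exclusion plane

Labels cannot distinguish marrow from air (both are class 0), so "outside
the bone" is detected geometrically: per slice, the fraction of angular bins
around the implant cross-section containing bone within a 5-voxel annulus.
Embedded levels score high even across thin marrow gaps; exposed-in-air
levels score zero. The plane is placed at the bottom of the topmost
contiguous run of slices scoring below 50%, perpendicular to the implant
axis. The 50% default is deliberately permissive so trabecular porosity does
not trigger spurious exclusion. Explicit point+normal planes are also
accepted; exclusion is monotone in the plane position.

## The virtual histomorphometry arm

`extract_section` resamples a single-voxel-thick longitudinal plane through
the implant axis at a chosen angle (nearest-neighbour labels, optional
supersampling to mimic the finer pixel size of real microscopy).
`compute_bic2d` traces the implant profile with Moore 8-connected contour
following, measures length by the Freeman chain-code convention (1 per axial
step, √2 per diagonal — simple and oracle-checkable, since the commercial
package's length algorithm is unpublished), drops end-cap rows and segments
adjacent to excluded pixels, and reports the bone-adjacent fraction. Both
sides of the profile are evaluated.

The point of the arm is the comparison it enables: on the same volume, 2D
BIC depends on the section angle (`section_sweep` quantifies the spread)
while pVA is one plane-independent number. On trabecular phantoms the
across-angle SD of single-section BIC2D is typically 8–15 percentage points
— the package's reproduction, in a controlled setting, of the observation
that single-section histomorphometry carries section-choice variance that a
full-interface 3D measure does not have.

## The phantom generator

`phantom_spec()`/`generate_phantom()` build the ground-truth test bed: a
conical implant (maximum diameter 3 mm, length 3 mm, 5° half-angle taper by
default) on the z axis, embedded in a bone block with about 1 mm of
surrounding bone, matching the geometry such implants are studied at. Four
contact modes: `full`, `none`, `sector` (bone touches the shell only inside
an azimuthal wedge of the requested fraction, with a ≥3-voxel marrow gap
elsewhere), and `trabecular` (a Gaussian random field smoothed at
`correlation_length`, thresholded to the requested bone volume fraction —
simple and controllable, not a microstructurally faithful trabecular model).
The true contact fraction is counted on the clean label adjacency before any
degradation.

One construction detail matters for fidelity of the *stated* contact
fraction: the marrow gap ring is extended one gap-width below the implant
bottom. Otherwise the solid bone floor under the implant reaches the lowest
lateral shell voxels through the simulated blur and adds ≈3 percentage
points of spurious contact concentrated in the bottom slices — contact the
sector geometry promises not to have.

Grey rendering maps labels to means (50, 120, 230 in arbitrary units —
ordered, well separated, implant brightest, as for titanium against bone),
then adds, in order: a bright halo decaying exponentially from the implant
surface (amplitude 25, decay 40 µm — a stand-in for residual metal
halation/beam hardening after vendor correction, modelled additively because
only the downstream artifact matters here, not its physics), Gaussian blur
(σ = one voxel by default, an imaging PSF at the sampling limit), and
Gaussian noise (σ = 8, a quarter of the smallest inter-class grey gap —
the regime in which thresholding should, and measurably does, keep voxelwise
error below 1%). A single RNG stream per phantom makes volumes
bit-reproducible from `rng_seed`.

What the phantom does *not* emulate: tomographic reconstruction itself
(projection physics, streaks, rings), polychromatic spectra, cortical vs
trabecular microstructure, or histological preparation artifacts. Passing
tests on phantoms therefore demonstrate the correctness and artifact
tolerance of the *measurement chain*, not the biological validity of any
particular scan.

## Problem sizes and numerical choices

Default phantom voxel size is 50 µm (a 60-voxel implant diameter) — coarse
compared to the 4–4.75 µm of real scans of such implants, but the pVA
construction is resolution-invariant by design and the tests verify exactly
that, so the package's own analyses run at desk scale. Ground-truth recovery
runs generate at 24 µm (125-voxel diameter) and box-resample once to 48 µm
(62 voxels), mirroring the resample-first processing order; recovery of
known contact fractions {0.2, 0.4, 0.6, 0.8} through the full
blur+noise+halo chain is accurate to ≤ 0.022 in the contact fraction,
within the ±0.03 the design targets. Dispersion comparisons use ten
trabecular phantoms at 100 µm with 18 section angles.

Other conventions: voxel indices are 0-based with half-open crop boxes;
faces live between voxel i and i+1 of their axis; all lengths are µm
internally (DICOM mm converted at the boundary); MetaImage is the canonical
interchange format (bit-exact round trip: doubles for grey, bytes for
labels); TIFF stacks are normalized to [0,1] with a JSON sidecar carrying
range and spacing; the DICOM reader/writer is a minimal explicit-VR
little-endian implementation sufficient for uncompressed monochrome series.

## Statistics

The group comparison battery matches small-sample implant-study practice:
mean ± SD per group and method, sample-size-weighted pooled means, Levene's
W (group-mean centres) for variance homogeneity, pairwise Mann-Whitney U
tests, and Pearson correlation between the 2D and 3D measures (Spearman by
flag; the choice of coefficient in the motivating analyses is not recorded,
so Pearson is a documented default). The Mann-Whitney p is exact by full
enumeration of group assignments for combined n ≤ 20 — at n of 4–6 per group
the normal approximation is not defensible — reporting
`p = P(min(U₁,U₂) ≤ observed)` under the permutation null, with average
ranks under ties; larger samples use the tie-corrected normal approximation.
No multiple-testing correction is applied by default (a Holm option exists),
matching the descriptive use of these tests.

## Known limitations

* pVA's staircase cancellation is exact only when numerator and denominator
  share the voxelization; comparing areas (not ratios) across resolutions
  still carries the 4/π-type inflation — `aliasing_report` quantifies it.
* The halo model is additive-exponential; it does not reproduce dark bands
  or streaks, so cleanup performance against those artifact classes is
  untested.
* The trabecular field controls BV/TV and correlation length only; plate/rod
  architecture, anisotropy and cortical shells are out of scope.
* The automatic exclusion plane is constrained to be perpendicular to the
  implant axis; oblique seating needs an explicit plane.
* 2D contour length uses the chain-code convention, which itself
  over-measures smooth curves; BIC2D is again a ratio of lengths measured
  the same way, so the bias largely cancels within a section.
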