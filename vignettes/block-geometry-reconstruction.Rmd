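---
title: "Block-geometry PET modeling and OSEM reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Block-geometry PET modeling and OSEM reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blockpet)
```

## The problem

PET scanners detect pairs of back-to-back 511 keV photons; each
coincidence defines a line of response (LOR) between two crystals.
Iterative reconstruction inverts the linear forward model

    q = N L X f + s + r

where `f` is the voxelized activity, `X` the geometric system matrix of
voxel/LOR intersection lengths, `L` the diagonal attenuation factors,
`N` the diagonal normalization factors, and `s`, `r` scatter and randoms
(both zero throughout this package). `X` depends entirely on where the
crystals actually are. Real scanners place rectangular crystal blocks
flat on the faces of a regular polygonal prism, with different gaps
between crystals within a block and between blocks. Describing such a
scanner as a perfect cylinder of equally spaced crystals — and remapping
measured events onto that virtual cylinder — misplaces LORs by up to a
crystal pitch, which shows up as ring artifacts, inflated
coefficient of variation (COV) and degraded small-source recovery.

`blockpet` implements both descriptions behind one interface so the same
detector-index data can be reconstructed under either model.

## Geometry conventions

* All lengths in mm. The scanner axis is z; the axial center is z = 0.
* `inner_radius` runs from the axis to the crystal *inner face*; blocks
  are tangent to that circle. Detection positions sit `average_doi`
  behind the inner face along the block's outward normal. The default
  `average_doi` is half the crystal depth: for a uniform interaction
  probability along the crystal (no exponential weighting is attempted)
  the mean depth is the midpoint, and the value is configurable per
  scanner for anything better.
* The virtual cylindrical model uses the *same* inner radius with
  detection radius `inner_radius + average_doi`, keeping the DOI
  treatment of the two models symmetric.
* Ring index 0 is at the smallest z; transaxial crystal index 0 is the
  side-0 crystal (face centered on +x) with the smallest non-negative
  azimuth, increasing counter-clockwise. These conventions fix the bin
  formulas below; nothing else in the package depends on them.
* The cylindrical model's equally spaced rings are chosen so its first
  and last ring centers coincide with the block model's. Dividing the
  material extent by the ring count instead would make a
  single-crystal-per-block scanner with equal gaps (where the two models
  must coincide exactly — a property the test suite enforces) disagree
  with its own cylindrical description, so it was rejected.

## Sinogram parameterization

Bins are indexed by segment (signed ring difference, span 1 — no axial
compression), axial position, view, and tangential position, without arc
correction. With `Nd` detectors per ring the package *defines* the
mapping by its inverse,

    c1 = (v + floor(t/2))              mod Nd
    c2 = (v - floor((t+1)/2) + Nd/2)   mod Nd ,

`t` in `-Nd/2+1 … Nd/2-1`, which enumerates every unordered transaxial
crystal pair with `c1 ≠ c2` exactly once (the forward direction is a
precomputed lookup table; bijectivity is checked exhaustively on a small
scanner). Pairs sharing a transaxial index would need the excluded
`t = -Nd/2` slot; they lie at the extreme edge of the transaxial FOV and
are counted as rejected during histogramming. The tangential range may
be trimmed (`num_tangential`); the default is `Nd/2` rounded to even,
and the published sinogram sizes use 100.

`lor_from_bin()` reads both endpoints from the detector map of the
active geometry mode. In cylindrical mode applied to block-scanner data
this reproduces — deliberately — the misplacement the block model
removes.

## Projectors

`X` is computed on the fly by Siddon raytracing (C++): exact
intersection lengths of each ray with a half-open, axis-aligned voxel
grid centered on the scanner center. Voxel identity along the ray is
decided at segment midpoints, which is robust on voxel boundaries and
guarantees the summed lengths telescope exactly to the clipped chord.
Each bin may be sampled by `n_rays` parallel rays offset across one
crystal pitch in the tangential (in-plane, LOR-perpendicular) direction,
offsets `pitch·((k-1/2)/n - 1/2)` so the bundle is symmetric with zero
mean; the bin value is the ray average. Rays are not extended beyond the
detection positions, and no axial spreading is applied. The back
projector shares the traversal code, making the pair exactly adjoint —
the property OSEM's convergence rests on, tested via inner-product
identities. A sparse system-matrix cache (`system_matrix()`) can replace
the on-the-fly path with bit-comparable results when memory allows.

## OSEM

`osem_reconstruct()` is standard ordered-subsets EM on view-interleaved
subsets (subset k = views ≡ k mod n), sequential subset order, update

    f ← (f / sens_k) · X_kᵀ( c_k · q_k / max(c_k · X_k f, floor) )

with `c = attenuation / normalization` and `sens_k = X_kᵀ c_k`. Choices
a maintainer should know:

* the start image is uniform inside the FOV cylinder inscribed in the
  grid (zero outside), so no voxel is favoured;
* the ratio floor is 1e-20 — it only rescues 0/0 in bins the current
  estimate cannot reach and does not bias populated bins;
* "subiterations" counts subset updates (24 subiterations at 6 subsets =
  4 full passes), matching the convention used for the published
  protocols;
* voxels with zero subset sensitivity are pinned to 0; output is
  non-negative by construction.

With one subset the algorithm is MLEM; the tests verify the Poisson
log-likelihood is non-decreasing and that total forward-projected counts
equal total measured counts after each full uncorrected iteration.

## Corrections

**Normalization.** A thin active plane containing the axis is acquired
at `n` equally spaced angles over 180°. For each position the
`num_views/n` views most orthogonal to the plane are extracted (these
are the uniformly illuminated ones); with 6 positions on a 96-view
scanner the windows tile all views disjointly, 16 per position. The
assembled sinogram is averaged over each bin's orbit under the
scanner's rotational symmetry (crystal shifts by whole polygon sides)
and the axial mirror — the mean is used rather than the sum so trim
boundaries and orbit fixed points cannot distort relative factors —
then inverted and rescaled to mean 1 over hit bins. Bins never hit
invert to infinity and receive `cap_value` (default: the largest finite
factor, mirroring "replaced by a maximum value" without inventing a
constant). At ~1000 folded counts per bin the factors carry
100/√1000 ≈ 3.2% relative noise, which propagates into the
reconstruction — normalizing with noisy factors can *raise* the COV of
an already-uniform block-model image, and the tests only assert the
orderings, not absolute values.

**Attenuation.** Factors are `exp(-∫ μ dl)` along each bin's rays
(averaged over the exponentials), with μ in cm⁻¹ (0.096 for water at
511 keV); factors are exactly 1 where the μ-map is empty.

## The synthetic acquisition generator

`simulate_acquisition()` replaces Monte Carlo transport with the
analytic expectation: attenuation-weighted block-geometry forward
projection of the voxelized phantom (≥10 rays), scaled to the requested
total coincidences, then Poisson-sampled under an explicit seed. Ground
truth is *always* the block geometry; the cylindrical pipeline only ever
sees `remap_to_cylindrical()` output, in which each physical detection
position is assigned to the nearest virtual detector (nearest ring plane
in z, nearest uniform azimuth). Because physical azimuths are not
uniform, some virtual detectors are never assigned and their bins stay
empty — the zero-bin pattern of the cylindrical model — while a
single-crystal-per-block scanner remaps onto itself.

Deliberately **not** emulated: positron range, photon non-collinearity,
scatter, randoms, energy resolution and windows, detector-efficiency
variation, dead time, and inter-crystal penetration. The published
comparison is geometric, and its own normalization scans disable these
effects; but it means a green directional test here establishes that the
*geometric remapping error* alone reproduces the reported orderings
(COV, SOR, PTV, empty bins), not that the absolute published values are
recovered — those came from full Monte Carlo physics at far larger
statistics. The plane source is a 1 mm slab (thickness is not stated
anywhere; it only rescales expected counts), air-filled, 120 × 32 mm.

The Derenzo layout is likewise a modeling choice: six 60° sectors, one
sphere diameter per sector, complete triangular rows with
center-to-center spacing twice the diameter, 2 mm inner margin, 0.5 mm
wall clearance. Published figures show the conventional pattern but no
dimensions.

## Numerical choices and degenerate inputs

* Siddon tolerances: chord conservation and adjointness hold to 1e-9 and
  1e-6 relative respectively in the tests; voxel intervals are half-open
  `[low, high)` so boundary rays are counted once.
* `peak_to_valley()` on a profile whose valleys are exactly zero returns
  `Inf` flagged `capped`; a constant profile returns 1.
* ROI membership is by voxel-center inclusion; sample (n−1) standard
  deviations everywhere. Small spherical ROIs on coarse reconstructions
  should be evaluated after `resample_image()` (trilinear refinement),
  as the acceptance tests do.
* Orthogonal-view selection breaks exact angular ties toward the
  counter-clockwise neighbour so that equally spaced plane angles
  produce consistently shifted, disjoint windows.
* `histogram_listmode()` errors on malformed records (naming the record)
  but only *rejects* — and counts — events outside the trimmed
  tangential range, beyond the ring-difference limit, or sharing a
  transaxial crystal index.
* All stochastic APIs take explicit integer seeds and are bit
  deterministic for a fixed seed, including through the CLI.

## Known limitations

* No arc correction, no axial compression (span > 1), no TOF — by
  scope.
* Transaxial symmetries are not exploited and the system-matrix cache is
  a plain sparse matrix; large scanners should use the on-the-fly
  projectors.
* The interfile dialect is self-consistent and lossless for this
  package but not byte-compatible with any vendor dialect.
* CLI configuration files are JSON, not YAML (no YAML parser in the
  supported dependency set).
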