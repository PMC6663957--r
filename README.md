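# blockpet

Modeling block-detector PET scanners and measuring what the extra
geometric fidelity buys at image level.

Most pre-clinical and clinical PET scanners are built from rectangular
blocks of scintillator crystals arranged on the faces of a regular
polygonal prism. Reconstruction software, however, has traditionally
described the scanner as a perfect cylinder of equally spaced crystals,
and resampled ("remapped") the measured coincidences onto that virtual
cylinder before reconstructing. The remapping assigns lines of response
(LORs) to wrong sinogram bins: some bins are hit too often, others never,
and the reconstructed images inherit ring artifacts, inflated
non-uniformity and degraded resolution.

`blockpet` implements both scanner models end to end, so the two can be
compared on identical data:

* **geometry** — Cartesian detector-position maps for the
  *blocks-on-cylindrical* model (blocks laid flat on polygon faces,
  distinct crystal-level and block-level gaps, detection at the average
  depth of interaction) and for the idealized *cylindrical* model;
* **projection data** — segment / axial position / view / tangential
  sinogram indexing (span 1, no arc correction), exact
  bin ↔ detector-pair ↔ LOR conversions for both models, and list-mode
  histogramming;
* **projectors** — Siddon raytracing through the voxel grid (Rcpp), with
  multi-ray tangential sampling per LOR and a matched (exactly adjoint)
  forward/back projector pair implementing X of the forward model
  `q = N L X f + s + r` (s = r = 0 here);
* **osem_recon** — fully-3D OSEM with view-interleaved subsets and the
  factorized system model N·L·X;
* **corrections** — normalization factors N estimated from rotating
  plane-source acquisitions (orthogonal-view extraction, symmetry
  folding, inversion, capping of never-hit bins) and attenuation factors
  L from the exponential of the forward-projected μ-map
  (μ_water = 0.096 cm⁻¹ at 511 keV);
* **phantom_sim** — analytic synthetic acquisitions replacing Monte Carlo:
  voxelized phantoms (Derenzo, uniform cylinder, point source, NEMA NU-4
  IQ, plane source), block-geometry forward projection, Poisson counting
  noise, and the nearest-virtual-detector remapping that reproduces the
  cylindrical model's distortion;
* **metrics** — COV, FWHM, spill-over ratio, peak-to-valley, NEMA NU-4
  recovery coefficients;
* **io_cli** — interfile-style headers with a run-time `geometry`
  keyword (`cylindrical` / `blocks-on-cylindrical`), float32 payloads,
  and a `pet_cli()` command line chaining
  simulate → histogram → normalize → reconstruct → evaluate.

## Worked example

A reduced-scale version of the published comparison (one axial block of
the 8×8-crystal dodecagon scanner → 8 rings × 192 crystals, 10⁶ true
coincidences, OSEM with 6 subsets, 24 subiterations, 10 rays):

```r
library(blockpet)
sb     <- scanner_b_spec(n_blocks_axial = 1)
info_b <- proj_data_info(sb)                        # block model
info_c <- proj_data_info(sb, mode = "cylindrical")  # virtual cylinder
grid   <- voxel_image(dims = c(63, 63, 8), voxel_size = c(1.1, 1.1, 2.1875))

vox <- voxelize_phantom(uniform_cylinder_phantom(), grid)
attn <- attenuation_sinogram(vox$mu, info_b, n_rays = 1)
q_b  <- simulate_acquisition(vox$activity, NULL, info_b, 1e6,
                             seed = 42, n_rays = 10, attn = attn)
q_c  <- remap_to_cylindrical(q_b, info_c)           # what the old model sees

cfg <- recon_config(n_subsets = 6, n_subiterations = 24, n_rays = 10)
rec_b <- osem_reconstruct(q_b, cfg, grid, attn = attn)
rec_c <- osem_reconstruct(q_c, cfg, grid,
                          attn = attenuation_sinogram(vox$mu, info_c, 1))

roi <- roi_cylinder(c(0, 0, 0), 50, 12)
cov_roi(rec_b, roi)   # 19.1  (% COV, block model)
cov_roi(rec_c, roi)   # 31.7  (% COV, cylindrical model)
```

Both reconstructions use *the same* simulated block-scanner events; only
the geometric model differs. The block model nearly halves the
coefficient of variation of the uniform cylinder before any normalization
(19.1% vs 31.7% at this desk scale). Adding rotating-plane-source
normalization (`simulate_plane_runs()` + `build_normalization()`, seed
101, 6e8 counts/position) narrows the gap while preserving the ordering:
20.0% vs 24.9% in the same experiment. `tests/testthat/test-acceptance.R`
runs this pipeline and also reproduces the spill-over-ratio and peak-to-valley orderings
on the Derenzo phantom and the always-empty sinogram bins created by the
cylindrical remapping).

## Vignette

`vignettes/block-geometry-reconstruction.Rmd` documents the model
conventions (indexing, bin formulas, DOI treatment), the OSEM and
correction factorization, what the synthetic generator does and does not
emulate, and the numerical choices (tolerances, floors, tie-breaks).
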