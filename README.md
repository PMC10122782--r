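# petsr

Super-resolution motion-compensated list-mode PET reconstruction, at desk
scale, in R.

## The problem

PET resolution is limited by detector crystal width: every coincidence is
binned onto the fixed, finite set of chords (lines of response, LORs) joining
crystal pairs. If the scanned object moves **and the rigid motion is tracked
continuously with sub-resolution accuracy**, each event can be repositioned
into a common reference frame along a continuum of chords. The repositioned
data sample projection space far more densely than the static scanner, and an
event-by-event motion-compensated list-mode OSEM reconstruction on a voxel
grid finer than the crystal pitch can then resolve structure beyond the
intrinsic resolution — super-resolution (SR) powered by the usually unwanted
head motion.

`petsr` is for researchers studying this mechanism quantitatively: it
provides the whole chain as testable, seeded, pure-software components.

## What is inside

* **Geometry / transforms** — 2D detector ring, voxel grids, LOR
  enumeration, full 3D rigid-transform algebra (`rigid_transform`,
  `compose()`, `invert()`, `apply_rigid()`).
* **Calibration** — paired-point rigid registration by SVD
  (`fit_rigid_svd()`), the tracker-to-image chain
  `L = Mc MRef MT^-1 Mc^-1` (`global_transform()`, `calibrated_track()`), a
  hand-eye variant from relative motions (`calibrate_relative()`), and
  software time-base alignment (`align_timebases()`).
* **Simulation** — hot-spot and rod digital phantoms, six motion-pattern
  generators (linear, circular, linear+circular, brownian, spiral, random
  back-and-forth) at 20/30/60 Hz, and a Poisson list-mode simulator under
  continuous rigid motion (`simulate_listmode()`).
* **Projection** — multi-ray Siddon projector (Rcpp) with Gaussian PSF
  modelling split between image and projection space; forward/back
  projection form an exact adjoint pair.
* **Reconstruction** — `lm_osem_sr()`: event-by-event motion-compensated
  list-mode OSEM with pose-aggregated events, masked time-averaged
  sensitivity (two strategies: per-pose projection-space and image-space
  averaging), attenuation/normalisation/scatter/randoms hooks, and a
  log-likelihood + background-noise trace (`tidy()`, `glance()`,
  `autoplot()`).
* **Metrics** — `cnr()`, single- and multi-window `ssim()`,
  `line_profile()`, `mpvr()` (mean peak-to-valley ratio).
* **Benchmark** — `sweep_config()` / `run_sweep()` / `summarize_sweep()`:
  the pattern-by-amplitude resolution study with a static reference band.
* **CLI** — `inst/scripts/petsr` with `simulate`, `calibrate`,
  `reconstruct`, `evaluate` and `bench` subcommands over the same functions.

The update implemented by `lm_osem_sr()` is, for voxel $j$ and events $m$ in
the current subset,

$$\rho_j \leftarrow \frac{\rho_j}{\tilde S_j}
  \sum_m P_{i'_m j}\,
  \frac{1}{I_{i'_m}(P\rho)_{i'_m} + (S_m+R_m)/(a_m N_m)},$$

with $i'_m = L_t^{-1}(i_m)$ the motion-corrected LOR, $P$ the PSF-augmented
multi-ray Siddon system matrix and $\tilde S$ the time-averaged sensitivity
image. See the methods vignette (`vignettes/super-resolution-pet.Rmd`) for
the model, the study conditions and every numerical choice.

## Worked example

Simulate a moving acquisition of the nine-spot phantom (2.4 mm spots, 12 mm
pitch, 10:1 contrast) on a 64-detector ring with 4 mm system resolution,
reconstruct with and without super-resolution, and measure the mean
peak-to-valley ratio (MPVR) on the profile through the middle spot row:

```r
library(petsr)

g    <- scanner_geometry(ring_radius = 50, n_detectors = 64)
psf  <- psf_budget(system_fwhm = 4, crystal_width = g$crystal_width)
proj <- projector_config(n_rays = 5, crystal_width = g$crystal_width)
ph   <- make_hotspot_phantom()

track <- generate_motion("linear", amplitude_step = 1.5, n_frames = 100)
lm    <- simulate_listmode(ph, track, g, psf, proj,
                           total_counts = 2e6, seed = 21)

cfg_sr <- recon_config(voxel_grid(64, 1), n_iterations = 32, n_subsets = 8,
                       psf = psf, projector = proj)
rec    <- lm_osem_sr(lm, track, cfg_sr)
rec
#> <petsr_recon> 64 x 64 @ 1 mm; 32 iterations x 8 subsets; 2001313 events, 9 poses

prof <- line_profile(rec$image, c(-18, 0), c(18, 0), n_samples = 361)
mpvr(prof, peak_positions = c(6, 18, 30), valley_positions = c(12, 24))
#> [1] 10.73324
```

The same acquisition without motion, reconstructed on the standard 2 mm grid
at matched iterations, gives an MPVR of about `4.4`: the moving acquisition
resolves the spots roughly 2.5 times better than the static reference,
because the tracked 1.5 mm-per-frame translation sweeps the spots across the
~4.9 mm crystals and the repositioned events oversample projection space.
(`autoplot(rec)` shows the image; `tidy(rec)` the per-iteration
log-likelihood.)

The full pattern-by-amplitude study is one call:

```r
sweep <- run_sweep(sweep_config())   # linear pattern, 5 amplitudes x 5 replicates
summarize_sweep(sweep)
autoplot(summarize_sweep(sweep))     # MPVR curves + static reference band
```

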