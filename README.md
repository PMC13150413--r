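# mdpost

Statistical post-processing of atomistic molecular-dynamics trajectories
in R. The package is for simulators — materials chemists, zeolite and
water people, machine-learning-potential practitioners — who have
trajectories on disk and need *observables with uncertainties*, not just
averages: is the run converged, what is the diffusion coefficient and
its error bar, what do the pair correlations, coordination numbers,
hydrogen-bond networks and cluster populations look like, and which
frames are worth keeping for training a potential.

## What it computes

* **Convergence and error analysis** for scalar observables
  (`sem_acf()`, `block_sem()`, `block_scan()`): the statistical
  inefficiency `g = 1 + 2 Σ (1 − k/N) ρ_k` (truncated at the first
  negative ACF lag), `sem = s √(g/N)`, the integrated autocorrelation
  time `τ_int = g Δt/2`, and a block-averaging scan with automatic
  plateau selection.
* **Self-diffusion** via the Einstein relation `M(τ) ≈ 2dDτ + b` on a
  windowed (multiple-time-origin) mean-square displacement of unwrapped
  paths, with the fit interval split into sub-windows whose independent
  slopes give D and its SEM (`msd_windowed()`, `fit_diffusion()`).
* **Partial RDFs** `g_AB(r)` under periodic boundary conditions with
  element- or index-based selections, ideal-gas normalization (an
  uncorrelated system gives g ≡ 1), per-frame stacks, and first-minimum
  detection (`prdf()`, `first_minimum()`).
* **Coordination numbers** with fixed, RDF-first-minimum (dynamic), or
  van-der-Waals-radii cutoffs (`coordination_number()`).
* **Hydrogen-bond networks** from the geometric D–H⋯A criterion, with
  per-molecule averages, across-frame standard deviations, and
  graph-based connected-component counts (`find_hbonds()`,
  `hbond_stats()`).
* **Cluster dynamics** with DBSCAN on minimum-image distances, the
  outlier-aware size conventions, and fragmentation flags
  (`cluster_frame()`, `cluster_timeseries()`).
* **Diversity subsampling** by farthest-point sampling over invariant
  pair-distance-histogram descriptors (or any plugged-in descriptor
  matrix), with a diversity-convergence diagnostic (`fps_rank()`,
  `diversity_curve()`).
* **Volumetric densities** on a fractional grid, exactly normalized,
  with plane projections and Gaussian-cube output (`density_grid()`,
  `project_density()`).

Inputs are (extended-)XYZ trajectories and two-column CSV series; seeded
synthetic generators (`make_ar1()`, `make_brownian()`, `make_lattice()`,
`make_water_dimer()`, `make_water_box()`, `make_clustered_points()`,
`make_uniform_gas()`) provide test inputs with analytic ground truth.
Units: fs, Angstrom, Angstrom²/ps. Indices are 1-based.

## Worked example

Error analysis of a strongly correlated observable, then diffusion from
a Brownian ensemble whose true D is 0.23 Å²/ps:

```r
library(mdpost)

ser <- make_ar1(1e5, phi = 0.9, sigma = 1, seed = 42)  # g_true = 19
sem_acf(ser)
#> ar1(phi=0.9): mean = -0.0415088, sem = 0.0316 (acf)
#>   g = 18.9, tau_int = 9.44 fs, n_eff = 5299 of 100000

sc <- block_scan(ser)
sprintf("block plateau sem = %.4g (block size %d)", sc$plateau_sem,
        sc$plateau_block_size)
#> "block plateau sem = 0.02778 (block size 26)"

tr <- make_brownian(n_atoms = 256, n_frames = 2000, D = 0.23,
                    dt = 10, box = 25, seed = 42)
fit_diffusion(msd_windowed(tr, max_lag = 200))
#> D = 0.2279 +/- 0.0011 A^2/ps (d = 3, 5 sub-windows, fit 0-2000 fs)
```

The naive `s/√N` error of the AR(1) series would be ~0.007; the
ACF-aware estimate is 4.5× larger because only ~5300 of the 100000
samples are effectively independent (`g ≈ 19`). The block-averaging
plateau agrees within ~10%. The diffusion fit recovers the generator's
D within about 1% with a sub-window error bar.

A command-line front end wraps the same functions
(`inst/cli/mdpost`), with unified flags `--traj_path`, `--frame_skip`,
`--output_dir`, `--workers` across the subcommands `error-analysis`,
`msd`, `prdf`, `cn`, `hbond`, `cluster`, `subsample`, `density`,
`fixtures`; every run writes CSVs plus a JSON manifest, and outputs are
byte-identical for any worker count.

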