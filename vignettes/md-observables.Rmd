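---
title: "Statistically qualified observables from MD trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistically qualified observables from MD trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdpost)
```

`mdpost` turns raw atomistic molecular-dynamics trajectories into
observables that come with a defensible uncertainty: standard errors for
scalar time series, diffusion coefficients with sub-window error bars,
pair correlation functions, coordination numbers, hydrogen-bond network
statistics, cluster-dynamics series, diversity-ranked subsamples, and
volumetric densities. This vignette explains the models and estimators,
the parameters that matter, the numerical conventions, and what the
synthetic test fixtures do and do not demonstrate about real data.

Units are fixed throughout: time in femtoseconds, distances in Angstrom,
diffusion coefficients in Angstrom^2/ps. Atom and structure indices are
1-based, following R convention.

## Trajectory model and periodic geometry

A trajectory is an ordered list of frames with a shared atom count and
element ordering, a simulation cell (one shared cell, or one per frame,
so constant-pressure runs are handled), and the time step between stored
frames. Input is plain or extended XYZ; lattice vectors and per-axis
periodicity are read from the `Lattice="..."`/`pbc="..."` comment
fields. Readers never wrap coordinates: analyses apply the minimum-image
convention on demand.

Minimum-image displacements are computed by rounding fractional
coordinates, which is exact for any displacement in orthorhombic cells.
For triclinic cells the rounded image is refined by an exhaustive search
over the 27 neighboring images; this is exact whenever the relevant
distance is below half the minimal cell height, and that bound is the
one the package warns about when a cutoff exceeds it. Distances exactly
equal to a cutoff count as inside (closed interval) everywhere.

All frame-wise analyses follow one parallel contract: a pure function is
mapped over frames and the results are reduced in frame order, so output
is identical for any worker count, including one.

## Uncertainty for scalar observables

For a series $x_1,\dots,x_N$ with sampling interval $\Delta t$, the
normalized autocorrelation function uses the biased ($1/N$)
autocovariance, the standard choice when the ACF is integrated. The
statistical inefficiency is

$$ g \;=\; 1 + 2 \sum_{k=1}^{K} \Bigl(1 - \tfrac{k}{N}\Bigr)\,\rho_k, $$

with the sum truncated at the first lag where $\rho_k$ drops below zero.
This first-negative-crossing rule is the conservative standard when no
windowing scheme is prescribed; the maximum lag is user-overridable
(default `min(N - 1, 2000)` samples). The triangular $(1 - k/N)$ factor
is the finite-sample correction of the integrated-autocorrelation
estimator; we adopt it and document it because the alternative (a plain
sum) differs only at order $k/N$. The reported quantities are
$\mathrm{sem} = s\sqrt{g/N}$, $\tau_{\mathrm{int}} = g\,\Delta t/2$, and
$N_\mathrm{eff} = N/g$. For a stationary AR(1) process with coefficient
$\varphi$ the exact value is $g = (1+\varphi)/(1-\varphi)$, which is what
the test suite checks against.

Block averaging divides the series into contiguous equal blocks
(tail remainder dropped, keeping blocks equal-length and the estimate
unbiased) and reports the standard deviation of block means over
$\sqrt{n_\mathrm{blocks}}$ with the $(n_\mathrm{blocks}-1)$ denominator.
Because no plateau-selection algorithm is standard, `block_scan()` makes
its rule explicit: walking from small to large blocks over a
log-spaced scan (default 24 counts between $N/4$ and 4), the first
window of three consecutive SEMs that pairwise agree within 10% marks
convergence and the plateau is their median; if no window qualifies the
scan reports the largest-block median with `converged = FALSE`. For
uncorrelated data the curve is flat and the plateau is $s/\sqrt{N}$; for
correlated data it rises until blocks exceed the correlation time and
then agrees with the ACF estimate (the suite requires the ratio to land
in [0.7, 1.4] for AR(1) at $N = 10^5$).

The module is unit-agnostic in the observable: energies, temperatures or
chemical shifts are read from two-column CSV and the label is echoed,
never interpreted.

## Diffusion from windowed MSD

Self-diffusion uses the Einstein relation $M(\tau) \approx 2dD\tau + b$
on the time-origin-averaged ("windowed") mean-square displacement of
unwrapped paths. Unwrapping accumulates minimum-image frame-to-frame
displacements and refuses to proceed when a per-frame displacement
reaches half the minimal cell height, since the image choice is then
ambiguous — the remedy is storing frames more often. Origins are taken
at stride 1 by default (maximal averaging, unweighted); the stride is
exposed for speed.

The fit interval defaults to all available lag times and is split into
`n_subwindows` (default 5) contiguous equal sub-intervals, each fitted
independently by least squares; the headline $D$ is the mean of
sub-window slopes over $2d$ and its SEM their standard deviation over
$\sqrt{n_\mathrm{subwindows}}$. One sub-window reproduces the single
global fit exactly and reports SEM 0 with an explicit flag. Because the
MSD values entering different sub-windows are computed from the same
underlying displacements, the sub-window estimates are correlated and
the quoted SEM is an in-sample agreement measure rather than a strict
frequentist standard error; the test suite therefore validates coverage
at the level of independent replicate trajectories. Finite-size
corrections toward the infinite-box limit are out of scope by design.

## Pair correlations and coordination

The partial RDF histograms minimum-image A–B distances per frame and
normalizes each bin by the ideal-gas expectation
$(N_A N_B - |A \cap B|)\,V_\mathrm{shell}/V$ for ordered pairs, which
(i) makes an uncorrelated system give $g \equiv 1$, (ii) is symmetric in
the two selections so `prdf(A, B)` equals `prdf(B, A)` bin-wise, and
(iii) handles arbitrary index-based selections — including overlapping
ones — with the same normalization logic as element selections. The
per-frame cell volume enters the normalization, so NPT data are
normalized correctly frame by frame. Bin width is always explicit
(default 0.05 Angstrom), never inferred; a per-frame $g(r)$ stack can be
retained for frame-wise output.

`first_minimum()` smooths $g(r)$ with a 5-bin moving average (shrinking
at the edges) before extremum detection, because raw bin noise otherwise
produces spurious minima, and requires the dip below the first peak to
exceed 1% of the peak height to reject plateaus. Coordination numbers
count neighbors within a cutoff, averaged over center atoms and frames,
in three modes: a fixed cutoff; a dynamic cutoff set once per trajectory
from the first minimum of the center–neighbor RDF (recomputing it per
frame would make the cutoff itself noisy, so the trajectory-level choice
is deliberate); and a van der Waals mode with per-pair cutoff
$(r_A + r_B) \times \mathrm{scale}$ from a shipped Bondi-style radii
table that can be overridden per element.

## Hydrogen-bond networks

Hydrogen bonds use the direct geometric criterion: every hydrogen is
first attached to its nearest donor-candidate atom within 1.2 Angstrom
(ties broken to the lower index and flagged), and a bond D–H⋯A is
assigned when the H⋯A minimum-image distance is at most `d_HA_cut` and
the internal D–H⋯A angle (180° = linear) at least `angle_cut`. The
defaults 2.5 Angstrom and 130° are declared package defaults in the
range commonly used for water; both are mandatory CLI-overridable and
nothing in the package depends on them being universal. Bonds across
periodic images are found by construction. The per-molecule average
counts each bond for both its donor and acceptor molecule (the
convention under which bulk water sits near 3.8 bonds per molecule); a
donated-only mode is provided. Each frame also yields a network graph —
molecules as vertices, bonds as edges — whose connected-component count
is reported alongside the across-frame standard deviation of the bond
counts. Smoothed probabilistic bond definitions and bond lifetime
kinetics are out of scope.

## Cluster dynamics

`cluster_frame()` implements DBSCAN on the minimum-image distance
matrix of the selected atoms. A core point has at least `min_samples`
points within `eps` counting itself (the standard inclusive convention);
clusters are connected components of core points plus border points,
with border points attached to their lowest-index core neighbor and
cluster ids assigned by ascending minimal member index, making labels
deterministic. Running on minimum-image distances is essential: a clump
straddling the periodic boundary must cluster identically to its
centered translate. At the common operating point `min_samples = 2`,
the algorithm reduces exactly to connected components of the
eps-threshold graph with isolated vertices as outliers, which is the
independent oracle the tests compare against.

Outliers are never clusters. Both size conventions are always computed:
the headline average excludes outliers, and an inclusive variant counts
each outlier as a size-1 cluster. The trajectory-level series flags
frames whose cluster count exceeds its modal value as fragmentation
events.

## Subsampling by farthest-point sampling

Structure sets are ranked by greedy max-min selection in descriptor
space: each new pick maximizes the minimal Euclidean distance to the
already-selected set, with exact ties broken toward the lower index so
the ranking is deterministic without a seed. The built-in descriptor is
a normalized histogram of all pairwise interatomic distances per
structure — invariant under rotations, translations and atom
permutations — which keeps the module fully testable offline; SOAP or
any other per-structure descriptor can be plugged in as a plain matrix,
since the ranking only sees rows. The diversity curve reports the
min-distance trace normalized to the first measured distance and the
rank at which it falls below a fraction (default 5%) of that value,
the practical "nothing new is being added" diagnostic. The default
start index is 1 (deterministic) rather than random.

## Volumetric densities

Selected atoms of every frame are wrapped into the cell by fractional
coordinates and binned on a regular fractional grid with half-open
[0, 1) voxels — a position exactly on a boundary lands in the
higher-index voxel. The density is counts over (samples × voxel
volume), so it integrates to exactly 1; plane projections sum along the
orthogonal axis weighted by the voxel extent and integrate to exactly 1
over the plane (the pixel area is defined from the voxel volume so this
holds for non-orthogonal cells too). No smoothing is applied by
default. Output formats are long-form CSV and plain-text Gaussian cube
(negative voxel counts flagging Angstrom units); interactive 3D
rendering is out of scope.

## Synthetic fixtures and what the tests show

Every test input is generated by a seeded, RNG-state-preserving
generator with analytic ground truth:

* `make_ar1()` — stationary AR(1) with known $g$ and ACF; the error
  analysis is validated at $\varphi = 0.9$, $N = 10^5$, averaged over
  seeds.
* `make_brownian()` — periodic Gaussian walkers with known $D$; the
  headline validation uses 256 walkers × 2000 frames at
  $D = 0.23\ \mathrm{A^2/ps}$ and requires recovery within 5%.
* `make_lattice()` — simple-cubic lattice whose first shell holds
  exactly 6 neighbors; jittered variants give two-shell RDFs for the
  dynamic-cutoff path.
* `make_water_dimer()` / `make_water_chain()` — constructed geometries
  with exact H-bond distances and angles, giving exact hand counts.
* `make_water_box()` — random rigid waters used solely for
  oracle-equivalence tests of the bond machinery; it is *not* a
  physical water model and its bond statistics are not water's.
* `make_clustered_points()` — Gaussian clumps with known memberships.
* `make_uniform_gas()` — the ideal-gas reference for RDF normalization
  and density uniformity.

These fixtures exercise the estimators where the right answer is known
exactly or analytically. What passing them does **not** show: agreement
with any particular force field or electronic-structure water model,
behavior on under-sampled trajectories shorter than the observable's
correlation time, or descriptor quality of the built-in pair-distance
histogram relative to SOAP on chemically subtle datasets. Problem sizes
in the shipped tests (e.g. $N = 10^5$ series, 512k atom-frames for
diffusion, 500-atom boxes for RDF and FPS oracles) were chosen as the
smallest scales at which the analytic targets are statistically
resolvable at the stated tolerances.

## Known limitations

* Triclinic minimum-image search covers one neighbor shell; cutoffs far
  beyond half the minimal cell height are flagged but not enumerated to
  arbitrary image depth.
* The sub-window diffusion SEM is an agreement measure across correlated
  sub-fits, as discussed above.
* The vdW radii table covers common elements only; missing elements are
  an explicit error with a per-element override.
* Binary trajectory formats (DCD/XTC/TRR) are not read; extended XYZ and
  CSV are the interchange formats.
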