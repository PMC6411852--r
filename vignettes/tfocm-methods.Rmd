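---
title: "Traction force optical coherence microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Traction force optical coherence microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tfocm)
```

Traction force microscopy (TFM) reconstructs the forces a cell exerts on its
surroundings from the deformations those forces induce in a substrate of
known mechanics. `tfocm` implements a TFM variant built on spectral-domain
optical coherence microscopy (OCM): label-free interferometric volumetric
imaging of a cell embedded in a soft, bead-seeded hydrogel, refocused
computationally, tracked over a time lapse that ends in a chemically relaxed
reference state, and inverted through a regularized linear-elastic
finite-element model. This vignette records the models, the tunable
parameters, the numerical choices, and the limits of what the synthetic
validation can show.

## The instrument forward model

A spectral-domain OCM system records, per transverse beam position $(x, y)$,
an interference spectrum over vacuum wavenumber $k$. A scatterer of
amplitude $a$ at depth $z$ contributes fringes

$$ a\, E(k)\, e^{i 2 n k (z + \Delta z_{cg}(x,y))}\, T_\delta(x - x_j,\, y - y_j), $$

with $E(k)$ the Gaussian source envelope (center wavelength 800 nm,
bandwidth 160 nm FWHM by default), $n$ the medium index, $\Delta z_{cg}$ a
coherence-gate offset map (path-length differences across the scan), and
$T_\delta$ the transverse defocus response at defocus
$\delta = z - z_f(x,y)$ from the focal-depth map $z_f$. The defocus response
is the angular-spectrum propagation of a Gaussian pupil truncated at the NA,
with double-pass axial spatial frequency
$k_z(q) = \sqrt{(2nk_0)^2 - q_x^2 - q_y^2}$ evaluated at the central
wavenumber $k_0$. Because the simulator freezes the defocus phase at $k_0$,
the computational adaptive optics (CAO) kernel — the conjugate phase — is
its exact inverse; chromatic defocus is deliberately not modeled, so the
simulator/CAO pair is self-consistent by construction. Per-slow-scan-line
phase jitter (white, reflecting the slow axis's greater susceptibility to
interferometric phase fluctuation), a bulk transverse phase carrier
$e^{i\mathbf q\cdot(x,y)}$ from beam/stage tilt, depth fall-off (dB/mm), and
complex sensor noise complete the model. The noise floor is specified in dB
relative to the image amplitude of a unit scatterer, which is the natural
reference for bead-detection questions.

Scenes hold polystyrene-like beads drawn uniformly at the experimental
concentration (1.6e8 beads/mL, giving the characteristic spacing
$(10^{12}/1.6\times10^8)^{1/3} \approx 18\ \mu m$), an ellipsoidal cell
phantom filled with randomly phased interior scatterers (fully developed
speckle; phases re-randomized between burst repeats to emulate dynamic
intracellular speckle), and optionally a planar coverslip reflector used as
the phase/coherence-gate reference.

### Desk-scale grid

The default grid is 256 spectral samples and 96 x 96 beams over
320 x 160 x 160 um^3, preserving the full-scale instrument's axial voxel
pitch (1.25 um) at a fraction of its 2048 x 1024 x 1024 extent; validation
runs use a further-reduced 128 x 64 x 64 grid over 160 x 107 x 107 um^3.
All artifact mechanisms scale with voxel pitch and map *slopes*, not with
absolute FOV, with one important consequence: focal-plane tilt and
coherence-gate curvature amplitudes must shrink proportionally with the FOV
to stay in the "small tilt/curvature" regime in which a transversely
invariant CAO kernel (plus demodulation) is valid. The default maps are
scaled accordingly (sub-micrometre tilts across the reduced FOV).

## The six-step image-formation chain

1. **Volume reconstruction** — background (mean-spectrum) subtraction,
   optional resampling from a non-uniform wavenumber grid, optional Hann
   window, inverse Fourier transform along $k$. The complex field is kept.
2. **Coherence-gate curvature removal** — the coverslip is located per beam
   by peak detection with sub-voxel parabolic refinement, a 2D polynomial
   (order 2 by default, configurable to 4) is fitted, and the offset is
   removed per A-scan. The removal multiplies the spectrum by
   $e^{-i2nk\Delta z_{cg}}$ at the *true* wavenumbers: the field's axial
   carrier $2nk_0$ does not lie on a DFT bin of the sampled envelope, so an
   envelope-domain Fourier shift would leave a per-beam residual phase that
   becomes a transverse chirp for curved maps and wrecks demodulation and
   refocusing downstream. This is the single most delicate numerical point
   in the module.
3. **Focal-plane registration** — the focal-depth map is estimated by
   maximizing a normalized intensity-variance sharpness metric of refocused
   tiles (4 x 4 tile grid, coarse grid plus parabolic refinement in trial
   depth). Slices are ranked by energy times intensity contrast so that the
   bright but featureless reflector plane cannot dominate the metric. The
   map is fitted with a first-order polynomial by default: a *tilt* adds a
   pure linear transverse phase that the later demodulation removes exactly,
   whereas map curvature would add an uncorrectable chirp — this is why the
   method is stated for small tilt/curvature only.
4. **Phase registration** — one phase per slow-scan line, estimated as the
   phase of the inner product against a jitter-suppressed mean reference,
   iterated three times from two starting points (zero, and the dominant
   line-to-line phase ramp from the circular mean of adjacent-line
   increments: a carrier whose slow-axis component completes full cycles
   across the FOV would null the naive reference). The slow-axis component
   of the bulk carrier is absorbed here by design. Because a free phase per
   line can always overfit the reference, the correction is applied only if
   phases estimated from half the voxels also improve the alignment of the
   other half; the step requires a static reference structure (reflector or
   dense far-field scatterers) to make per-line phase identifiable at all.
5. **Bulk demodulation** — the remaining carrier is the peak of the
   depth-averaged transverse power spectrum, refined to sub-bin precision by
   parabolic interpolation of the log spectrum and, when the brightest plane
   is laterally uniform (reflector-like), by its direct phase gradient. An
   uncorrected carrier shears CAO-refocused volumes: a lateral bead offset
   growing linearly with defocus and flipping sign across focus.
6. **CAO refocusing** — per depth, multiply the transverse spectrum by
   $e^{-i(z - z_f)(k_z(q) - 2nk_0)}$ (evanescent region zeroed). All six
   steps are unitary on the complex field, and `apply_cao` refuses to run
   before steps 2–5 unless forced, because the chain order is what makes
   the refocused geometry trustworthy. The kernel sign convention is fixed
   empirically as the sign that sharpens a below-focus bead under this
   package's forward model; both signs are exposed for real-data dialects.

The property that matters for TFM is not sharpness but *geometric
fidelity*: after the full chain, bead centroids land within 0.25 voxel RMS
of their ground-truth positions at all depths, which is a stricter demand
than restoring resolution.

## Bead localization and tracking

Volumes are depth-normalized by a per-slice brightness scale smoothed with
a wide lowess fit — the scale must vary only on the fall-off length, since
slice-to-slice quantile fluctuations would distort each bead's own axial
profile and bias its depth centroid — then binarized at a single global
threshold, labeled with 26-connected
components, filtered by the stated size rules (< 16 voxels dropped at full
scale — the desk-scale pipeline uses 6 because its point-spread function
spans fewer voxels; objects above the 99th size percentile dropped: cell
body, aggregates, debris), and summarized by intensity-weighted centroids
with background-subtracted weights. The default threshold is a contrast
split — the geometric midpoint between the background median and the
bead-peak quantile — chosen over a plain Otsu split because beads occupy a
vanishing fraction of the volume and single-histogram methods tend to land
inside the background mode; Otsu remains available as an option.

Matching between time points uses feature vectors of offsets to the
`k_neighbors = 10` nearest neighbors, scored by offsets conserved within a
quarter of the mean spacing, with mutual-best acceptance followed by
relaxation of the leftovers against accepted neighbor motion. This exploits
the elastic-solid assumption that deformations vary on scales longer than
the bead spacing, and therefore also survives rigid motions larger than the
spacing. Tracks are chained to the final (relaxed) time point, which defines
zero displacement; gaps of one missing time point are closed, longer gaps
split the track. Rigid drift per time point is the componentwise median
displacement of beads farther than `far_field_radius` from the cell
(default 150 um at full scale, 70–110 um on the reduced FOVs — it must
exceed the ~100 um reach of cell-induced deformations, scaled likewise);
with fewer than ten far-field beads the correction is skipped and logged.
Two further guards reflect failure modes the synthetic scenes exposed:
detections inside the dilated segmented cell body are discarded before
tracking (dynamic intracellular speckle fragments into bead-sized blobs that
hop between time points), and beads whose displacement deviates from their
six nearest neighbors' median by more than max(0.5 um, five times the median
deviation) are rejected after drift correction — the same smooth-deformation
physics the matcher itself relies on.

## Cell geometry

Bursts of co-registered reduced-FOV volumes are collapsed by the voxelwise
standard deviation of the magnitude, which emphasizes dynamic intracellular
speckle and suppresses static background — including, as a known failure
mode, quiet fine protrusions whose speckle is static over the burst.
K-means (2 clusters by default) on the Gaussian-smoothed log of that volume
segments the cell; log features make the segmentation invariant to global
intensity scaling. The largest component is kept, holes filled, and a
radius-1 closing applied. Surfaces are extracted by marching tetrahedra on
the Kuhn subdivision of the (pre-smoothed, zero-padded) mask, Taubin
smoothed, and optionally decimated by vertex clustering (preferring a
somewhat larger watertight mesh over a smaller leaky one).

The volumetric cube-minus-cell mesh is built natively rather than through a
tet-then-hex conversion chain: a structured Kuhn tetrahedral grid is carved
(removing any element with a node or centroid inside the cell, so the
exposed staircase lies outside the surface), the exposed boundary nodes are
projected onto the cell surface with tangential relaxation to remove
staircase pleats, and projections that would invert elements are backed
off. Boundary facets exactly partition into `outer` (the imaging box) and
`cell` labels, with cell-facet normals pointing out of the elastic domain
(into the cell). What the inverse solver needs is this facet-label
contract, not a particular element zoo.

## Elasticity

The substrate is linear elastic, homogeneous, isotropic and time-invariant,
with defaults E = 90 Pa and Poisson ratio 0.45 (nearly incompressible; the
limit 0.5 is rejected because the displacement formulation degenerates
there). Internal units are um / Pa / Pa·um² with a single centralized
conversion (1 Pa·um² = 1e-3 nN). Linear tetrahedra lock volumetrically near
incompressibility, so the dilatational term is assembled with mean dilatation
over each parent grid hexahedron (a B-bar treatment); the uniform-strain
patch test remains exact to machine precision and the pressurized-cavity
benchmark converges monotonically under refinement. The outer boundary is
fixed (zero displacement) by default — far-field beads show essentially no
motion — and a displacement-function boundary condition is exposed, used by
the validation suite to impose analytic (Kelvin, cavity) far fields so that
oracle comparisons measure discretization error rather than box-size
effects. The Kelvin point-force solution is the analytic oracle throughout:

$$ u_i = \frac{F_j}{16\pi\mu(1-\nu) r}\left[(3-4\nu)\delta_{ij} + \frac{r_i r_j}{r^2}\right]. $$

## Traction inversion

The forward operator $G$ maps stacked per-facet traction components
(piecewise constant, one 3-vector per cell-surface facet) to stacked bead
displacements, built column-by-column from one cached factorization. The
inverse problem minimizes
$\|\hat G\hat t - \hat u\|^2 + \lambda^2\|\hat t\|^2$ in variables
normalized by the Young's modulus (tractions) and ~one voxel (displacements),
subject to exact force and moment balance — quasi-static motion makes the
balance categorical, so it is enforced by projecting onto the null space of
the six constraint rows, never penalized. The projected operator's SVD gives
the whole regularization path cheaply; singular directions more than ten
orders below the largest are truncated as round-off (they would otherwise
fabricate a spurious L-curve branch at tiny lambda).

Lambda is selected by the L-curve: the maximum-curvature corner of
(log residual, log solution norm) over a dense log-spaced grid, with a
speed guard masking the flat stretches where curvature is numerical noise.
If no corner exists the solver falls back to 1e-7 on the normalized
operator, the recorded default of the full-scale workflow; note that any
such coefficient is only meaningful relative to an operator scaling, and
with this package's normalization the corner on the validation problems
sits near 1e-2. On the contracting-sphere phantom at 1% displacement noise
the L-curve solution recovers the uniform normal traction within 10% with
cosine similarity above 0.9, and the residual lands at the noise floor
(discrepancy-principle cross-check).

Summaries per time point: the dipole matrix
$M = \mathrm{sym}\sum_f x_f \otimes t_f A_f$, its largest-|eigenvalue|
eigenvector as the principal stress axis, and the total force
$F = \tfrac12\sum_f |t_f\cdot\hat p| A_f$ — half the sum of absolute
projected pulls, representing the equal-and-opposite contraction. This
concretization of "total force along the principal stress axis" is this
package's own definition and should be cited as such, not attributed to any
external workflow. For an isotropically contracting sphere $M$ is a
multiple of the identity, the axis is flagged degenerate, and
$F = p\pi a^2$.

## The pipeline and its study conditions

`run_pipeline()` executes simulate → reconstruct (six steps) → track →
segment → mesh → solve → summarize from one declarative configuration, with
every random draw seeded from one master seed. The default schedule holds
five time points with traction amplitudes (0.6, 0.9, 1.0, 0.4, 0) of a
15 Pa uniform normal contraction — rising activity, inhibition, relaxation —
with the final, traction-free time point as the reference state, mirroring
a contractility-inhibition experiment (at full scale: 3 h at 5-minute
sampling, inhibitor after 30 min). Forward deformations are generated once
at peak amplitude through the ground-truth phantom mesh and scaled per time
point (linearity). The coherence-gate and focal-depth maps are instrument
properties, so the pipeline estimates them once (on the first volume) and
reuses them for the whole series: re-estimating them per time point would
let estimation noise masquerade as bead motion. At the working numerical
aperture the focal-depth estimate carries a constant bias of order the
Rayleigh range; it cancels in the registration (which only applies the map
minus its mean) and therefore never enters displacements. Each time point is segmented, meshed, and inverted
independently; the L-curve lambda is selected at the largest-deformation
time point and reused across the series, matching the single-coefficient
practice of the full-scale workflow. The reconstruction uses the Hann
window: at the desk-scale axial pitch the unwindowed point-spread function
spans barely one voxel and off-grid beads would split between slices.

Validation problem sizes (chosen once): 128 x 64 x 64 voxels over
160 x 107 x 107 um^3 for the pipeline, ~290 beads, ~350-facet cell
surfaces, structured grids of 10–20 cells per axis for the FEM, 200 beads
and ~130 facets for the inverse benchmarks.

## What the synthetic validation does and does not show

The generator reproduces the *mechanisms* that make this pipeline
non-trivial — defocus, gate curvature, focal tilt, phase jitter, carrier
shear, speckle, noise, bead-limited sampling — under known ground truth, so
the suite demonstrates that each correction removes its artifact and that
the inversion recovers known tractions at realistic noise. It does not
emulate: chromatic defocus or dispersion (hook provided, default zero),
higher-order aberrations, multiple scattering or non-circular-Gaussian
speckle statistics, nonlinear or viscoelastic substrate behavior, incomplete
relaxation of the reference state (surfaced only as a diagnostic), fibrous
matrix structure, or cell shapes beyond smooth ellipsoid unions. Passing
tests therefore certify the computational chain, not the biology; absolute
force scales on real gels also inherit the uncertainty of the measured
modulus. The bead density itself limits traction resolution to features no
finer than the ~18 um spacing, and reconstruction noise grows monotonically
as beads get sparser or noisier — a trend the suite checks qualitatively.
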