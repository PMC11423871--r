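---
title: "Nematic analysis of oocyte spindle microscopy: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nematic analysis of oocyte spindle microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nemspindle)
```

# The science in brief

Metaphase-II (MII) oocyte spindles are dense networks of microtubules.
Because microtubules align locally with one another, the network behaves as
a nematic liquid crystal: its steady-state architecture is governed by an
anchoring condition on the spindle surface plus bulk nematic elasticity, and
its fluctuations transmit torque the way nematics do. Each condensed
chromosome excludes microtubules, carving an elongated, tactoid-like *void*
into the network; deformation of the director field around these voids
mediates a long-range repulsion between chromosomes that organizes the
metaphase plate. This package implements the full quantitative chain behind
that picture — from raw polarized-light movies to the Monte Carlo model of
chromosome packing — together with synthetic-data generators that make every
stage testable against known ground truth.

The pipeline analyses two kinds of data:

* **LC-PolScope movies**: paired images of optical retardance $r(\mathbf r, t)$
  (nm) and slow axis $\theta(\mathbf r, t)$ (rad, mod $\pi$). For a spindle
  whose long axis lies in the image plane, retardance is proportional to the
  projected microtubule density,
  $r \approx A_0 \int \rho \, do$ with $A_0 \approx 7.5\,\mathrm{nm}^2$ per
  microtubule, and the slow axis reports the projected director.
* **Two-channel confocal stacks** (microtubules + chromosomes), used for the
  metaphase-plate configuration.

# Geometry: the pole-indented tactoid

The spindle outline is modelled by four circle arcs: two convex arcs that
intersect at *virtual poles* $(\pm L_0, 0)$ with belt apex $(0, \pm R_0)$,
and two concave polar-cap arcs of radius $r_0$ centred on the virtual poles
(`tactoid()`, `make_tactoid_boundary()`). With strong anchoring — tangential
on the convex belt, normal on the caps — the interior director lies tangent
to the unique family of circles through both virtual poles:

$$\theta_{\rm arcs}(x, y) = \operatorname{atan2}\!\big({-x},\, y - c(x,y)\big),
\qquad c = \frac{x^2 + y^2 - L_0^2}{2y},$$

implemented in `theta_arcs()`. This field is fully determined by $L_0$: once
the boundary is fitted, the interior pattern contains no free parameters,
which is why rescaled orientation fields from spindles of different size
collapse onto one master field.

`fit_tactoid()` recovers $(L_0, R_0, r_0)$ from a boundary curve by a nested
deterministic search: for each candidate $L_0$ (coarse log-spaced grid scan,
then local refinement — the loss is not unimodal once points are reassigned
between arcs), boundary points are assigned to the convex or cap arcs by
their residuals and the two circle fits are solved in closed form. The cap
radius is seeded from the low quantile of pole distances, because cap points
are always the innermost points around each pole; a mean over an angular
window would be contaminated by convex points for thin caps. Mirror symmetry
about both axes is enforced (left/right caps share one $r_0$); fitting the
caps independently is not implemented. Fits flag themselves `degenerate`
when no distinct cap sector survives (fewer than 3% of points), which is
what happens for a circular boundary.

All angle arithmetic is nematic: orientations live on the mod-$\pi$ circle,
averages use $\tfrac12\arg\sum e^{2i\theta}$ (`nematic_mean()`), and
distances are computed on the doubled angle (`nematic_diff()`), so $0$ and
$\pi$ never disagree.

# Synthetic data

`spindle_truth()` + `render_polscope_movie()` generate PolScope movies with
known ground truth. Retardance is an exact line integral of density through
the revolved tactoid minus void interiors (units: $A_0$ nm$^2$ $\times$
$\mu$m$^{-2}$ $\times$ $\mu$m $= 10^{-3}$ nm); the slow axis is
$\theta_{\rm arcs}$ plus a sampled fluctuation field; rigid drift, Gaussian
retardance noise and angular jitter emulate acquisition. Defaults are a
typical MII spindle: $L_0 = 15.2$, $R_0 = 8$, $r_0 = 4\ \mu$m, and
$\rho_0 = 25\ \mu\mathrm m^{-2}$, chosen so the central retardance is a few
nm as in real recordings. Voids (`void_truth()`) are circle-arc profiles of
chord $\beta$ revolved about the spindle axis and scaled anisotropically so
the waist is an ellipse with semi-axes $(a, b)$ — this reproduces both the
observed arc-shaped axial profile and the elliptical plate cross-section.

Orientational fluctuations (`sample_fluctuation_field()`) are Gaussian
random fields synthesized by spectral filtering of white noise with an
isotropic $|q|^{-2}$ equal-time spectrum (the active-nematic signature) and
an Ornstein–Uhlenbeck temporal kernel; the temporal statistics of the real
system are not specified by the physics used here, and the OU kernel is the
simplest stationary choice. Fields are rescaled to the requested RMS
amplitude per realization and multiplied by `void_boost` inside void masks.
The default amplitude (0.05 rad) is set so that instantaneous angle images
show a few degrees of mottle, as real movies do. What the generator does
*not* emulate: photorealistic optics (the point-spread function is a plain
Gaussian), cytoplasmic background, spindle-shape fluctuations, and any
coupling between density and orientation beyond the prescribed variance
boost — so passing tests demonstrate correctness of the *estimators*, not
realism of the images.

Pixel convention everywhere: pixel $(i, j)$ of a matrix is centred at
$((j-\tfrac12)\Delta,\ (i-\tfrac12)\Delta)$, row-major, physical units in
$\mu$m.

# Registration

`register_movie()` implements a four-step rigid registration: (1) the ROI
crop is assumed done (synthetic movies are rendered cropped); (2) each
retardance frame is blurred (3 $\mu$m), thresholded at half its robust
maximum (99.9th percentile — the plain maximum is noise-inflated on real
data), and the centre of brightness of the largest component gives the
per-frame translation; (3) one rotation, estimated from the whole movie,
makes the retardance-weighted nematic mean of the slow axis horizontal; (4)
each frame is aligned to a 10-frame moving-average reference by
cross-correlating gradient-magnitude images on the integer grid with
parabolic sub-pixel refinement, falling back to the coarse result (with a
warning) if the fine shift diverges. Retardance is resampled bilinearly; the
slow axis is resampled through its doubled-angle vector field
$(\cos 2\theta, \sin 2\theta)$ — never by averaging raw angles across the
branch cut — and the frame rotation is added to the angle values so
orientations transform as directions.

On synthetic movies the recovered drift is accurate to $\lesssim 0.05$ px
and rotations to $\lesssim 0.01^\circ$; the tests assert the looser
0.5 px / 0.5$^\circ$ contracts.

# Boundary extraction and its accuracy

`extract_boundary()` subtracts the corner-median background, blurs by
1 $\mu$m, and takes, on each polar ray from the spindle centre, the radius
of maximum gradient magnitude. Two accuracy regimes matter:

* On a sharp 2-D outline (step edge), the boundary is recovered to a pixel
  on the convex sectors; the 1 $\mu$m blur rounds the re-entrant cap
  corners, so cap-sector errors reach a few pixels.
* On *projected* retardance images the silhouette edge is a square-root
  profile, whose blurred gradient peak sits systematically inside the
  geometric outline (a few tenths of a micron), and near the poles the
  projection of the annulus around the indentation fills the region between
  the cap arc and the convex outline, so the gradient boundary there
  interpolates between the two. Fits of $(L_0, R_0, r_0)$ from projected
  images consequently carry a percent-level inward bias that cancels in
  rescaled (dimensionless) comparisons; the rescale-invariance test checks
  exactly that.

# Fluctuation spectra

`compute_fluctuations()` takes $\delta n_y(\mathbf r, t) \approx
\theta(\mathbf r, t) - \theta_{\rm arcs}(\mathbf r)$ in a centred box of
side $\lambda_0 = 8\ \mu$m, where the time-averaged angle stays within
$15^\circ$ and the small-angle identification of the angle difference with
the transverse director component is accurate to about 1%.
`fluct_spectrum()` mirror-pads the stack in all three dimensions, computes

$$c_{nn}(\mathbf q, \omega) = \frac{|\widetilde{\delta n}_y|^2}{\tau_0 \lambda_0^2},
\qquad
s_{nn}(\mathbf q) = \frac{1}{2\pi}\sum_\omega c_{nn}\,\Delta\omega,$$

and removes modes beyond the diffraction cutoff $|q| > 2\pi/\lambda_{im}$
($\lambda_{im} = 0.530\ \mu$m). The normalization is fixed by Parseval:
$\sum_q s_{nn} (\Delta q / 2\pi)^2$ equals the time-averaged spatial
variance exactly, and removing the cutoff ring changes it by exactly the
ring's weight. Doubling the padding width must not (and does not) change
the spectrum at common modes. Two numerical notes: the Nyquist row of a
mirror-padded transform vanishes identically and is dropped from slices;
and for *periodic* synthetic fields, slices are evaluated with
`pad = "none"`, because mirror-reflecting an already-periodic realization
injects seam leakage that distorts single-realization slopes of steep
spectra.

`slice_qy()` evaluates $s_{nn}(q_0, q_y)$ at the lowest axial mode
$q_0 = 2\pi/\lambda_0$ (averaged over $\pm q_0$ and $\pm q_y$). Because the
axial mode is fixed, the theoretical slice is $\propto (q_0^2+q_y^2)^{-1}$;
slope checks therefore regress on $|q| = (q_0^2+q_y^2)^{1/2}$.
`find_spectral_peak()` calls a peak any interior local maximum of the raw
slice (a single padded-grid bin can carry a genuine comb line, so no
smoothing) that exceeds a background $A\,(q_0^2+q_y^2)^{p/2}$ — fitted
through the three lowest and three highest points — by at least twice the
MAD of the relative residuals and by at least 50% (chi-square mode noise
stays well below that after averaging). Homogeneous fields yield no peak;
fields with fluctuations concentrated in regularly spaced voids yield a
peak within one bin of $2\pi/\text{spacing}$. The per-spindle slice is
symmetrized first and averaged across spindles afterwards; averaging before
normalization would weight spindles by duration.

`local_binarize()` implements the local adaptive rule (pixel $\geq$ mean
over a 2 $\mu$m disk, with in-image normalization at borders and a
floating-point guard on the $\geq$). Note the rule's own fixed point: any
locally constant region maps to 1. `density_fluctuation_coupling()` returns
the least-squares slope of $\langle|\delta\theta|\rangle_t$ against
$\langle r\rangle_t$ over box pixels and the low/high-density class ratio.
The class ratio is a *diluted* readout of a built-in variance enhancement —
the binarization classes only partly coincide with true void footprints —
so tests assert detection, null behaviour, boundedness and monotonicity
rather than exact recovery.

# Density inversion and void shape

For a cylindrically symmetric spindle, the transverse retardance profile at
axial position $x$ is $r(x, y) = 2 \times 10^{-3} A_0 \rho_x(x) \sqrt{R(x)^2 - y^2}$.
`fit_cross_sections()` estimates $R$ per column from the *support* of the
profile: since $r^2 = C (R^2 - y^2)$, two near-edge samples extrapolate the
zero crossing exactly, independent of pixel phase; the density is then the
exact area integral $\rho_x = \int r \, dy / (10^{-3} A_0 \pi R^2)$. This
estimator is unbiased in the presence of voids, unlike the joint
least-squares fit of $(\rho_x, R)$ (available as `R_mode = "free"`), which
trades density against radius when voids deplete the chord interior —
the two agree on void-free columns, and the support-based $R(x)$ reproduces
the fitted tactoid silhouette to well under a percent. The normalization
reference is a robust high quantile (median of the top quartile) of
$\rho_x$ over columns with well-developed cross sections ($R$ at least half
the maximum), which excludes stubby tip columns whose radii are unreliable.

`void_fractions()` attributes the missing density to voids: the plate-area
fraction is $1 - \rho_x(0)$ (averaged over $|x| < 0.5\ \mu$m) and the
volume fraction weights the deficit by the local cross-section area.
Deficits are only counted inside the *central window* between the void-free
shoulders; outside it, the annular polar-cap cross sections would
masquerade as voids. `void_width_profile()` divides the missing area
equally among $n_{\rm chr} = 20$ voids, converts to an effective diameter
$d(x) = 2\sqrt{A_{\rm void}(x)/\pi}$, and fits a circle-arc width profile
with waist $w$ and chord $\beta$ using the sagitta relation
$\rho_c = \beta^2/(4w) + w/4$. By construction of the area attribution, the
waist estimates the geometric mean $\sqrt{ab}$ of anisotropic void cross
sections; the tests verify this across aspect ratios 1–2.5. Voids are
treated as identical and in phase along the axis — the same simplification
as an "average void profile".

# Metaphase-plate analysis

`reslice_to_plate()` finds the best-fit plane of the chromosome channel
from intensity-weighted principal axes (the plate normal is the
smallest-variance direction of the slab-like distribution) and resamples
both channels on that plane by trilinear interpolation; synthetic stacks
tilted by 30° are recovered to better than a degree.

`segment_chromosomes()` applies the stated chain — Gaussian blur, local
adaptive binarization (1.5 $\mu$m), erosion by a 0.4 $\mu$m disk — inside a
plate boundary derived from the total intensity (blank backgrounds would
otherwise binarize to speckle under the $\geq$-mean rule). The blur
parameter is read as a $\sim 4\sigma$ full width ($\sigma = 0.5\ \mu$m):
with $\sigma$ at or above 1 $\mu$m, neighbouring chromosomes at the
observed 2.4 $\mu$m spacing merge irrecoverably, while $\sigma = 0.5\ \mu$m
suppresses shot noise without bridging. The erosion radius interpretation
(0.4 $\mu$m disk) shrinks sections by roughly the binarization's expansion;
residual size biases of the chain are at the tens-of-percent level on the
narrow axis, which is why chromosome dimensions are summarized from
second-moment ellipse fits (`fit_ellipses()`, exact for ideal masks, with a
$\Delta^2/12$ pixel-integration correction) and why the acceptance decision
(19–20 components) is returned rather than silently applied. Connected
components are 4-connected.

`pair_correlation()` computes the edge-corrected pair correlation
$g_{II}(s)$ by FFT autocorrelation of the zero-padded masks — exactly
equivalent to pair counting — normalizing the chromosome-pair counts by the
boundary-pair counts per radial bin (0.1 $\mu$m) and by the squared mean
coverage. Identities: $g_{II}(0) = 1/\phi$ for coverage $\phi$, $g \equiv 1$
for uniformly random masks at any density (the edge correction removes all
boundary-shape trends). `gii_extrema()` averages curves across spindles or
replicates, lightly smooths (3-point), finds the first interior minimum
beyond the point where the curve drops below $g(0)/2$ (the near-field
shoulder) and the following maximum — both refined by parabolic
interpolation and required to rise by at least 0.05 (prominence, fixed in
advance of any ensemble measurement) — and bootstraps spindles (resampling
curves with replacement, 1000 draws by default; the CI is the bootstrap SD).

# The defect-quadrupole model

A 2-D void of length $\beta$ and width $D$ in a uniform far-field director
is represented by four half-integer defects on the axis: $-\tfrac12$ at
$(\pm\beta/2, 0)$ and $+\tfrac12$ at $(\pm p, 0)$. In the one-constant
Frank approximation each contribution $k_i \arg(z - z_i)$ is harmonic, so
the superposition solves the bulk Euler–Lagrange equation; the void
boundary is *emergent* — the separatrix of the director through the outer
defects — rather than an imposed anchoring condition. `solve_geometry()`
finds $p$ by bisection so the traced lens has width $D$ (the width is
monotone decreasing in $p$; as $p \to \beta/2$ the $\pm\tfrac12$ pairs
annihilate and the lens closes). Streamlines are integrated with RK4 at
step $\beta/800$ on the unit line field with orientation continuity; the
upper branch leaves the $-\tfrac12$ core at $60^\circ$ (the separatrix
angle of a $-\tfrac12$ defect) and is terminated at the abscissa of the
opposite defect, where the miss distance (closure tolerance $\beta/100$)
guards the construction — forward shooting along a separatrix is unstable,
so integration past the far defect is not attempted, and the lower branch
follows by mirror symmetry.

For two aligned voids offset by $d$ perpendicular to the far-field
director, the interaction is the charge-neutral cross-pair sum

$$U_{\rm int}(d)/k = -2\pi \sum_{i \in A,\ j \in B} k_i k_j \ln |r_i - r_j|,$$

well-defined without a reference scale because each cluster is neutral. It
is positive and strictly decreasing at all separations and decays as
$d^{-4}$ in the far field (the aligned-quadrupole law; dipole moments
vanish by symmetry). The tests verify the sum against a brute-force
numerically integrated Frank cross-energy
$\int \nabla\theta_A\!\cdot\!\nabla\theta_B\, dA$ with regularized cores to
0.03%. Rigid superposition is used at all separations; at small $d/\beta$
the true two-void problem would re-solve the defect geometry
self-consistently, a known approximation risk of this construction. The
energy prefactor convention ($-2\pi k\, k_i k_j \ln r$) only rescales
$U/k$; slopes, monotonicity and Monte Carlo configurations are unaffected.

# Monte Carlo chromosome placement

`random_placement()` is random sequential insertion of hard ellipses
(full axes $2.1 \times 0.8\ \mu$m) in a disk, rejecting overlap and
boundary violation; `anneal_plate()` is Metropolis annealing with
single-particle translation+rotation moves, hard constraints rejected
outright, a tabulated pair potential of the center-to-center distance
(surface-to-surface separation via the Perram–Wertheim scaled gap is an
option), and a geometric temperature schedule ($T_0 = 20 \to T_f = 1$ over
600 sweeps of 20 moves). Overlap detection uses the exact Perram–Wertheim
contact criterion in compiled code, verified against a point-membership
oracle; the disk default of 6.5 $\mu$m puts 20 ellipses at the observed
~20% plate coverage.

The repulsion amplitude is calibrated so that $U(s^*) = 1\,k_BT$ at the
observed typical chromosome spacing $s^* = 2.4\ \mu$m. This is the
thermal-scale choice: the interaction at the typical spacing is comparable
to thermal energy, which keeps the ensemble a liquid with robust local
order. Substantially stronger coupling (e.g. $5\,k_BT$ at $s^*$) makes the
effective interaction diameter exceed the geometric packing spacing
($\approx 2.77\ \mu$m for 20 centres in the disk) and freezes the ensemble
into a boundary-compressed near-crystal — measurably *not* "ordering
without freezing". Extremum existence is robust over at least a
$3\times$ amplitude range; the *location* of the $g_{II}$ maximum is set by
the packing density and sits near 2.7 $\mu$m in this geometry for every
coupling and schedule we probed, somewhat above the $\sim$2.4 $\mu$m seen
with experimentally derived boundaries. Steric-only ensembles at this
density are not structureless either: at high replicate counts the contact
shell of hard convex particles appears as a weak ($\sim$0.1) interior
feature, and the fully-inside wall convention leaves a mask-depleted rim
that pulls the long-distance tail below one. Both effects are properties
of the null model itself, not detection noise.

`simulate_ensemble()` renders every final configuration to masks at the
analysis pixel size and pushes them through the *identical* pair-correlation
code path used for imaging data.

# Problem sizes and numerical defaults

The shipped tests exercise movies of a few dozen frames at 0.2–0.4 $\mu$m
pixels, $64^2$ fluctuation grids, and Monte Carlo ensembles of 25–200
replicates; the headline ensemble quantities use 200 replicates of 20
ellipses with 200 bootstrap draws, which reproduce extremum locations to
$\pm 0.01\ \mu$m across seeds. Key tolerances: tactoid round-trips to 0.5%;
registration contracts 0.5 px / 0.5°; spectrum slopes $\pm 0.2$ on
seed-averaged slices; void waist/length recovery within 15%; Frank-energy
cross-check within 2%.

# Known limitations

* Boundary extraction on projected images carries a sub-micron inward edge
  bias (square-root edge under blur) and cannot resolve the cap arc where
  the annulus projection fills the indentation; dimensionless shape ratios
  are unaffected.
* The segmentation chain's size biases (blur/binarize/erode) reach tens of
  percent on the narrow chromosome axis; counts and positions are reliable,
  absolute axis lengths are not.
* The defect-quadrupole interaction uses rigid superposition; small-$d$
  behaviour is approximate.
* The Monte Carlo boundary is an ideal disk; experimentally derived,
  irregular plate outlines shift the pair-correlation maximum and soften
  the steric null's residual structure.
* The generator's fluctuation fields are Gaussian with prescribed
  statistics; they validate estimators, not microscope physics.
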