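---
title: "A mechanochemical model of spindle-cortex crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A mechanochemical model of spindle-cortex crosstalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlecortex)
```

## The model

Dividing animal cells position and orient their mitotic spindle through
cortical force generators: the Gai--LGN--NuMA complex recruits dynein, which
pulls on astral microtubules. `spindlecortex` implements a two-way coupling
between this machinery and the spindle itself, in which the chromatin is not
a passive cargo but actively patterns the cortex: a Ran-GTP signal centred
on the DNA accelerates the unbinding of cortical LGN within a finite range
of the chromatin. The cortex pulls the spindle; the spindle's DNA erases the
cortex behind it; the cortex re-forms slowly elsewhere. This feedback has no
static equilibrium in general, and the package's purpose is to simulate its
consequences and to quantify them the same way live-imaging data are
quantified.

### Cortical LGN field

Bound LGN is a concentration `c(x, t)` on a one-dimensional cortex path
(periodic circle or finite line) or on a closed two-dimensional cell
contour, obeying

    dc/dt = D d2c/dx2 + b - koff(x) c

with a constant binding source `b` from an unlimited cytoplasmic reservoir
and a position-dependent unbinding rate: `koff = koff_near` within the
inhibition range `d_inh` of the DNA edge and `koff_far` beyond it, joined by
a logistic step of width `sigma`. Concentrations are dimensionless: `b =
koff_far` by default, so the unperturbed far-field steady state is 1 and
`c` reads as "fold of the resting cortical level".

| parameter | default | units | meaning |
|---|---|---|---|
| `D` | 0.01 | um^2/min | cortical LGN mobility (accumulations are nearly immobile) |
| `koff_near` | 1/10 | 1/min | unbinding near the DNA (~10 min timescale) |
| `koff_far` | 1/90 | 1/min | unbinding far from the DNA (~90 min timescale) |
| `d_inh` | 4 | um | inhibition range, measured from the DNA edge |
| `sigma` | 0.5 | um | smoothness of the near/far switch |
| `w_dna` | 4 | um | DNA half-extent (interval footprint in 1D) |

Two choices here were genuinely open. First, the DNA footprint: we model it
as an interval (1D) or a disc/segment (2D) of finite extent, with the
inhibition range measured from its *edge* — the 4 um range is an
edge-to-cortex distance in the imaging statistic it matches, so the model
measures it the same way. Second, the switch width: nothing pins `sigma`; we
default to 0.5 um because a perfectly hard step locks the transition layer
to the grid, and expose `sigma = 0` for comparison.

### Spindle motion in one dimension

A monopolar spindle is a rigid DNA--centrosome pair (`xc = xn + delta`)
advected by the LGN-weighted pull on its astral microtubules:

    v = v0 * Int cbar(x) pMT(x - xc) dx

where `cbar = c / <c>` is the mean-normalized field, `pMT(u) = sign(u)
rho(|u|)/2` is the signed density of microtubule plus ends built from the
astral length distribution `rho`, and `v0` (um/min) absorbs the dynein force
per unit LGN at the reference concentration, the microtubule number, and the
friction coefficient — it is the single mechanical free parameter, fitted
per cell (population value 6.7 um/min). The default `rho` is an exponential
of mean 6 um truncated at 20 um; `mt_empirical()` accepts a two-column table
so a measured histogram can be dropped in.

With the default parameters this feedback loop is linearly unstable: an
arbitrarily small asymmetry grows until the spindle travels at constant
speed (~1.3 um/min at defaults) behind a co-moving LGN depletion trough — a
traveling wave. On a finite line the wave cannot run forever: ahead of the
spindle the force integral is truncated at the cortex ends, so the spindle
decelerates, turns, and oscillates end to end, fastest at the line centre.
A bipolar spindle (two asters flanking a central plate) has an exactly
symmetric rest state; whether perturbations decay or grow into a moving
state depends on parameters, and `bipolar_moving_params()` ships a
configuration in the moving regime.

### Rounding and bipolar orientation in two dimensions

Mitosis is modelled as two phases separated at `t_bipolar = 9` min after
nuclear envelope breakdown. In phase I the cell outline (an ellipse with
half-axes `a`, `b`) relaxes exponentially toward the rounded circle while
the spindle angle is frozen: cortex-bound LGN is remapped conservatively
onto each new contour (concentration scales with inverse segment length, so
rounding *concentrates* LGN), and the DNA — a disc of radius `r_dna` —
inhibits the cortex wherever it comes within `d_inh`. Because the interphase
short axis is the only part of the cortex within range, phase I converts
cell *shape* into a cortical *pattern*: LGN crescents at the long-axis
poles. In phase II the DNA becomes the metaphase plate (a segment of
half-length `w_plate` perpendicular to the spindle axis) and the spindle
rotates under the cortical torque

    Gamma = sum_poles Int dtheta P(l >= d(theta)) c(contact) [r x f]_z

summing unit pulls along each microtubule direction, weighted by the
probability that an astral microtubule reaches the cortex and by the LGN
concentration at its contact point; `dphi/dt = mu_r * Gamma`.

Geometry defaults are chosen for a HeLa-like cell: interphase half-axes 20
and 7 um, rounded radius 10 um, rounding time constant 4 min (rounding is
essentially complete when the bipolar spindle forms), chromatin disc radius
5 um, plate half-length 6 um (a ~12 um metaphase plate, whose tips come
within the 4 um range of a 10 um cortex), pole half-separation 5 um. The
rotational mobility `mu_r = 0.5` was calibrated once — so that a defaults
run starting at 45 degrees completes its reorientation within ~20 min of
phase II — and then frozen; it is a unit conversion, not a fitting knob.

Two conventions differ deliberately between 1D and 2D. The 1D velocity uses
the mean-normalized `cbar`, which makes the per-cell `v0` fit exactly
scale-invariant in intensity. The 2D torque uses `c` on its absolute scale
(far-field steady state 1), because the torque must scale with the *amount*
of cortical force generators: `lgn_scale` multiplies the binding source `b`
to emulate LGN RNAi, and alignment degrades as the source is reduced —
normalizing `c` would hide exactly the effect being modelled. An optional
external cue is an additive, Gaussian-localized binding source on the
contour; a strong cue perpendicular to the long axis captures the spindle,
showing the intrinsic patterning is overridable.

The simulation runs in the body frame of the interphase ellipse and rotates
all reported angles by `axis_angle` afterwards, so rotational equivariance
holds exactly rather than to solver tolerance. Spindle angles are nematic
(`phi` and `phi + pi` identical); reported nematic angles live in
`(-pi/2, pi/2]`.

## Numerical choices

* **Scheme.** Strang splitting per step: half an exchange step, a full
  diffusion step, half an exchange step. The exchange half-steps use the
  pointwise exact exponential update (exact for pure binding/unbinding,
  positive for any `dt`), and diffusion uses backward Euler, whose
  propagator is the inverse of an M-matrix and therefore cannot create
  negative values. The composed step is positivity-preserving
  unconditionally; the backward-Euler diffusion bounds the overall accuracy,
  so the scheme's stationary profile sits a first-order-in-`dt` offset from
  the direct boundary-value steady state (~5e-5 relative at the default
  `dt = 0.05`, halving with `dt`).
* **Diffusion propagator.** On a periodic grid the propagator is a
  circulant convolution. When the kernel is narrow (the default regime:
  `D dt / dx^2 ~ 1e-2`) it is applied as an explicit paired convolution
  `k0 c_i + sum_j k_j (c_{i-j} + c_{i+j})`, which keeps a mirror-symmetric
  field mirror-symmetric *to the last bit* — this is what makes the
  unperturbed bipolar configuration an exact rest state of the
  discretization rather than a slowly drifting one. Wide kernels fall back
  to an FFT solve; line domains use a cached dense inverse with no-flux
  ends.
* **Grid.** `dx = 0.2` um resolves the diffusive boundary layer
  `sqrt(D/koff)` (0.3--0.95 um for the default rates); the test suite
  includes a convergence check that the traveling-wave speed moves by less
  than 2% when `dx` and `dt` are halved.
* **Force quadrature.** The 1D aster integral is evaluated as
  `(1/2) Int rho(u) [cbar(xc+u) - cbar(xc-u)] du` on node-aligned offsets
  with trapezoid weights: the sign discontinuity of `pMT` at the centrosome
  is handled analytically, a uniform field gives exactly zero force, and
  mirror reflection negates the force exactly. Interpolation queries landing
  on grid nodes are snapped to them, again for exact symmetry.
* **Advection.** Explicit Euler on the spindle position with sub-stepping so
  the spindle never crosses more than half a grid cell per velocity
  evaluation.
* **Torque quadrature.** 720 microtubule directions per pole by default;
  the test suite checks a 10^4-direction brute-force quadrature agrees
  within 1%. Ray--ellipse contact points are solved in closed form.
* **Seeds.** The only randomness in the simulators is the seeded sign and
  placement of the initial perturbation; synthetic-data noise draws are
  decoupled from the simulation seed so the same dynamics can be observed
  under different noise realizations. All cohort draws derive from one
  master seed.

## The synthetic-data generator

`make_monopolar_dataset()`, `make_line_dataset()`,
`make_rounding_dataset()` and `make_cohort()` emulate the data the
quantification stage expects from live imaging: kymographs of normalized
cortical intensity along a 1D path with a DNA track (frame intervals 2, 3
or 5 min), trajectories, contour intensity series during rounding with
shrinking ellipse axes, and per-cell `v0` drawn from a zero-truncated
normal with mean and SD both 6.7 um/min. Imaging noise is multiplicative
Gaussian (default SD 0.1 of signal) plus additive Gaussian background
(0.05 +/- 0.02 of the signal scale), clamped at zero — placeholder values of
a realistic order, not measured ones, and exposed as configuration. Every
dataset carries a ground-truth manifest written to a separate directory;
the quantification functions never read it, so recovery tests are honest.

What the generator does *not* emulate — and hence what passing recovery
tests do not establish about real data: segmentation and manual-tracking
error in the DNA track, photobleaching and other slow intensity drifts,
spatially correlated speckle, out-of-focus contributions in the 2D contour
intensities, and any 3D effects (centrosome tilting, cortex curvature out
of plane). The zero-truncation of the per-cell `v0` draws also means the
sample mean of a synthetic cohort sits above the nominal population mean
(by ~29% when SD equals the mean) — the recovery tests compare against the
truncated-normal mean, not the nominal one.

## Quantification pipeline

The measurement procedures mirror the imaging analysis exactly so they can
be applied unchanged to synthetic or real tables: background subtraction
with global (spatiotemporal-mean) or per-frame normalization; the per-cell
`v0` fit, which is a closed-form least squares through the origin on the
cumulative unit-`v0` displacement and is exactly intensity-scale-invariant
and linear in the observed displacement; a formal least-squares version of
the kymograph-matching parameter fit (Nelder--Mead on the log of `D`,
`koff_near`, `koff_far`, `d_inh`, forward model = the imposed-track
simulator; the experimental analogue was tuned by hand, so the fitter also
accepts fixed parameters); the inhibition-range statistic (minimum DNA
distance of sites above the 0.975 intensity quantile, linear-interpolation
sample quantile, ties included); frame-to-frame speeds and maximum
excursion with the 10 um flag; moving-average phase portraits
(central differences, one-sided at the ends); and cohort alignment
summaries of `a = cos 2 phi`.

One caveat on the quantile statistic: on a noiseless, monotone steady-state
profile the top-quantile sites concentrate at the farthest plateau, so the
statistic reads the far tail, not the transition — it is designed for
noisy, patterned frames (where supra-threshold sites scatter over the
high-LGN region and the minimum distance tracks its near edge). For
recovering the model's inhibition range from clean profiles the package
provides `estimate_inhibition_midpoint()`, which reconstructs the local
off-rate from the stationary balance and locates its transition midpoint.

## Problem sizes and runtimes

The shipped tests and the acceptance script use an 80 um periodic domain at
`dx = 0.2` (400 nodes), runs of 120--450 min of biological time at
`dt = 0.05` min, 256-node contours for 40 min of rounding/orientation, a
12-angle grid for the alignment basin, and single-fit kinetic recoveries on
41-frame kymographs. These sizes keep every stage at seconds to a couple of
minutes on one core while leaving the traveling wave, the oscillation, and
the reorientation fully developed.

## Known limitations

* The 1D model cannot capture spindle turns: the centrosome--DNA offset
  `delta` is rigid and never flips at reversals.
* Microtubule forces are mean-field integrals over the length distribution;
  there is no stochastic microtubule dynamics.
* The bipolar force law sums both asters without occlusion by the central
  plate.
* The 2D spindle is pinned to the cell centre (rotation only), and cortical
  mechanics (stiffness gradients, myosin) are outside the model.
* Cytoplasmic LGN depletion is neglected (reservoir assumption), so
  `lgn_scale` acts on the source only.
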