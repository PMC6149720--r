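---
title: "Methods: lamellar neutron diffraction reduction and bilayer structure"
author: "lamellar package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lamellar neutron diffraction reduction and bilayer structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamellar)
```

## The measurement and the model

Oriented lipid multilayers hydrated from water vapour diffract a
monochromatic neutron beam into a ladder of lamellar Bragg reflections.
Each reflection order $h$ samples one Fourier amplitude of the
one-dimensional neutron scattering length density (NSLD) profile
$\rho(z)$ across the repeating bilayer + water unit cell. The package
implements the full chain from rocking-scan peak tables to structural
parameters:

$$\rho(z) \;=\; \frac{F_{0,\mathrm{abs}}}{D} \;+\;
  \frac{1}{k}\,\frac{2}{D} \sum_{h=1}^{h_\mathrm{max}}
  F_h \cos\!\Big(\frac{2\pi h z}{D}\Big),$$

with $D$ the lamellar repeat distance from the Bragg equation
$2D\sin\theta_h = h\lambda$, $F_h$ the signed structure factors,
$k$ the absolute scale, and $F_{0,\mathrm{abs}}$ the forward-scattering
term fixing the profile offset via $A\,F_{0,\mathrm{abs}} = b_l - \rho_w V_l$
(generalized to include an alcohol at mole ratio $x$:
$b_l + x b_a$ and $V_l + x V_a$). Structure factor magnitudes come from
integrated peak intensities,

$$|F_h| = \sqrt{I_h / (L_f A_c F_c)},\qquad
  L_f = 1/\sin 2\theta_h,\qquad
  A_c = \frac{\sin\theta_h}{2\mu t}\Big[1 - e^{-2\mu t/\sin\theta_h}\Big],\qquad
  F_c = \mathrm{erf}\!\Big(\frac{l\sin\theta_h}{8\sigma}\Big),$$

the Lorentz, absorption and beam-footprint (flux) corrections for a
monochromatic beam. The $8\sigma$ denominator in $F_c$ is implemented
as printed in the source formula; because the same expression under a
Gaussian-beam convention would read $\sqrt{8}\sigma$, both variants are
available (`instrument_config(flux_denominator=)`), with "as-printed"
the default.

All lengths are Angstrom, all densities $10^{-6}\,\mathrm{\AA^{-2}}$,
angles are degrees ($2\theta$) at the I/O boundary and radians
($\theta$) internally.

### Conventions

Two printed-formula ambiguities had to be resolved:

* **Fourier normalization.** The package defines
  $F_h = \int_{-D/2}^{D/2} \rho(z)\cos(2\pi h z/D)\,dz$ — the unique
  convention conjugate to the synthesis equation above, under which
  $F_0$ equals the profile mean times $D$ and
  `synthesize_profile(theoretical_structure_factors(p))` is the
  identity as $h_\mathrm{max}\to\infty$.
* **Profile offset.** $F_{0,\mathrm{abs}}$ follows the printed
  per-molecule relation exactly. Absolute offsets of reconstructed
  profiles are therefore conventional; every structural output of the
  package (peak positions, interface midpoints) is deliberately
  invariant to the DC term and to $k$.

## Contrast variation: signs, scale, and the water distribution

For a centrosymmetric bilayer the phase problem reduces to a sign per
reflection. Measuring at several D$_2$O/H$_2$O ratios makes each signed
$F_h$ an affine function of the water NSLD $\rho_w$:
$F_h(\rho_w) = B_h + \rho_w W_h$, where $W_h$ is the cosine coefficient
of the water distribution $w(z)$. Water NSLD itself is computed from
the coherent scattering lengths of H, D and O and the 30 Å$^3$
molecular volume of water (`water_nsld()`), which places the
contrast-match point at 8.1% D$_2$O — the reason measurements at 8%
D$_2$O expose the bilayer-only profile and its head-to-head distance
$D_{HH}$.

`assign_signs()` works in two stages:

1. **Within each order**, all $2^{C-1}$ sign patterns across the $C$
   contrasts are searched exhaustively and scored by (inverse-variance
   weighted) linearity in the D$_2$O fraction. Near-ties are flagged
   ambiguous and the runner-up pattern is reported. When magnitude
   uncertainties are supplied, a reflection weaker than $3\sigma$ takes
   its sign from the fitted line — a point at a contrast zero crossing
   has a noise-dominated sign of its own.
2. **Between orders**, linearity is provably blind to a whole-order
   sign flip (it negates the fitted line and leaves residuals
   unchanged), so the per-order orientation is fixed physically: the
   fitted slopes must match the cosine coefficients of an interfacial
   error-function water step. Step templates over a grid of Gibbs-plane
   positions and widths are scored by magnitude-space cosine
   similarity; the winning template orients every order and
   simultaneously fixes the global sign (water rises towards the cell
   edge; equivalently the headgroup maxima of the water-matched profile
   come out positive). Orders whose water leverage is small are flagged
   (`weak_leverage`), and reflections below 2% of the strongest
   magnitude are marked `cell_indeterminate`: their reported sign
   carries no information at the measurement precision, which is the
   honest statement of what contrast variation can and cannot phase.

`absolute_scale()` determines $k$ from the same affine structure: the
per-order slopes $\partial F_h/\partial\rho_w$ equal $k\,W_h$ for a
unit-plateau water step, so a grid-plus-Nelder-Mead fit of (Gibbs plane
$z_0$, width, scale) to the slope vector returns $k$ without ever
synthesizing a profile. This is equivalent to requiring the
reconstructed water distribution to plateau at 1 between bilayers, and
it is deterministic.

`water_distribution()` recovers $w(z)$ from pairwise profile
differences divided by the water-NSLD differences. Pairs are combined
with weights $\propto \Delta\rho_w^2$, which is identical to the
per-point regression of $\rho(z)$ on $\rho_w$ and prevents the
low-leverage 8%/20% pair from dominating the noise. The result is
normalized so the outer 10% of the cell averages 1; at the
interlamellar spacings typical of vapour-hydrated samples
($D_W \approx 8$–$9$ Å) the water fraction has no fully saturated
plateau, so this normalization is a defined convention rather than an
asymptote, and downstream estimators are affine-invariant on purpose.

## Bilayer thickness: a resolution-aware Gibbs fit

`gibbs_interface()` fits each side of $w(z)$ with an error-function
step and reports $D_B = 2 z_0$. Two numerical points matter:

* A 5–6 order Fourier reconstruction rings. Fitting a plain step to the
  ringing profile biases $z_0$ by several tenths of an Angstrom. When
  the water distribution carries its truncation order, the step model
  is therefore pushed through the same truncation before comparison
  (an error-function step as it would actually be observed at that
  resolution). The fit is a grid over $z_0$ (0.05 Å) and width
  (0.25 Å) with the baseline solved linearly — the amplitude is tied to
  the unit plateau through the same outer-10% normalization applied to
  the data — followed by continuous refinement.
* The mean-position (integral Gibbs construction) estimator is always
  computed and reported as `D_B_integral`, and is the fallback when the
  step fit fails; the step fit is the primary estimator because the
  integral construction needs a trustworthy DC term, which the printed
  forward-scattering convention does not pin down.

`head_to_head()` locates the two headgroup maxima of the water-matched
profile by 3-point parabolic interpolation — deterministic and honest
about what a 5-order reconstruction can resolve; no spline smoothing.

Derived quantities close the chain with exact identities that are
asserted at assembly time: $D = D_B + D_W$,
$A = 2(V_l + x V_a)/D_B$ (the Gibbs volumetric identity), and the
interlamellar water count $n_W = A D_W / (2 V_w)$, whose factor-2
(half-slab per unit cell) convention is stated in every output header
because it is the field's most common source of confusion. Molecular
volumes are user inputs with literature-typical defaults
(`scattering_constants`); absolute areas inherit their uncertainty.

## The forward model and what passing tests mean

`bilayer_model()` builds a centrosymmetric fluid-phase NSLD profile:
headgroup Gaussians at $\pm z_H$, a methyl trough at the center, an
acyl-chain plateau occupying the non-water volume, and
$\rho_w\,w(z)$ with $w$ a complementary-error-function step at
$\pm D_B/2$. `simulate_peak_table()` then inverts the entire reduction:
theoretical structure factors, Bragg angles, corrections, a single
global intensity scale (the strongest reflection across all contrasts
is normalized to 1), and counting noise.

Two noise models are available. The default, $\sigma_I =
\mathrm{noise}\cdot\sqrt{I}$, is the Gaussian limit of Poisson counting:
with the strongest peak at 1, `noise_scale = 0.01` is equivalent to
counting the strongest peak to $10^4$ events, with weak orders
proportionally noisier — the regime that actually limits 5th-order data.
The `relative` model applies a uniform fractional error to every peak
(uniformly well-measured data). Validation uses both: parameter-recovery
statistics under counting noise, sign-recovery rates under uniform 1%
noise, because under counting statistics reflections at contrast zero
crossings are provably sign-indeterminate no matter the estimator.

`random_bilayer_model()` draws models spanning the sample family the
package targets — PC multilayers with and without n-alkanols at
97–98% relative humidity: $D$ 52–56 Å, $D_B/D$ 0.82–0.88, headgroups
3.5–5.5 Å inside the Gibbs plane, interface widths 2–3 Å, headgroup
amplitudes 2–3 and methyl troughs $-0.9$ to $-0.4$ in NSLD units. These
ranges are what the parameter-recovery statistics refer to.

What the generator does *not* emulate: instrument background shapes,
detector pixelation, multiple scattering, mosaic-spread leakage between
orders, or hydration drift during a scan. Recovery statistics on
synthetic tables therefore bound the algorithmic error of the chain,
not the total experimental error budget.

A validation note on precision: at counting-statistics noise
(`noise_scale = 0.01`) and $h_\mathrm{max} = 5$, the median $D_B$
recovery error of the whole chain is at the estimator's information
limit — a coefficient-space Monte Carlo with the chain's propagated
coefficient noise gives a median of $\approx 0.5$ Å when the interface
width must be co-estimated (and $\approx 0.1$ Å were it known). Runs
across seeds land on either side of 0.5 Å; that spread is a property of
the measurement, not of the implementation.

## Peak reduction

`fit_rocking_curve()` fits a shared-center Gaussian + Lorentzian sum on
a constant background to an $\omega$ scan; the Gaussian width
$\sigma_G$ (degrees) is the mosaicity of the aligned stack. The fit is
unbounded (box constraints provoke spurious singular-gradient stops in
the Levenberg–Marquardt implementation); widths are reported as
absolute values and a fit wandering outside the scan window is flagged,
never returned silently. Flat scans are detected before fitting.

`integrate_peak()` fits a Gaussian on a constant (optionally linear)
background and returns the analytic area $a\sigma\sqrt{2\pi}$,
monitor-normalized when monitor counts exist (output records whether
normalization was applied), with the uncertainty propagated from the
fit covariance by the delta method. Each peak is fitted independently;
nothing in the data model forces shared widths across orders.

`index_and_fit_lattice()` regresses $\sin\theta_h$ on $h$ through the
origin ($D = \lambda/2\,\mathrm{slope}$). Unlabelled peaks get the
consecutive labelling starting at $h=1$ (the lamellar first order is
always present in these samples) that minimizes the residual RMS;
an assignment whose $2\theta$ residual RMS exceeds 0.1° is rejected
with the worst reflection named.

`extrapolate_full_hydration()` fits
$D(t) = D_\infty - \Delta D\,e^{-t/\tau}$ to the D-spacing kinetics of
a sample taking up water (saturation typically within a few hundred
minutes); a decreasing series is handled by negative $\Delta D$, a
non-saturating series returns the last value with a warning flag.

## Trajectory observables

The order-analysis module computes the coarse-grained simulation
observables on labelled bead frames (read from a documented XYZ dialect
or GRO files; orthorhombic periodic boxes):

* `order_parameter()`: $P_2 = \tfrac12(3\langle\cos^2\theta\rangle-1)$
  per bond type, pooled over molecules and frames (pooled rather than
  frame-weighted averaging; documented choice), with standard errors.
* `density_profile()`: per-leaflet-folded number densities with the
  central-90% span. The bilayer center is the mean $z$ of the lipid
  beads per frame — robust to membrane drift — and leaflets are
  assigned by instantaneous sign of $z$, which mis-assigns particles
  mid-flip (documented limitation).
* `bilayer_thickness_pp()`: the phosphate-to-phosphate distance
  $D_{PP}$, the simulation analogue of $D_{HH}$.
* `lateral_rdf()`: the in-plane pair distribution within one leaflet,
  minimum-image in $x$–$y$, normalized with the excess convention
  $\rho_{2D} = (N-1)/L_xL_y$ so an ideal-gas plane gives exactly 1
  without finite-$N$ bias.
* `group_distance()`: signed mean-position separations between bead
  groups per leaflet (positive = first group farther from the center).

`synthetic_frames()` generates fixtures with an exactly prescribed
ensemble $P_2$ by mixing the isotropic orientation distribution with
fully aligned (or fully in-plane) bonds; endpoints $P_2 = 1$ and
$-0.5$ are deterministic. Bond length defaults to 4.7 Å, the
coarse-grained bead bond of roughly four heavy atoms.

## Problem sizes and numerical choices

The shipped validation uses 50-model ensembles for sign recovery and
100-model ensembles for structural recovery at $h_\mathrm{max}=5$ and
three contrasts (8, 20, 50% D$_2$O), $10^4$-bond isotropic fixtures for
$P_2$ nulls, and 15 frames of 400 points for the RDF null — sizes at
which the sampling error of each check is several times smaller than
its tolerance. Structure-factor integrals use composite Simpson
quadrature (the periodic extension of a bilayer profile has a
derivative jump at the cell edge, which holds trapezoid quadrature at
$O(h^2)$); profile grids default to 0.5 Å, far below the
$D/2h_\mathrm{max} \approx 5$ Å resolution of the data. Degenerate
inputs — flat scans, empty leaflets, single particles, duplicate
contrasts, $D_B > D$ — raise flags or errors rather than numbers.

## Worked example

```{r example, eval = FALSE}
m <- bilayer_model()                       # DOPC-like reference cell
contrasts <- lapply(c(0.08, 0.20, 0.50), contrast_spec)
tab <- simulate_peak_table(m, contrasts, hmax = 5, noise_scale = 0.01,
                           seed = 1)
res <- reduce_sample(tab)
res$structure
res$sf                                     # signed F_h, k, diagnostics
```

## Known limitations

* Signs only: non-centrosymmetric (complex-phase) structures are out of
  scope.
* Absolute areas depend on user-supplied molecular volumes; only the
  volumetric identity and trends are checkable without sample-specific
  volumetry.
* The water-step template family assumes a single error-function
  interface per side; strongly structured interbilayer water would
  bias $k$ and the per-order orientation stage.
* Binary trajectory formats are not read; convert to GRO/XYZ text
  first.
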