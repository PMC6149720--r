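# lamellar

Reduction and analysis of small-angle neutron diffraction (SAND) data from
aligned lipid multilayers, for membrane biophysicists studying how small
molecules (general anesthetics, n-alkanols, peptides) reshape the bilayer
and its water interface.

Stacked bilayers hydrated from water vapour diffract into 5–6 lamellar
Bragg orders. Each order samples one Fourier amplitude of the neutron
scattering length density (NSLD) profile across the unit cell:

    rho(z) = F0abs/D + (1/k)(2/D) * sum_h F_h cos(2 pi h z / D)

with the repeat distance `D` from the Bragg equation
`2 D sin(theta_h) = h lambda`, and signed structure factors obtained from
integrated intensities via `|F_h| = sqrt(I_h / (L_f A_c F_c))` (Lorentz,
absorption and beam-footprint corrections). Measuring at several D2O/H2O
ratios makes each signed `F_h` linear in the water scattering density:
this fixes the signs (the centrosymmetric phase problem), sets the
absolute scale `k`, and isolates the water distribution `w(z)`, whose
error-function Gibbs surface defines the bilayer thickness `D_B`, the
water layer `D_W = D - D_B`, and the area per unit cell
`A = 2 (V_lipid + x V_alcohol) / D_B`. The profile measured at 8% D2O —
the contrast-match point of water — exposes the bilayer alone and its
head-to-head distance `D_HH`.

The package covers the whole chain:

* **Peak reduction** — rocking-curve mosaicity fits (Gaussian +
  Lorentzian), Gaussian peak integration with background subtraction and
  monitor normalization, lattice indexing, and extrapolation of the
  fully hydrated D-spacing from hydration kinetics.
* **Corrections & phasing** — the correction factors, contrast-variation
  sign assignment with explicit ambiguity flags, forward scattering, and
  a deterministic water-plateau determination of `k`.
* **Profile reconstruction** — Fourier synthesis, `D_HH`, multi-contrast
  water distributions, and a resolution-aware error-function Gibbs fit
  for `D_B`.
* **Structure parameters** — areas, interlamellar water counts (factor-2
  convention stated in every output), validated per-sample records.
* **Trajectory observables** for coarse-grained simulations — P2 bond
  order parameters, number-density profiles with 90% spans,
  phosphate-to-phosphate thickness `D_PP`, lateral 2D radial
  distribution functions, and group mean-position distances.
* **A forward model** (`bilayer_model`, `simulate_peak_table`,
  `synthetic_frames`) that generates ground-truth profiles, theoretical
  structure factors, noisy peak tables and coordinate frames, so every
  stage is validated by round-trip parameter recovery — no experimental
  data required.

## Worked example

Simulate a DOPC-like sample measured at the three study contrasts with
counting noise, then run the full reduction:

```r
library(lamellar)
m <- bilayer_model()                        # D 54 A, Gibbs plane at 22.75 A
contrasts <- lapply(c(0.08, 0.20, 0.50), contrast_spec)
tab <- simulate_peak_table(m, contrasts, hmax = 5, noise_scale = 0.01, seed = 1)
res <- reduce_sample(tab)
res$lattice; res$sf; res$structure
```

```
Lattice fit: D = 54.0000 A (lambda = 4.5707 A, 15 reflections, RMS 0 deg)
Structure factor set: D = 54.00 A, 5 orders, 3 contrasts, k = 0.01547
      8%D2O  20%D2O  50%D2O
h=1 -0.3510 -0.4413 -0.6764
h=2 -0.1825 -0.1128  0.0669
h=3  0.2443  0.2039  0.0847
h=4 -0.1539 -0.1265 -0.0562
h=5 -0.0421 -0.0491 -0.0776
Bilayer structure (Angstrom):
  D = 54.00  D_B = 46.33  D_HH = 37.28  D_W = 7.67  A = 56.25 A^2  n_W = 7.2
```

Reading the output: the lattice fit reproduces the generator's repeat
distance exactly; the signed structure factors vary linearly with the
D2O fraction (the h=2 line crosses zero between 20% and 50% — exactly
the behaviour contrast variation exploits); and the recovered Gibbs
thickness `D_B = 46.33 A` and head-to-head distance `D_HH = 37.28 A`
sit within the counting-noise error of the generator truth (45.5 A and
37.25 A for this model). `D = D_B + D_W` and `A * D_B = 2 V_lipid` hold
exactly by construction. The methods vignette
(`vignettes/bilayer-diffraction-methods.Rmd`) documents every model,
convention and tolerance.

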