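---
title: "Disentangling a dye absorption lineshape: vibronic progression, dimerization, and nanocavity strong coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disentangling a dye absorption lineshape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibromix)
```

## The problem

Aqueous methylene blue (MeB) absorbs around 664 nm (1.87 eV) with a
persistent shoulder some 40--70 meV to the blue. Whether that shoulder is
an H-aggregate dimer band, a vibronic progression of the monomer, a higher
electronic state, or something else has real consequences: in
nanoparticle-on-mirror (NPoM) plasmonic cavities, the disappearance of the
shoulder has been used as evidence that a cucurbit[7]uril host ties up at
most one dye, i.e. that observed Rabi splitting is *single-molecule*
strong coupling. `vibromix` implements the three model layers needed to
take that question apart quantitatively:

1. **Franck--Condon vibronic lineshapes** for harmonic ground/excited
   surfaces at finite temperature (`fc_overlap_1d()`,
   `thermal_stick_spectrum()`, `convolve_gaussian()`);
2. **monomer--dimer equilibrium superposition** of basis spectra with
   least-squares recovery of the dimerization constant
   (`speciate()`, `composite_spectrum()`, `fit_dimerization()`);
3. a **classical input/output coupled-oscillator cavity model**
   (`cavity_susceptibility()`, `extinction_spectrum()`,
   `analyze_polaritons()`).

A seeded synthetic-data layer (`make_meb_monomer()`,
`make_dilution_series()`, `make_cavity_fixture()`) supplies every input,
so the whole pipeline runs without quantum-chemistry or spectrometer
data.

## The vibronic model

Each electronic transition is described by an adiabatic (0--0) energy
$E_{00}$ and a set of independent harmonic modes, mode $j$ having
ground/excited wavenumbers $\omega''_j, \omega'_j$ and a dimensionless
displacement $\Delta_j$ between the two surface minima (expressed in
ground-state coordinates, so the Huang--Rhys factor is
$S_j = \Delta_j^2/2$ at equal frequencies). This is the adiabatic-Hessian
picture with the Duschinsky rotation fixed to the identity: each ground
mode pairs with exactly one excited mode. That restriction is deliberate
-- the mechanistic statements we care about are mode-by-mode (modes 25
and 27 of MeB, at 454 and 510 cm$^{-1}$), and the independent-mode
overlaps are where all the physics of the shoulder lives. The API keeps
the mode list explicit so a rotation argument could be added without
breaking the surface.

One-dimensional overlaps $\langle \chi''_m | \chi'_n \rangle$ are
computed by a two-index ladder-operator recursion seeded with the closed
form

$$\langle 0 | 0 \rangle = \sqrt{\frac{2\sqrt{f}}{1+f}}
  \exp\!\left(-\frac{f\Delta^2}{2(1+f)}\right), \qquad
  f = \omega'/\omega'',$$

which reduces to the familiar limits: $|\langle 0|0\rangle|^2 =
2\sqrt{\omega'\omega''}/(\omega'+\omega'')$ for pure distortion and the
Poisson progression $|\langle 0|n\rangle|^2 = e^{-S}S^n/n!$ for pure
displacement. The recursion is exact to machine precision against direct
quadrature of the Hermite-Gaussian wavefunctions (the test suite sweeps
all $m,n \le 6$, frequency ratios 0.5--2 and $|\Delta| \le 3$ and finds
agreement at the $10^{-15}$ level). One subtlety worth recording: because
$\Delta$ is dimensionless *in the coordinates of the ground surface*,
swapping the roles of the two surfaces rescales it, and the exact swap
symmetry is
`fc_overlap_1d(m, n, w1, w2, d) == fc_overlap_1d(n, m, w2, w1, -d*sqrt(w2/w1))`.

At finite temperature, initial states are enumerated per mode up to a cap
(default 2 quanta -- at 300 K a 454 cm$^{-1}$ mode keeps only ~11% of its
population outside $m=0$, and ~1% beyond $m=1$) and weighted with the
full geometric-ladder Boltzmann populations; final states run to 8 quanta
per mode, and lines below $10^{-6}$ of the strongest are dropped, with
the retained fraction reported so truncation is never silent. Sticks are
broadened with unit-area Gaussians of width 0.022 eV. The width is
interpreted as the standard deviation by default; since reference
lineshape computations do not always state whether such a number is
$\sigma$ or FWHM, `convolve_gaussian(width_type = "fwhm")` provides the
other convention.

```{r monomer}
mono <- meb_like_monomer_spectrum()   # 2.14 eV, 454/510 cm^-1, 300 K
detect_peaks(mono)
```

The displacement default ($\Delta = 0.5$ per mode, $S = 0.125$) is an
explicitly arbitrary number: real MeB displacements are not tabulated in
the sources this model emulates. It was calibrated once, against the
lineshape geometry itself: one global maximum at the 0--0 energy and
exactly one *unresolved* shoulder 40--70 meV above it. Displacements of
0.7 and beyond split the vibronic satellite into a resolved second peak,
which is the wrong regime for MeB. All such invented defaults live in
`synthetic_defaults`, marked ARBITRARY or ILLUSTRATIVE, so none of them
can masquerade as a literature value.

## Peaks and shoulders

`detect_peaks()` estimates the curve and its first two derivatives with a
Savitzky--Golay filter (window $= 5\times$ the smoothing scale, default
0.01 eV). Peaks are strict local maxima of the smoothed curve above a
relative height floor ($10^{-3}$ of the maximum, suppressing ripples on
numerically flat tails). Shoulders are runs of negative second derivative
that contain no local maximum and sit on a monotone flank -- the
signature of a band hiding under a stronger neighbour -- scored by peak
curvature relative to the strongest curvature in the spectrum. The score
threshold (default 0.02) was fixed once so that the MeB-like doublet
yields exactly one shoulder; SG edge transients are excluded by a
half-window guard at both ends.

## The dimer equilibrium

H-aggregate dimer bands are modelled as single bright Gaussians at the
upper-exciton energies (2.25 eV parallel, 2.23 eV antiparallel); the
lower exciton is dark and contributes nothing. Speciation at total dye
concentration $C_i$ follows from $K_D = [D]/[M]^2$:

$$[M] = \frac{-1 + \sqrt{1 + 8 K_D C_i}}{4 K_D}, \qquad
  [D] = \frac{C_i - [M]}{2}.$$

Numerically the closed form loses up to half its digits to cancellation
when $K_D C_i$ is small, so below $K_D C_i = 10^{-4}$ the series
$[M] = C_i(1 - 2x + 8x^2 - 40x^3 + 224x^4)$ is used; both branches agree
with a brute-force root finder to better than $10^{-12}$ at the switch,
and mass balance $[M] + 2[D] = C_i$ holds to machine precision by
construction.

The composite spectrum applies the superposition with the **full** dimer
concentration factor on each conformer term (the form in which the
equation is printed in the motivating work); if the two conformers are
instead taken as equal halves of the dimer population,
`conformer_weighting = "split"` halves each factor. Verbatim is the
default because fidelity to the printed equation takes precedence; the
choice only rescales $\varepsilon_D$ by 2, so fitted dimerization
constants are unaffected.

No literature $K_D$ is bundled -- it is cited, not printed, in the
motivating work -- so `k_d` is a required argument everywhere, and the
synthetic generator uses an arbitrary, clearly-labelled
$2.0\times10^3\ \mathrm{M^{-1}}$.

```{r fit}
ser <- make_dilution_series(seed = 1)   # 400.5 uM, ratio 0.794, 1% noise
b <- attr(ser, "basis")
fit <- fit_dimerization(ser, b$a_m, b$a_da, b$a_db,
                        init = list(k_d = 500, eps_m = 1e4, eps_d = 1e4))
c(k_d = fit$k_d, eps_m = fit$eps_m, eps_d = fit$eps_d)
```

`fit_dimerization()` runs Levenberg--Marquardt least squares over the
stacked residuals of the whole series, parameterized in
$\log_{10} K_D$ (keeping $K_D$ positive) with three starts one decade
apart to dodge local minima. On the synthetic 8-point dilution ladder
(starting at 400.5 uM, each step transferring a 0.794 volume fraction)
with 1% multiplicative noise, the median $K_D$ error across 20 seeds is
about 1%; the suite asserts it stays below 10%. Noise is multiplicative
Gaussian on absorbance, emulating the dominant cuvette path-length error
mode of the measurements this generator imitates; a constant-offset
component is deliberately absent by default because baseline correction
(`baseline_correct()`, subtract-the-minimum) removes exactly that.

What the generator does *not* emulate: spectrometer filter-switch
discontinuities, wavelength-dependent stray light, shot noise, or any
deviation of the true basis spectra from the model's own monomer/dimer
shapes. Passing the recovery test therefore demonstrates the estimator's
correctness and noise robustness, not that real MeB data would be this
well-behaved.

## The cavity model

The NPoM nanocavity is a damped oscillator at $\omega_c$ (full linewidth
$\kappa$) coupled to molecular transitions $j$ (energy $\omega_j$, full
linewidth $\gamma_j$, coupling $g_j$):

$$\chi(E) = \left[\omega_c - E - \tfrac{i\kappa}{2}
  - \sum_j \frac{g_j^2}{\omega_j - E - \tfrac{i\gamma_j}{2}}\right]^{-1}.$$

All linewidths are **full** widths, entering as halves in the complex
frequencies -- stated prominently because half-width conventions are the
main reproducibility hazard in this model class. Extinction is the
absorptive spectral function $\mathrm{Im}\,\chi$ (positive-definite with
this sign convention; the same quantity appears as $-\mathrm{Im}\,\chi$
under the opposite time-phase convention), which reduces to a Lorentzian
of FWHM $\kappa$ for the bare cavity; a dark-field-like $|\chi|^2$
scattering mode is a flag away. For a single transition the peak
positions can be checked against the $2\times 2$ complex eigenvalue
problem, whose resonant splitting is
$2\sqrt{g^2 - (\kappa - \gamma)^2/16}$, the textbook $2g$ in the lossless
limit.

The two-transition fixture couples the 0--0 line and the vibronic
shoulder 56 meV above it, with $g_{vib} = g_{00}\sqrt{I_{vib}/I_{00}}$
(transition dipole $\propto$ square root of Franck--Condon intensity,
computed from the monomer model's own 0 K stick spectrum). Cavity
parameters ($\kappa = 0.15$ eV, $\gamma = 0.08$ eV, $g_{00} = 0.15$ eV)
are illustrative strong-coupling values.

**Where the cavity sits is not a free detail.** With the cavity pinned
exactly to the 0--0 line, a systematic scan of this model family
($\kappa$ 0.1--0.4 eV, $\gamma$ 0.03--0.15 eV, $g_{00}$ 0.1--0.2 eV,
coupling ratios 0.5--1, both detection modes) shows the upper polariton
always comes out *weaker* than the lower one: the UP lies closer to the
vibronic transition and cedes more of its cavity weight to it. The
characteristic experimental signature of a vibronically structured
emitter -- a more intense UP and a weaker, non-Lorentzian LP -- only
appears when the plasmon is tuned into the molecular band as a whole,
which is also how NPoM experiments tune it (to the dye's absorption
band, not to a hidden 0--0 sub-line). `make_cavity_fixture()` therefore
centers the two-transition cavity at the midpoint of the two
transitions, while the single-transition fixture stays exactly on
resonance, where its doublet is symmetric to within 1%.

```{r cavity}
grid <- energy_grid(1.0, 2.8, 0.002)
analyze_polaritons(extinction_spectrum(make_cavity_fixture(FALSE), grid))
analyze_polaritons(extinction_spectrum(make_cavity_fixture(TRUE), grid))
```

Including the vibronic transition makes the UP more intense than the LP,
hangs a high-energy shoulder on the LP, and widens the UP--LP separation
at identical 0--0 coupling -- the three qualitative fingerprints by which
even a modest vibronic band announces itself in single-molecule
polariton spectra.

## Numerical choices and degenerate inputs

- Energies are eV throughout; $hc = 1239.8420$ eV nm and
  1 cm$^{-1} = 1.239842\times10^{-4}$ eV are mutually consistent.
  Reported values are rounded half-away-from-zero (`round_half_up()`) to
  2 decimals (eV) or integers (meV), matching common reporting precision.
- Wavelength-sampled spectra are converted to eV *before* resampling.
  No Jacobian (density-per-unit-energy) correction is applied by
  default, matching how such lineshapes are usually compared across
  units; apply it manually if band integrals across unit systems must
  agree.
- `resample_spectrum()` refuses to extrapolate rather than padding --
  silent baseline fabrication is worse than an error.
- Empty stick lists broaden to a flat zero spectrum; a zero-mode system
  is a pure 0--0 line; zero couplings reproduce the bare cavity exactly;
  `speciate(0, c_i)` is the exact monomer-only limit.
- Thermal enumeration refuses to generate more than $10^6$ candidate
  lines and says which knobs to turn instead.
- Pipeline outputs (`run_pipeline()`) embed no timestamps, so identical
  configurations produce byte-identical artifacts, verified by MD5 in
  the manifest.

## Problem sizes

The shipped test-and-acceptance workloads use: a $7\times7$ quantum grid
over 30 (ratio, displacement) pairs for the quadrature cross-check, 169
$(K_D, C_i)$ pairs spanning six decades each for speciation, 20
Monte-Carlo seeds of an 8-point dilution ladder on a 163-point energy
grid for $K_D$ recovery, and 901-point grids for cavity spectra. These
sizes were chosen so every property is exercised across its full
parameter range while the whole suite stays interactive.

## Known limitations

- Independent-mode approximation: no Duschinsky mixing, no
  anharmonicity, no Herzberg--Teller intensity borrowing (the
  intensity-borrowing mechanism is the one this model family argues
  against for MeB).
- The dimer model has exactly two conformers, both reduced to a single
  bright Gaussian; no trimers or higher aggregates; no host-guest
  binding equilibrium.
- The cavity model is classical and linear: no Jaynes--Cummings ladder,
  no electromagnetic simulation of the NPoM geometry, no time-domain
  response.
- Synthetic displacements, $K_D$, absorptivities and cavity parameters
  are stand-ins, labelled as such in `synthetic_defaults`; conclusions
  that depend on their precise values should not be drawn from this
  package's defaults.
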