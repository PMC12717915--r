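# vibromix

Tools for disentangling the absorption lineshape of dimerizing cationic
dyes — methylene blue (MeB) being the motivating case — and for asking
what that lineshape does inside a plasmonic nanocavity.

The blue shoulder on the MeB absorption band has been attributed over
the years to H-aggregate dimers, vibronic progression, higher electronic
states and more. The attribution matters: in nanoparticle-on-mirror
(NPoM) cavities the shoulder's disappearance has been read as proof of
single-molecule strong coupling. `vibromix` implements the three model
layers needed to take the question apart:

- **Franck–Condon vibronic lineshapes.** Exact 1-D overlap amplitudes
  ⟨χ″ₘ|χ′ₙ⟩ for harmonic oscillators differing in frequency and
  equilibrium position, via a stable two-index recursion seeded by the
  closed-form ⟨0|0⟩ (Poisson progression e⁻ˢSⁿ/n!, S = Δ²/2, in the
  displaced equal-frequency limit). Finite-temperature stick spectra in
  the independent-mode adiabatic-Hessian approximation, Gaussian
  broadening, and peak/shoulder detection.
- **Monomer–dimer equilibrium.** Speciation from
  [M] = (−1+√(1+8K_D C_i))/(4K_D) with a series branch where the closed
  form cancels; composite solution spectra
  A(ν) = ε_M[M]A_M(ν) + ε_D[D]A_DA(ν) + ε_D[D]A_DB(ν); nonlinear
  least-squares recovery of K_D, ε_M, ε_D from dilution series.
- **Nanocavity strong coupling.** Classical input/output susceptibility
  χ(E) = [ω_c − E − iκ/2 − Σⱼ gⱼ²/(ωⱼ − E − iγⱼ/2)]⁻¹, extinction and
  scattering spectra, 2×2 closed-form polariton eigenvalues, Rabi
  splitting and upper/lower-polariton asymmetry reports.

Seeded generators (`make_meb_monomer()`, `make_dilution_series()`,
`make_cavity_fixture()`) supply every input, so the whole pipeline runs
with no quantum-chemistry or spectrometer data. Every invented default
is collected in `synthetic_defaults` and labelled ARBITRARY or
ILLUSTRATIVE.

## Worked example

```r
library(vibromix)

# the reported wavelength arithmetic
round_half_up(nm_to_ev(678), 2)        # 1.83  (eV at 678 nm)
round_half_up(energy_shift_mev(678, 664))  # 39  (meV blue shift)

# 1. monomer vibronic lineshape: 0-0 at 2.14 eV, modes 454/510 cm^-1,
#    300 K, 0.022 eV Gaussian width
mono <- meb_like_monomer_spectrum()
detect_peaks(mono)
#> <peak_set> 1 peak(s), 1 shoulder(s)
#> peaks:
#>   energy   height score
#>  2.14019 13.54613     1
#> shoulders:
#>   energy     score
#>  2.20619 0.1390941
```

One global peak at the 0–0 energy and exactly one unresolved shoulder
66 meV above it — the one-peak-plus-shoulder geometry the model exists
to reproduce.

```r
# 2. recover K_D from a noisy synthetic dilution ladder
#    (400.5 uM start, 0.794 transfer ratio, 1% multiplicative noise)
ser <- make_dilution_series(seed = 1)
b <- attr(ser, "basis")
fit <- fit_dimerization(ser, b$a_m, b$a_da, b$a_db,
                        init = list(k_d = 500, eps_m = 1e4, eps_d = 1e4))
round(c(k_d = fit$k_d, eps_m = fit$eps_m, eps_d = fit$eps_d), 1)
#>     k_d   eps_m   eps_d
#>  2018.3 50148.9 39846.9
```

The generating values were K_D = 2000 M⁻¹, ε_M = 5·10⁴, ε_D = 4·10⁴: the
fit lands within ~1% despite the noise.

```r
# 3. what the vibronic shoulder does to the polariton doublet
grid <- energy_grid(1.0, 2.8, 0.002)
analyze_polaritons(extinction_spectrum(make_cavity_fixture(TRUE), grid))
#> <polariton_report> LP 1.7180 eV (h 0.939), UP 2.0620 eV (h 1)
#>   splitting 0.3440 eV, UP/LP asymmetry 1.065, 2 peak(s), 1 shoulder(s)
```

Against the single-transition reference (symmetric doublet, splitting
0.304 eV), coupling the vibronic shoulder makes the upper polariton more
intense, hangs a high-energy shoulder on the lower one, and widens the
splitting — the fingerprints of vibronic structure in single-molecule
polariton spectra.

A thin command-line wrapper covering `convert`, `fcspec`, `mix`,
`fit-kd`, `cavity`, `synth` and `run` (the full pipeline with a
checksummed manifest) is installed at
`system.file("cli", "vibromix.R", package = "vibromix")`.

The methods vignette (`vignettes/absorption-lineshape.Rmd`) documents
the models, their assumptions, the numerical choices and the known
limitations.

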