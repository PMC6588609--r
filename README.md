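# mdesim

Spectrally modulated multidimensional diffusion encoding (MDE) for
diffusion MRI: waveform design, frequency-domain signal prediction for
restricted and Gaussian compartments, Monte Carlo cross-validation, powder
statistics, and the size/anisotropy subtraction contrasts.

## The problem and who this is for

Conventional diffusion MRI entangles two distinct microstructural
properties — the *size* of diffusion-restricting compartments (through
time-dependent diffusion) and their *shape* (microscopic anisotropy) — so
that very different tissues can produce identical signal curves. An
augmented MDE protocol disentangles them with three measurements that share
the same b-value but differ in b-tensor shape and spectral content:

* **isotropic** encoding by magic-angle spinning of the q-vector (q-MAS),
* **tuned** directional encoding — the x channel of the isotropic waveform
  scaled by √3, whose encoding power spectrum matches the isotropic one,
* **detuned** directional encoding — a single-axis waveform whose dephasing
  equals the dephasing *magnitude* |F(t)| of the isotropic one, which
  concentrates its encoding power at low frequencies.

Two contrasts then follow from raw signal subtraction of powder-averaged,
normalised signals at a chosen b-value b\*:

* size contrast `E_detuned(b*) − E_tuned(b*)` — sensitive to restrictions
  whose size makes diffusion time-dependent inside the encoding band,
* anisotropy contrast `E_tuned(b*) − E_isotropic(b*)` — sensitive to
  microscopic anisotropy regardless of orientation dispersion.

The package is for sequence developers and microstructure modellers who
want to design such protocols, predict their signals for known geometries,
and validate analysis pipelines on synthetic phantoms with known ground
truth.

## The model at the core

In the Gaussian (second-cumulant) approximation, a compartment with
diffusion spectrum **D**(ω) attenuates the signal as `E = exp(−β)` with

    β = (1/2π) ∫ Fᵀ(ω) D(ω) F(−ω) dω ,     ADC = β / b ,

where **F**(ω) is the spectrum of the dephasing vector
`F(t) = γ ∫₀ᵗ g(t′) dt′` and the b-tensor is `b = ∫ F(t) ⊗ F(t) dt` (its
trace is the b-value). Restricted geometries enter through closed-form
spectra `λ(ω) = Σ_k B_k a_k ω² / (a_k² + ω²)` with geometry-specific
eigenmode roots (planar, cylindrical, spherical; `D(ω) = R λ(ω) R⁻¹` for
orientation R). An independent compiled random-walk Monte Carlo engine
(barrier rejection, per-particle RNG streams, phase-moment accumulation)
cross-validates the frequency-domain predictions.

## Worked example

```r
library(mdesim)

iso <- qmas_fixture()               # shipped 23 ms q-MAS waveform
iso
#> <mde_waveform> label=isotropic, 1150 samples, dt=2e-05 s, tau=23 ms
#>   max |g| = 500.0 mT/m, b = 41.0 s/mm2
b_tensor(iso)
#> <mde_btensor> b = 41.0 s/mm2, eigenvalue spread = 2.7e-06

detuned <- derive_detuned(iso)
sp <- dephasing_spectrum(detuned)
100 * band_power(sp, 50) / sum(diag(sp$b_band))
#> detuned power below 50 Hz: 95.7 %   (tuned: 35.9 %)

prot <- protocol()                  # 12 b-values 240-4800 s/mm2, 15 orientations
cv <- predict_signals(make_phantom("yeast"), prot)
cv$detuned
#> <mde_curve> label=detuned, 13 b-values (0-4800 s/mm2), analytic
#>           b         E
#> 1         0 1.0000000
#> 2 240000000 0.8886432
#> ...

size_contrast(cv$tuned, cv$detuned, b_to_si(4800))
#> <mde_contrast> size = +0.3679 at b = 4800 s/mm2
anisotropy_contrast(cv$tuned, cv$isotropic, b_to_si(4800))
#> <mde_contrast> anisotropy = +0.0014 at b = 4800 s/mm2
```

The yeast-like phantom (spheres + free water) shows a large positive size
contrast — the detuned encoding, with its power at low frequencies where
restricted diffusion looks slow, attenuates far less than the tuned one —
and essentially zero anisotropy contrast, because both compartments are
isotropic. Thin dispersed channels (`make_phantom("liquid_crystal")`) show
the opposite signature, free solutions (`"polymer"`) neither, large
dispersed cylinders (`"microfibers"`) both.

A shell entry point covering waveform generation, spectra, prediction,
simulation and maps is installed under
`system.file("cli", "mde.R", package = "mdesim")`.

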