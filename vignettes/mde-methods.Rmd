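---
title: "Methods: spectrally modulated diffusion encoding in mdesim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectrally modulated diffusion encoding in mdesim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdesim)
```

## The signal model and its assumptions

`mdesim` predicts diffusion-weighted MR signal attenuation in the Gaussian
(second-cumulant) approximation: the spin-phase distribution accumulated in
each compartment is treated as Gaussian, so the per-compartment signal is
mono-exponential in the attenuation factor,

$$ E = e^{-\beta}, \qquad
   \beta = \frac{1}{2\pi}\int_{-\infty}^{\infty}
           \mathbf{F}^{\mathrm T}(\omega)\,\mathbf{D}(\omega)\,
           \mathbf{F}(-\omega)\, d\omega , $$

where $\mathbf F(\omega)$ is the spectrum of the dephasing vector
$\mathbf F(t) = \gamma\int_0^t \mathbf g(t')\,dt'$ of the effective
gradient waveform $\mathbf g(t)$, and $\mathbf D(\omega)$ is the
compartment's diffusion spectrum (the frequency representation of its
velocity autocorrelation). The b-tensor is
$\mathbf b = \int \mathbf F(t)\otimes\mathbf F(t)\,dt$, its trace is the
b-value, and $\mathrm{ADC} = \beta/b$ is the initial slope of
$\ln E$ versus $b$. Because $\beta$ scales with the squared gradient
amplitude exactly as $b$ does, the ADC of a compartment depends only on the
*shape* of the waveform, and curves over a b-ladder are
$E(b) = e^{-\mathrm{ADC}\,b}$ per orientation. Multi-compartment systems
are fraction-weighted sums of such exponentials, powder averages are
arithmetic means over orientation frames.

The Gaussian approximation is the model's central assumption. It is exact
for Gaussian (free or tensor) diffusion at all $b$ and an approximation for
restricted diffusion; the package's own Monte Carlo engine quantifies the
error instead of an analytic cumulant correction (a deliberate scope
choice). At the reference configuration (cylinder of radius 2.5 µm,
$D_0 = 10^{-9}\,\mathrm{m^2/s}$, isotropic encoding with
$\tau = 23$ ms, $b \le 4800\,\mathrm{s/mm^2}$) the acceptance suite bounds
the deviation of the simulated single-orientation decay from
mono-exponential at below 1 % of the normalised signal.

## The three encodings

The protocol combines three waveforms that share the encoding time and,
after per-b amplitude rescaling, the b-value exactly:

* **Isotropic (q-MAS).** The dephasing vector spins on a cone at the magic
  angle $\zeta = \arccos(1/\sqrt3)$:
  $\mathbf q(t) = q_0\, a(t)\,[\sin\zeta\cos\psi,\ \sin\zeta\sin\psi,\
  \cos\zeta]$ with envelope $a(t)=\sin^2(\pi t/\tau)$ and azimuthal rate
  $\dot\psi \propto a(t)^2$ normalised to `n_turns` (default 4) full
  turns. The rate rule makes the $a^2$-weighted time averages of
  $\cos^2\psi$ and $\sin^2\psi$ exactly $1/2$ over whole turns, so the
  b-tensor is isotropic up to discretisation (eigenvalue spread
  $\sim 3\times10^{-6}$ for the shipped fixture).
* **Tuned directional.** The x channel of the isotropic waveform scaled by
  $\sqrt3$. Tuning requires the x channel's power spectrum to resemble one
  third of the trace spectrum. With the spinning-cone axis on a laboratory
  axis it does not: the axial channel is pure low-frequency envelope and
  the transverse channels pure high-frequency modulation. `generate_qmas()`
  therefore rotates the cone axis onto the body diagonal
  $(1,1,1)/\sqrt3$ by default, which makes the three laboratory channels
  equivalent under a 120° rotation about the cone axis and their spectra
  near-identical. This is a design choice of the package (the cone-axis
  orientation is free — any global rotation preserves the isotropic
  b-tensor) made so that the derived tuned waveform is spectrally matched.
* **Detuned directional.** A single-axis waveform whose scalar dephasing is
  the dephasing *magnitude* $F_d(t) = |\mathbf F(t)|$ of the isotropic
  waveform. Since $\sum_t F_d^2 = \sum_t |\mathbf F|^2$, its b equals the
  isotropic b exactly under the package's discrete convention. $|\mathbf
  F(t)|$ varies only on the encoding-time scale, so the detuned spectrum
  concentrates at low frequencies (95.7 % of its power below 50 Hz for the
  shipped $\tau = 23$ ms fixture, versus 35.9 % for the tuned waveform —
  both numbers computed by `band_power()` in the acceptance script).

**Measured tuning quality.** With the shipped generator defaults the tuned
and isotropic ADCs on spheres with $D_0=10^{-9}\,\mathrm{m^2/s}$,
$\tau=23$ ms agree to 0.10 % at $R=1$ µm and 1.27 % at $R=2.5$ µm, but
only to 4.5 % at $R=5$ µm, where the diffusion spectrum varies most
rapidly inside the encoding band. The simple closed-form envelope and
azimuthal rule used here are not a constrained-optimised design; published
optimised waveforms tune better, and any numeric waveform can be
substituted through `read_waveform()` — all downstream machinery is
waveform-agnostic.

## Discrete conventions

A waveform sample is the gradient amplitude held constant over one `dt`
interval, exactly as a discrete waveform is played out by a scanner.
Consequences, all exact rather than approximate:

* integration (cumulative sum) and differencing invert each other, so
  generated and derived waveforms are refocused to machine precision
  (checked against the echo-condition tolerance
  $|\int g\,dt| \le 10^{-9}\,\max|g|\,\tau$ per axis);
* the detuned derivation preserves b exactly;
* the discrete Parseval identity makes the frequency-domain b-tensor equal
  the time-domain one on the full FFT grid, so the stored-band agreement is
  limited only by the 25 kHz band truncation (relative error
  $\sim 5\times10^{-9}$ for the shipped waveforms, versus the
  $10^{-4}$ contract).

The derivative of $|\mathbf F(t)|$ in the detuned derivation is taken on
the sampled grid without smoothing; $|\mathbf F|$ is non-smooth at zero
crossings and the derived waveform is what would actually be played.

## Spectral analysis parameters

* Time step for spectra: waveforms are resampled to 1 µs before the FFT.
  Linear interpolation of the dephasing is exact for a piecewise-constant
  gradient, so resampling introduces no error in $\mathbf F(t)$.
* FFT length: $2^{21}$ points (zero padded), about 0.48 Hz frequency
  spacing. The stored one-sided band is 0–25 kHz with per-bin weights (2,
  or 1 at DC) so band sums reproduce two-sided integrals; smooth encoding
  waveforms hold a negligible fraction of power above that band.
* Quadrature for $\beta$: midpoint sum over the stored grid, truncated
  where the cumulative encoding power reaches $1-10^{-6}$ of the total;
  the neglected in-band and out-of-band power is assigned the
  high-frequency limit of each principal spectrum. For Gaussian
  compartments this correction is exact, which is why the free-diffusion
  closed form $E=e^{-bD_0}$ is reproduced to machine precision; for
  restricted compartments the residual error is bounded by the neglected
  power times $D_0$.

## Restricted diffusion spectra

Per restricted principal axis,

$$ \lambda(\omega) = \sum_{k=1}^{K} B_k\,
   \frac{a_k\,\omega^2}{a_k^2+\omega^2}, \qquad
   a_k = \frac{\alpha_k^2 D_0}{R^2}, $$

with geometry-specific roots and weights: plane (reflecting plates at
$\pm R$; the half-separation convention, stated to avoid the $d$ versus
$d/2$ ambiguity): $\alpha_k = (2k-1)\pi/2$, $B_k = 2R^2/\alpha_k^4$;
cylinder: $\alpha_k$ the roots of $J_1'$, $B_k =
2(R/\alpha_k)^2/(\alpha_k^2-1)$; sphere: $\alpha_k$ the roots of $j_1'$,
$B_k = 2(R/\alpha_k)^2/(\alpha_k^2-2)$. Bessel-derivative roots are found
by sign-change scanning and bisection to $10^{-12}$; the tests verify them
against an independent `uniroot` oracle and the first roots 1.8412
(cylinder) and 2.0816 (sphere).

$\lambda(0)=0$, $\lambda$ rises monotonically in $|\omega|$, and
$\lambda(\infty) = \sum_k B_k a_k \to D_0$ (completeness). The partial
sums converge slowly, like $1 - 2/(\pi^2 K)$: at $K=50$ about 0.4 % of
the weight is missing, and reaching the $10^{-3}$ residual the package's
completeness contract demands requires $K \gtrsim 203$. The default is
therefore $K = 250$ (residual $8\times10^{-4}$, verified for all three
geometries); `eigenmode_table()` warns with the achieved residual when
called with a smaller $K$. Spectra are cached per frequency grid so powder
sweeps reuse them.

Cylinders expose a flat axial spectrum $D_0$ and the restricted transverse
spectrum on two axes; planes the reverse; spheres are isotropic. All
results depend on $R$, $D_0$ and $\tau$ only through the relative encoding
time $\sqrt{D_0\tau}/R$ (the scaling-law acceptance check matches
configurations at $10^{-3}$).

## Monte Carlo engine

The independent oracle is a compiled random walk: per-axis Gaussian steps
of variance $2D_0\,\delta t$, barriers enforced by rejection (a step whose
endpoint would leave the restriction is discarded and the particle stays
put for that step). Rejection is known to bias near-wall density when
steps are large, hence the precondition RMS step $\sqrt{6D_0\,\delta t}
\le R/2$ and the default 5000 steps. Particles start uniformly inside the
restriction (rejection sampling from the bounding box), at the origin for
free diffusion. Each particle owns an RNG stream keyed by (seed, particle
index) — a splitmix-seeded xoshiro256++ generator with Box–Muller normals
— so trajectories are bitwise reproducible and unchanged when the particle
count grows.

Phases are not stored per orientation. The walk accumulates per particle
the moment matrix $M_{ab} = \gamma\,\delta t\sum_t g_a(t)\,r_b(t)$ per
waveform; the phase for substrate orientation $R$ and amplitude scaling
$s$ is $\varphi = s\sum_{ab}R_{ab}M_{ab}$, so the full 60-orientation,
13-b-value protocol costs one walk. The signal is
$E = \langle\cos\varphi\rangle$; the residual imaginary part
$\langle\sin\varphi\rangle$, zero in expectation, is reported as a sanity
metric alongside the standard error of $E$. The choice of
$\langle\cos\varphi\rangle$ over $|\langle e^{i\varphi}\rangle|$ is
deliberate and documented: it is unbiased, whereas the magnitude has a
noise floor. Monte Carlo ADCs are taken from the decay between the two
lowest b-values (0 and 100 s/mm² by default; other pairs via
`mc_adc(b_pair=)`). Gradient amplitudes are rescaled per b-value as
$\sqrt{b/b_\mathrm{ref}}$, exactly as a scanner adjusts amplitudes, so
every encoding hits each b identically.

Waveforms are coarse-grained onto the walk grid by interpolating the
dephasing and differencing — each walk step sees the average gradient over
its interval. The walk duration must equal the waveform duration; the
orientation rotates the substrate frame relative to the gradient frame.

## Powder statistics and fits

Orientation sets default to a deterministic spherical-Fibonacci scheme
(spherical moments accurate to $O(n^{-2})$; the identity frame at $n=1$),
with a seeded uniform-rotation alternative. $\langle\mathrm{ADC}\rangle$
and $V_D$ are population moments — the orientation set is the design, not
a sample. The second-cumulant powder form
$\exp[-\langle\mathrm{ADC}\rangle b + V_D b^2/2]$ and the third-order fit
$S = S_0\exp(-c_1 b + c_2 b^2/2 - c_3 b^3/6)$ (free $S_0$; this sign
convention is tested by round trip) use b rescaled to its maximum
internally for conditioning; starting values come from a cubic fit of
$\log S$ and the optimiser is Levenberg–Marquardt on the raw residuals,
which converges on exactly generated data to $10^{-6}$ or better.

**Fit precision at finite SNR.** With 12–13 points over 240–4800 s/mm²
and Rician noise at SNR 50, the standard error of $\hat c_1$ is 5–8 % of
$c_1$ for realistic curves — single-realisation recovery near 5 % is
therefore a property of the noise draw as much as of the fitter. The test
suite pins the documented seed for the point check and bounds the error by
three times the estimator's spread in the general check.

## Phantoms, noise and maps

`make_phantom()` ships eight archetypes. The four materials-style systems
follow the stratification by size and anisotropy: yeast = 50 % spheres
($R=2.5$ µm) + 50 % free, both $D_0=10^{-9}\,\mathrm{m^2/s}$ (identical
to the simulation benchmark system); microfibers = dispersed cylinders
$R=5$ µm; liquid crystal = dispersed cylinders $R=2$ nm (transverse
diffusivity effectively zero at encoding frequencies — apparently 1D,
time-independent diffusion); polymer = three flat isotropic diffusivities.
The four tissue-style archetypes (wm, gm, cerebellum, pbs) are
*illustrative* mixtures of thin cylinders, spheres, anisotropic Gaussian
and free compartments with documented, overridable fractions — they are
not fits to any measured tissue curve. Overlap/divergence calls use
documented thresholds: curves overlap when $\max_b|\Delta E| \le 0.01$ and
diverge when $\ge 0.03$; both are configurable arguments of
`phantom_panel()`. Under the default microfiber model the
tuned−isotropic contrast is small (+0.004 at $b^\*=4800$ s/mm²) though
strictly positive: a 5 µm liquid-filled cylinder at $\tau=23$ ms is only
weakly anisotropic. Real fiber phantoms with packing water and diameter
dispersion show larger anisotropy; adding components to the system is the
supported way to emulate that.

Rician noise is injected as the magnitude of
$(E+\mathcal N(0,\sigma)) + i\,\mathcal N(0,\sigma)$, $\sigma = 1/\mathrm{SNR}$,
seeded. Voxel maps normalise by the fitted $S_0$ by default (a flag
selects the raw $b=0$ frame), subtract at $b^\*$, and smooth with an
isotropic Gaussian kernel specified by FWHM in physical millimetres
($\sigma = \mathrm{FWHM}/\sqrt{8\ln 2}$), truncated at $3\sigma$ and
renormalised at edges via a convolved ones-mask.

## What the synthetic data do and do not show

The generator emulates: ideal per-compartment Gaussian-approximation
signals from monodisperse impermeable geometries, exact powder designs,
Rician magnitude noise, and label-pure voxels. It does not emulate:
compartment exchange or permeable membranes, polydisperse sizes,
relaxation weighting, imaging artefacts (motion, distortion, partial
volume), concomitant fields, or realistic orientation coherence. Passing
tests therefore demonstrate the correctness and internal consistency of
the encoding theory, spectral quadrature, simulator and map pipeline — not
that the phantom archetypes quantitatively match any particular measured
material.

## Problem sizes used by the shipped checks

Unit tests run reduced configurations (walks of a few thousand particles,
FFTs of $2^{18}$–$2^{19}$ points). The acceptance suite and
`scripts/acceptance.R` use the reference configuration where it matters:
5000-step walks with $10^5$ particles for the mono-exponentiality bound,
$3\times10^4$–$5\times10^4$ particles across 15 orientations for the
cross-engine comparison, and full $2^{21}$-point spectra everywhere.

## Known limitations

* The q-MAS generator is a closed-form design, not a constrained-optimised
  waveform; its spectral tuning degrades for restrictions whose
  correlation rates sit mid-band (4.5 % ADC mismatch at $R=5$ µm, above),
  and its gradient demand at matched b is far higher than optimised
  designs (the shipped fixture reaches $b=41$ s/mm² at 500 mT/m; the full
  ladder to 4800 s/mm² implies amplitudes well above typical caps —
  irrelevant for simulation, relevant for hardware realism).
* Eigenmode completeness converges like $1/K$; the high-frequency tail of
  $\lambda$ is correspondingly truncated at the $10^{-3}$ level for the
  default $K=250$.
* Single-realisation cumulant-fit recovery at SNR 50 is noise-limited, as
  quantified above.
* The Monte Carlo rejection scheme biases near-wall density at coarse
  steps; the step-size precondition keeps the walk inside the regime where
  the cross-engine agreement contract (5 % of $D_0$) holds.
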