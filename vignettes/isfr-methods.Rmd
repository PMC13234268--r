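---
title: "Modeling single-fiber and imaging single-fiber reflectance"
author: "isfr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling single-fiber and imaging single-fiber reflectance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(isfr)
```

## The measurement and the model

Single-fiber reflectance (SFR) spectroscopy collects the light returned by
a turbid medium through the same multimode fiber that illuminates it;
imaging SFR (iSFR) projects the fiber face onto the sample through air, so
the glass-tissue contact interface is replaced by an air-tissue interface
and the spot size and numerical aperture (NA) become free design
parameters. Because source and detector overlap, most detected photons
have scattered only a few times: the signal lives in the *subdiffuse*
regime, where reflectance depends on the detailed shape of the
single-scattering phase function and diffusion theory alone is
insufficient.

The package implements a semi-empirical forward model for the total
collected reflectance,

$$R_\mathrm{total} = (1 + X)\,\eta_c\, a_1\, R_\mathrm{diffuse},$$

with three ingredients:

* $R_\mathrm{diffuse}$, the diffuse contribution: the radial dipole
  kernel with extrapolated boundary condition, integrated against the
  distance density of two uniform points on the collection disk
  (`sfr_diffuse()`). The boundary coefficient is $A = 1.027$ for
  glass-tissue and $A = 2.6355$ for air-tissue — the only two interfaces
  supported, as no general formula in the indices is adopted.
* $\eta_c\,a_1$, the angular collection term: $\eta_c$ is the Lambertian
  cone fraction and $a_1$ an empirical correction for the non-Lambertian
  escape radiance.
* $X$, the subdiffuse-to-diffuse ratio
  $X = a_2\,\bigl(p_{sb}/(\mu_s' d_f)^2\bigr)^{a_3}
  \exp\!\bigl[b_1 (\mu_a/\mu_s')^{b_2}\bigr]$, where $p_{sb}$ is the
  semi-ballistic descriptor of the phase function: the probability of one
  backward deflection within 1° of 180°, divided by the probability of
  not scattering within 23° of forward (`pf_psb()`).

The five constants $a_1, a_2, a_3, b_1, b_2$ are shipped per modality and
NA (`model_params()`), with an alternative older SFR literature set
(`source = "post"`). Linear interpolation between tabulated NAs is
available and flagged; extrapolation is refused.

### The collection-efficiency convention

The Lambertian cone fraction can be written against the tissue index or
the external index. The shipped constants are only mutually consistent
with the *external* convention $\eta_c = (\mathrm{NA}/n_\mathrm{ext})^2$:
measured against this package's transport engine, the in-cone escape
enhancement times the external-Lambertian fraction reproduces the shipped
$a_1$ for both interfaces to better than 3% (glass) and 0.5% (air),
whereas the tissue-index convention would displace both modalities by
15-45%. `predict_reflectance()` therefore uses the external index;
`collection_efficiency()` itself is the plain ratio arithmetic so either
convention can be formed explicitly.

## Phase functions

Three analytic families cover experimentally observed tissue phase
functions: two-term Henyey-Greenstein (TTHG), modified Henyey-Greenstein
(MHG, an HG term plus a $3\cos^2\theta/4\pi$ term) and Reynolds-McCormick
(RMC, Gegenbauer kernel with closed-form normalization). `pf_grid()`
enumerates the candidate grids ("N steps" meaning N evenly spaced values
including both endpoints; the RMC `g_r` range shrinks with `alpha`) and
retains members with anisotropy $0.5 \le g_1 \le 0.95$ — the band typical
of soft tissue. This band reproduces the published survivor counts for
the MHG (15) and RMC (46) families exactly; for the TTHG family it
retains 138 members where the reference reports 146, a discrepancy we
could not resolve under any defensible reading of the printed grid (the
printed $g_1/g_2$ exclusion text reproduces none of the three counts).
The printed rule remains available via `pf_grid(filter = "g1_g2")`.

Angular moments are computed by adaptive quadrature split at 5° to protect
forward peaks (relative tolerance 1e-8 or better); closed forms (HG
$g_n = g^n$, mixture linearity, the $2/5$ second moment of the
$\cos^2$ kernel) serve as independent oracles in the tests, never as the
implementation. Sampling uses a $2^{15}$-node inverse-CDF table in
$\cos\theta$ with linear interpolation, gated by a Kolmogorov-Smirnov
test at the 1% level.

Across the retained grid the descriptor $p_{sb}$ is concentrated in the
$10^{-6}$-$10^{-4}$ span for which the empirical model is parameterized;
TTHG members with strong backward lobes exceed it (up to $\sim 3\times
10^{-2}$) and are excluded from model benchmarks, though kept in the grid
export.

## White Monte Carlo and the single-integral approximation

The transport engine (`mc_simulate()`) is absorption-free ("white")
Monte Carlo in a homogeneous semi-infinite medium: free paths are
exponential in $\mu_s$, deflections come from the tabulated phase
function, and every boundary crossing applies stochastic unpolarized
Fresnel transmission, including total internal reflection at the
air-tissue interface. Photons launch from a point on the boundary,
uniformly in solid angle within the in-tissue cone
$\sin\theta \le \mathrm{NA}/n_\mathrm{tissue}$ (a uniform-in-angle
alternative exists for sensitivity checks). Detection keeps photons
leaving within the same cone and within a radial cap. Each record stores
the exit radius and the total in-medium path length, so absorption is
applied afterwards as $e^{-\mu_a l}$ (`absorption_weights()`) and one
simulation serves every absorption coefficient.

Spot-size generality comes from the single-integral approximation: a
photon exiting at displacement $\rho$ from its entry point lands inside
the collection disk with the closed-form overlap probability
`overlap_weight()`, so the finite-spot reflectance is a per-photon
weighted average with no radial binning (`geometry_reflectance()`).
Its correctness is asserted against a direct finite-disk simulation in
which the source disk is also the physical detector.

Two estimators share the engine. The analog estimator records physical
exits. For narrow acceptance cones (NA of a few hundredths, where fewer
than one photon in a thousand is accepted) a next-event ("peel-off")
estimator integrates, at every near-surface collision, the probability of
scattering directly into the cone and escaping, and stores it as a
weighted record; analog exits are then not recorded, keeping the total
estimator unbiased. The cone integral uses a 2-point Gauss-Legendre rule
in the polar cosine and 8 azimuth nodes; the exit point and path length
use the cone center, an approximation that is excellent for the narrow
cones the estimator is intended for and is validated against the analog
estimator (agreement 0.4% ± 1.2% at NA 0.05). Russian roulette below
$10^{-3}$ of the cone solid angle bounds the record count without bias.
Standard errors treat photons, not records, as the independent unit.

Terminations: photons are killed beyond a configurable total path
(`max_path_mm`) or depth, emulating a large lossy computational domain;
losses are counted in the result. At the absorption levels of interest
the photons truncated by the desk-scale caps carry weights of $e^{-1}$ to
$e^{-5}$ on path-length tails holding a few percent of the detected mass,
a sub-percent bias.
Seeds are mandatory everywhere; batches use counter-style seeds
(`seed + batch`) so runs are reproducible and restartable. Desk-scale
benchmark runs cap paths at 100-200 mm.

## Fitting the model constants

`fit_model()` reproduces the two-step relative least-squares procedure:
scattering constants $(a_1, a_2, a_3)$ on the absorption-free subset
($\mu_a = 0$ rows, where the absorption exponential is identically one),
then $(b_1, b_2)$ on the full dataset with the scattering constants
frozen. Residuals are $(R_\mathrm{model} - R_\mathrm{MC})/R_\mathrm{MC}$,
weighting the decades of reflectance equally; rows are equally weighted
(inverse-variance weighting by the `rel_se` column is deliberately off by
default, as the reference procedure states relative weighting only).
Positivity is enforced by optimizing log-parameters with
Levenberg-Marquardt; eight log-spaced $a_2$ starts guard against local
minima, ties broken by the smaller parameter norm. Approximate 95%
confidence intervals come from the residual Jacobian via the delta
method. `fit_geometry_params()` wraps the whole pipeline — transport,
sweep, two-step fit — at desk scale for one geometry; on
model-generated data the fit recovers known constants to solver
precision (the core recovery property), and on this package's own MC
data it lands within the reference brackets (same order of magnitude for
$a_2$, within ~10% for the others).

## Tissue spectra

`tissue_model()` carries the wavelength parameterizations about
$\lambda^* = 650$ nm: a scattering power law $a(\lambda/\lambda^*)^{-b}$,
whole-blood absorption mixing $v_{f,\mathrm{blood}}[sO_2\,
\mu_{a,\mathrm{HbO_2}} + (1 - sO_2)\mu_{a,\mathrm{Hb}}]$, and a cubic
$p_{sb}(\lambda) = 10^{-5}(p_1 x + p_2 x^2 + p_3 x^3)$. Two presets are
shipped: skin ($a = 4.6$ mm$^{-1}$, $b = 1.4$, 1% blood) and generic soft
tissue ($a = 1.9$ mm$^{-1}$, $b = 1.3$, 5% blood), both at 70% oxygen
saturation. The bundled chromophore table is a synthetic compilation of
whole-blood absorption at 150 g/L hemoglobin reproducing the canonical
spectral features (Soret band, the 540/577 nm oxyhemoglobin double peak,
the 555 and 760 nm deoxy peaks, isosbestic points near 500/570/800 nm);
absolute values scale with the assumed concentration, which the table
header states. It is adequate for simulation studies, not for clinical
oximetry.

Monte Carlo ground-truth spectra need a complete phase function, not a
scalar $p_{sb}$: the reference realization is a TTHG with $\alpha = 0.8$,
$g_b = -0.05$ and forward anisotropy falling linearly from 0.8 at 400 nm
to 0.7 at 900 nm (`reference_phase_function()`). The presets' cubic
coefficients are fitted once to this realization's descriptor curve, so
simulated truth and parameterized truth agree. Noise injection
(`add_noise()`) is Gaussian per spectral point with standard deviation
equal to a fraction of the spectrum's root-mean-square, making it
scale-equivariant in the reflectance.

## Inverse retrieval

`retrieve_properties()` minimizes the relative least-squares spectral
objective over the seven parameters $(a, b, v_{f,\mathrm{blood}}, sO_2,
p_1, p_2, p_3)$ with bounded Levenberg-Marquardt restarted from 50
uniform random points in the bound box, then polishes the best start to
tight tolerances (objective tolerance $10^{-12}$). Default bounds are
$a \in [0.1, 30]$ mm$^{-1}$, $b \in [0.1, 4]$,
$v_{f,\mathrm{blood}} \in [0, 0.3]$, $sO_2 \in [0, 1]$ and
$p_{1..3} \in [-30, 30]$; the cubic coefficients of realistic descriptor
curves are individually large with strong cancellation, which is why the
box is generous and why $p_{sb}(\lambda)$ is reported through its curve
RMSE and its value at $\lambda^*$, never through raw coefficients. A
smooth penalty keeps $p_{sb}(\lambda)$ inside the model's validity span
$[10^{-6}, 10^{-4}]$.

On model-generated spectra ("inverse crime") every parameter is recovered
to solver precision. On Monte Carlo spectra the errors do not vanish at
zero noise: the forward model's local bias (about 5% at the 500 µm /
NA 0.05 geometry studied) propagates into the parameters, and because the
objective has no free gain, a flat reflectance offset must be absorbed by
physical parameters along the $\mu_s'(\lambda)$-versus-$p_{sb}$
competition ridge. For the skin preset this yields median errors of
roughly 3-13% per parameter at 1% RMS noise. The soft-tissue preset is
harsher: with 5% blood, $\mu_a/\mu_s'$ reaches $\approx 3.6$ in the Soret
band, where the dipole-based diffuse term is far outside its validity and
the forward model underpredicts the Monte Carlo reference by 25-30%; the
relative objective then genuinely prefers a degenerate solution
(scattering amplitude biased low by more than half, compensated by the
descriptor curve) — an identifiability collapse of the model form itself,
reproduced even when the optimizer is started at the truth. Users fitting
strongly absorbing tissue should restrict the spectral range or constrain
the descriptor.

## Problem sizes and what the tests show

Simulation sizes here are desk-scale by design: reference work uses
$\sim 10^6$ grid combinations at GPU scale and $\ge 10^6$ detected
photons per spectrum point, while this package's checks use a random
subsample of the parameter space (10 phase functions × 3 scattering
levels × 2 spot sizes × 4 absorptions per modality, at $\ge 10^4$
detected photons) and spectra at 26 wavelengths with per-point Monte
Carlo noise held at 0.25%. At these sizes the forward model reproduces
its reference accuracy (medians of a few percent, roughly three quarters
of points within 10%), and the fitting and retrieval machinery
demonstrates exact self-consistency plus the documented bias floors on
cross-engine data. What passing tests do *not* show: accuracy on real
tissue (no instrument response, calibration, specular handling or
heterogeneity is modeled), behavior outside the tabulated NA range, or
chromophores beyond hemoglobin.

## Numerical choices

* Quadratures: disk integrals use composite 24-node Gauss-Legendre panels
  concentrated near the dipole peak ($\rho \lesssim 5 z_0$), checked
  against `stats::integrate` at $10^{-7}$; phase-function moments use
  adaptive quadrature with a 5° split.
* The $\rho \to 0$ limit of the pair density divided by $2\pi\rho$ is
  finite ($4/\pi d_f^2$); the overlap weight uses the closed form
  directly, so no special handling is needed.
* Transport RNG is xoshiro256++ seeded by splitmix64 (counter-style per
  batch), independent of R's RNG; R-side sampling helpers preserve and
  restore the global RNG state.
* Degenerate inputs error early: non-positive $\mu_s'$ or $d_f$,
  unsupported interfaces, unseeded stochastic calls, finite-source
  records fed to the point-source converter.
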