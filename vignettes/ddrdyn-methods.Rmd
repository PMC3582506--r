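---
title: "Models and methods behind ddrdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ddrdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddrdyn)
```

`ddrdyn` analyzes the first minutes of the cellular response to DNA
double-strand breaks (DSBs) induced by ionizing radiation, combining
three ingredients: FRAP-based estimation of protein mobility and binding
turnover, mono-exponential analysis of recruitment kinetics at
radiation-induced foci, and a minimal mass-action model of focus
formation that links the two across damage densities (LET). This
vignette explains each model, its assumptions, the tunable parameters,
and the numerical and design choices made where more than one sound
option existed.

## FRAP forward models

### Pure diffusion

For a uniform circular bleach region of radius $w$ in an effectively
unbounded 2-D medium, the normalized recovery is the classical
closed form

$$F(t) = e^{-2\tau_D/t}\left[I_0\!\left(\tfrac{2\tau_D}{t}\right) +
I_1\!\left(\tfrac{2\tau_D}{t}\right)\right],
\qquad \tau_D = \frac{w^2}{4D},$$

with $I_0$, $I_1$ modified Bessel functions of the first kind
(`soumpasis_frap()`). The curve depends on $t/\tau_D$ only, which is
what makes the diffusion coefficient identifiable from a single
well-sampled recovery. We evaluate the expression with exponentially
scaled Bessel functions so that small $t$ (large arguments) cannot
overflow. An incomplete bleach of depth $\theta$ rescales the curve
affinely to $[\theta, 1]$; the underlying transport problem is linear,
so this is exact, not an approximation.

The default geometry is a 1.5 µm spot radius — half the measured 3.0 µm
laser-spot FWHM, idealized as a uniform disc — inside a cylindrical
nucleus of radius 9.4 µm. Both are `bleach_geometry()` fields, not
constants.

### Diffusion–reaction with nucleus-wide binding

When binding sites are distributed homogeneously (pan-nuclear binding of
MDC1 after very dense damage), the recovery solves a linear
reaction–diffusion system with immobile bound complexes. Its Laplace
transform is closed-form:

$$\bar F(p) = \frac{1}{p}
 - \frac{F_{eq}}{p}\bigl[1 - 2K_1(qw)I_1(qw)\bigr]
   \Bigl[1 + \tfrac{k^*_{on}}{p + k_{off}}\Bigr]
 - \frac{C_{eq}}{p + k_{off}},
\qquad q^2 = \frac{p}{D}\Bigl(1 + \frac{k^*_{on}}{p+k_{off}}\Bigr),$$

where $F_{eq} = k_{off}/(k^*_{on}+k_{off})$ and
$C_{eq} = 1 - F_{eq}$ are the equilibrium free and bound fractions.
$k^*_{on}$ is an *effective* association rate — the product of the
intrinsic on-rate and the free-site density, which FRAP cannot separate.
The product $K_1(x)I_1(x)$ is computed from scaled Bessel functions
(the $e^{\pm x}$ factors cancel exactly), with the asymptote $1/(2x)$
beyond $x = 10^5$.

Two limits anchor the implementation and are asserted in the tests:
with $k^*_{on} = 0$ the transform reduces *identically* to the
pure-diffusion solution (via the Wronskian
$I_0K_1 + I_1K_0 = 1/x$), and when both rates are fast compared to
$1/\tau_D$ the curve collapses onto pure diffusion with
$D_{eff} = D/(1 + k^*_{on}/k_{off})$ — the effective-diffusion
interpretation used for untreated cells, available directly as
`effective_diffusion_coefficient()`.

### Diffusion–reaction with focus-confined binding

Binding at a radiation-induced focus is modeled as a two-region radial
boundary-value problem: inside $r < w$ the free protein (diffusing with
the effective coefficient measured in untreated cells) exchanges with
immobile sites at rates $(k^*_{on}, k_{off})$; outside it diffuses
freely. Bleach region, binding region and focus coincide — the
experiment bleaches single foci, and no separate focus radius is
measured. In the Laplace domain each region has a Bessel-function
solution; matching concentration and radial flux at $r = w$ gives a
2×2 system solved in closed form, and the reported signal is the
area-averaged free + bound concentration over the focus.

**Outer boundary.** The package defaults to an *open* outer region (the
free concentration approaches its equilibrium value far from the
focus). A closed nucleus with a zero-flux wall is available
(`outer_boundary = "reflecting"`), but under strong binding a finite
pool cannot replace the bleached bound molecules and recovery
necessarily stalls below 1, contradicting both the observed full
recovery of focal FRAP curves and the requirement that the forward
model converge to 1. The open choice treats the nucleus-wide pool as a
reservoir — appropriate while the bleached molecules are a small
fraction of the total, the same assumption the closed-form
nucleus-wide model makes. For pure diffusion the two choices agree to
better than $10^{-3}$ over the times where FRAP data carry information.

### Numerical Laplace inversion

Both reaction models are inverted with the Stehfest algorithm
(`stehfest_invert()`): $f(t) \approx (\ln 2/t)\sum_j V_j \bar f(j\ln
2/t)$ with the standard weights. $N = 12$ terms is the default — beyond
$N \approx 14$ the alternating weights (up to $\sim 10^5$ at $N=12$)
amplify double-precision round-off faster than the truncation error
shrinks. The method samples the transform on the real axis only, so it
is exact for smooth monotone originals (FRAP recoveries are both) but
degrades near branch points; the test suite pins its accuracy on five
known transform pairs, including $1/\sqrt{p}$ as the hard case.

## FRAP fitting

Raw measurements are double-normalized
(`double_normalize()`): bleach-ROI and whole-cell traces are
background-subtracted, the ROI is normalized to its pre-bleach mean and
divided by the whole-cell trace normalized to *its* pre-bleach mean.
Any multiplicative acquisition-bleaching factor common to both traces
cancels exactly, and the pre-bleach mean is 1 by construction.

Diffusion coefficients are fitted by 1-D minimization of the summed
squared residuals over $\log_{10} D$ (`fit_effective_diffusion()`).
Binding constants are fitted with `fit_binding_constants()`: the
objective over $(k^*_{on}, k_{off})$ is multi-modal, so start values
are permuted in decade steps from $10^{-6}$ to $10^{6}$ (a 13×13 grid),
a Nelder–Mead run is started from every pair in log space with box
constraints $[10^{-8}, 10^{8}]$ 1/s, and the best optimum is polished.
Residuals are unweighted; pre-bleach frames are excluded and the first
post-bleach frame defines $t = 0^+$. The free diffusion coefficient is
*fixed* from untreated-cell fits rather than co-fitted — FRAP curves
constrain two binding rates and a timescale poorly when all three float.

Two pieces of mobility arithmetic round out the module:
`scaled_diffusion_estimate()` implements the cube-root mass scaling
$D_{calc} = D_{ref}(m_{ref}/m)^{1/3}$ for spherical proteins of equal
density, and `traversal_time()` the 2-D mean-squared-displacement
relation $t = r^2/(4D)$.

## Recruitment analysis

Recruitment curves at damage foci are normalized to 0 before
irradiation and 1 at the plateau (`normalize_recruitment()`). The
plateau is fitted jointly with the time constant rather than taken as a
last-frames mean: curves that have not fully saturated by the end of
the observation window would otherwise be systematically
mis-normalized. A curve whose fitted plateau is indistinguishable from
three baseline standard deviations is flagged `no_recruitment` instead
of being force-scaled.

The kinetics are summarized by the mono-exponential
$I(t) = P(1 - e^{-(t-\mathrm{lag})/\tau})$
(`fit_mono_exponential()`): $\tau$ is the time after onset at which
63% ($1 - 1/e$) of the plateau is reached. The lag is fixed at 0 by
default — appropriate for sensors and mediators that arrive without
upstream processing (NBS1, ATM, MDC1) — and can be freed for
late-arriving factors with a pronounced lag phase (53BP1-like
curves). `tau_vs_let()` tabulates $\tau$ with its asymptotic standard
error against LET.

## The minimal focus-formation model

The ODE model (`ddr_parameters()`, `simulate_ddr()`) tracks effective
concentrations in a fixed volume around the damage foci — no spatial
resolution, one compartment, mass-action kinetics:

1. MRN binds reversibly to DSB-proximal ("inner") sites, whose number
   scales linearly with LET (`dsb_count()`, 28 DSBs at 170 keV/µm by
   default).
2. Inner-focus MRN captures inactive ATM and releases it as active ATM.
3. Active ATM rebinds inner MRN reversibly; MRN carrying ATM in either
   form cannot dissociate.
4. Free active ATM phosphorylates H2AX catalytically; the focus carries
   a fixed capacity of 3500 H2AX sites.
5. MDC1 binds free γH2AX reversibly.
6. Recruited MDC1 offers independent docking sites for MRN (reversible)
   and active ATM (irreversible) — the "outer" focus.

Deliberately absent: free-ATM autophosphorylation, γH2AX
dephosphorylation, ATM dissociation from the outer focus, H2AX
phosphorylation by outer-bound ATM, and all pathway-specific repair
factors. The model describes the first ~700 s, where these omissions
do not change the observable readouts.

**Bookkeeping choices.** MRN- and ATM-docking on recruited MDC1 are
independent occupancies, avoiding a combinatorial explosion of ternary
species. Only cargo-free recruited MDC1 dissociates from γH2AX; under
independence the cargo-free amount is
$(\mathrm{rec}-M_{outer})(\mathrm{rec}-ATM_{outer})/\mathrm{rec}$.
The DSB number is continuous — it enters only as a site-capacity scale.

**Variants.** `ck2_inhibited` zeroes the outer MRN docking rate (CK2
inhibition abolishes the MDC1–NBS1 interaction), isolating the
inner-focus binding mode. `mdc1_diffusion_limited` caps the available
MDC1 pool at $c\sqrt{4Dt}$ with $D = 0.029$ µm²/s — the scaling of
diffusive supply in cylindrical geometry — for the low-LET regime where
slow MDC1 diffusion becomes rate limiting; the proportionality constant
$c$ is a fit parameter, not a measured value.

**Default parameters.** The dissociation rate of MDC1 from γH2AX
defaults to the FRAP-measured X-ray focus value ($425\times10^{-5}$
1/s). The remaining rates and totals are package choices, selected once
so that the default model reproduces the established qualitative
behavior — recruitment accelerating with LET, ATM activation saturating
within minutes at high but not low LET, the inner-focus share of MRN
rising from negligible (<1% at 170 keV/µm) to dominant at the highest
LETs, and recruited MDC1 saturating at the H2AX capacity — and they
should be replaced by fitted values for any quantitative application.
The MRN dissociation rates `k_mi_off` and `k_mo_off` in particular are
placeholders, not measurements. One known consequence of the default
totals: the transient overshoot of inner-focus MRN (caused at high LET
by ATM occupancy blocking MRN dissociation until the ATM pool is
exhausted) has, with these defaults, a smaller counterpart at low LET
driven by depletion of free MRN into the outer focus. Only the
high-LET transient is asserted by the tests.

**Integration.** `deSolve::ode` with `lsoda` (relative tolerance
$10^{-8}$, absolute $10^{-10}$) by default; an adaptive Cash–Karp
Runge–Kutta pair is available via `method = "rk45ck"`. All four
conservation laws (MRN, ATM, H2AX, MDC1 pools, plus inner sites) hold
to $10^{-6}$ relative along every trajectory by construction of the
derivative function, and the tests verify this.

## Shared-parameter estimation

`fit_ddr_parameters()` fits one parameter set to a whole panel of
recruitment curves; only the DSB number differs between the simulations
(from each curve's LET). The objective (`panel_objective()`) is the
plain sum of squared residuals over all curves and time points.
Optimization is Nelder–Mead in $\log_{10}$ parameter space — the rates
span many decades and the simplex degenerates on badly scaled axes —
with seeded jittered restarts (default 5) because the simplex is local.

Measured curves are plateau-normalized, so the model must be brought
onto that scale. Two conventions are supported: `scale_mode =
"plateau"` (default) divides each simulated curve by its own end-window
value, making the objective independent of the readout scales;
`"signal_scale"` compares raw scaled readouts and leaves per-protein
scale factors to be fitted as shared parameters. MDC1 curves are
excluded from the default objective — the basic model over-predicts
early MDC1 recruitment at low LET unless the diffusion-limited variant
is used — and can be included with a switch.

## Synthetic data

`generate_frap_raw()` and `generate_recruitment_panel()` produce the
inputs the pipeline consumes from the package's own forward models:
FRAP raw triplets (ROI/whole-cell/background, with pre-bleach frames,
optional acquisition bleaching and multiplicative Gaussian noise) and
plateau-normalized multi-LET recruitment panels with pre-irradiation
frames and additive Gaussian noise on the normalized scale. Defaults
mirror the experimental designs: 5 pre-bleach frames, recruitment
sampled over 0–700 s, noise σ = 0.02, all seeded and bit-reproducible.

What the generator emulates — and what it does not: it reproduces the
curve *structure* of the experiments (normalization conventions,
sampling, acquisition bleaching, noise scatter) but not image-level
effects (pixels, point-spread functions, photon statistics, focus
drift) or biological variability between cells. Passing round-trip
tests therefore demonstrates the estimators' correctness and their
noise robustness under the stated noise model, not performance on any
particular microscope's data.

## Problem sizes used by the test suite

The shipped tests run the full pipeline at desk scale: FRAP curves of
50–150 frames, the 13×13 decade start grid on noise-free curves,
50-replicate noise-robustness loops with reduced start grids,
a 3×3 binding-rate grid against an explicit finite-difference PDE
oracle (grid spacing 0.05 µm, time step $0.2\,\Delta r^2/D$, domain
15 µm), and ten seeded generate-and-refit rounds of a three-curve
recruitment panel with five free rates and a single restart from a
fixed perturbed start. These sizes were chosen as the smallest at which
each property is meaningfully exercised.

## Known limitations

* The FRAP models are 2-D (cylindrical nucleus, uniform disc bleach);
  3-D geometry, Gaussian bleach profiles and multi-state binding are out
  of scope.
* $k^*_{on}$ confounds on-rate and site density; only $k_{off}$ is a
  pure binding property.
* The focus model has no spatial structure beyond the $\sqrt{t}$ MDC1
  variant, no nucleus-wide γH2AX spreading, and no repair (DSBs do not
  disappear); it is a model of the first ~700 s only.
* With strong binding and realistic noise, $(k^*_{on}, k_{off})$ from a
  single focal FRAP curve can be weakly identified; the decade grid
  finds the global optimum, but confidence regions can be wide. Only
  asymptotic standard errors are reported, not profile likelihoods.
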