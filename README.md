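# ddrdyn

Quantitative analysis of the early DNA double-strand-break (DSB)
response in living cells: FRAP-based estimation of protein mobility and
binding turnover, recruitment-kinetics analysis at radiation-induced
foci across damage densities (LET), and a minimal mass-action model of
MRN/NBS1–ATM–γH2AX–MDC1 focus formation fitted jointly to multi-LET
recruitment panels. Written for researchers analyzing live-cell
beamline-microscopy and photobleaching experiments on DNA-repair
proteins.

## What it computes

**FRAP.** Recovery of a uniformly bleached disc of radius *w* is modeled
three ways:

* pure diffusion (closed form):
  `F(t) = exp(-2τ_D/t) [I₀(2τ_D/t) + I₁(2τ_D/t)]` with `τ_D = w²/(4D)`;
* diffusion–reaction with nucleus-wide binding sites (Laplace-domain
  solution, Stehfest numerical inversion);
* diffusion–reaction with focus-confined binding sites (two-region
  radial boundary-value problem, same inversion).

Fitting recovers the effective diffusion coefficient `D_eff`, or the
effective association and dissociation rates `k*_on`, `k_off` of one
reversible binding reaction via a 13×13 decade grid of start values and
Nelder–Mead refinement. Rapid transient binding yields
`D_eff = D / (1 + k*_on/k_off)`.

**Recruitment.** Normalized focus-intensity curves are summarized by the
mono-exponential time constant τ — the time after irradiation at which
63% of the plateau is reached — and tabulated against LET.

**Focus-formation model.** A mass-action ODE system in which MRN binds
DSB-proximal ("inner") sites whose number scales linearly with LET
(28 DSBs at 170 keV/µm), activates ATM, which phosphorylates H2AX
(fixed outer capacity 3500 sites), recruiting MDC1 and thereby
additional MRN and ATM ("outer" focus). One parameter set is fitted to
all curves at once; only the DSB number differs between simulations.

## Worked example

```r
library(ddrdyn)

# --- mobility arithmetic -------------------------------------------------
geom <- bleach_geometry(fwhm_um = 3.0, nucleus_radius_um = 9.4)
scaled_diffusion_estimate(12, 27, 137)   # expected D for a 137 kDa protein
#> [1] 6.983326
traversal_time(6.3, 0.029)               # seconds to cross 6.3 um
#> [1] 342.1552

# --- FRAP round trip: generate, normalize, refit -------------------------
raw <- generate_frap_raw("pure_diffusion", D = 12, geom = geom,
                         noise = noise_model(relative_sigma = 0,
                                             acquisition_bleach_rate = 0.02))
curve <- double_normalize(raw$times, raw$roi, raw$whole_cell,
                          raw$background, raw$n_prebleach)
fit_effective_diffusion(curve, geom)
#> FRAP fit (pure_diffusion)
#>   D_eff: 12 um^2/s
#>   SSE: 7.338621e-19

# --- recruitment time constant -------------------------------------------
t <- seq(2, 700, by = 2)
cv <- recruitment_curve(c(-10, t), c(0, 1 - exp(-t / 125)),
                        let_value = 14350, protein = "ATM")
fit_mono_exponential(cv)
#> Mono-exponential recruitment fit
#>   tau: 125 s (se 0)
#>   plateau: 1   lag: 0 s

# --- focus model across LET ----------------------------------------------
out <- simulate_ddr(ddr_parameters(), let_value = 10290,
                    t_grid = seq(0, 700, by = 10))
readout_inner_fraction(out, 700)   # share of NBS1 bound directly at DSBs
#> [1] 0.3489534
```

The diffusion fit returns the generating coefficient (12 µm²/s) despite
the imposed acquisition bleaching, because double normalization cancels
it; τ = 125 s is recovered exactly from the exact curve; and at high
LET roughly a third of focus-bound NBS1 sits directly at break ends
with the package's default parameter set (the share grows monotonically
with LET).

A thin command-line wrapper over the same functions ships at
`inst/cli/ddrdyn.R` (`simulate-frap`, `simulate-recruitment`,
`fit-frap`, `fit-recruitment`, `fit-model`, `report`).

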