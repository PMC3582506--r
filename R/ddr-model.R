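# Minimal mass-action ODE model of the early DNA double-strand-break
# response: MRN binding at the inner (DSB-proximal) and outer
# (MDC1/gammaH2AX-dependent) focus compartments, ATM activation at
# inner-focus MRN, H2AX phosphorylation by free active ATM, and MDC1
# recruitment, with the DSB number scaled linearly with LET.

#' Parameters of the DSB-response ODE model
#'
#' Rate constants, species totals and readout scalings of the minimal
#' focus-formation model. Concentrations are relative units in a fixed
#' volume around the damage foci; second-order rates are per concentration
#' unit per second. The dissociation rates of MDC1 from gammaH2AX
#' (`k_md_off`) defaults to the X-ray focus value measured by FRAP
#' (425e-5 1/s). The MRN dissociation rates `k_mi_off` and `k_mo_off` are
#' package defaults, not measured values, and should be set explicitly
#' (from FRAP fits) for any quantitative reuse.
#'
#' @param k_mi_on,k_mi_off MRN association to free DSB-proximal (inner)
#'   sites and dissociation of ATM-free inner MRN.
#' @param k_act_on Capture of unactivated ATM by inner-focus MRN.
#' @param k_act Activation and release of captured ATM as active ATM.
#' @param k_ai_on,k_ai_off Reversible binding of active ATM to inner MRN;
#'   MRN carrying ATM (either form) cannot dissociate.
#' @param k_ph Catalytic phosphorylation of H2AX by free active ATM.
#' @param k_md_on,k_md_off MDC1 binding to free gammaH2AX; only recruited
#'   MDC1 carrying neither MRN nor ATM dissociates.
#' @param k_mo_on,k_mo_off MRN docking on recruited MDC1 (outer focus).
#' @param k_ao_on Irreversible docking of active ATM on recruited MDC1,
#'   independent of MRN occupancy.
#' @param mrn_total,atm_total,mdc1_total Species totals.
#' @param h2ax_total H2AX site capacity of the outer focus (default 3500).
#' @param sites_per_dsb Inner MRN binding sites per DSB.
#' @param dsb_per_let Slope of the linear LET to DSB-number map
#'   (default 28/170 DSB per keV/µm, i.e. 28 DSBs at 170 keV/µm).
#' @param signal_scale_nbs1,signal_scale_atm,signal_scale_mdc1 Linear
#'   scalings mapping bound-species sums to measured signals.
#' @param mdc1_diffusion_D Effective MDC1 diffusion coefficient (µm²/s)
#'   used by the diffusion-limited variant (default 0.029).
#' @param mdc1_diffusion_coef Proportionality constant c in the
#'   diffusion-limited available-MDC1 law c * sqrt(4 D t) (relative
#'   concentration per µm).
#' @return An object of class `ddr_parameters`.
#' @export
ddr_parameters <- function(k_mi_on = 1.2e-5, k_mi_off = 1e-2,
                           k_act_on = 4e-6, k_act = 5e-2,
                           k_ai_on = 1e-6, k_ai_off = 1e-2,
                           k_ph = 1.5e-3,
                           k_md_on = 2e-4, k_md_off = 425e-5,
                           k_mo_on = 1e-5, k_mo_off = 1e-2,
                           k_ao_on = 1e-6,
                           mrn_total = 4000, atm_total = 1000,
                           mdc1_total = 5000, h2ax_total = 3500,
                           sites_per_dsb = 1, dsb_per_let = 28 / 170,
                           signal_scale_nbs1 = 1, signal_scale_atm = 1,
                           signal_scale_mdc1 = 1,
                           mdc1_diffusion_D = 0.029,
                           mdc1_diffusion_coef = 300) {
  p <- as.list(environment())
  rates <- c("k_mi_on", "k_mi_off", "k_act_on", "k_act", "k_ai_on",
             "k_ai_off", "k_ph", "k_md_on", "k_md_off", "k_mo_on",
             "k_mo_off", "k_ao_on")
  for (nm in rates) check_scalar(p[[nm]], nm, lower = 0)
  for (nm in c("mrn_total", "atm_total", "mdc1_total", "h2ax_total",
               "sites_per_dsb", "mdc1_diffusion_D", "mdc1_diffusion_coef")) {
    check_scalar(p[[nm]], nm, lower = 0, strict_lower = TRUE)
  }
  check_scalar(p$dsb_per_let, "dsb_per_let", lower = 0)
  structure(p, class = "ddr_parameters")
}

ddr_species <- c("M_free", "S_inner_free", "M_inner", "M_inner_ATM",
                 "M_inner_ATMp", "ATM_free", "ATMp_free", "H2AX",
                 "gH2AX_free", "MDC1_free", "MDC1_rec", "M_outer",
                 "ATM_outer")

#' Number of DSBs induced at a given LET
#'
#' The DSB number entering the model scales linearly with LET:
#' `dsb_per_let * let_value`. With the default slope of 28/170 per
#' keV/µm, carbon ions at 170 keV/µm correspond to 28 DSBs. The value is
#' continuous (not rounded): it enters the model only as a site-capacity
#' scale.
#'
#' @param let_value Linear energy transfer (keV/µm), >= 0.
#' @param params A [ddr_parameters()].
#' @return DSB number (continuous).
#' @examples
#' dsb_count(170)  # 28
#' @export
dsb_count <- function(let_value, params = ddr_parameters()) {
  check_scalar(let_value, "let_value", lower = 0)
  stopifnot(inherits(params, "ddr_parameters"))
  params$dsb_per_let * let_value
}

#' Build the mass-action derivative function of the DSB-response model
#'
#' Reactions: (R1) reversible MRN binding to free inner sites; (R2)
#' capture of unactivated ATM by inner MRN; (R3) activation and release
#' of active ATM; (R4) reversible binding of active ATM to inner MRN
#' (ATM-occupied MRN cannot dissociate); (R5) catalytic H2AX
#' phosphorylation by free active ATM; (R6) reversible MDC1 binding to
#' free gammaH2AX (only cargo-free recruited MDC1 dissociates); (R7)
#' reversible MRN docking on recruited MDC1; (R8) irreversible active-ATM
#' docking on recruited MDC1, independent of MRN occupancy. MRN and ATM
#' docks on recruited MDC1 are independent occupancies. There is no free
#' ATM autophosphorylation, no gammaH2AX dephosphorylation, no ATM
#' dissociation from the outer focus and no H2AX phosphorylation by
#' outer-bound ATM: a minimal model of the first ~700 s.
#'
#' @param params A [ddr_parameters()].
#' @param n_dsb DSB number (continuous), >= 0.
#' @param variant `"standard"`, `"ck2_inhibited"` (outer MRN docking
#'   abolished: `k_mo_on = 0`) or `"mdc1_diffusion_limited"` (the
#'   available MDC1 pool grows as `min(mdc1_total, c*sqrt(4 D t))`,
#'   emulating diffusion-limited supply in cylindrical geometry).
#' @return A function `(t, state)` returning the named derivative vector;
#'   species order is given by the `species` attribute.
#' @export
build_reaction_system <- function(params, n_dsb,
                                  variant = c("standard", "ck2_inhibited",
                                              "mdc1_diffusion_limited")) {
  stopifnot(inherits(params, "ddr_parameters"))
  check_scalar(n_dsb, "n_dsb", lower = 0)
  variant <- match.arg(variant)
  p <- params
  k_mo_on <- if (variant == "ck2_inhibited") 0 else p$k_mo_on
  diff_limited <- variant == "mdc1_diffusion_limited"
  deriv <- function(t, state) {
    s <- as.list(state)
    v1f <- p$k_mi_on * s$M_free * s$S_inner_free
    v1r <- p$k_mi_off * s$M_inner
    v2 <- p$k_act_on * s$ATM_free * s$M_inner
    v3 <- p$k_act * s$M_inner_ATM
    v4f <- p$k_ai_on * s$ATMp_free * s$M_inner
    v4r <- p$k_ai_off * s$M_inner_ATMp
    v5 <- p$k_ph * s$ATMp_free * s$H2AX
    mdc1_free <- s$MDC1_free
    if (diff_limited) {
      avail <- min(p$mdc1_total,
                   p$mdc1_diffusion_coef * sqrt(4 * p$mdc1_diffusion_D *
                                                  max(t, 0)))
      mdc1_free <- max(avail - s$MDC1_rec, 0)
    }
    v6f <- p$k_md_on * mdc1_free * s$gH2AX_free
    # only recruited MDC1 with both docks empty dissociates; under
    # independent occupancies the cargo-free amount is
    # (rec - M_outer)(rec - ATM_outer)/rec
    bare <- if (s$MDC1_rec > 0) {
      max(s$MDC1_rec - s$M_outer, 0) *
        max(s$MDC1_rec - s$ATM_outer, 0) / s$MDC1_rec
    } else 0
    v6r <- p$k_md_off * bare
    v7f <- k_mo_on * s$M_free * max(s$MDC1_rec - s$M_outer, 0)
    v7r <- p$k_mo_off * s$M_outer
    v8 <- p$k_ao_on * s$ATMp_free * max(s$MDC1_rec - s$ATM_outer, 0)
    c(M_free = -v1f + v1r - v7f + v7r,
      S_inner_free = -v1f + v1r,
      M_inner = v1f - v1r - v2 + v3 - v4f + v4r,
      M_inner_ATM = v2 - v3,
      M_inner_ATMp = v4f - v4r,
      ATM_free = -v2,
      ATMp_free = v3 - v4f + v4r - v8,
      H2AX = -v5,
      gH2AX_free = v5 - v6f + v6r,
      MDC1_free = -v6f + v6r,
      MDC1_rec = v6f - v6r,
      M_outer = v7f - v7r,
      ATM_outer = v8)
  }
  attr(deriv, "species") <- ddr_species
  attr(deriv, "variant") <- variant
  deriv
}

ddr_initial_state <- function(params, n_dsb) {
  stats::setNames(
    c(params$mrn_total, params$sites_per_dsb * n_dsb, 0, 0, 0,
      params$atm_total, 0, params$h2ax_total, 0, params$mdc1_total,
      0, 0, 0),
    ddr_species
  )
}

#' Simulate the DSB-response model at a given LET
#'
#' Integrates the mass-action system from the undamaged initial state
#' (all proteins free, all H2AX unphosphorylated, inner sites set by
#' [dsb_count()]) over `t_grid` with an adaptive stiff/non-stiff solver
#' (relative tolerance 1e-8). An adaptive Cash-Karp Runge-Kutta method is
#' available via `method = "rk45ck"`.
#'
#' @param params A [ddr_parameters()].
#' @param let_value LET (keV/µm).
#' @param t_grid Output times (s), starting at 0 (irradiation).
#' @param variant See [build_reaction_system()].
#' @param method deSolve integration method (default `"lsoda"`).
#' @return An object of class `ddr_output`: a list with `times`, signal
#'   series (`nbs1_signal`, `nbs1_inner_signal`, `atm_signal`,
#'   `atm_inner_signal`, `mdc1_signal`, `atmp_total`) and the raw `state`
#'   matrix.
#' @export
simulate_ddr <- function(params, let_value, t_grid = seq(0, 700, by = 2),
                         variant = "standard", method = "lsoda") {
  stopifnot(inherits(params, "ddr_parameters"))
  if (t_grid[1L] != 0) stop_domain("t_grid must start at 0 (irradiation)")
  check_times(t_grid, "t_grid")
  n_dsb <- dsb_count(let_value, params)
  deriv <- build_reaction_system(params, n_dsb, variant)
  y0 <- ddr_initial_state(params, n_dsb)
  rhs <- function(t, y, parms) list(deriv(t, y))
  meth <- if (identical(method, "rk45ck")) deSolve::rkMethod("rk45ck") else
    method
  sol <- deSolve::ode(y = y0, times = t_grid, func = rhs, parms = NULL,
                      method = meth, rtol = 1e-8, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0) {
    stop_domain("integration failed at LET ", let_value)
  }
  st <- sol[, ddr_species, drop = FALSE]
  inner_mrn <- st[, "M_inner"] + st[, "M_inner_ATM"] + st[, "M_inner_ATMp"]
  inner_atm <- st[, "M_inner_ATM"] + st[, "M_inner_ATMp"]
  structure(
    list(times = sol[, "time"],
         nbs1_signal = params$signal_scale_nbs1 *
           (inner_mrn + st[, "M_outer"]),
         nbs1_inner_signal = params$signal_scale_nbs1 * inner_mrn,
         atm_signal = params$signal_scale_atm *
           (inner_atm + st[, "ATM_outer"]),
         atm_inner_signal = params$signal_scale_atm * inner_atm,
         mdc1_signal = params$signal_scale_mdc1 * st[, "MDC1_rec"],
         atmp_total = st[, "ATMp_free"] + st[, "M_inner_ATMp"] +
           st[, "ATM_outer"],
         state = st,
         let_value = let_value, variant = variant, params = params),
    class = "ddr_output"
  )
}

#' Inner-focus fraction of the NBS1 signal
#'
#' Fraction of the total NBS1 (MRN) signal bound directly at DSB ends
#' (inner focus) rather than docked on MDC1 in the surrounding chromatin,
#' interpolated at time `t`. Increases with LET: inner site capacity
#' scales with the DSB number while the outer focus capacity is fixed.
#'
#' @param output A `ddr_output` from [simulate_ddr()].
#' @param t Time (s) within the simulated range.
#' @return Fraction in \[0, 1\], or `NA` (with a warning) if the total
#'   signal vanishes at `t`.
#' @export
readout_inner_fraction <- function(output, t) {
  stopifnot(inherits(output, "ddr_output"))
  if (t < min(output$times) || t > max(output$times)) {
    stop_domain("t outside the simulated range")
  }
  tot <- stats::approx(output$times, output$nbs1_signal, xout = t)$y
  inn <- stats::approx(output$times, output$nbs1_inner_signal, xout = t)$y
  if (!is.finite(tot) || tot <= 0) {
    warning("total NBS1 signal is zero at t = ", t)
    return(NA_real_)
  }
  inn / tot
}
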