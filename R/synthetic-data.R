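# Synthetic-data generation: FRAP raw triplets and multi-LET recruitment
# panels produced from the package's own forward models with controlled
# noise, so that every analysis stage can be exercised end to end without
# external data.

#' Measurement-noise model for synthetic data
#'
#' Multiplicative Gaussian intensity noise (standard deviation
#' `relative_sigma` times the signal) plus an exponential whole-signal
#' decay with rate `acquisition_bleach_rate` emulating photobleaching
#' during image acquisition — the effect double normalization corrects
#' for. Seeded generation is bit-reproducible.
#'
#' @param relative_sigma Relative noise scale, >= 0 (default 0.02,
#'   matching the visual scatter of typical live-cell curves).
#' @param acquisition_bleach_rate Exponential acquisition-bleaching rate
#'   (1/s), >= 0.
#' @param seed Integer RNG seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(relative_sigma = 0.02, acquisition_bleach_rate = 0,
                        seed = 1L) {
  check_scalar(relative_sigma, "relative_sigma", lower = 0)
  check_scalar(acquisition_bleach_rate, "acquisition_bleach_rate", lower = 0)
  structure(list(relative_sigma = relative_sigma,
                 acquisition_bleach_rate = acquisition_bleach_rate,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Generate a raw FRAP measurement triplet from a forward model
#'
#' Produces bleach-region, whole-cell and background intensity series on a
#' common time grid, as acquired: the noise-free normalized forward model
#' (1 during pre-bleach frames), scaled to a detector baseline, multiplied
#' by the acquisition-bleaching decay and the multiplicative noise, on top
#' of a constant background. [double_normalize()] applied to the output
#' recovers the forward-model curve exactly when sigma = 0.
#'
#' @param model_kind `"pure_diffusion"`, `"local_binding"` or
#'   `"global_binding"`.
#' @param D Diffusion coefficient (µm²/s): the effective coefficient for
#'   pure diffusion, the free/unbound coefficient for the binding models.
#' @param rates A [binding_rates()] (ignored for pure diffusion).
#' @param geom A [bleach_geometry()].
#' @param n_prebleach Number of pre-bleach frames (default 5).
#' @param frame_interval Frame spacing (s).
#' @param duration Post-bleach duration (s).
#' @param noise A [noise_model()].
#' @param roi_baseline,whole_baseline,background_level Detector scales.
#' @return A list with `times`, `roi`, `whole_cell`, `background`,
#'   `n_prebleach`, `truth` (the noise-free normalized model values).
#' @export
generate_frap_raw <- function(model_kind = c("pure_diffusion",
                                             "local_binding",
                                             "global_binding"),
                              D, rates = NULL, geom = bleach_geometry(),
                              n_prebleach = 5L, frame_interval = 0.1,
                              duration = 10, noise = noise_model(),
                              roi_baseline = 1000, whole_baseline = 2000,
                              background_level = 50) {
  model_kind <- match.arg(model_kind)
  stopifnot(inherits(noise, "noise_model"))
  if (model_kind != "pure_diffusion" && !inherits(rates, "binding_rates")) {
    stop_domain("rates are required for the binding models")
  }
  t_pre <- -rev(seq_len(n_prebleach)) * frame_interval
  t_post <- seq(frame_interval, duration, by = frame_interval)
  times <- c(t_pre, t_post)
  model <- switch(model_kind,
    pure_diffusion = soumpasis_frap(t_post, D, geom),
    local_binding = local_binding_frap(t_post, D, rates, geom),
    global_binding = global_binding_frap(t_post, D, rates, geom))
  truth <- c(rep(1, n_prebleach), model)
  set.seed(noise$seed)
  decay <- exp(-noise$acquisition_bleach_rate * (times - times[1L]))
  eps_roi <- stats::rnorm(length(times), 0, noise$relative_sigma)
  eps_whole <- stats::rnorm(length(times), 0, noise$relative_sigma)
  list(times = times,
       roi = background_level + roi_baseline * truth * decay * (1 + eps_roi),
       whole_cell = background_level +
         whole_baseline * decay * (1 + eps_whole),
       background = rep(background_level, length(times)),
       n_prebleach = as.integer(n_prebleach),
       truth = truth)
}

#' Generate a multi-LET recruitment panel from the ODE model
#'
#' Simulates the DSB-response model per (LET, protein) combination,
#' normalizes each curve to plateau 1 (value at the end of the simulated
#' window), adds Gaussian noise on the normalized scale and prepends
#' zero-mean pre-irradiation frames — the structure of beamline
#' recruitment data.
#'
#' @param params A [ddr_parameters()].
#' @param let_values LET values (keV/µm).
#' @param proteins Protein labels, subset of NBS1/ATM/MDC1; the panel is
#'   the full LET x protein cross.
#' @param t_max Post-irradiation duration (s), default 700.
#' @param dt Frame spacing (s).
#' @param n_pre Pre-irradiation frames.
#' @param noise A [noise_model()]; `relative_sigma` acts additively on
#'   the normalized (plateau = 1) scale.
#' @param variant Model variant.
#' @return A [dataset_panel()]; empty `let_values` gives an empty list of
#'   curves (not a panel).
#' @export
generate_recruitment_panel <- function(params = ddr_parameters(),
                                       let_values, proteins = "NBS1",
                                       t_max = 700, dt = 10, n_pre = 5L,
                                       noise = noise_model(),
                                       variant = "standard") {
  stopifnot(inherits(params, "ddr_parameters"),
            inherits(noise, "noise_model"))
  if (length(let_values) == 0L) return(list())
  set.seed(noise$seed)
  t_post <- seq(dt, t_max, by = dt)
  t_pre <- -rev(seq_len(n_pre)) * dt
  curves <- list()
  for (L in let_values) {
    out <- simulate_ddr(params, L, c(0, t_post), variant = variant)
    for (pr in proteins) {
      sig <- signal_for_protein(out, pr)[-1L]
      plateau <- sig[length(sig)]
      if (plateau <= 0) stop_domain("no recruitment signal for ", pr,
                                    " at LET ", L)
      y <- c(rep(0, n_pre), sig / plateau) +
        stats::rnorm(n_pre + length(sig), 0, noise$relative_sigma)
      curves[[length(curves) + 1L]] <-
        recruitment_curve(c(t_pre, t_post), y, let_value = L, protein = pr)
    }
  }
  dataset_panel(curves)
}
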