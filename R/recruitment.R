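# Normalization of recruitment curves measured during/after irradiation
# and extraction of the mono-exponential time constant (time to ~63% of
# the plateau), summarized as a function of LET.

#' Recruitment curve container
#'
#' @param times Times since irradiation (s); negative values are
#'   pre-irradiation frames. Strictly increasing.
#' @param intensities Normalized mean focus intensities (0 before
#'   irradiation, 1 at the plateau).
#' @param let_value Linear energy transfer of the ion species (keV/µm).
#' @param ion Ion species label.
#' @param protein Protein label (e.g. "NBS1", "ATM", "MDC1").
#' @param flags Character vector of data-quality flags.
#' @return An object of class `recruitment_curve`.
#' @export
recruitment_curve <- function(times, intensities, let_value = NA_real_,
                              ion = "", protein = "", flags = character()) {
  check_times(times, "times")
  if (length(intensities) != length(times)) {
    stop_domain("times and intensities must have equal length")
  }
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         let_value = let_value, ion = ion, protein = protein, flags = flags),
    class = "recruitment_curve"
  )
}

mono_exp <- function(t, plateau, tau, lag = 0) {
  ifelse(t >= lag, plateau * (1 - exp(-(t - lag) / tau)), 0)
}

#' Normalize a raw recruitment curve to 0 (baseline) and 1 (plateau)
#'
#' The pre-irradiation mean is subtracted and the curve is divided by the
#' plateau of a jointly fitted mono-exponential (fitting the plateau is
#' more robust to noise at the end of the curve than a last-frames mean).
#' A curve whose fitted plateau does not exceed three standard deviations
#' of the pre-irradiation baseline is flagged `"no_recruitment"` and
#' returned baseline-subtracted but unscaled.
#'
#' @param times Times (s); irradiation at `irradiation_time`.
#' @param intensities Raw mean focus intensities.
#' @param irradiation_time Time of irradiation on the input time axis
#'   (default 0). Output times are relative to it.
#' @param let_value,ion,protein Metadata carried into the result.
#' @return A [recruitment_curve()]; check `flags` for `"no_recruitment"`.
#' @export
normalize_recruitment <- function(times, intensities, irradiation_time = 0,
                                  let_value = NA_real_, ion = "",
                                  protein = "") {
  check_times(times, "times")
  t <- times - irradiation_time
  pre <- t < 0
  if (sum(pre) < 3L) {
    stop_domain("need at least 3 pre-irradiation frames")
  }
  if (sum(!pre) < 10L) {
    stop_domain("need at least 10 post-irradiation frames")
  }
  y <- intensities - mean(intensities[pre])
  sd_pre <- stats::sd(intensities[pre])
  fit <- try_mono_fit(t[!pre], y[!pre], fit_lag = FALSE)
  if (is.null(fit) || !is.finite(fit$plateau) ||
      fit$plateau <= max(3 * sd_pre, .Machine$double.eps)) {
    return(recruitment_curve(t, y, let_value, ion, protein,
                             flags = "no_recruitment"))
  }
  recruitment_curve(t, y / fit$plateau, let_value, ion, protein)
}

# Internal mono-exponential least squares with safe fallbacks.
try_mono_fit <- function(t, y, fit_lag = FALSE) {
  p0 <- max(stats::median(y[t >= stats::quantile(t, 0.7)]),
            max(y) * 0.5, .Machine$double.eps)
  # crude tau start: first crossing of 63% of the plateau guess
  above <- which(y >= 0.632 * p0)
  tau0 <- if (length(above) > 0L) max(t[above[1L]], diff(range(t)) / 50) else
    diff(range(t)) / 3
  out <- tryCatch({
    if (fit_lag) {
      fit <- minpack.lm::nlsLM(
        y ~ ifelse(t >= lag, plateau * (1 - exp(-(t - lag) / tau)), 0),
        start = list(plateau = p0, tau = tau0, lag = 0),
        lower = c(0, 1e-6, 0),
        upper = c(Inf, Inf, max(t)),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    } else {
      fit <- minpack.lm::nlsLM(
        y ~ plateau * (1 - exp(-t / tau)),
        start = list(plateau = p0, tau = tau0),
        lower = c(0, 1e-6),
        control = minpack.lm::nls.lm.control(maxiter = 500)
      )
    }
    cf <- stats::coef(fit)
    se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                   error = function(e) rep(NA_real_, length(cf)))
    list(plateau = unname(cf["plateau"]), tau = unname(cf["tau"]),
         lag = if (fit_lag) unname(cf["lag"]) else 0,
         tau_se = unname(se["tau"]),
         sse = sum(stats::resid(fit)^2))
  }, error = function(e) NULL)
  out
}

#' Fit a mono-exponential recruitment model
#'
#' Fits \eqn{I(t) = P\,(1 - e^{-(t - lag)/\tau})} (0 before the onset) to
#' the post-irradiation part of a normalized recruitment curve by least
#' squares. The time constant \eqn{\tau} is the time after onset at which
#' the curve reaches \eqn{1 - 1/e \approx 63\%} of the plateau P. The
#' onset lag is fixed to 0 by default (appropriate for NBS1, ATM and
#' MDC1); free it for proteins arriving after upstream processing steps,
#' which show a pronounced lag phase.
#'
#' @param curve A normalized [recruitment_curve()].
#' @param fit_lag Also fit an onset delay (default FALSE).
#' @return An object of class `tau_fit` with fields `tau`, `tau_se`,
#'   `plateau`, `lag`, `sse`, `converged`.
#' @export
fit_mono_exponential <- function(curve, fit_lag = FALSE) {
  stopifnot(inherits(curve, "recruitment_curve"))
  post <- curve$times >= 0
  fit <- try_mono_fit(curve$times[post], curve$intensities[post],
                      fit_lag = fit_lag)
  if (is.null(fit)) {
    return(structure(list(tau = NA_real_, tau_se = NA_real_,
                          plateau = NA_real_, lag = NA_real_, sse = NA_real_,
                          converged = FALSE),
                     class = "tau_fit"))
  }
  structure(c(fit, list(converged = TRUE)), class = "tau_fit")
}

#' @export
print.tau_fit <- function(x, ...) {
  cat("Mono-exponential recruitment fit\n")
  cat("  tau: ", format(signif(x$tau, 3)), " s",
      if (is.finite(x$tau_se)) paste0(" (se ", format(signif2(x$tau_se)), ")"),
      "\n", sep = "")
  cat("  plateau: ", format(signif(x$plateau, 3)),
      "   lag: ", format(signif(x$lag, 3)), " s\n", sep = "")
  invisible(x)
}

#' Summarize recruitment time constants as a function of LET
#'
#' @param fits List of `tau_fit` objects from [fit_mono_exponential()].
#' @param let_values LET of each fit (keV/µm).
#' @param proteins Protein label of each fit.
#' @param ions Optional ion labels.
#' @return A data frame sorted by LET (ties keep input order) with columns
#'   `protein`, `ion`, `let_kev_um`, `tau_s`, `tau_se_s`, `plateau`, `sse`.
#' @export
tau_vs_let <- function(fits, let_values, proteins, ions = NULL) {
  n <- length(fits)
  if (n == 0L) stop_domain("need at least one fit")
  if (length(let_values) != n || length(proteins) != n) {
    stop_domain("let_values and proteins must match the number of fits")
  }
  if (is.null(ions)) ions <- rep("", n)
  tab <- data.frame(
    protein = as.character(proteins),
    ion = as.character(ions),
    let_kev_um = as.numeric(let_values),
    tau_s = vapply(fits, function(f) f$tau, numeric(1)),
    tau_se_s = vapply(fits, function(f) f$tau_se, numeric(1)),
    plateau = vapply(fits, function(f) f$plateau, numeric(1)),
    sse = vapply(fits, function(f) f$sse, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab[order(tab$let_kev_um), , drop = FALSE]
}
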