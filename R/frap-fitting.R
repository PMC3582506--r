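# Normalization of raw FRAP measurements and estimation of diffusion
# coefficients and binding constants by fitting the forward models,
# including the decade start-value grid search for (kon_star, koff).

#' FRAP curve container
#'
#' @param times Times relative to the bleach (s); negative values are
#'   pre-bleach frames. Strictly increasing.
#' @param intensities Normalized fluorescence values.
#' @param n_prebleach Number of pre-bleach frames.
#' @param label Free-text condition label.
#' @return An object of class `frap_curve`.
#' @export
frap_curve <- function(times, intensities, n_prebleach = 0L, label = "") {
  check_times(times, "times")
  if (length(intensities) != length(times)) {
    stop_domain("times and intensities must have equal length")
  }
  structure(
    list(times = as.numeric(times), intensities = as.numeric(intensities),
         n_prebleach = as.integer(n_prebleach), label = label),
    class = "frap_curve"
  )
}

#' Double normalization of raw FRAP measurements
#'
#' Normalizes a bleach-region intensity trace to its pre-bleach mean and
#' corrects for fluorescence loss during image acquisition using the
#' whole-cell signal:
#' \deqn{F(t) = \frac{roi(t) - bg(t)}{\langle roi - bg\rangle_{pre}}\cdot
#'   \frac{\langle whole - bg\rangle_{pre}}{whole(t) - bg(t)}.}
#' After normalization the pre-bleach mean is exactly 1 and any common
#' multiplicative acquisition-bleaching factor cancels.
#'
#' @param times Shared time grid (s), bleach at t = 0.
#' @param roi_raw Raw bleach-region intensities.
#' @param whole_cell_raw Raw whole-cell intensities.
#' @param background Optional background trace (scalar or series);
#'   default 0.
#' @param n_prebleach Number of leading pre-bleach frames (>= 1).
#' @param label Condition label carried through.
#' @return A normalized [frap_curve()].
#' @export
double_normalize <- function(times, roi_raw, whole_cell_raw,
                             background = 0, n_prebleach, label = "") {
  check_times(times, "times")
  n <- length(times)
  if (length(roi_raw) != n || length(whole_cell_raw) != n) {
    stop_domain("roi_raw and whole_cell_raw must match the time grid")
  }
  if (length(background) == 1L) background <- rep(background, n)
  if (length(background) != n) {
    stop_domain("background must be a scalar or match the time grid")
  }
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1L || n_prebleach >= n) {
    stop_domain("n_prebleach must be >= 1 and leave post-bleach frames")
  }
  roi <- roi_raw - background
  whole <- whole_cell_raw - background
  bad <- which(whole <= 0)
  if (length(bad) > 0L) {
    stop_domain("whole-cell signal <= background at frame ", bad[1L])
  }
  pre <- seq_len(n_prebleach)
  roi_pre <- mean(roi[pre])
  whole_pre <- mean(whole[pre])
  if (roi_pre <= 0) {
    stop_domain("pre-bleach bleach-region mean <= background")
  }
  frap_curve(times, (roi / roi_pre) * (whole_pre / whole),
             n_prebleach = n_prebleach, label = label)
}

#' @rdname fit_effective_diffusion
#' @export
print.frap_fit <- function(x, ...) {
  cat("FRAP fit (", x$model_kind, ")\n", sep = "")
  if (!is.null(x$D_eff)) {
    cat("  D_eff: ", format(signif2(x$D_eff)), " um^2/s\n", sep = "")
  }
  if (!is.null(x$rates)) {
    cat("  kon_star: ", format(signif2(x$rates$kon_star)), " 1/s",
        "   koff: ", format(signif2(x$rates$koff)), " 1/s\n", sep = "")
  }
  cat("  SSE: ", format(x$sse), "\n", sep = "")
  invisible(x)
}

post_bleach <- function(curve) {
  keep <- curve$times >= 0 & curve$times > .Machine$double.eps
  list(t = curve$times[keep], y = curve$intensities[keep])
}

#' Fit the pure-diffusion FRAP model
#'
#' Least-squares estimation of the effective diffusion coefficient from a
#' normalized FRAP curve by fitting [soumpasis_frap()] over D (and
#' optionally the bleach depth). Pre-bleach frames are excluded; the first
#' post-bleach frame defines t = 0+.
#'
#' @param curve A normalized [frap_curve()].
#' @param geom A [bleach_geometry()].
#' @param fit_bleach_depth Also fit the bleach depth (default FALSE; the
#'   depth is then taken from `geom`).
#' @param D_range Log10 search bounds for D (µm²/s).
#' @return An object of class `frap_fit` with fields `model_kind`,
#'   `D_eff`, `sse`, `converged`.
#' @export
fit_effective_diffusion <- function(curve, geom = bleach_geometry(),
                                    fit_bleach_depth = FALSE,
                                    D_range = c(1e-4, 1e3)) {
  stopifnot(inherits(curve, "frap_curve"), inherits(geom, "bleach_geometry"))
  pb <- post_bleach(curve)
  if (length(pb$t) < 10L) {
    stop_domain("need at least 10 post-bleach frames")
  }
  sse_d <- function(log10d, theta = geom$bleach_depth) {
    g <- bleach_geometry(geom$spot_radius_um, geom$nucleus_radius_um, theta)
    sum((soumpasis_frap(pb$t, 10^log10d, g) - pb$y)^2)
  }
  if (!fit_bleach_depth) {
    opt <- stats::optimize(sse_d, interval = log10(D_range), tol = 1e-10)
    res <- list(model_kind = "pure_diffusion", D_eff = 10^opt$minimum,
                rates = NULL, sse = opt$objective, converged = TRUE)
  } else {
    obj <- function(par) sse_d(par[1L], stats::plogis(par[2L]))
    opt <- stats::optim(c(mean(log10(D_range)), stats::qlogis(0.05)), obj,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    res <- list(model_kind = "pure_diffusion", D_eff = 10^opt$par[1L],
                rates = NULL, sse = opt$value,
                bleach_depth = stats::plogis(opt$par[2L]),
                converged = opt$convergence == 0L)
  }
  structure(res, class = "frap_fit")
}

#' Fit binding constants with a decade start-value grid
#'
#' Estimates the effective association and dissociation rates of a
#' diffusion-reaction FRAP model by least squares. To cope with the
#' multi-modal objective, the start values of kon_star and koff are
#' permuted in decade steps over `start_decades` (default 1e-6 to 1e6,
#' i.e. a 13 x 13 grid) and a derivative-free local optimization is run
#' from each pair; the best converged optimum is returned and then
#' polished. The free diffusion coefficient is fixed (taken from
#' untreated-cell analysis), not fitted.
#'
#' @param curve A normalized [frap_curve()].
#' @param model_kind `"local_binding"` or `"global_binding"`.
#' @param D_free Fixed diffusion coefficient of the unbound fraction
#'   (µm²/s).
#' @param geom A [bleach_geometry()].
#' @param start_decades Log10 start values permuted for both rates.
#' @param maxit_grid Local-optimizer iteration cap per start.
#' @param maxit_polish Iteration cap for polishing the best start.
#' @param bounds Box constraints on both rates (1/s).
#' @return A `frap_fit` with `rates`, `sse`, `start_values_tried`,
#'   `best_start`.
#' @export
fit_binding_constants <- function(curve,
                                  model_kind = c("local_binding",
                                                 "global_binding"),
                                  D_free, geom = bleach_geometry(),
                                  start_decades = -6:6,
                                  maxit_grid = 150L,
                                  maxit_polish = 500L,
                                  bounds = c(1e-8, 1e8)) {
  stopifnot(inherits(curve, "frap_curve"), inherits(geom, "bleach_geometry"))
  model_kind <- match.arg(model_kind)
  check_scalar(D_free, "D_free", lower = 0, strict_lower = TRUE)
  pb <- post_bleach(curve)
  lb <- log10(bounds[1L])
  ub <- log10(bounds[2L])
  forward <- if (model_kind == "local_binding") {
    function(r) local_binding_frap(pb$t, D_free, r, geom)
  } else {
    function(r) global_binding_frap(pb$t, D_free, r, geom)
  }
  obj <- function(par) {
    if (any(par < lb) || any(par > ub)) return(1e10)
    r <- binding_rates(10^par[1L], 10^par[2L])
    f <- tryCatch(forward(r), error = function(e) NULL)
    if (is.null(f)) return(1e10)
    sum((f - pb$y)^2)
  }
  starts <- as.matrix(expand.grid(kon = start_decades, koff = start_decades))
  best <- NULL
  n_tried <- 0L
  for (i in seq_len(nrow(starts))) {
    n_tried <- n_tried + 1L
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = maxit_grid, reltol = 1e-10))
    if (is.null(best) || o$value < best$value) {
      best <- o
      best$start <- starts[i, ]
    }
  }
  if (is.null(best) || best$value >= 1e10) {
    stop_domain("all start values failed for ", model_kind)
  }
  polish <- stats::optim(best$par, obj, method = "Nelder-Mead",
                         control = list(maxit = maxit_polish,
                                        reltol = 1e-14))
  structure(
    list(model_kind = model_kind,
         D_eff = NULL,
         rates = binding_rates(10^polish$par[1L], 10^polish$par[2L]),
         sse = polish$value,
         start_values_tried = n_tried,
         best_start = 10^best$start,
         converged = polish$convergence == 0L),
    class = "frap_fit"
  )
}

#' Mass-scaled diffusion coefficient for a spherical protein
#'
#' Under equal protein density and spherical shape the diffusion
#' coefficient scales with the cube root of the mass ratio:
#' \deqn{D_{calc} = D_{ref}\,(m_{ref}/m)^{1/3}.}
#' With GFP (27 kDa, 12 µm²/s) as reference this gives 7.0 µm²/s for a
#' 137 kDa and 5.7 µm²/s for a 257 kDa fusion protein.
#'
#' @param D_ref Reference diffusion coefficient (µm²/s).
#' @param mass_ref Reference mass (kDa).
#' @param mass Target mass (kDa).
#' @return The scaled diffusion coefficient (µm²/s).
#' @export
scaled_diffusion_estimate <- function(D_ref, mass_ref, mass) {
  check_scalar(D_ref, "D_ref", lower = 0, strict_lower = TRUE)
  check_scalar(mass_ref, "mass_ref", lower = 0, strict_lower = TRUE)
  check_scalar(mass, "mass", lower = 0, strict_lower = TRUE)
  D_ref * (mass_ref / mass)^(1 / 3)
}

#' Mean time to diffuse a given distance in two dimensions
#'
#' From the 2-D mean-squared-displacement relation \eqn{\langle r^2\rangle
#' = 4Dt}, the average time to cover a distance r is \eqn{t = r^2/(4D)}.
#' At D = 12 µm²/s a 6.3 µm path (the mean distance to the center of a
#' 9.4 µm cylindrical nucleus) takes 0.83 s.
#'
#' @param distance Distance (µm).
#' @param D Diffusion coefficient (µm²/s).
#' @return Time (s).
#' @export
traversal_time <- function(distance, D) {
  check_scalar(distance, "distance", lower = 0, strict_lower = TRUE)
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  distance^2 / (4 * D)
}
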