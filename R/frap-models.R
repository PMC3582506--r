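# Forward models of fluorescence recovery after photobleaching (FRAP):
# closed-form pure diffusion for a uniform circular bleach spot, and
# Laplace-domain diffusion-reaction models with either nucleus-wide
# ("global") or focus-confined ("local") binding, inverted numerically
# with the Stehfest algorithm.

#' Bleach-spot and nucleus geometry for FRAP models
#'
#' Describes the boundary-value problem solved by the FRAP forward models:
#' a uniform circular bleach region of radius `spot_radius_um` inside a
#' cylindrical nucleus of radius `nucleus_radius_um`. When the laser spot is
#' characterized by its full width at half maximum instead, pass `fwhm_um`
#' and the spot radius is taken as half the FWHM (uniform-disc
#' idealization of the measured spot profile).
#'
#' @param spot_radius_um Radius w of the bleached disc (µm). Ignored when
#'   `fwhm_um` is given.
#' @param nucleus_radius_um Radius of the (cylindrical) nucleus (µm);
#'   default 9.4 µm.
#' @param bleach_depth Fraction of the pre-bleach intensity remaining
#'   inside the spot immediately after the bleach; 0 means complete
#'   bleaching.
#' @param fwhm_um Optional measured full width at half maximum of the
#'   bleach spot (µm); sets `spot_radius_um = fwhm_um / 2`.
#' @return An object of class `bleach_geometry`.
#' @examples
#' bleach_geometry(fwhm_um = 3.0)  # 1.5 um spot in a 9.4 um nucleus
#' @export
bleach_geometry <- function(spot_radius_um = 1.5, nucleus_radius_um = 9.4,
                            bleach_depth = 0, fwhm_um = NULL) {
  if (!is.null(fwhm_um)) {
    check_scalar(fwhm_um, "fwhm_um", lower = 0, strict_lower = TRUE)
    spot_radius_um <- fwhm_um / 2
  }
  check_scalar(spot_radius_um, "spot_radius_um", lower = 0, strict_lower = TRUE)
  check_scalar(nucleus_radius_um, "nucleus_radius_um",
               lower = spot_radius_um, strict_lower = TRUE)
  check_scalar(bleach_depth, "bleach_depth", lower = 0, upper = 1,
               strict_upper = TRUE)
  structure(
    list(spot_radius_um = spot_radius_um,
         nucleus_radius_um = nucleus_radius_um,
         bleach_depth = bleach_depth,
         fwhm_um = if (is.null(fwhm_um)) 2 * spot_radius_um else fwhm_um),
    class = "bleach_geometry"
  )
}

#' Effective binding rates of a single reversible binding reaction
#'
#' `kon_star` is the effective association rate, i.e. the product of the
#' intrinsic on-rate and the equilibrium free-binding-site density (the two
#' factors are not separately identifiable from FRAP). `koff` is the
#' dissociation rate. The equilibrium free and bound fractions follow as
#' `F_eq = koff / (kon_star + koff)` and `C_eq = kon_star / (kon_star + koff)`.
#'
#' @param kon_star Effective association rate (1/s), >= 0.
#' @param koff Dissociation rate (1/s), > 0.
#' @return An object of class `binding_rates` with fields `kon_star`,
#'   `koff`, `F_eq`, `C_eq`.
#' @examples
#' binding_rates(kon_star = 587e-3, koff = 425e-5)
#' @export
binding_rates <- function(kon_star, koff) {
  kon_star <- unname(kon_star)
  koff <- unname(koff)
  check_scalar(kon_star, "kon_star", lower = 0)
  check_scalar(koff, "koff", lower = 0, strict_lower = TRUE)
  structure(
    list(kon_star = kon_star, koff = koff,
         F_eq = koff / (kon_star + koff),
         C_eq = kon_star / (kon_star + koff)),
    class = "binding_rates"
  )
}

#' Pure-diffusion FRAP recovery for a uniform circular bleach spot
#'
#' Closed-form recovery curve for free diffusion into a uniformly bleached
#' disc of radius w in an effectively unbounded plane:
#' \deqn{F(t) = e^{-2\tau_D/t}\,[I_0(2\tau_D/t) + I_1(2\tau_D/t)],\qquad
#'       \tau_D = w^2/(4D),}
#' with \eqn{I_0, I_1} modified Bessel functions of the first kind. For an
#' incomplete bleach (depth \eqn{\theta > 0}) the curve is rescaled
#' affinely to run from \eqn{\theta} to 1.
#'
#' @param t Times since the bleach (s), >= 0; vectorized.
#' @param D Diffusion coefficient (µm²/s).
#' @param geom A [bleach_geometry()].
#' @return Normalized intensities in \[bleach_depth, 1\].
#' @examples
#' g <- bleach_geometry(spot_radius_um = 1.5)
#' soumpasis_frap(c(0.01, 0.1, 1, 10), D = 12, geom = g)
#' @export
soumpasis_frap <- function(t, D, geom = bleach_geometry()) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_domain("t must be finite and non-negative")
  }
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(geom, "bleach_geometry"))
  tau_d <- geom$spot_radius_um^2 / (4 * D)
  f <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tau_d / t[pos]
  # exponentially scaled Bessel functions keep exp(-x) * I(x) finite
  f[pos] <- besselI(x, 0, expon.scaled = TRUE) +
    besselI(x, 1, expon.scaled = TRUE)
  theta <- geom$bleach_depth
  theta + (1 - theta) * f
}

# Stehfest weights V_j for an even number of terms.
stehfest_weights <- function(n_terms) {
  if (n_terms %% 2L != 0L || n_terms < 6L || n_terms > 18L) {
    stop_domain("n_terms must be an even integer between 6 and 18")
  }
  n2 <- n_terms %/% 2L
  v <- numeric(n_terms)
  for (j in seq_len(n_terms)) {
    k_lo <- floor((j + 1) / 2)
    k_hi <- min(j, n2)
    s <- 0
    for (k in k_lo:k_hi) {
      s <- s + k^n2 * factorial(2 * k) /
        (factorial(n2 - k) * factorial(k) * factorial(k - 1) *
           factorial(j - k) * factorial(2 * k - j))
    }
    v[j] <- (-1)^(n2 + j) * s
  }
  v
}

#' Stehfest numerical inversion of a Laplace transform
#'
#' Approximates \eqn{f(t)} from its Laplace transform \eqn{\bar f(p)}
#' on the real axis:
#' \deqn{f(t) \approx \frac{\ln 2}{t}\sum_{j=1}^{N} V_j\,
#'       \bar f\!\left(\frac{j \ln 2}{t}\right)}
#' with the standard Stehfest weights \eqn{V_j}. The method is exact for
#' polynomially smooth originals and degrades for originals with
#' singularities or oscillations; N = 12 is a good accuracy/round-off
#' compromise in double precision.
#'
#' @param fbar A vectorized function of the (real, positive) Laplace
#'   variable p.
#' @param t Times (s), strictly positive; vectorized.
#' @param n_terms Even number of terms N, between 6 and 18.
#' @return Approximate inverse transform values at `t`.
#' @examples
#' stehfest_invert(function(p) 1 / (p + 1), t = 1)  # ~ exp(-1)
#' @export
stehfest_invert <- function(fbar, t, n_terms = 12L) {
  check_times(t, positive = TRUE)
  v <- stehfest_weights(n_terms)
  ln2 <- log(2)
  # all p values for all t at once; fbar must be vectorized
  p <- as.vector(outer(seq_len(n_terms) * ln2, 1 / t))
  fv <- fbar(p)
  if (length(fv) != length(p) || any(!is.finite(fv))) {
    stop_domain("fbar must return finite values for every required p > 0")
  }
  fm <- matrix(fv, nrow = n_terms)
  (ln2 / t) * as.vector(crossprod(fm, v))
}

# K1(x) * I1(x), overflow-safe (the e^x and e^-x scalings cancel).
bessel_k1i1 <- function(x) {
  out <- numeric(length(x))
  big <- x > 1e5
  out[big] <- 1 / (2 * x[big])
  xs <- x[!big]
  out[!big] <- besselK(xs, 1, expon.scaled = TRUE) *
    besselI(xs, 1, expon.scaled = TRUE)
  out
}

#' Diffusion-reaction FRAP with nucleus-wide ("global") binding
#'
#' Laplace-domain solution for recovery of a circular bleach spot when
#' binding sites are homogeneously distributed throughout the nucleus and
#' bound complexes are immobile:
#' \deqn{\bar F(p) = \frac{1}{p}
#'   - \frac{F_{eq}}{p}\left[1 - 2 K_1(qw) I_1(qw)\right]
#'     \left[1 + \frac{k^*_{on}}{p + k_{off}}\right]
#'   - \frac{C_{eq}}{p + k_{off}},\qquad
#'   q^2 = \frac{p}{D}\left(1 + \frac{k^*_{on}}{p + k_{off}}\right),}
#' inverted with [stehfest_invert()]. With \eqn{k^*_{on} = 0} this reduces
#' to the pure-diffusion recovery of [soumpasis_frap()]; when both rates
#' are fast compared to diffusion it approaches pure diffusion with
#' \eqn{D_{eff} = D/(1 + k^*_{on}/k_{off})}.
#'
#' @param t_grid Times since the bleach (s), strictly increasing, > 0.
#' @param D Free diffusion coefficient (µm²/s).
#' @param rates A [binding_rates()].
#' @param geom A [bleach_geometry()].
#' @param n_terms Stehfest terms, see [stehfest_invert()].
#' @return Normalized intensities on `t_grid`.
#' @export
global_binding_frap <- function(t_grid, D, rates, geom = bleach_geometry(),
                                n_terms = 12L) {
  check_times(t_grid, "t_grid", positive = TRUE)
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(rates, "binding_rates"), inherits(geom, "bleach_geometry"))
  w <- geom$spot_radius_um
  kon <- rates$kon_star
  koff <- rates$koff
  feq <- rates$F_eq
  ceq <- rates$C_eq
  fbar <- function(p) {
    bind <- 1 + kon / (p + koff)
    q <- sqrt(p / D * bind)
    k1i1 <- bessel_k1i1(q * w)
    1 / p - (feq / p) * (1 - 2 * k1i1) * bind - ceq / (p + koff)
  }
  f <- stehfest_invert(fbar, t_grid, n_terms)
  if (any(!is.finite(f))) {
    stop_domain("global binding model evaluation produced non-finite values")
  }
  theta <- geom$bleach_depth
  theta + (1 - theta) * f
}

#' Diffusion-reaction FRAP with focus-confined ("local") binding
#'
#' Radially symmetric two-region model of recovery at a bleached
#' radiation-induced focus. Inside the focus (r < w, coinciding with the
#' bleach region) the free species diffuses with `D_free` and binds
#' reversibly (`kon_star`, `koff`) to immobile sites; outside it diffuses
#' freely. The model is solved in the Laplace domain with continuity of
#' concentration and radial flux at r = w and, by default, an open outer
#' region in which the free concentration approaches its equilibrium value
#' far from the focus (the nucleus-wide pool acts as a reservoir, so the
#' recovery always returns to 1, as observed experimentally). A reflecting
#' (zero-flux) outer boundary at the nucleus radius is available via
#' `outer_boundary = "reflecting"`; with strong binding the closed domain
#' then recovers to less than 1 because a finite pool cannot replace the
#' bleached bound molecules.
#'
#' The initial condition is the focus at `bleach_depth` times its bound +
#' free steady state, the outside at steady state; the reported value is
#' the mean of free + bound over the focus disc, normalized to pre-bleach.
#' `D_free` is the effective diffusion coefficient of the unbound fraction,
#' normally fixed from untreated-cell FRAP.
#'
#' @inheritParams global_binding_frap
#' @param D_free Diffusion coefficient of the unbound fraction (µm²/s).
#' @param outer_boundary `"open"` (default) or `"reflecting"`.
#' @return Normalized intensities on `t_grid`.
#' @export
local_binding_frap <- function(t_grid, D_free, rates,
                               geom = bleach_geometry(),
                               n_terms = 12L,
                               outer_boundary = c("open", "reflecting")) {
  check_times(t_grid, "t_grid", positive = TRUE)
  check_scalar(D_free, "D_free", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(rates, "binding_rates"), inherits(geom, "bleach_geometry"))
  outer_boundary <- match.arg(outer_boundary)
  w <- geom$spot_radius_um
  rn <- geom$nucleus_radius_um
  kon <- rates$kon_star
  koff <- rates$koff
  feq <- rates$F_eq
  ceq <- rates$C_eq
  theta <- geom$bleach_depth
  fbar <- function(p) {
    bind <- 1 + kon / (p + koff)
    q1 <- sqrt(p / D_free * bind)   # interior decay constant
    q2 <- sqrt(p / D_free)          # exterior decay constant
    a <- q1 * w
    b <- q2 * w
    # scaled-Bessel ratios are overflow-safe at any argument
    i1i0_a <- besselI(a, 1, expon.scaled = TRUE) /
      besselI(a, 0, expon.scaled = TRUE)
    k0k1_b <- besselK(b, 0, expon.scaled = TRUE) /
      besselK(b, 1, expon.scaled = TRUE)
    if (outer_boundary == "reflecting") {
      # region 2 basis K0(q2 r) + kappa I0(q2 r), zero flux at r = rn;
      # kappa = K1(q2 rn) / I1(q2 rn) ~ e^{-2 q2 rn}
      eps <- exp(-2 * q2 * (rn - w))
      sK1R <- besselK(q2 * rn, 1, expon.scaled = TRUE)
      sI1R <- besselI(q2 * rn, 1, expon.scaled = TRUE)
      sI0b <- besselI(b, 0, expon.scaled = TRUE)
      sI1b <- besselI(b, 1, expon.scaled = TRUE)
      sK0b <- besselK(b, 0, expon.scaled = TRUE)
      sK1b <- besselK(b, 1, expon.scaled = TRUE)
      c0 <- (sK1R * sI0b) / (sI1R * sK0b)
      c1 <- (sK1R * sI1b) / (sI1R * sK1b)
      k0k1_b <- k0k1_b * (1 + eps * c0) / (1 - eps * c1)
    }
    denom <- 1 + (q1 / q2) * i1i0_a * k0k1_b
    favg <- theta * feq / p +
      (1 - theta) * (feq / p) * (2 * i1i0_a / a) / denom
    cavg <- (kon * favg + theta * ceq) / (p + koff)
    favg + cavg
  }
  f <- stehfest_invert(fbar, t_grid, n_terms)
  if (any(!is.finite(f)) || any(f < -1e-6)) {
    stop_domain("local binding model evaluation produced invalid intensities")
  }
  f
}

#' Effective diffusion coefficient under rapid transient binding
#'
#' When binding and release are fast compared to diffusion across the
#' bleach spot, a diffusing-and-binding protein behaves as if freely
#' diffusing with
#' \deqn{D_{eff} = \frac{D}{1 + k^*_{on}/k_{off}}.}
#'
#' @param D Free diffusion coefficient (µm²/s).
#' @param rates A [binding_rates()].
#' @return The effective diffusion coefficient (µm²/s), <= D.
#' @examples
#' effective_diffusion_coefficient(12, binding_rates(9, 1))  # 1.2
#' @export
effective_diffusion_coefficient <- function(D, rates) {
  check_scalar(D, "D", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(rates, "binding_rates"))
  D / (1 + rates$kon_star / rates$koff)
}
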