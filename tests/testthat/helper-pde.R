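# Independent finite-difference oracle for the focus-local
# diffusion-reaction FRAP problem: explicit time stepping of the radial
# PDE on [0, r_max] with reflecting ends. Free species f diffuses
# everywhere; inside the focus (r < w) it exchanges with immobile bound
# species c at rates kon (on) and koff (off). Initial condition: focus
# bleached to depth theta times its equilibrium, outside at equilibrium.
# The reported signal is the area-weighted mean of f + c over the focus.
# With r_max well beyond the diffusion length the reflecting far boundary
# emulates an open reservoir.
fd_local_frap <- function(t_out, D, kon, koff, w, theta = 0,
                          r_max = 15, dr = 0.05, dt = NULL) {
  if (is.null(dt)) dt <- 0.2 * dr^2 / D
  r <- seq(0, r_max, by = dr)
  n <- length(r)
  inside <- r < w
  feq <- koff / (kon + koff)
  ceq <- kon / (kon + koff)
  f <- rep(feq, n)
  f[inside] <- theta * feq
  c_b <- ifelse(inside, theta * ceq, 0)
  # face radii for the conservative cylindrical Laplacian
  r_plus <- r + dr / 2
  r_minus <- pmax(r - dr / 2, 0)
  denom <- ifelse(r > 0, r * dr^2, dr^2)
  sig <- numeric(length(t_out))
  wgt <- r[inside]
  wgt[1L] <- dr / 8  # center cell has area ~ pi (dr/2)^2
  t_now <- 0
  k_out <- 1L
  n_steps <- ceiling(max(t_out) / dt)
  for (s in seq_len(n_steps)) {
    fp <- c(f[-1L], f[n - 1L])   # ghost: reflect at r_max
    fm <- c(f[2L], f[-n])        # ghost: reflect at 0
    lap <- (r_plus * (fp - f) - r_minus * (f - fm)) / denom
    lap[1L] <- 4 * (f[2L] - f[1L]) / dr^2
    react <- ifelse(inside, -kon * f + koff * c_b, 0)
    f <- f + dt * (D * lap + react)
    c_b <- c_b + dt * ifelse(inside, kon * f - koff * c_b, 0)
    t_now <- t_now + dt
    while (k_out <= length(t_out) && t_now >= t_out[k_out]) {
      tot <- f[inside] + c_b[inside]
      sig[k_out] <- sum(tot * wgt) / sum(wgt)
      k_out <- k_out + 1L
    }
  }
  sig
}
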