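# Forward FRAP models: closed-form diffusion, Stehfest inversion,
# diffusion-reaction models and their limiting behaviors.

test_that("pure-diffusion recovery has the closed-form value at t = tau_D", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  tau_d <- 1.5^2 / (4 * 12)
  # e^-2 (I0(2) + I1(2)), high-precision reference value
  expect_equal(soumpasis_frap(tau_d, 12, g), 0.5238, tolerance = 1e-3)
  expect_equal(soumpasis_frap(1e7 * tau_d, 12, g), 1, tolerance = 1e-4)
  expect_equal(soumpasis_frap(0, 12, g), 0)
})

test_that("pure-diffusion recovery depends on t / tau_D only", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  t <- seq(0.05, 5, by = 0.05)
  expect_equal(soumpasis_frap(t, 3, g), soumpasis_frap(t / 4, 12, g),
               tolerance = 1e-12)
})

test_that("incomplete bleaching rescales the recovery to [theta, 1]", {
  g0 <- bleach_geometry(spot_radius_um = 1.5, bleach_depth = 0)
  g3 <- bleach_geometry(spot_radius_um = 1.5, bleach_depth = 0.3)
  t <- c(0, 0.1, 1, 10)
  expect_equal(soumpasis_frap(t, 12, g3),
               0.3 + 0.7 * soumpasis_frap(t, 12, g0), tolerance = 1e-12)
})

test_that("invalid diffusion inputs are rejected", {
  g <- bleach_geometry()
  expect_error(soumpasis_frap(-1, 12, g), "non-negative")
  expect_error(soumpasis_frap(1, -2, g), "must be >")
  expect_error(bleach_geometry(spot_radius_um = 10, nucleus_radius_um = 9.4))
  expect_error(bleach_geometry(bleach_depth = 1))
  expect_error(binding_rates(-1, 1))
  expect_error(binding_rates(1, 0))
})

test_that("Stehfest inversion reproduces five known transform pairs", {
  t <- c(0.5, 1, 2, 3, 5)
  expect_equal(stehfest_invert(function(p) 1 / p, t), rep(1, 5),
               tolerance = 1e-8)
  expect_equal(stehfest_invert(function(p) 1 / p^2, t), t,
               tolerance = 1e-6)
  # the exponential pair is accurate in absolute terms (the relative
  # error grows as the original decays toward zero)
  t_exp <- c(0.5, 1, 2, 3)
  expect_lt(max(abs(stehfest_invert(function(p) 1 / (p + 1), t_exp) -
                      exp(-t_exp))), 1e-4)
  a <- 2
  expect_equal(stehfest_invert(function(p) 1 / (p * (p + a)), t),
               (1 - exp(-a * t)) / a, tolerance = 1e-4)
  # 1/sqrt(p) has a branch point; the method is less accurate there
  expect_equal(stehfest_invert(function(p) 1 / sqrt(p), t),
               1 / sqrt(pi * t), tolerance = 1e-5)
})

test_that("Stehfest configuration errors are caught", {
  expect_error(stehfest_invert(function(p) 1 / p, 1, n_terms = 7),
               "even")
  expect_error(stehfest_invert(function(p) 1 / p, 1, n_terms = 20),
               "even integer between")
  expect_error(stehfest_invert(function(p) rep(NA_real_, length(p)), 1),
               "finite")
  expect_error(stehfest_invert(function(p) 1 / p, 0), "positive")
})

test_that("global-binding model reduces to pure diffusion without binding", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  t <- seq(0.02, 10, length.out = 60)
  gb <- global_binding_frap(t, 12, binding_rates(0, 1), g)
  expect_equal(gb, soumpasis_frap(t, 12, g), tolerance = 1e-4)
})

test_that("fast exchange gives effective diffusion D / (1 + kon/koff)", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  tau_d <- 1.5^2 / (4 * 12)
  koff <- 1e3 / tau_d
  r <- binding_rates(9 * koff, koff)
  t <- seq(0.05, 20, length.out = 50)
  gb <- global_binding_frap(t, 12, r, g)
  expect_equal(gb, soumpasis_frap(t, 12 / 10, g), tolerance = 2e-2)
})

test_that("reaction models recover fully and stay within [0, 1]", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  r <- binding_rates(0.05, 0.01)
  t <- 10^seq(-1, 5, by = 0.5)
  for (f in list(global_binding_frap(t, 2, r, g),
                 local_binding_frap(t, 2, r, g))) {
    expect_true(all(f >= -1e-6 & f <= 1 + 1e-6))
    expect_true(all(diff(f) > -1e-3))
    expect_equal(f[length(f)], 1, tolerance = 1e-3)
  }
})

test_that("local-binding model reduces to pure diffusion without binding", {
  g <- bleach_geometry(spot_radius_um = 1.5, nucleus_radius_um = 9.4)
  tau_d <- 1.5^2 / (4 * 2)
  t <- seq(0.05, 5, length.out = 40) * tau_d
  lb <- local_binding_frap(t, 2, binding_rates(0, 1), g)
  expect_equal(lb, soumpasis_frap(t, 2, g), tolerance = 2e-2)
})

test_that("more binding slows local-focus recovery at every time", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  koff <- 0.1
  t <- c(0.5, 2, 10, 50)
  curves <- sapply(c(0, 0.1, 1, 10) * koff, function(kon) {
    local_binding_frap(t, 2, binding_rates(kon, koff), g)
  })
  for (i in seq_along(t)) {
    expect_true(all(diff(curves[i, ]) <= 1e-9),
                info = paste("t =", t[i]))
  }
})

test_that("local-binding model matches a finite-difference PDE oracle", {
  g <- bleach_geometry(spot_radius_um = 1, nucleus_radius_um = 9.4)
  t_out <- seq(0.5, 10, by = 0.5)
  for (kon in c(0.05, 0.5, 5)) {
    for (koff in c(0.05, 0.5, 5)) {
      mod <- local_binding_frap(t_out, 1, binding_rates(kon, koff), g)
      fd <- fd_local_frap(t_out, 1, kon, koff, w = 1)
      expect_lt(max(abs(mod - fd)), 2e-2)
    }
  }
})

test_that("reflecting outer boundary matches the open solution early on", {
  g <- bleach_geometry(spot_radius_um = 1.5, nucleus_radius_um = 9.4)
  r <- binding_rates(0.2, 0.05)
  t <- seq(0.1, 2, by = 0.1)  # diffusion length << nucleus radius
  open <- local_binding_frap(t, 1, r, g)
  refl <- local_binding_frap(t, 1, r, g, outer_boundary = "reflecting")
  expect_equal(refl, open, tolerance = 1e-3)
})

test_that("effective diffusion coefficient follows 1 / (1 + kon/koff)", {
  expect_equal(effective_diffusion_coefficient(12, binding_rates(0, 1)), 12)
  expect_equal(effective_diffusion_coefficient(12, binding_rates(1, 1)), 6)
  expect_equal(effective_diffusion_coefficient(12, binding_rates(9, 1)), 1.2)
})
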