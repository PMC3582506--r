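# Double normalization of raw FRAP data and parameter estimation:
# diffusion coefficients, binding constants, mobility arithmetic.

test_that("double normalization cancels acquisition bleaching exactly", {
  t <- seq(-0.5, 5, by = 0.1)
  # constant signals: everything normalizes to 1
  cv <- double_normalize(t, rep(200, length(t)), rep(400, length(t)),
                         0, n_prebleach = 5)
  expect_equal(cv$intensities, rep(1, length(t)), tolerance = 1e-12)
  # common exponential decay cancels
  lambda <- 0.07
  cv2 <- double_normalize(t, 0.5 * exp(-lambda * t), exp(-lambda * t),
                          0, n_prebleach = 5)
  expect_equal(cv2$intensities, rep(1, length(t)), tolerance = 1e-12)
  # plain ratio arithmetic: pre-mean 200, post frame 80, constant whole
  roi <- c(rep(200, 5), rep(80, length(t) - 5))
  cv3 <- double_normalize(t, roi, rep(500, length(t)), 0, n_prebleach = 5)
  expect_equal(cv3$intensities[10], 0.4, tolerance = 1e-12)
  expect_equal(mean(cv3$intensities[1:5]), 1, tolerance = 1e-9)
})

test_that("double normalization is idempotent for constant whole-cell", {
  t <- seq(-0.5, 5, by = 0.1)
  g <- bleach_geometry()
  y <- c(rep(1, 5), soumpasis_frap(t[t >= 0], 5, g))
  cv1 <- double_normalize(t, y, rep(1, length(t)), 0, n_prebleach = 5)
  cv2 <- double_normalize(t, cv1$intensities, rep(1, length(t)), 0,
                          n_prebleach = 5)
  expect_equal(cv1$intensities, cv2$intensities, tolerance = 1e-12)
})

test_that("data-quality problems are reported with a frame index", {
  t <- seq(-0.5, 5, by = 0.5)
  whole <- rep(100, length(t)); whole[4] <- 0
  expect_error(
    double_normalize(t, rep(50, length(t)), whole, 0, n_prebleach = 2),
    "frame 4")
  expect_error(
    double_normalize(t, rep(50, length(t)), rep(100, length(t)), 0,
                     n_prebleach = 0), "n_prebleach")
})

make_diffusion_curve <- function(D, geom, t = seq(0.1, 10, length.out = 100)) {
  frap_curve(c(-0.5, t), c(1, soumpasis_frap(t, D, geom)), n_prebleach = 1)
}

test_that("effective diffusion coefficients are recovered from noise-free curves", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  fit_gfp <- fit_effective_diffusion(make_diffusion_curve(12, g), g)
  expect_equal(fit_gfp$D_eff, 12, tolerance = 0.01)
  t_slow <- seq(5, 2000, length.out = 150)
  fit_mdc1 <- fit_effective_diffusion(
    make_diffusion_curve(0.029, g, t_slow), g)
  expect_equal(fit_mdc1$D_eff, 0.029, tolerance = 0.01)
})

test_that("diffusion fits are invariant under joint time/length rescaling", {
  k <- 9
  g1 <- bleach_geometry(spot_radius_um = 1.5)
  g2 <- bleach_geometry(spot_radius_um = 1.5 * sqrt(k))
  t <- seq(0.1, 10, length.out = 80)
  c1 <- frap_curve(c(-1, t), c(1, soumpasis_frap(t, 5, g1)), n_prebleach = 1)
  c2 <- frap_curve(c(-1, t * k), c(1, soumpasis_frap(t * k, 5, g2)),
                   n_prebleach = 1)
  expect_equal(fit_effective_diffusion(c1, g1)$D_eff,
               fit_effective_diffusion(c2, g2)$D_eff, tolerance = 1e-6)
})

make_binding_curve <- function(kind, D, kon, koff, geom,
                               t = seq(4, 1200, length.out = 80),
                               sigma = 0, seed = 1) {
  fwd <- if (kind == "local_binding") local_binding_frap else
    global_binding_frap
  y <- fwd(t, D, binding_rates(kon, koff), geom)
  if (sigma > 0) {
    set.seed(seed)
    y <- y * (1 + rnorm(length(y), 0, sigma))
  }
  frap_curve(c(-1, t), c(1, y), n_prebleach = 1)
}

test_that("a curve generated without binding refits as pure diffusion", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  t <- seq(0.1, 10, length.out = 60)
  cv <- make_binding_curve("global_binding", 2, 0, 1, g, t)
  fit <- fit_binding_constants(cv, "global_binding", 2, g,
                               start_decades = c(-4, -1, 2),
                               maxit_grid = 120)
  expect_lt(fit$rates$kon_star, 1e-6)
  dfit <- fit_effective_diffusion(cv, g)
  expect_lt(abs(fit$sse - dfit$sse), 1e-6)
})

test_that("binding constants are recovered from 1%-noise curves (both models)", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  # truth values chosen so both rates act on the sampled window: binding
  # neither so slow that koff never shows nor so fast that it averages out
  cases <- list(
    list(kind = "local_binding", D = 1, kon = 0.05, koff = 0.01,
         grid = c(-3, -1), t = seq(0.5, 300, length.out = 60)),
    list(kind = "global_binding", D = 0.029, kon = 74e-5, koff = 193e-5,
         grid = c(-4, -2), t = seq(10, 1200, length.out = 60))
  )
  for (cs in cases) {
    ok <- vapply(1:50, function(seed) {
      cv <- make_binding_curve(cs$kind, cs$D, cs$kon, cs$koff, g,
                               t = cs$t, sigma = 0.01, seed = seed)
      fit <- fit_binding_constants(cv, cs$kind, cs$D, g,
                                   start_decades = cs$grid,
                                   maxit_grid = 100, maxit_polish = 300)
      abs(fit$rates$kon_star / cs$kon - 1) < 0.15 &&
        abs(fit$rates$koff / cs$koff - 1) < 0.15
    }, logical(1))
    expect_gte(mean(ok), 0.9)
  }
})

test_that("the decade start grid finds the optimum of a dense random-start search", {
  g <- bleach_geometry(spot_radius_um = 1.5)
  set.seed(42)
  cases <- list(c(0.5, 0.02), c(3e-3, 8e-3))
  t <- seq(5, 1000, length.out = 50)
  for (cs in cases) {
    cv <- make_binding_curve("global_binding", 0.5, cs[1], cs[2], g, t)
    grid_fit <- fit_binding_constants(cv, "global_binding", 0.5, g,
                                      maxit_grid = 60, maxit_polish = 400)
    # random-start oracle: many log-uniform starts, same local optimizer
    pb_t <- cv$times[cv$times > 0]
    pb_y <- cv$intensities[cv$times > 0]
    obj <- function(par) {
      f <- tryCatch(global_binding_frap(pb_t, 0.5,
                                        binding_rates(10^par[1], 10^par[2]),
                                        g),
                    error = function(e) NULL)
      if (is.null(f)) return(1e10)
      sum((f - pb_y)^2)
    }
    starts <- matrix(runif(200, -6, 6), ncol = 2)
    oracle_best <- min(apply(starts, 1, function(s) {
      optim(s, obj, method = "Nelder-Mead",
            control = list(maxit = 60))$value
    }))
    expect_lte(grid_fit$sse, oracle_best + 1e-8)
  }
})

test_that("cube-root mass scaling reproduces the calculated diffusion table", {
  expect_equal(scaled_diffusion_estimate(12, 27, 27), 12)
  expect_equal(signif(scaled_diffusion_estimate(12, 27, 137), 2), 7.0)
  expect_equal(signif(scaled_diffusion_estimate(12, 27, 257), 2), 5.7)
})

test_that("mean traversal times follow r^2 / (4D)", {
  expect_equal(signif(traversal_time(6.3, 12), 2), 0.83)
  expect_equal(traversal_time(6.3, 0.25), 40, tolerance = 0.01)
  expect_equal(traversal_time(6.3, 0.029), 340, tolerance = 0.01)
})
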