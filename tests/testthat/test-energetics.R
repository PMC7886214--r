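test_that("dissipation function matches its closed forms on canonical fields", {
  fl <- fluid_props()  # mu = 0.0042 Pa s
  h <- 0.002; n <- 21
  # rigid rotation: zero strain rate, zero dissipation
  rot <- make_flow_field(flow_spec("solid_rotation", list(omega = 37),
                                   grid_shape = c(n, n), grid_spacing = h))
  expect_lt(ved_instant(rot, fl), 1e-12)
  # pure shear gamma: VED = mu * gamma^2 * A over the grid extent, exact for
  # a linear field under second-order differences
  sh <- make_flow_field(flow_spec("pure_shear", list(gamma = 5),
                                  grid_shape = c(n, n), grid_spacing = h))
  area <- ((n - 1) * h)^2
  expect_equal(ved_instant(sh, fl), fl$dynamic_viscosity * 25 * area,
               tolerance = 1e-10)
  # translation adds nothing
  uni <- make_flow_field(flow_spec("uniform", list(u = 0.7, v = -0.2),
                                   grid_shape = c(n, n), grid_spacing = h))
  expect_lt(ved_instant(uni, fl), 1e-15)
})

test_that("VED is Galilean invariant and non-negative on arbitrary fields", {
  fl <- fluid_props()
  for (seed in 1:5) {
    f <- random_smooth_field(seed = seed)
    v0 <- ved_instant(f, fl)
    expect_gte(v0, 0)
    g <- f
    g$u_mps <- g$u_mps + 0.7
    g$v_mps <- g$v_mps - 0.2
    expect_equal(ved_instant(g, fl), v0, tolerance = 1e-12)
  }
})

test_that("ordered-pair sum form equals the expanded dissipation function", {
  # independent evaluation of (mu/2) * sum_ij (du_i/dx_j + du_j/dx_i)^2
  fl <- fluid_props()
  for (seed in 1:3) {
    f <- random_smooth_field(n = 15, seed = seed)
    m <- mitralflow:::field_matrices(f)
    h <- m$spacing
    grad_x <- function(M) {
      g <- M
      nc <- ncol(M)
      g[, 2:(nc - 1)] <- (M[, 3:nc] - M[, 1:(nc - 2)]) / (2 * h)
      g[, 1] <- (-3 * M[, 1] + 4 * M[, 2] - M[, 3]) / (2 * h)
      g[, nc] <- (3 * M[, nc] - 4 * M[, nc - 1] + M[, nc - 2]) / (2 * h)
      g
    }
    ux <- grad_x(m$u); vx <- grad_x(m$v)
    uy <- t(grad_x(t(m$u))); vy <- t(grad_x(t(m$v)))
    phi <- (ux + ux)^2 + (uy + vx)^2 + (vx + uy)^2 + (vy + vy)^2
    wx <- rep(1, ncol(phi)); wx[c(1, ncol(phi))] <- 0.5
    wy <- rep(1, nrow(phi)); wy[c(1, nrow(phi))] <- 0.5
    oracle <- fl$dynamic_viscosity / 2 * sum(phi * outer(wy, wx)) * h^2
    expect_equal(ved_instant(f, fl), oracle, tolerance = 1e-12)
  }
})

test_that("VED converges at second order to the analytic vortex dissipation", {
  skip_if_not_installed("pracma")
  fl <- fluid_props()
  circ <- 2e-3; rc <- 0.004; L <- 0.02
  exact <- pracma::integral2(
    function(x, y) lamb_oseen_phi(x, y, L / 2, L / 2, circ, rc,
                                  fl$dynamic_viscosity),
    0, L, 0, L, reltol = 1e-12)$Q
  errs <- vapply(c(33, 65, 129), function(n) {
    f <- make_flow_field(flow_spec("lamb_oseen",
                                   list(circulation = circ, core_radius = rc),
                                   grid_shape = c(n, n),
                                   grid_spacing = L / (n - 1)))
    abs(ved_instant(f, fl) - exact) / exact
  }, numeric(1))
  orders <- log2(errs[-length(errs)] / errs[-1])
  expect_true(all(orders > 1.6 & orders < 2.4))
})

test_that("masking and degenerate grids behave as contracted", {
  fl <- fluid_props()
  n <- 9; h <- 0.001
  g <- expand.grid(y = (0:(n - 1)) * h, x = (0:(n - 1)) * h)
  # a masked hot spot must not contribute to the integral
  u <- 0.1 * g$y / h
  mask <- rep(FALSE, n^2)
  hot <- which(g$x == 4 * h & g$y == 4 * h)
  u[hot] <- 100
  mask[hot] <- TRUE
  f_masked <- velocity_field(g$x, g$y, u, 0 * u, mask = mask, spacing = h)
  f_clean <- velocity_field(g$x, g$y, 0.1 * g$y / h, 0 * u, spacing = h)
  v_masked <- ved_instant(f_masked, fl)
  v_clean <- ved_instant(f_clean, fl)
  # the hot node is excluded; only its neighbours' stencils change
  expect_lt(abs(v_masked - v_clean) / v_clean, 0.1)
  expect_warning(
    v0 <- ved_instant(velocity_field(g$x, g$y, u, u, mask = TRUE,
                                     spacing = h), fl),
    "all nodes masked")
  expect_equal(v0, 0)
  tiny <- expand.grid(y = (0:1) * h, x = (0:1) * h)
  expect_error(ved_instant(velocity_field(tiny$x, tiny$y, tiny$x * 0,
                                          tiny$x * 0, spacing = h), fl),
               "3 nodes")
})

test_that("VED series scales quadratically and preserves time", {
  fl <- fluid_props()
  f <- random_smooth_field(n = 13, seed = 2)
  times <- seq(0, 0.9, by = 0.1)
  amps <- sin(pi * times)^2 + 0.1
  fields <- lapply(amps, function(a) {
    g <- f
    g$u_mps <- a * g$u_mps
    g$v_mps <- a * g$v_mps
    g
  })
  vs <- ved_series(fields, fl, times = times, cycle_period = 1)
  expect_equal(vs$t_s, times)
  expect_equal(vs$ved_W_per_m, amps^2 * vs$ved_W_per_m[1] / amps[1]^2,
               tolerance = 1e-10)
  # constant fields give a constant series
  const <- ved_series(rep(list(f), 4), fl, times = 0:3, cycle_period = 4)
  expect_equal(diff(range(const$ved_W_per_m)), 0)
  # mismatched grids are an error
  small <- random_smooth_field(n = 9, seed = 3)
  expect_error(ved_series(list(f, small), fl, times = 0:1), "mismatched")
})

test_that("synthetic E/A jet cycle produces exactly two VED maxima", {
  vs <- ved_series(rest_jet_series(n_frames = 60, grid = 40))
  v <- vs$ved_W_per_m
  maxima <- which(diff(sign(diff(v))) == -2) + 1
  expect_equal(length(maxima[v[maxima] > 1e-9 * max(v)]), 2)
})

test_that("TVED integrates the series and tiles it periodically", {
  # constant 1 W/m over one second is exactly 1 J/m
  const <- mitralflow:::new_ved_series(seq(0, 1, by = 0.01),
                                       rep(1, 101), cycle_period = 1)
  expect_equal(tved(const, 1), 1)
  # linearity in the viscosity of the upstream evaluation
  ser <- rest_jet_series(n_frames = 50)
  v1 <- ved_series(ser, fluid_props(dynamic_viscosity = 0.0042))
  v2 <- ved_series(ser, fluid_props(dynamic_viscosity = 0.0084))
  expect_equal(tved(v2, 1), 2 * tved(v1, 1), tolerance = 1e-12)
  # periodic tiling of a one-cycle rest series to 1 s matches the per-cycle
  # integral scaled by the cycle count 1 / 0.857
  period <- beat_spec("rest")$period
  one_cycle <- mitralflow:::trapz_integral(
    c(v1$t_s, period), c(v1$ved_W_per_m, v1$ved_W_per_m[1]))
  expect_lt(abs(tved(v1, 1) - one_cycle / period) / (one_cycle / period),
            0.005)
  expect_error(tved(v1, -1), "positive")
  short <- mitralflow:::new_ved_series(seq(0, 0.3, by = 0.01),
                                       rep(1, 31), cycle_period = 0.857)
  expect_error(tved(short, 1), "full cycle")
})

test_that("peak detection reports windowed maxima and degenerate cases", {
  period <- 1
  t <- seq(0, 0.99, by = 0.01)
  two_lobe <- 0.3 * sin(pi * pmin(t, 0.1) / 0.1)^2 * (t <= 0.1) +
    0.2 * sin(pi * (t - 0.5) / 0.1)^2 * (t >= 0.5 & t <= 0.6)
  vs <- mitralflow:::new_ved_series(t, two_lobe, cycle_period = period)
  pk <- detect_peaks(vs, first_window = c(0, 0.15),
                     second_window = c(0.45, 0.65))
  expect_equal(pk$value_W_per_m, c(0.3, 0.2))
  expect_equal(pk$time_s, c(0.05, 0.55))
  # swapping the windows swaps the peaks
  pk2 <- detect_peaks(vs, first_window = c(0.45, 0.65),
                      second_window = c(0, 0.15))
  expect_equal(pk2$value_W_per_m, c(0.2, 0.3))
  # monotone stretch returns the endpoint with a warning
  ramp <- mitralflow:::new_ved_series(t, t, cycle_period = period)
  # monotone in both windows -> one endpoint warning per window
  expect_warning(expect_warning(pk3 <- detect_peaks(ramp), "monotone"),
                 "monotone")
  expect_equal(pk3$value_W_per_m[1], 0.15)
  expect_error(detect_peaks(vs, first_window = c(0.9, 0.8)))
})

test_that("replicate ANOVA matches hand-computed sums of squares", {
  # groups {1,2,3} and {2,3,4}: SSB = 1.5 (df 1), SSW = 4 (df 4) -> F = 1.5
  out <- anova_recordings(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(out$statistic, 1.5)
  expect_equal(out$p.value, stats::pf(1.5, 1, 4, lower.tail = FALSE))
  # five identical recordings: no between-group variance
  rec <- replicate(5, c(0.1, 0.5, 0.3, 0.2), simplify = FALSE)
  expect_equal(anova_recordings(rec)$statistic, 0)
  # permutation within groups leaves F unchanged
  a <- c(1, 5, 2, 4); b <- c(2, 3, 6, 1)
  expect_equal(anova_recordings(list(a, b))$statistic,
               anova_recordings(list(rev(a), sample(b)))$statistic)
  expect_error(anova_recordings(list(1:3)), "at least two")
  expect_error(anova_recordings(list(1:3, 1:4)), "equal length")
  # tidy/glance expose the statistic
  td <- tidy(anova_recordings(list(c(1, 2, 3), c(2, 3, 4))))
  expect_equal(td$statistic, 1.5)
  expect_named(glance(anova_recordings(list(c(1, 2, 3), c(2, 3, 4)))),
               c("statistic", "p.value", "n_recordings", "n_samples"))
})
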