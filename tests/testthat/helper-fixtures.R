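# Shared fixture builders and independent oracles used across the suite.

# uniform-displacement pair: displacement (dx_px, dy_px) rendered at the
# given image size; returns the pair plus the matching piv config
uniform_pair <- function(dx_px, dy_px = 0, image = c(256, 256),
                         mag = 1e-4, dt = 1e-3, seed = 7,
                         density = 0.02, noise_sd = 0) {
  spec <- flow_spec("uniform",
                    list(u = dx_px * mag / dt, v = -dy_px * mag / dt),
                    grid_shape = c(9, 9),
                    grid_spacing = max(image) * mag / 8)
  pair <- render_particle_pair(
    make_flow_field(spec),
    imaging_spec(image_shape = image, magnification = mag,
                 frame_interval = dt, particle_density = density,
                 noise_sd = noise_sd, seed = seed))
  list(pair = pair,
       config = piv_config(magnification = mag, frame_interval = dt),
       mag = mag, dt = dt)
}

# displacements (px) recovered by the package from a velocity field
recovered_px <- function(field, mag, dt) {
  list(dx = field$u_mps * dt / mag, dy = -field$v_mps * dt / mag)
}

# independent full-frame correlation oracle: integer lag of the circular
# cross-correlation peak between two images (dy, dx)
fullframe_peak_lag <- function(a, b) {
  am <- a - mean(a); bm <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(am)) * stats::fft(bm), inverse = TRUE))
  pk <- arrayInd(which.max(cc), dim(cc))
  wrap <- function(i, n) {
    l <- i - 1L
    if (l > n / 2) l - n else l
  }
  c(dy = wrap(pk[1], nrow(a)), dx = wrap(pk[2], ncol(a)))
}

# coefficient of determination of a recovered field against the analytic
# model, on interior valid nodes
interior_r2 <- function(field, spec, margin_m) {
  rng_x <- range(field$x_m); rng_y <- range(field$y_m)
  sel <- field$x_m > rng_x[1] + margin_m & field$x_m < rng_x[2] - margin_m &
    field$y_m > rng_y[1] + margin_m & field$y_m < rng_y[2] - margin_m &
    field$valid
  tru <- mitralflow:::eval_flow_model(spec, field$x_m, field$y_m)
  num <- sum((field$u_mps[sel] - tru$u[sel])^2 +
               (field$v_mps[sel] - tru$v[sel])^2)
  den <- sum((tru$u[sel] - mean(tru$u[sel]))^2 +
               (tru$v[sel] - mean(tru$v[sel]))^2)
  1 - num / den
}

# smooth pseudo-random polynomial/trig velocity field for invariance tests
random_smooth_field <- function(n = 17, h = 0.002, seed = 1) {
  withr::with_seed(seed, {
    a <- stats::rnorm(6); b <- stats::rnorm(6)
    xs <- (0:(n - 1)) * h
    g <- expand.grid(y = xs, x = xs)
    L <- (n - 1) * h
    u <- a[1] + a[2] * g$x + a[3] * g$y + a[4] * g$x * g$y +
      a[5] * sin(2 * pi * g$x / L) + a[6] * cos(2 * pi * g$y / L)
    v <- b[1] + b[2] * g$x + b[3] * g$y + b[4] * g$x * g$y +
      b[5] * cos(2 * pi * g$x / L) + b[6] * sin(2 * pi * g$y / L)
    velocity_field(g$x, g$y, u, v, spacing = h)
  })
}

# analytic dissipation density of the Lamb-Oseen vortex (for quadrature
# oracles): phi(r) = mu * r^2 * f'(r)^2 with f = vtheta / r
lamb_oseen_phi <- function(x, y, xc, yc, circulation, core_radius, mu) {
  r2 <- (x - xc)^2 + (y - yc)^2
  r <- sqrt(r2)
  fp <- ifelse(r > 0,
               circulation / (2 * pi) *
                 (-2 / r^3 * (1 - exp(-r2 / core_radius^2)) +
                    2 / (r * core_radius^2) * exp(-r2 / core_radius^2)),
               0)
  mu * r2 * fp^2
}

# small standard jet series for energetics/pipeline tests
rest_jet_series <- function(n_frames = 50, grid = 48, beat = beat_spec("rest"),
                            orifice_cm2 = 2.2, domain = 0.08) {
  sigma <- sqrt(orifice_cm2 * 1e-4 / pi)
  spec <- flow_spec("transmitral_jet",
                    params = list(jet_width = 2 * sigma),
                    grid_shape = c(grid, grid),
                    grid_spacing = domain / (grid - 1))
  make_flow_series(spec, beat, n_frames = n_frames)
}
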