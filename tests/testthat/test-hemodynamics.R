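test_that("diastolic windows follow the pressure crossover", {
  t <- seq(0, 2, by = 0.004)
  la <- pressure_trace(t, rep(10, length(t)), "LA")
  lv <- pressure_trace(t, rep(8, length(t)), "LV")
  w <- diastolic_windows(la, lv)
  expect_equal(nrow(w), 1)
  expect_equal(c(w$start_s, w$end_s), range(t))
  # LV above LA everywhere: no filling window
  w2 <- diastolic_windows(lv, la)
  expect_equal(nrow(w2), 0)
  expect_error(
    diastolic_windows(pressure_trace(t, rep(10, length(t)), "LA"),
                      pressure_trace(t + 10, rep(8, length(t)), "LV")),
    "overlap")
})

test_that("generator round-trip: windows match the filling-lobe timing", {
  beat <- beat_spec("rest")
  tr <- make_pressure_traces(beat, diastolic_offset = 3.2, n_cycles = 3)
  w <- diastolic_windows(tr$la, tr$lv)
  # two filling lobes (E and A) per cycle
  expect_equal(nrow(w), 6)
  per_cycle <- sum(w$duration_s) / 3
  expect_equal(per_cycle, (beat$e_fraction + beat$a_fraction) * beat$period,
               tolerance = 0.02)
})

test_that("catheter gradient recovers the generating diastolic offset", {
  beat <- beat_spec("rest")
  for (g in c(1.3, 3.2, 5.0, 5.9)) {
    tr <- make_pressure_traces(beat, diastolic_offset = g)
    expect_equal(catheter_mean_gradient(tr$la, tr$lv), g, tolerance = 0.02)
  }
  # zero offset: equal diastolic pressures, zero mean gradient
  tr0 <- make_pressure_traces(beat, diastolic_offset = 0)
  expect_equal(catheter_mean_gradient(tr0$la, tr0$lv), 0)
  # linear in the offset
  tr1 <- make_pressure_traces(beat, 2)
  tr2 <- make_pressure_traces(beat, 4)
  expect_equal(2 * catheter_mean_gradient(tr1$la, tr1$lv),
               catheter_mean_gradient(tr2$la, tr2$lv), tolerance = 1e-6)
  # no filling window at all is an error
  t <- seq(0, 1, by = 0.004)
  expect_error(
    catheter_mean_gradient(pressure_trace(t, rep(5, length(t)), "LA"),
                           pressure_trace(t, rep(9, length(t)), "LV")),
    "no diastolic window")
  expect_error(make_pressure_traces(beat, 1, noise_sd = -1))
  # traces are seed-reproducible
  a <- make_pressure_traces(beat, 3, noise_sd = 0.4, seed = 2)
  b <- make_pressure_traces(beat, 3, noise_sd = 0.4, seed = 2)
  expect_identical(a$la$p_mmHg, b$la$p_mmHg)
})

test_that("Doppler mean gradient implements the simplified Bernoulli mean", {
  t <- seq(0, 0.5, by = 0.001)
  expect_equal(doppler_mean_gradient(doppler_envelope(t, rep(1, length(t)))),
               4)
  expect_equal(doppler_mean_gradient(doppler_envelope(t, rep(2, length(t)))),
               16)
  # half-sine lobe, peak 1 m/s: time-mean of 4 sin^2 = 2 exactly
  v <- sin(pi * t / 0.2)
  v[t >= 0.2] <- 0
  v[v < 0] <- 0
  expect_equal(doppler_mean_gradient(doppler_envelope(t, v)), 2)
  expect_error(doppler_mean_gradient(doppler_envelope(t, rep(0, length(t)))),
               "zero everywhere")
  # generated E/A envelope matches its analytic mean
  beat <- beat_spec("rest")
  env <- make_doppler_envelope(beat, e_peak = 1, a_peak = 1 / 1.8)
  analytic <- 2 * (beat$e_fraction + beat$a_fraction / 1.8^2) /
    (beat$e_fraction + beat$a_fraction)
  expect_equal(doppler_mean_gradient(env), analytic, tolerance = 0.02)
  # equal peaks give two equal envelope maxima
  env2 <- make_doppler_envelope(beat, e_peak = 0.8, a_peak = 0.8)
  expect_equal(max(env2$v_mps), 0.8, tolerance = 1e-3)
  e_lobe_max <- max(env2$v_mps[env2$t_s / beat$period > 0.3])
  a_lobe_max <- max(env2$v_mps[env2$t_s / beat$period < 0.3])
  expect_equal(e_lobe_max, a_lobe_max, tolerance = 1e-3)
})

test_that("Doppler and catheter gradients agree on Bernoulli-consistent data", {
  beat <- beat_spec("rest")
  tr <- make_pressure_traces(beat, diastolic_offset = 3.2, n_cycles = 1)
  dp <- pmax(tr$la$p_mmHg - tr$lv$p_mmHg, 0)
  env <- doppler_envelope(tr$la$t_s, sqrt(dp / 4))
  cath <- catheter_mean_gradient(tr$la, tr$lv)
  dopp <- doppler_mean_gradient(env)
  expect_equal(dopp, cath, tolerance = 0.02)
})

test_that("Gorlin valve areas reproduce the benchmark values and scalings", {
  expect_equal(signif(gorlin_mva(70, 60.08, 0.465, 1.3), 2), 2.2)
  expect_equal(signif(gorlin_mva(70, 60.08, 0.465, 3.2), 2), 1.4)
  # quadrupling the gradient halves the area exactly
  base <- gorlin_mva(70, 60.08, 0.465, 1.3)
  expect_equal(gorlin_mva(70, 60.08, 0.465, 4 * 1.3), base / 2)
  # strictly decreasing in gradient, increasing in stroke volume
  gr <- gorlin_mva(70, 60.08, 0.465, seq(0.5, 6, by = 0.5))
  expect_true(all(diff(gr) < 0))
  sv <- gorlin_mva(70, seq(40, 100, by = 10), 0.465, 2)
  expect_true(all(diff(sv) > 0))
  expect_error(gorlin_mva(70, 60.08, 0.465, 0), "positive")
})
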