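test_that("three-point Gaussian fit recovers analytic subpixel offsets", {
  # a sampled Gaussian peak exp(-(x - d)^2 / s^2) restores d exactly
  mk_plane <- function(dx, dy, s = 0.8) {
    outer(-2:2, -2:2, function(i, j) exp(-((j - dx)^2 + (i - dy)^2) / s^2))
  }
  for (d in c(-0.4, -0.1, 0.17, 0.3)) {
    off <- subpixel_peak(mk_plane(d, -d / 2))
    expect_equal(unname(off["dx"]), d, tolerance = 1e-6)
    expect_equal(unname(off["dy"]), -d / 2, tolerance = 1e-6)
  }
  # symmetric peak (equal neighbours) sits exactly on the integer node
  sym <- matrix(c(0, 1, 0, 1, 5, 1, 0, 1, 0), 3, 3)
  expect_equal(unname(subpixel_peak(sym)), c(0, 0))
  # peak on the plane border is a precondition violation
  border <- matrix(0, 5, 5); border[1, 3] <- 1
  expect_error(subpixel_peak(border), "border")
  # non-positive neighbours fall back to the parabolic fit, with a message
  neg <- matrix(c(0, -1, 0, 2, 5, 2, 0, -1, 0), 3, 3, byrow = TRUE)
  expect_message(subpixel_peak(neg), "parabolic")
})

test_that("multipass recovers uniform displacements within PIV error bounds", {
  for (d in c(0.25, 0.5, 3.25, -0.5, -3.25)) {
    up <- uniform_pair(d, -d / 3)
    fld <- multipass_piv(up$pair, up$config)
    px <- recovered_px(fld, up$mag, up$dt)
    expect_lt(abs(mean(px$dx) - d), 0.1)
    expect_lt(sqrt(mean((px$dx - d)^2)), 0.2)
    expect_lt(abs(mean(px$dy) + d / 3), 0.1)
  }
  up0 <- uniform_pair(0, 0)
  fld0 <- multipass_piv(up0$pair, up0$config)
  px0 <- recovered_px(fld0, up0$mag, up0$dt)
  expect_lt(max(abs(c(px0$dx, px0$dy))), 0.05)
})

test_that("a slow solid-rotation field is recovered with high fidelity", {
  mag <- 1e-4; dt <- 1e-3
  spec <- flow_spec("solid_rotation", list(omega = 10),
                    grid_shape = c(33, 33), grid_spacing = 256 * mag / 32)
  pair <- render_particle_pair(
    make_flow_field(spec),
    imaging_spec(image_shape = c(256, 256), magnification = mag,
                 frame_interval = dt, seed = 9))
  fld <- multipass_piv(pair, piv_config(magnification = mag,
                                        frame_interval = dt))
  expect_gt(interior_r2(fld, spec, margin_m = 24 * mag), 0.98)
})

test_that("recovered field is invariant to a common integer image shift", {
  up <- uniform_pair(1.3, 0.7, image = c(192, 192))
  fld <- multipass_piv(up$pair, up$config)
  roll <- function(m, k) {
    idx_r <- ((seq_len(nrow(m)) - 1 - k) %% nrow(m)) + 1
    idx_c <- ((seq_len(ncol(m)) - 1 - k) %% ncol(m)) + 1
    m[idx_r, idx_c]
  }
  shifted <- up$pair
  shifted$frame_a <- roll(shifted$frame_a, 8)
  shifted$frame_b <- roll(shifted$frame_b, 8)
  fld2 <- multipass_piv(shifted, up$config)
  # shifting both frames by one node step relabels the grid: interior node
  # (i, j) of the shifted pair sees the content of node (i-1, j-1)
  m1 <- mitralflow:::field_matrices(fld)
  m2 <- mitralflow:::field_matrices(fld2)
  nr <- nrow(m1$u); nc <- ncol(m1$u)
  # rows of the matrices ascend in y (i.e. descend in image row); an 8 px
  # downward image shift moves content up one node row in y order
  a <- m1$u[3:(nr - 3), 3:(nc - 3)]
  b <- m2$u[(3 - 1):(nr - 4), (3 + 1):(nc - 2)]
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("node grid follows the window/step contract", {
  up <- uniform_pair(1, 0, image = c(120, 200))
  fld <- multipass_piv(up$pair, up$config)
  dims <- attr(fld, "dims")
  step <- 16 * 0.5
  expect_equal(dims[1], floor((120 - 16) / step) + 1)
  expect_equal(dims[2], floor((200 - 16) / step) + 1)
  expect_equal(attr(fld, "spacing_m"), step * up$mag)
})

test_that("multipass PIV is deterministic for a fixed pair", {
  up <- uniform_pair(2.2, -1.1, image = c(128, 128))
  f1 <- multipass_piv(up$pair, up$config)
  f2 <- multipass_piv(up$pair, up$config)
  expect_identical(f1$u_mps, f2$u_mps)
  expect_error(multipass_piv(list(frame_a = matrix(0, 64, 64),
                                  frame_b = matrix(0, 64, 32))),
               "identical dimensions")
})

test_that("normalized-median validation flags and repairs a spike", {
  n <- 7; h <- 0.001
  g <- expand.grid(y = (0:(n - 1)) * h, x = (0:(n - 1)) * h)
  u <- rep(1, n^2); v <- rep(0.5, n^2)
  fld <- velocity_field(g$x, g$y, u, v, spacing = h)
  spiked <- fld
  k <- which(abs(spiked$x_m - 3 * h) < 1e-12 & abs(spiked$y_m - 3 * h) < 1e-12)
  spiked$u_mps[k] <- 10
  out <- validate_vectors(spiked)
  kk <- which(abs(out$x_m - 3 * h) < 1e-12 & abs(out$y_m - 3 * h) < 1e-12)
  expect_false(out$valid[kk])
  expect_equal(out$u_mps[kk], 1)  # median of the valid neighbours

  # an already-smooth field passes through unaltered
  smooth <- validate_vectors(fld)
  expect_equal(smooth$u_mps, fld$u_mps)
  expect_true(all(smooth$valid))
})

test_that("nodes without valid neighbours are flagged but unchanged", {
  n <- 5; h <- 0.001
  g <- expand.grid(y = (0:(n - 1)) * h, x = (0:(n - 1)) * h)
  fld <- velocity_field(g$x, g$y, rep(1, n^2), rep(0, n^2),
                        valid = FALSE, spacing = h)
  fld$u_mps[13] <- 50  # centre node, everything else already invalid
  out <- validate_vectors(fld)
  expect_equal(out$u_mps[13], 50)
  expect_false(out$valid[13])
})

test_that("masked nodes are excluded from validation medians", {
  n <- 7; h <- 0.001
  g <- expand.grid(y = (0:(n - 1)) * h, x = (0:(n - 1)) * h)
  mask <- rep(FALSE, n^2)
  u <- rep(1, n^2)
  # poison a masked node with an absurd value: it must neither be flagged
  # nor drag its neighbours' medians
  k <- 25
  mask[k] <- TRUE
  u[k] <- 1e6
  fld <- velocity_field(g$x, g$y, u, rep(0, n^2), mask = mask, spacing = h)
  out <- validate_vectors(fld)
  expect_true(all(out$valid[!out$mask]))
  expect_equal(out$u_mps[out$mask], 1e6)  # untouched
})
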