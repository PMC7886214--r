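#' Render a synthetic tracer-particle image pair
#'
#' Seeds tracer particles uniformly over the frame, renders them as 2D
#' Gaussian blobs (e^-2 intensity diameter = `particle_diameter`), advects
#' each particle by the local velocity over `frame_interval`, and renders the
#' second exposure. Particles leaving the frame between exposures are simply
#' not drawn in the second frame; no new particles are injected. Optional
#' additive Gaussian gray-level noise is drawn independently per frame.
#'
#' Pixel/physical coordinate contract: continuous pixel coordinates run
#' `px in [0, ncol]`, `py in [0, nrow]` with the origin at the top-left pixel
#' corner and `py` increasing downward; physical coordinates are
#' `x = px * magnification`, `y = (nrow - py) * magnification`, so the
#' physical y axis points up and a positive `v` moves particles toward
#' smaller row indices.
#'
#' @param field A [velocity_field()] sampled on the imaged domain; velocities
#'   are interpolated bilinearly at particle positions (clamped at the grid
#'   edge).
#' @param imaging An [imaging_spec()].
#' @return A `particle_image_pair`: list with numeric matrices `frame_a`,
#'   `frame_b` (gray levels in `[0, 1]`), `magnification`, `frame_interval`
#'   and the `imaging` spec.
#' @export
render_particle_pair <- function(field, imaging) {
  stopifnot(inherits(imaging, "imaging_spec"))
  m <- field_matrices(field)
  h <- imaging$image_shape[1]; w <- imaging$image_shape[2]
  mag <- imaging$magnification; dt <- imaging$frame_interval

  dat <- withr::with_seed(imaging$seed, {
    n <- round(imaging$particle_density * h * w)
    list(px = stats::runif(n, 0, w), py = stats::runif(n, 0, h),
         noise_a = if (imaging$noise_sd > 0)
           stats::rnorm(h * w, 0, imaging$noise_sd) else NULL,
         noise_b = if (imaging$noise_sd > 0)
           stats::rnorm(h * w, 0, imaging$noise_sd) else NULL)
  })
  x_phys <- dat$px * mag
  y_phys <- (h - dat$py) * mag
  u <- bilinear_interp(m$x, m$y, m$u, x_phys, y_phys)
  v <- bilinear_interp(m$x, m$y, m$v, x_phys, y_phys)
  dx <- u * dt / mag
  dy <- -v * dt / mag
  disp <- sqrt(dx^2 + dy^2)
  if (any(disp > imaging$max_displacement_px * (1 + 1e-9))) {
    stop(sprintf(
      "maximum particle displacement %.2f px exceeds the %.2f px limit (quarter of the final interrogation window)",
      max(disp), imaging$max_displacement_px), call. = FALSE)
  }

  sigma <- imaging$particle_diameter / 4  # e^-2 radius = diameter/2
  frame_a <- render_particles(dat$px, dat$py, h, w, sigma, imaging$intensity)
  frame_b <- render_particles(dat$px + dx, dat$py + dy, h, w, sigma,
                              imaging$intensity)
  if (!is.null(dat$noise_a)) {
    frame_a <- frame_a + matrix(dat$noise_a, h, w)
    frame_b <- frame_b + matrix(dat$noise_b, h, w)
  }
  structure(list(frame_a = clamp01(frame_a), frame_b = clamp01(frame_b),
                 magnification = mag, frame_interval = dt,
                 imaging = imaging),
            class = "particle_image_pair")
}

clamp01 <- function(m) pmin(pmax(m, 0), 1)

# additive Gaussian-blob rendering; each particle touches a small patch only
render_particles <- function(px, py, h, w, sigma, intensity) {
  img <- matrix(0, h, w)
  r <- ceiling(3.5 * sigma)
  inside <- px > -r & px < w + r & py > -r & py < h + r
  px <- px[inside]; py <- py[inside]
  for (k in seq_along(px)) {
    # pixel (i, j) has centre (j - 0.5, i - 0.5) in continuous coordinates
    j0 <- max(1L, floor(px[k] - r)); j1 <- min(w, ceiling(px[k] + r))
    i0 <- max(1L, floor(py[k] - r)); i1 <- min(h, ceiling(py[k] + r))
    if (j0 > j1 || i0 > i1) next
    gx <- exp(-((j0:j1) - 0.5 - px[k])^2 / (2 * sigma^2))
    gy <- exp(-((i0:i1) - 0.5 - py[k])^2 / (2 * sigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + intensity * outer(gy, gx)
  }
  img
}

#' @export
print.particle_image_pair <- function(x, ...) {
  cat(sprintf("<particle_image_pair> %d x %d px, dt %.3g s, %.3g m/px\n",
              nrow(x$frame_a), ncol(x$frame_a), x$frame_interval,
              x$magnification))
  invisible(x)
}
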