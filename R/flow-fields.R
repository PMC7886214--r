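#' Sample a prescribed flow model on a grid
#'
#' Evaluates the kinematic flow model of a [flow_spec()] at the grid nodes
#' and returns a [velocity_field()]. Deterministic given the spec.
#'
#' @param spec A [flow_spec()].
#' @return A `velocity_field` tibble in m/s.
#' @examples
#' f <- make_flow_field(flow_spec("uniform", list(u = 0.3, v = 0)))
#' unique(f$u_mps)
#' @export
make_flow_field <- function(spec) {
  stopifnot(inherits(spec, "flow_spec"))
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]; h <- spec$grid_spacing
  xs <- (seq_len(nc) - 1) * h
  ys <- (seq_len(nr) - 1) * h
  g <- expand.grid(y_m = ys, x_m = xs, KEEP.OUT.ATTRS = FALSE)
  uv <- eval_flow_model(spec, g$x_m, g$y_m)
  mask <- if (is.null(spec$mask)) FALSE else {
    # spec$mask rows follow the matrix convention of field_matrices
    as.vector(spec$mask)
  }
  velocity_field(g$x_m, g$y_m, uv$u, uv$v, valid = TRUE, mask = mask,
                 spacing = h)
}

# evaluate the analytic model at arbitrary physical coordinates
eval_flow_model <- function(spec, x, y) {
  p <- spec$params
  h <- spec$grid_spacing
  xc <- (spec$grid_shape[2] - 1) * h / 2
  yc <- (spec$grid_shape[1] - 1) * h / 2
  switch(spec$model,
    uniform = list(u = rep(p$u %||% 0, length(x)),
                   v = rep(p$v %||% 0, length(x))),
    solid_rotation = {
      om <- p$omega %||% 1
      list(u = -om * (y - yc), v = om * (x - xc))
    },
    pure_shear = {
      g <- p$gamma %||% 1
      list(u = g * y, v = rep(0, length(x)))
    },
    lamb_oseen = {
      circ <- p$circulation %||% 1e-3
      rc <- p$core_radius %||% (6 * h)
      r2 <- (x - xc)^2 + (y - yc)^2
      # angular velocity vtheta/r, finite at r = 0
      f <- ifelse(r2 > 0,
                  circ / (2 * pi * r2) * (1 - exp(-r2 / rc^2)),
                  circ / (2 * pi * rc^2))
      list(u = -f * (y - yc), v = f * (x - xc))
    },
    transmitral_jet = {
      vp <- p$peak_velocity %||% 1
      sig <- (p$jet_width %||% (8 * h)) / 2
      xj <- (p$center_frac %||% 0.5) * (spec$grid_shape[2] - 1) * h
      list(u = rep(0, length(x)),
           v = -vp * exp(-((x - xj) / sig)^2))
    },
    stop("unknown flow model: ", spec$model, call. = FALSE)
  )
}

#' Generate one cycle of transmitral-jet velocity fields
#'
#' Builds a time series of jet fields whose amplitude follows the E/A
#' activation waveform of `beat`. The jet peak velocity is calibrated so that
#' the volume carried through an axisymmetric Gaussian orifice of scale
#' `sigma = jet_width/2` (flux `Q(t) = pi * sigma^2 * Vpeak(t)`) integrates to
#' the beat's stroke volume over one cycle.
#'
#' @param spec A [flow_spec()] with `model = "transmitral_jet"`; its
#'   `peak_velocity` entry is ignored (set by the stroke-volume calibration).
#' @param beat A [beat_spec()].
#' @param n_frames Number of frames per cycle (>= 2), at times
#'   `(0:(n-1)) / n * period`.
#' @param noise_sd Additive velocity noise, m/s (0 = none).
#' @param seed Integer seed for the noise (ignored when `noise_sd = 0`).
#' @return A `flow_series` tibble: columns `frame`, `t_s` plus the
#'   [velocity_field()] columns, with attributes `spacing_m`, `dims`,
#'   `cycle_period`, `beat`, `jet_sigma` and `v0` (calibrated peak velocity).
#' @export
make_flow_series <- function(spec, beat, n_frames = 100, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(spec, "flow_spec"), inherits(beat, "beat_spec"),
            n_frames >= 2, noise_sd >= 0)
  if (spec$model != "transmitral_jet") {
    stop("make_flow_series requires a 'transmitral_jet' flow model",
         call. = FALSE)
  }
  sigma <- (spec$params$jet_width %||% (8 * spec$grid_spacing)) / 2
  sv_m3 <- beat$stroke_volume * 1e-6
  v0 <- sv_m3 / (pi * sigma^2 * beat$period * ea_waveform_mean(beat))

  phases <- (seq_len(n_frames) - 1) / n_frames
  amps <- v0 * ea_waveform(phases, beat)
  base_spec <- spec
  base_spec$params$peak_velocity <- 1
  base <- make_flow_field(base_spec)

  frames <- purrr::map2(seq_len(n_frames), amps, function(k, a) {
    f <- base
    f$u_mps <- f$u_mps * a
    f$v_mps <- f$v_mps * a
    tibble::add_column(tibble::as_tibble(f),
                       frame = k, t_s = (k - 1) / n_frames * beat$period,
                       .before = 1)
  })
  out <- dplyr::bind_rows(frames)
  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      list(u = stats::rnorm(nrow(out), 0, noise_sd),
           v = stats::rnorm(nrow(out), 0, noise_sd))
    })
    out$u_mps <- out$u_mps + noise$u
    out$v_mps <- out$v_mps + noise$v
  }
  structure(out,
            spacing_m = attr(base, "spacing_m"),
            dims = attr(base, "dims"),
            cycle_period = beat$period,
            beat = beat, jet_sigma = sigma, v0 = v0,
            class = c("flow_series", class(out)))
}

#' Split a flow series into per-frame velocity fields
#'
#' @param series A `flow_series` from [make_flow_series()].
#' @return A list with `times` (s) and `fields` (list of [velocity_field()]).
#' @export
series_fields <- function(series) {
  stopifnot(inherits(series, "flow_series"))
  sp <- attr(series, "spacing_m")
  split_frames <- split(tibble::as_tibble(series), series$frame)
  times <- vapply(split_frames, function(d) d$t_s[1], numeric(1))
  fields <- purrr::map(split_frames, function(d) {
    velocity_field(d$x_m, d$y_m, d$u_mps, d$v_mps, d$valid, d$mask,
                   spacing = sp)
  })
  ord <- order(times)
  list(times = unname(times[ord]), fields = unname(fields[ord]))
}

#' Volume carried by a jet series over one cycle
#'
#' Measures the instantaneous inflow rate of each frame from the transverse
#' jet profile at the inlet row: for an axisymmetric Gaussian jet of scale
#' `sigma`, the volumetric flux is `Q = sigma * sqrt(pi)` times the line
#' integral of the inflow velocity across the jet,
#' `integral of (-v) dx`. The rate is integrated over the cycle with
#' periodic closure. Used to verify stroke-volume conservation.
#'
#' @param series A `flow_series`.
#' @return A list with `rate` (tibble `t_s`, `q_m3ps`) and `volume_ml`.
#' @export
integrated_inflow <- function(series) {
  stopifnot(inherits(series, "flow_series"))
  sigma <- attr(series, "jet_sigma")
  period <- attr(series, "cycle_period")
  inlet_y <- max(series$y_m)
  q <- series |>
    tibble::as_tibble() |>
    dplyr::filter(.data$y_m == inlet_y) |>
    dplyr::arrange(.data$t_s, .data$x_m) |>
    dplyr::group_by(.data$frame, .data$t_s) |>
    dplyr::summarise(
      q_m3ps = sigma * sqrt(pi) *
        max(trapz_integral(.data$x_m, pmax(-.data$v_mps, 0)), 0),
      .groups = "drop") |>
    dplyr::arrange(.data$t_s)
  tt <- c(q$t_s, period)
  qq <- c(q$q_m3ps, q$q_m3ps[1])
  list(rate = q, volume_ml = trapz_integral(tt, qq) * 1e6)
}

# trapezoidal integral (base building block used across the package)
trapz_integral <- function(t, y) {
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}
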