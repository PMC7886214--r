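#' Instantaneous viscous energy dissipation of a planar field
#'
#' Computes the planar viscous dissipation rate per unit out-of-plane depth,
#'
#' \deqn{VED = \frac{\mu}{2} \sum_{i,j \in \{1,2\}}
#'   \left(\frac{\partial u_i}{\partial x_j} +
#'         \frac{\partial u_j}{\partial x_i}\right)^2 \, dA,}
#'
#' summed over grid nodes with tensor-product trapezoidal cell weights
#' (`dA = spacing^2` at interior nodes, half/quarter cells at the grid
#' boundary, giving a second-order quadrature). Velocity gradients are
#' second-order central differences (one-sided second-order at boundaries and
#' next to masked/invalid nodes); nodes with fewer than two usable neighbours
#' along an axis are excluded from the integral. Expanding the ordered-pair
#' sum gives the standard 2D dissipation function
#' `2 mu (u_x^2 + v_y^2) + mu (u_y + v_x)^2`, which is what is evaluated;
#' the identity is asserted in the test suite. Units: W/m with velocities in
#' m/s, spacing in m and viscosity in Pa s.
#'
#' The quantity is a sum of squares of gradients, so it is non-negative,
#' invariant under adding any constant velocity (Galilean invariance), and
#' exactly zero for rigid motions (translation + rotation) on linear fields.
#'
#' @param field A [velocity_field()] with at least 3 x 3 nodes per axis.
#' @param fluid A [fluid_props()].
#' @return A single number, W/m. All-masked fields return 0 with a warning.
#' @export
ved_instant <- function(field, fluid = fluid_props()) {
  stopifnot(inherits(fluid, "fluid_props"))
  m <- field_matrices(field)
  if (nrow(m$u) < 3 || ncol(m$u) < 3) {
    stop("VED needs at least 3 nodes per axis", call. = FALSE)
  }
  ok <- m$valid & !m$mask & is.finite(m$u) & is.finite(m$v)
  if (!any(ok)) {
    warning("all nodes masked or invalid; VED = 0")
    return(0)
  }
  h <- m$spacing
  ux <- fd_gradient(m$u, h, ok, axis = "x")
  uy <- fd_gradient(m$u, h, ok, axis = "y")
  vx <- fd_gradient(m$v, h, ok, axis = "x")
  vy <- fd_gradient(m$v, h, ok, axis = "y")
  mu <- fluid$dynamic_viscosity
  phi <- 2 * mu * (ux^2 + vy^2) + mu * (uy + vx)^2
  use <- ok & is.finite(phi)
  # tensor-product trapezoidal weights: interior nodes carry a full cell
  # (spacing^2), grid-boundary nodes half/quarter cells, so the node sum is a
  # second-order quadrature of the dissipation density over the grid extent
  wx <- rep(1, ncol(phi)); wx[c(1, length(wx))] <- 0.5
  wy <- rep(1, nrow(phi)); wy[c(1, length(wy))] <- 0.5
  wgt <- outer(wy, wx) * h^2
  sum(phi[use] * wgt[use])
}

# validity-aware finite differences on a matrix (rows = ascending y,
# cols = ascending x). Central where both neighbours are usable, one-sided
# second-order otherwise, NA when neither stencil applies.
fd_gradient <- function(M, h, ok, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "y") return(t(fd_gradient(t(M), h, t(ok), "x")))
  nr <- nrow(M); nc <- ncol(M)
  pad <- function(mat, k) {
    # shift columns by k, NA-padding
    out <- matrix(NA_real_, nr, nc)
    src <- seq_len(nc) + k
    keep <- src >= 1 & src <= nc
    out[, keep] <- mat[, src[keep]]
    out
  }
  padl <- function(mat, k) {
    out <- matrix(FALSE, nr, nc)
    src <- seq_len(nc) + k
    keep <- src >= 1 & src <= nc
    out[, keep] <- mat[, src[keep]]
    out
  }
  Mm1 <- pad(M, -1L); Mp1 <- pad(M, 1L)
  Mm2 <- pad(M, -2L); Mp2 <- pad(M, 2L)
  Om1 <- padl(ok, -1L); Op1 <- padl(ok, 1L)
  Om2 <- padl(ok, -2L); Op2 <- padl(ok, 2L)
  g <- matrix(NA_real_, nr, nc)
  ctr <- Om1 & Op1
  fwd <- !ctr & Op1 & Op2
  bwd <- !ctr & !fwd & Om1 & Om2
  g[ctr] <- (Mp1[ctr] - Mm1[ctr]) / (2 * h)
  g[fwd] <- (-3 * M[fwd] + 4 * Mp1[fwd] - Mp2[fwd]) / (2 * h)
  g[bwd] <- (3 * M[bwd] - 4 * Mm1[bwd] + Mm2[bwd]) / (2 * h)
  g
}

#' VED time series of a field sequence
#'
#' Applies [ved_instant()] to each frame of a flow series (or list of
#' fields) and returns the temporal evolution of viscous energy dissipation.
#'
#' @param fields A `flow_series` tibble from [make_flow_series()] /
#'   [multipass_piv()] frames, or a list of [velocity_field()]s.
#' @param fluid A [fluid_props()].
#' @param times Frame times in s (required for a list of fields; taken from
#'   the series otherwise).
#' @param cycle_period Cycle period in s; defaults to the series attribute
#'   or, failing that, the time span of the frames.
#' @param condition Optional label (`"rest"` / `"exercise"`).
#' @return A `ved_series` tibble (`t_s`, `ved_W_per_m`) with attributes
#'   `cycle_period` and `condition`.
#' @export
ved_series <- function(fields, fluid = fluid_props(), times = NULL,
                       cycle_period = NULL, condition = NA_character_) {
  if (inherits(fields, "flow_series")) {
    cycle_period <- cycle_period %||% attr(fields, "cycle_period")
    sf <- series_fields(fields)
    times <- times %||% sf$times
    fields <- sf$fields
  }
  stopifnot(is.list(fields), length(fields) >= 2,
            !is.null(times), length(times) == length(fields))
  dims <- lapply(fields, function(f) attr(f, "dims"))
  if (length(unique(dims)) != 1) {
    stop("frames have mismatched grids", call. = FALSE)
  }
  ved <- vapply(fields, ved_instant, numeric(1), fluid = fluid)
  if (is.null(cycle_period)) {
    cycle_period <- diff(range(times)) + stats::median(diff(times))
  }
  new_ved_series(times, ved, cycle_period, condition)
}

new_ved_series <- function(t, ved, cycle_period, condition = NA_character_) {
  stopifnot(all(diff(t) > 0), all(ved >= 0), cycle_period > 0)
  structure(tibble::tibble(t_s = as.numeric(t), ved_W_per_m = as.numeric(ved)),
            cycle_period = cycle_period, condition = condition,
            class = c("ved_series", class(tibble::tibble())))
}

#' Total viscous energy dissipation over a fixed duration
#'
#' Trapezoidal time integral of a VED series over `[0, duration]` (the area
#' under the VED curve, J/m). When the requested duration exceeds the
#' recorded span the series is extended periodically by its cycle period, so
#' a 1 s total can be formed from a single cycle shorter than 1 s.
#'
#' @param series A `ved_series` covering at least one full cycle.
#' @param duration Integration duration in s (> 0), default 1.
#' @return Total dissipated energy per unit depth, J/m.
#' @export
tved <- function(series, duration = 1.0) {
  stopifnot(inherits(series, "ved_series"))
  if (duration <= 0) stop("duration must be positive", call. = FALSE)
  t <- series$t_s - series$t_s[1]
  v <- series$ved_W_per_m
  period <- attr(series, "cycle_period")
  dt_med <- stats::median(diff(t))
  if (max(t) + 1.5 * dt_med < period && max(t) < duration) {
    stop("series must cover at least one full cycle", call. = FALSE)
  }
  if (max(t) >= duration) {
    grid <- sort(unique(c(t[t <= duration], duration)))
    return(trapz_integral(grid, stats::approx(t, v, xout = grid)$y))
  }
  # periodic extension: wrap the sample times by the cycle period
  knots_one <- t[t < period]
  f_wrap <- function(tt) {
    stats::approx(c(knots_one, period), c(v[t < period], v[1]),
                  xout = tt %% period, rule = 2)$y
  }
  n_rep <- ceiling(duration / period) + 1L
  knots <- as.vector(outer(knots_one, (0:n_rep) * period, "+"))
  knots <- sort(unique(c(knots[knots <= duration], duration)))
  trapz_integral(knots, f_wrap(knots))
}

#' Detect the two VED peaks of a cycle
#'
#' Returns the maxima of a VED series restricted to two phase windows. The
#' defaults mirror the peak times of the duplicator experiments: the first
#' window `[0, 0.15]` of the cycle captures the early-cycle peak (the
#' remaining effect of the A-wave) and the second window `[0.45, 0.65]` the
#' E-wave peak. A window in which the series is monotone returns its endpoint
#' maximum with a warning.
#'
#' @param series A `ved_series`.
#' @param first_window,second_window Two-element phase intervals (fractions
#'   of the cycle period, within `[0, 1]`).
#' @return A `ved_peaks` tibble with one row per peak: `peak` (`"first"`,
#'   `"second"`), `value_W_per_m`, `time_s`, `window_start_s`, `window_end_s`.
#' @export
detect_peaks <- function(series, first_window = c(0, 0.15),
                         second_window = c(0.45, 0.65)) {
  stopifnot(inherits(series, "ved_series"))
  period <- attr(series, "cycle_period")
  one <- function(win, label) {
    stopifnot(length(win) == 2, win[1] < win[2], win[1] >= 0, win[2] <= 1)
    lo <- win[1] * period; hi <- win[2] * period
    sel <- series$t_s >= lo & series$t_s <= hi
    if (!any(sel)) stop("empty peak window [", lo, ", ", hi, "] s",
                        call. = FALSE)
    tt <- series$t_s[sel]; vv <- series$ved_W_per_m[sel]
    k <- which.max(vv)
    monotone <- length(vv) >= 3 &&
      (all(diff(vv) >= 0) || all(diff(vv) <= 0))
    if (monotone && (k == 1 || k == length(vv))) {
      warning("VED is monotone in the ", label,
              " window; endpoint maximum returned")
    }
    tibble::tibble(peak = label, value_W_per_m = vv[k], time_s = tt[k],
                   window_start_s = lo, window_end_s = hi)
  }
  out <- dplyr::bind_rows(one(first_window, "first"),
                          one(second_window, "second"))
  structure(out, cycle_period = period,
            class = c("ved_peaks", class(out)))
}

#' Replicate-consistency ANOVA of VED recordings
#'
#' One-way analysis of variance across repeated VED recordings of the same
#' condition, treating each recording as a group of VED samples: a small F
#' (large p) indicates that between-recording dispersion is no larger than
#' the within-recording variation, i.e. the replicates are consistent.
#'
#' @param recordings A list of at least two equal-length, time-aligned
#'   `ved_series` objects (or numeric vectors).
#' @return A `ved_anova` object; see [tidy.ved_anova()] / [glance.ved_anova()].
#' @export
anova_recordings <- function(recordings) {
  if (!is.list(recordings) || length(recordings) < 2) {
    stop("need at least two recordings", call. = FALSE)
  }
  vals <- purrr::map(recordings, function(r) {
    if (inherits(r, "ved_series") || is.data.frame(r)) r$ved_W_per_m else as.numeric(r)
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1) {
    stop("recordings must be equal length and time-aligned", call. = FALSE)
  }
  dat <- tibble::tibble(
    value = unlist(vals, use.names = FALSE),
    recording = factor(rep(seq_along(vals), times = lens))
  )
  fit <- stats::oneway.test(value ~ recording, data = dat, var.equal = TRUE)
  structure(list(statistic = unname(fit$statistic),
                 p.value = unname(fit$p.value),
                 df = unname(fit$parameter),
                 n_recordings = length(vals),
                 n_samples = lens[1],
                 data = dat),
            class = "ved_anova")
}

#' @export
print.ved_anova <- function(x, ...) {
  cat(sprintf(
    "<ved_anova> %d recordings x %d samples: F = %.4g, p = %.4g\n",
    x$n_recordings, x$n_samples, x$statistic, x$p.value))
  invisible(x)
}
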