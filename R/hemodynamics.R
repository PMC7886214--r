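#' Diastolic (transmitral filling) windows of a pressure-trace pair
#'
#' Finds the maximal time intervals during which the left-atrial pressure is
#' at or above the left-ventricular pressure (the transmitral filling
#' periods). Intervals shorter than `min_duration` are discarded as
#' crossover chatter. The traces must share a common clock; when the grids
#' differ, the LV trace is interpolated onto the LA times over the
#' overlapping range.
#'
#' @param la,lv `pressure_trace` tibbles (or data frames with `t_s`,
#'   `p_mmHg`).
#' @param min_duration Debounce duration in s (default 0.02 = 20 ms).
#' @return A tibble of intervals (`start_s`, `end_s`, `duration_s`).
#' @export
diastolic_windows <- function(la, lv, min_duration = 0.02) {
  al <- align_traces(la, lv)
  diff_p <- al$la - al$lv
  t <- al$t
  runs <- rle(diff_p >= 0)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  # refine window edges to the interpolated zero-crossing of (la - lv)
  cross_before <- function(s) {
    if (s == 1L) return(t[1])
    t[s - 1L] + (t[s] - t[s - 1L]) *
      (0 - diff_p[s - 1L]) / (diff_p[s] - diff_p[s - 1L])
  }
  cross_after <- function(e) {
    if (e == length(t)) return(t[length(t)])
    t[e] + (t[e + 1L] - t[e]) *
      (0 - diff_p[e]) / (diff_p[e + 1L] - diff_p[e])
  }
  out <- tibble::tibble(
    start_s = vapply(starts[keep], cross_before, numeric(1)),
    end_s = vapply(ends[keep], cross_after, numeric(1))
  ) |>
    dplyr::mutate(duration_s = .data$end_s - .data$start_s) |>
    dplyr::filter(.data$duration_s >= min_duration)
  out
}

align_traces <- function(la, lv) {
  stopifnot(all(c("t_s", "p_mmHg") %in% names(la)),
            all(c("t_s", "p_mmHg") %in% names(lv)))
  if (length(la$t_s) == length(lv$t_s) &&
      max(abs(la$t_s - lv$t_s)) < 1e-9) {
    return(list(t = la$t_s, la = la$p_mmHg, lv = lv$p_mmHg))
  }
  lo <- max(min(la$t_s), min(lv$t_s))
  hi <- min(max(la$t_s), max(lv$t_s))
  if (lo >= hi) stop("pressure traces do not overlap in time", call. = FALSE)
  sel <- la$t_s >= lo & la$t_s <= hi
  list(t = la$t_s[sel], la = la$p_mmHg[sel],
       lv = stats::approx(lv$t_s, lv$p_mmHg, xout = la$t_s[sel])$y)
}

#' Catheter-derived mean transmitral gradient
#'
#' Time-average of the LA-LV pressure difference over the union of the
#' diastolic filling windows: the trapezoidal integral of the difference
#' divided by the total window duration.
#'
#' @inheritParams diastolic_windows
#' @return Mean gradient in mmHg.
#' @export
catheter_mean_gradient <- function(la, lv, min_duration = 0.02) {
  wins <- diastolic_windows(la, lv, min_duration)
  if (nrow(wins) == 0) {
    stop("no diastolic window found (LA never reaches LV pressure)",
         call. = FALSE)
  }
  al <- align_traces(la, lv)
  diff_p <- al$la - al$lv
  num <- 0; den <- 0
  for (k in seq_len(nrow(wins))) {
    inner <- al$t[al$t > wins$start_s[k] & al$t < wins$end_s[k]]
    knots <- unique(c(wins$start_s[k], inner, wins$end_s[k]))
    vals <- stats::approx(al$t, diff_p, xout = knots)$y
    num <- num + trapz_integral(knots, vals)
    den <- den + wins$duration_s[k]
  }
  num / den
}

#' Doppler-derived mean transmitral gradient
#'
#' Converts a continuous-wave Doppler envelope to a mean gradient with the
#' simplified Bernoulli relation `dP = 4 v^2` (mmHg, v in m/s) and averages
#' it over the flow period: the trapezoidal time integral of `4 v^2` divided
#' by the flow duration. The flow period is the union of contiguous regions
#' of positive velocity (including their bounding zero samples) that contain
#' at least one sample above `threshold`; the threshold exists to reject
#' noise-only blips, while the zero-bounded extension keeps the time-mean
#' exact for envelopes that touch zero.
#'
#' @param env A `doppler_envelope` (or data frame with `t_s`, `v_mps`).
#' @param threshold Minimal peak velocity of a genuine flow region, m/s.
#' @return Mean gradient in mmHg.
#' @export
doppler_mean_gradient <- function(env, threshold = 0.05) {
  stopifnot(all(c("t_s", "v_mps") %in% names(env)))
  v <- env$v_mps; t <- env$t_s
  if (all(v <= 0)) stop("envelope is zero everywhere", call. = FALSE)
  pos <- v > 0
  runs <- rle(pos)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  num <- 0; den <- 0; any_run <- FALSE
  for (k in which(runs$values)) {
    if (max(v[starts[k]:ends[k]]) <= threshold) next
    i0 <- max(1L, starts[k] - 1L)       # bounding zero sample, if present
    i1 <- min(length(v), ends[k] + 1L)
    any_run <- TRUE
    num <- num + trapz_integral(t[i0:i1], 4 * v[i0:i1]^2)
    den <- den + (t[i1] - t[i0])
  }
  if (!any_run) stop("no flow region above the velocity threshold",
                     call. = FALSE)
  num / den
}

#' Mitral valve area by the Gorlin equation
#'
#' `MVA = 0.85 * CO / (44.3 * HR * FP * sqrt(MPG))` with cardiac output
#' `CO = HR * SV` in mL/min, heart rate `HR` in beats/min, diastolic flow
#' period `FP` in s/beat and mean pressure gradient `MPG` in mmHg; the result
#' is in cm^2. The hydraulic constant is 44.3 and 0.85 is the empirical
#' mitral correction factor. Vectorised over its inputs.
#'
#' @param heart_rate Beats per minute (> 0).
#' @param stroke_volume mL per beat (> 0).
#' @param flow_period Diastolic flow period, s per beat (> 0).
#' @param mean_gradient Mean transmitral gradient, mmHg (> 0).
#' @param constant Mitral empirical constant (default 0.85).
#' @param factor Gorlin hydraulic factor (default 44.3).
#' @return Valve area in cm^2.
#' @examples
#' gorlin_mva(70, 60.08, 0.465, 1.3) # ~2.2 cm^2
#' gorlin_mva(70, 60.08, 0.465, 3.2) # ~1.4 cm^2
#' @export
gorlin_mva <- function(heart_rate, stroke_volume, flow_period, mean_gradient,
                       constant = 0.85, factor = 44.3) {
  if (any(mean_gradient <= 0)) {
    stop("mean_gradient must be positive (square-root domain)", call. = FALSE)
  }
  stopifnot(all(heart_rate > 0), all(stroke_volume > 0),
            all(flow_period > 0), constant > 0, factor > 0)
  co <- heart_rate * stroke_volume  # mL/min
  constant * co / (factor * heart_rate * flow_period * sqrt(mean_gradient))
}
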