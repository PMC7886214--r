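#' Synthetic left-atrial and left-ventricular pressure traces
#'
#' Generates co-sampled LA and LV pressure traces (default 4 ms sampling) with
#' canonical piecewise-smooth morphology: a flat LV diastolic baseline with a
#' raised-cosine systolic peak (~120 mmHg), and an LA trace with a v-wave
#' during systole. The contractually meaningful part is the diastolic
#' difference: during the E and A filling lobes the LA exceeds the LV by
#' `diastolic_offset` on time-average, modulated by the activation waveform;
#' during diastasis the LA sits marginally below the LV (a brief physiologic
#' crossover), and during systole the LV far exceeds the LA.
#'
#' @param beat A [beat_spec()].
#' @param diastolic_offset Mean diastolic LA-LV gradient over the filling
#'   lobes, mmHg (>= 0).
#' @param noise_sd Additive Gaussian noise per trace, mmHg (>= 0).
#' @param seed Integer seed for the noise.
#' @param n_cycles Number of cardiac cycles recorded.
#' @param dt Sampling interval in s (default 0.004 = 4 ms).
#' @return A list with `la` and `lv`, each a `pressure_trace` tibble
#'   (`t_s`, `p_mmHg`, `site`).
#' @export
make_pressure_traces <- function(beat, diastolic_offset, noise_sd = 0,
                                 seed = 1L, n_cycles = 3, dt = 0.004) {
  stopifnot(inherits(beat, "beat_spec"), diastolic_offset >= 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  t <- seq(0, n_cycles * beat$period - dt / 2, by = dt)
  phase <- (t / beat$period) %% 1

  sys_span <- systole_span(beat)
  u <- span_progress(phase, sys_span)  # in [0,1] inside systole, NA outside
  lv_base <- 8
  lv <- lv_base + ifelse(is.na(u), 0, 112 * 0.5 * (1 - cos(2 * pi * u)))

  # diastolic LA-LV difference: half-sine lobes over the filling waves
  # (linear contact at the lobe edges, so the pressure crossover can be
  # located by interpolation), normalised to a time-mean of exactly
  # diastolic_offset over the lobe support
  p_e <- (beat$e_fraction + beat$a_fraction) /
    ((2 / pi) * (beat$e_fraction + beat$a_fraction / beat$ea_ratio))
  delta <- diastolic_offset *
    (p_e * half_sine_lobe(phase, beat$e_center, beat$e_fraction) +
       p_e / beat$ea_ratio *
         half_sine_lobe(phase, beat$a_center, beat$a_fraction))

  # diastasis: LA dips marginally below LV (scaled by the offset so that a
  # zero-offset beat has exactly equal diastolic pressures)
  dia_span <- diastasis_span(beat)
  ud <- span_progress(phase, dia_span)
  dip <- ifelse(is.na(ud), 0,
                0.3 * diastolic_offset * sin(pi * ud))

  la <- lv + delta - dip
  # LA's own systolic morphology: baseline + v-wave, capped strictly below
  # the LV by a half-sine gap whose edge slope is commensurate with the
  # lobes', keeping the crossover sharply defined
  la <- ifelse(is.na(u), la,
               pmin(lv - 1.8 * diastolic_offset * sin(pi * u),
                    lv_base + 2 + 4 * sin(pi * u)^2))

  if (noise_sd > 0) {
    noise <- withr::with_seed(as.integer(seed), {
      list(la = stats::rnorm(length(t), 0, noise_sd),
           lv = stats::rnorm(length(t), 0, noise_sd))
    })
    la <- la + noise$la
    lv <- lv + noise$lv
  }
  list(la = pressure_trace(t, la, "LA"), lv = pressure_trace(t, lv, "LV"))
}

# systole fills the gap between the end of the A lobe and the start of the E
# lobe; diastasis the gap between the end of the E lobe and the next A lobe
systole_span <- function(beat) {
  c(beat$a_center + beat$a_fraction / 2, beat$e_center - beat$e_fraction / 2)
}
diastasis_span <- function(beat) {
  c(beat$e_center + beat$e_fraction / 2, 1 + beat$a_center - beat$a_fraction / 2)
}

# progress through a phase span (possibly wrapping past 1); NA outside
span_progress <- function(phase, span) {
  p <- phase
  p[p < span[1]] <- p[p < span[1]] + 1
  out <- (p - span[1]) / (span[2] - span[1])
  out[out < 0 | out > 1] <- NA_real_
  out
}

#' Pressure trace constructor
#'
#' @param t Time in s, strictly increasing and uniformly sampled.
#' @param p Pressure in mmHg.
#' @param site `"LA"` or `"LV"`.
#' @return A `pressure_trace` tibble (`t_s`, `p_mmHg`, `site`).
#' @export
pressure_trace <- function(t, p, site = c("LA", "LV")) {
  site <- match.arg(site)
  stopifnot(length(t) == length(p), all(diff(t) > 0))
  structure(tibble::tibble(t_s = as.numeric(t), p_mmHg = as.numeric(p),
                           site = site),
            class = c("pressure_trace", class(tibble::tibble())))
}

#' Synthetic continuous-wave Doppler envelope
#'
#' Builds a maximal-velocity envelope across one cycle: half-sine E and A
#' lobes placed at the beat's filling-lobe spans, zero elsewhere. With
#' `constant_velocity` set, the envelope is instead constant at that velocity
#' over the whole contiguous diastolic interval (E lobe through the following
#' A lobe).
#'
#' @param beat A [beat_spec()].
#' @param e_peak,a_peak Peak lobe velocities, m/s (>= 0).
#' @param fs Sampling rate in Hz (>= 200).
#' @param constant_velocity Optional constant override, m/s.
#' @param n_cycles Number of cycles recorded.
#' @return A `doppler_envelope` tibble (`t_s`, `v_mps`).
#' @export
make_doppler_envelope <- function(beat, e_peak, a_peak, fs = 1000,
                                  constant_velocity = NULL, n_cycles = 1) {
  stopifnot(inherits(beat, "beat_spec"), e_peak >= 0, a_peak >= 0, fs >= 200)
  if (lobes_overlap(beat$e_center, beat$e_fraction,
                    beat$a_center, beat$a_fraction)) {
    stop("E and A lobes overlap", call. = FALSE)
  }
  t <- seq(0, n_cycles * beat$period - 1 / (2 * fs), by = 1 / fs)
  phase <- (t / beat$period) %% 1
  if (!is.null(constant_velocity)) {
    dia <- c(beat$e_center - beat$e_fraction / 2,
             1 + beat$a_center + beat$a_fraction / 2)
    u <- span_progress(phase, dia)
    v <- ifelse(is.na(u), 0, constant_velocity)
  } else {
    v <- e_peak * half_sine_lobe(phase, beat$e_center, beat$e_fraction) +
      a_peak * half_sine_lobe(phase, beat$a_center, beat$a_fraction)
  }
  doppler_envelope(t, v)
}

half_sine_lobe <- function(phase, center, width) {
  d <- ((phase - center + 0.5) %% 1) - 0.5
  ifelse(abs(d) <= width / 2, cos(pi * d / width), 0)
}

#' Doppler envelope constructor
#'
#' @param t Time in s, strictly increasing.
#' @param v Maximal velocity in m/s (>= 0).
#' @return A `doppler_envelope` tibble (`t_s`, `v_mps`).
#' @export
doppler_envelope <- function(t, v) {
  stopifnot(length(t) == length(v), all(diff(t) > 0), all(v >= 0))
  structure(tibble::tibble(t_s = as.numeric(t), v_mps = as.numeric(v)),
            class = c("doppler_envelope", class(tibble::tibble())))
}
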