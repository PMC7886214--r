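#' Beat specification for the pulse-duplicator cycle
#'
#' Describes one cardiac cycle of the left-heart duplicator: heart rate,
#' stroke volume, and the timing of the two diastolic filling waves. The
#' inflow-jet amplitude follows a two-lobed activation waveform built from
#' raised-cosine lobes: an atrial (A) lobe at the start of the recorded cycle
#' (its peak is the "remaining effect of the A-wave" seen in early-cycle VED)
#' and a passive-filling (E) lobe in the second half of the cycle.
#'
#' Phase is the cycle fraction in `[0, 1)`. The A lobe occupies
#' `[a_center - a_fraction/2, a_center + a_fraction/2]`, the E lobe likewise
#' around `e_center`; lobes must not overlap (circularly). `ea_ratio` is the
#' E:A peak-amplitude ratio of the jet waveform.
#'
#' @param condition `"rest"` (70 bpm, 60.08 mL) or `"exercise"` (110 bpm,
#'   90.13 mL), setting `heart_rate`/`stroke_volume` defaults; either may be
#'   overridden.
#' @param heart_rate Beats per minute (> 0).
#' @param stroke_volume Stroke volume in mL (> 0).
#' @param e_fraction,a_fraction Widths of the E and A lobes as fractions of the
#'   cycle, each in (0, 1).
#' @param e_center,a_center Phase of each lobe centre, in \[0, 1).
#' @param ea_ratio E:A peak amplitude ratio (> 0).
#' @return A `beat_spec` list with the fields above plus `period` (s).
#' @examples
#' beat_spec("rest")$period # 60/70
#' @export
beat_spec <- function(condition = c("rest", "exercise"),
                      heart_rate = NULL, stroke_volume = NULL,
                      e_fraction = 0.25, a_fraction = 1 / 6,
                      e_center = 0.55, a_center = 1 / 12,
                      ea_ratio = 1.8) {
  condition <- match.arg(condition)
  defaults <- list(rest = c(70, 60.08), exercise = c(110, 90.13))[[condition]]
  heart_rate <- heart_rate %||% defaults[1]
  stroke_volume <- stroke_volume %||% defaults[2]
  stopifnot(heart_rate > 0, stroke_volume > 0,
            e_fraction > 0, e_fraction < 1,
            a_fraction > 0, a_fraction < 1,
            ea_ratio > 0)
  if (lobes_overlap(e_center, e_fraction, a_center, a_fraction)) {
    stop("E and A lobes overlap; adjust centers/fractions", call. = FALSE)
  }
  structure(
    list(condition = condition,
         heart_rate = heart_rate, stroke_volume = stroke_volume,
         e_fraction = e_fraction, a_fraction = a_fraction,
         e_center = e_center, a_center = a_center,
         ea_ratio = ea_ratio,
         period = 60 / heart_rate),
    class = "beat_spec"
  )
}

# circular overlap test for two lobe intervals on [0,1)
lobes_overlap <- function(c1, w1, c2, w2) {
  d <- abs(((c1 - c2 + 0.5) %% 1) - 0.5)
  d < (w1 + w2) / 2
}

#' @export
print.beat_spec <- function(x, ...) {
  cat(sprintf("<beat_spec> %s: %.0f bpm, SV %.2f mL, period %.3f s\n",
              x$condition, x$heart_rate, x$stroke_volume, x$period))
  cat(sprintf("  E lobe: center %.3f width %.3f; A lobe: center %.3f width %.3f; E:A %.2f\n",
              x$e_center, x$e_fraction, x$a_center, x$a_fraction, x$ea_ratio))
  invisible(x)
}

#' Diastolic activation waveform
#'
#' Normalised jet-amplitude waveform of a beat: two raised-cosine lobes (E and
#' A) on the cycle phase, the E lobe with unit peak and the A lobe with peak
#' `1/ea_ratio`. Zero outside the lobes.
#'
#' @param phase Numeric vector of cycle phases (any real; used modulo 1).
#' @param beat A [beat_spec()].
#' @return Numeric vector of amplitudes in `[0, 1]`.
#' @export
ea_waveform <- function(phase, beat) {
  stopifnot(inherits(beat, "beat_spec"))
  raised_cosine_lobe(phase, beat$e_center, beat$e_fraction, 1) +
    raised_cosine_lobe(phase, beat$a_center, beat$a_fraction, 1 / beat$ea_ratio)
}

raised_cosine_lobe <- function(phase, center, width, amplitude) {
  d <- ((phase - center + 0.5) %% 1) - 0.5
  ifelse(abs(d) <= width / 2,
         amplitude * 0.5 * (1 + cos(2 * pi * d / width)),
         0)
}

# mean of the waveform over one full cycle (analytic: raised-cosine lobe
# integrates to width * amplitude / 2)
ea_waveform_mean <- function(beat) {
  0.5 * (beat$e_fraction + beat$a_fraction / beat$ea_ratio)
}

#' Working-fluid properties
#'
#' The blood analogue of the duplicator is a water/glycerol mixture; defaults
#' are its dynamic viscosity (4.2 cP = 0.0042 Pa s) and density (1100 kg/m^3).
#'
#' @param dynamic_viscosity Dynamic viscosity in Pa s (> 0).
#' @param density Density in kg/m^3 (> 0).
#' @return A `fluid_props` list.
#' @export
fluid_props <- function(dynamic_viscosity = 0.0042, density = 1100) {
  stopifnot(dynamic_viscosity > 0, density > 0)
  structure(list(dynamic_viscosity = dynamic_viscosity, density = density),
            class = "fluid_props")
}

#' Flow-field specification
#'
#' Kinematic prescriptions used as PIV and dissipation fixtures. Models:
#' \describe{
#'   \item{uniform}{constant `(u, v)`; params `u`, `v` (m/s).}
#'   \item{solid_rotation}{rigid rotation about the grid centre; param `omega`
#'     (rad/s). Zero strain rate, hence zero viscous dissipation.}
#'   \item{pure_shear}{`u = gamma * y`, `v = 0`; param `gamma` (1/s).}
#'   \item{lamb_oseen}{Lamb–Oseen vortex about the grid centre; params
#'     `circulation` (m^2/s) and `core_radius` (m). Smooth everywhere, with a
#'     closed-form dissipation density used as a convergence oracle.}
#'   \item{transmitral_jet}{a downward Gaussian jet entering from the top
#'     boundary: `v(x, y) = -peak_velocity * exp(-((x - xc)/sigma)^2)` with
#'     `sigma = jet_width/2` (the e^-1 full width is `jet_width`); params
#'     `peak_velocity` (m/s), `jet_width` (m), `center_frac` (jet centre as a
#'     fraction of the domain width, default 0.5).}
#' }
#'
#' @param model Model name (see Details).
#' @param params Named list of model parameters.
#' @param grid_shape `c(rows, cols)` node counts (>= 2 each).
#' @param grid_spacing Node spacing in m (> 0).
#' @param mask Optional logical matrix of `grid_shape`; `TRUE` marks nodes
#'   outside the region of interest (excluded from validation and integrals).
#' @return A `flow_spec` list.
#' @export
flow_spec <- function(model = c("uniform", "solid_rotation", "pure_shear",
                                "lamb_oseen", "transmitral_jet"),
                      params = list(), grid_shape = c(33, 33),
                      grid_spacing = 0.0025, mask = NULL) {
  model <- tryCatch(match.arg(model),
                    error = function(e) stop("unknown flow model: ", model[1],
                                             call. = FALSE))
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 2),
            grid_spacing > 0,
            all(vapply(params, function(p) all(is.finite(p)), logical(1))))
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), all(dim(mask) == grid_shape))
  }
  structure(list(model = model, params = params,
                 grid_shape = as.integer(grid_shape),
                 grid_spacing = grid_spacing, mask = mask),
            class = "flow_spec")
}

#' Synthetic imaging specification
#'
#' Parameters of the synthetic tracer-particle camera: geometry, optics and
#' seeding. Defaults mirror a high-speed PIV camera recording 1632 x 1200 px
#' at 1000 fps with ~50 um polyamide tracers; particle images are rendered as
#' 2D Gaussians whose e^-2 intensity diameter equals `particle_diameter`.
#'
#' @param image_shape `c(rows, cols)` in px.
#' @param magnification Object-plane size of one pixel, m/px (> 0).
#' @param frame_interval Time between the two frames of a pair, s (> 0).
#' @param particle_density Mean particles per px^2.
#' @param particle_diameter Particle image diameter in px (>= 1).
#' @param intensity Peak particle intensity on a 0–1 gray scale.
#' @param noise_sd Additive Gaussian gray-level noise (0–1 scale) per frame.
#' @param max_displacement_px Largest admissible inter-frame displacement, px;
#'   defaults to one quarter of a 16 px final interrogation window.
#' @param seed Integer seed used for particle positions and noise.
#' @return An `imaging_spec` list.
#' @export
imaging_spec <- function(image_shape = c(1200, 1632),
                         magnification = 1e-4,
                         frame_interval = 1e-3,
                         particle_density = 0.02,
                         particle_diameter = 3,
                         intensity = 0.85,
                         noise_sd = 0,
                         max_displacement_px = 4,
                         seed = 1L) {
  stopifnot(length(image_shape) == 2, all(image_shape >= 16),
            magnification > 0, frame_interval > 0,
            particle_density > 0, particle_diameter >= 1,
            intensity > 0, noise_sd >= 0, max_displacement_px > 0)
  structure(list(image_shape = as.integer(image_shape),
                 magnification = magnification,
                 frame_interval = frame_interval,
                 particle_density = particle_density,
                 particle_diameter = particle_diameter,
                 intensity = intensity,
                 noise_sd = noise_sd,
                 max_displacement_px = max_displacement_px,
                 seed = as.integer(seed)),
            class = "imaging_spec")
}

#' PIV processing configuration
#'
#' Multi-pass FFT cross-correlation parameters. Defaults follow the standard
#' coarse-to-fine scheme: an initial 64 x 64 px interrogation window refined
#' to a final 16 x 16 px window with 50% overlap, three-point Gaussian
#' subpixel peak fitting, and normalized-median vector validation.
#'
#' @param pass_windows Integer window sizes in px, powers of two, strictly
#'   decreasing; one pass per entry.
#' @param overlap_fraction Window overlap in `[0, 0.75]`.
#' @param subpixel `"gaussian3"` (default) or `"parabolic"`.
#' @param validation_threshold Normalized-median residual threshold.
#' @param validation_eps Noise floor of the normalized-median test, px.
#' @param magnification m/px used to convert displacements to velocities.
#' @param frame_interval Inter-frame time in s.
#' @return A `piv_config` list.
#' @export
piv_config <- function(pass_windows = c(64L, 16L),
                       overlap_fraction = 0.5,
                       subpixel = c("gaussian3", "parabolic"),
                       validation_threshold = 2,
                       validation_eps = 0.1,
                       magnification = 1e-4,
                       frame_interval = 1e-3) {
  subpixel <- match.arg(subpixel)
  pass_windows <- as.integer(pass_windows)
  pow2 <- all(bitwAnd(pass_windows, pass_windows - 1L) == 0L)
  stopifnot(length(pass_windows) >= 1, all(pass_windows >= 8),
            pow2, all(diff(pass_windows) < 0) || length(pass_windows) == 1,
            overlap_fraction >= 0, overlap_fraction <= 0.75,
            validation_threshold > 0, validation_eps > 0,
            magnification > 0, frame_interval > 0)
  structure(list(pass_windows = pass_windows,
                 overlap_fraction = overlap_fraction,
                 subpixel = subpixel,
                 validation_threshold = validation_threshold,
                 validation_eps = validation_eps,
                 magnification = magnification,
                 frame_interval = frame_interval),
            class = "piv_config")
}
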