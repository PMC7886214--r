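#' Configuration of one duplicator experiment cell
#'
#' Bundles every stage parameter of a simulated experiment: the condition
#' (rest or exercise), the valve (normal or with severe annular
#' calcification, "mac"), and the simulation/processing sizes. Per-cell
#' defaults:
#'
#' * effective orifice area: normal 2.2 cm^2 at rest, opening to 3.0 cm^2 at
#'   exercise (a compliant valve opens wider at higher flow); mac fixed at
#'   1.4 cm^2 (a calcified orifice is flow-independent).
#' * catheter diastolic offset: normal 1.3 / 5.0 mmHg (rest / exercise),
#'   mac 3.2 / 5.9 mmHg.
#' * Doppler mean gradient targets: normal 2.1 / 8.2 mmHg, mac 2.7 / 9.9
#'   mmHg (the generator solves lobe peak velocities to match).
#' * diastolic flow period 0.465 s at rest; unset at exercise, so no
#'   exercise valve area is computed.
#'
#' @param condition `"rest"` or `"exercise"`.
#' @param valve `"normal"` or `"mac"`.
#' @param seed Integer base seed; replicate seeds are derived by fixed
#'   increments.
#' @param output_dir Optional directory for run artifacts.
#' @param n_frames Velocity-field frames per cycle.
#' @param grid_shape Field grid nodes `c(rows, cols)`.
#' @param domain Physical side length of the imaged square domain, m.
#' @param use_piv If `TRUE`, velocity fields are re-measured from rendered
#'   particle images by [multipass_piv()]; if `FALSE` the prescribed fields
#'   are analysed directly.
#' @param image_shape Synthetic camera frame `c(rows, cols)`, px.
#' @param frame_interval Intra-pair exposure separation, s.
#' @param n_replicates Replicate recordings per cell (default 5).
#' @param field_noise_sd Per-node velocity jitter of the generator, m/s.
#' @param orifice_area_cm2,catheter_offset_mmhg,doppler_gradient_mmhg,flow_period_s
#'   Cell parameters; `NULL` picks the per-cell default above.
#' @param fluid A [fluid_props()].
#' @return A `run_config` list.
#' @export
run_config <- function(condition = c("rest", "exercise"),
                       valve = c("normal", "mac"),
                       seed = 1L, output_dir = NULL,
                       n_frames = 40, grid_shape = c(64, 64),
                       domain = 0.08, use_piv = FALSE,
                       image_shape = c(192, 192), frame_interval = 2e-4,
                       n_replicates = 5, field_noise_sd = 0.005,
                       orifice_area_cm2 = NULL,
                       catheter_offset_mmhg = NULL,
                       doppler_gradient_mmhg = NULL,
                       flow_period_s = NULL,
                       fluid = fluid_props()) {
  condition <- match.arg(condition)
  valve <- match.arg(valve)
  key <- paste(valve, condition, sep = ".")
  areas <- c(normal.rest = 2.2, normal.exercise = 3.0,
             mac.rest = 1.4, mac.exercise = 1.4)
  offsets <- c(normal.rest = 1.3, normal.exercise = 5.0,
               mac.rest = 3.2, mac.exercise = 5.9)
  dopplers <- c(normal.rest = 2.1, normal.exercise = 8.2,
                mac.rest = 2.7, mac.exercise = 9.9)
  orifice_area_cm2 <- orifice_area_cm2 %||% unname(areas[key])
  catheter_offset_mmhg <- catheter_offset_mmhg %||% unname(offsets[key])
  doppler_gradient_mmhg <- doppler_gradient_mmhg %||% unname(dopplers[key])
  if (is.null(flow_period_s)) {
    flow_period_s <- if (condition == "rest") 0.465 else NA_real_
  }
  stopifnot(n_frames >= 2, n_replicates >= 1, domain > 0,
            orifice_area_cm2 > 0, catheter_offset_mmhg >= 0,
            doppler_gradient_mmhg > 0, field_noise_sd >= 0)
  structure(list(condition = condition, valve = valve,
                 seed = as.integer(seed), output_dir = output_dir,
                 n_frames = as.integer(n_frames),
                 grid_shape = as.integer(grid_shape),
                 domain = domain, use_piv = isTRUE(use_piv),
                 image_shape = as.integer(image_shape),
                 frame_interval = frame_interval,
                 n_replicates = as.integer(n_replicates),
                 field_noise_sd = field_noise_sd,
                 orifice_area_cm2 = orifice_area_cm2,
                 catheter_offset_mmhg = catheter_offset_mmhg,
                 doppler_gradient_mmhg = doppler_gradient_mmhg,
                 flow_period_s = flow_period_s,
                 fluid = fluid),
            class = "run_config")
}

#' Run one simulated experiment cell end to end
#'
#' Executes simulate -> (optional PIV) -> VED -> hemodynamics for one
#' condition/valve cell: generates the jet velocity-field cycle, optionally
#' re-measures it from rendered particle images, computes the VED series,
#' its two peaks and the 1 s TVED per replicate, runs the replicate ANOVA,
#' generates pressure traces and a Doppler envelope and measures both mean
#' gradients, and (at rest, where the flow period is known) the Gorlin valve
#' area. Deterministic for a fixed config and seed; artifacts are written to
#' `config$output_dir` when set.
#'
#' @param config A [run_config()].
#' @return A `run_report` tibble (`metric`, `value`, `unit`) with the
#'   replicate TVEDs, the VED series of the first replicate and provenance
#'   (config hash, seed, package version) as attributes.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log_lines <<- c(log_lines,
                    sprintf("%s  %-10s done in %.2f s",
                            format(Sys.time(), "%Y-%m-%d %H:%M:%S"), name,
                            as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  beat <- beat_spec(config$condition)
  fluid <- config$fluid
  sigma <- sqrt(config$orifice_area_cm2 * 1e-4 / pi)
  spacing <- config$domain / (config$grid_shape[2] - 1)
  spec <- flow_spec("transmitral_jet",
                    params = list(jet_width = 2 * sigma, center_frac = 0.5),
                    grid_shape = config$grid_shape, grid_spacing = spacing)

  replicate_series <- stage("ved", {
    purrr::map(seq_len(config$n_replicates), function(r) {
      seed_r <- config$seed + (r - 1L) * 1000L
      series <- make_flow_series(spec, beat, config$n_frames,
                                 noise_sd = config$field_noise_sd,
                                 seed = seed_r)
      if (config$use_piv) {
        measured <- piv_measure_series(series, config, seed_r)
        ved_series(measured$fields, fluid, times = measured$times,
                   cycle_period = beat$period, condition = config$condition)
      } else {
        ved_series(series, fluid, condition = config$condition)
      }
    })
  })
  vs <- replicate_series[[1]]
  peaks <- detect_peaks(vs)
  tveds <- vapply(replicate_series, tved, numeric(1), duration = 1.0)
  rep_anova <- if (config$n_replicates >= 2) {
    anova_recordings(replicate_series)
  } else NULL

  hemo <- stage("hemodynamics", {
    traces <- make_pressure_traces(beat, config$catheter_offset_mmhg,
                                   noise_sd = 0, seed = config$seed)
    env <- make_doppler_envelope(
      beat,
      e_peak = doppler_peak_for_gradient(beat, config$doppler_gradient_mmhg),
      a_peak = doppler_peak_for_gradient(beat, config$doppler_gradient_mmhg) /
        beat$ea_ratio)
    cath <- catheter_mean_gradient(traces$la, traces$lv)
    dopp <- doppler_mean_gradient(env)
    mva <- if (is.finite(config$flow_period_s)) {
      gorlin_mva(beat$heart_rate, beat$stroke_volume,
                 config$flow_period_s, cath)
    } else NA_real_
    list(traces = traces, env = env, cath = cath, dopp = dopp, mva = mva)
  })

  report <- tibble::tribble(
    ~metric, ~value, ~unit,
    "condition", NA_real_, config$condition,
    "valve", NA_real_, config$valve,
    "mva_calculated", hemo$mva, "cm^2",
    "mean_gradient_catheter", hemo$cath, "mmHg",
    "mean_gradient_doppler", hemo$dopp, "mmHg",
    "ved_first_peak", peaks$value_W_per_m[1], "W/m",
    "ved_first_peak_time", peaks$time_s[1], "s",
    "ved_second_peak", peaks$value_W_per_m[2], "W/m",
    "ved_second_peak_time", peaks$time_s[2], "s",
    "tved", mean(tveds), "J/m",
    "anova_f", if (is.null(rep_anova)) NA_real_ else rep_anova$statistic, "",
    "anova_p", if (is.null(rep_anova)) NA_real_ else rep_anova$p.value, ""
  )
  report <- structure(report,
                      config = config,
                      seed = config$seed,
                      config_hash = rlang::hash(unclass(config)),
                      package_version = as.character(
                        utils::packageVersion("mitralflow")),
                      tved_replicates = tveds,
                      ved_series = vs,
                      class = c("run_report", class(report)))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$output_dir
    write_ved_csv(vs, file.path(od, "ved_series.csv"))
    write_trace_csv(hemo$traces$la, file.path(od, "la_pressure.csv"))
    write_trace_csv(hemo$traces$lv, file.path(od, "lv_pressure.csv"))
    write_envelope_csv(hemo$env, file.path(od, "doppler_envelope.csv"))
    readr::write_csv(tibble::as_tibble(report), file.path(od, "summary.csv"))
    write_run_config(config, file.path(od, "config.txt"))
    writeLines(log_lines, file.path(od, "run.log"))
  }
  report
}

# re-measure each frame of a flow series through imaging + PIV
piv_measure_series <- function(series, config, seed) {
  sf <- series_fields(series)
  mag <- config$domain / config$image_shape[2]
  cfg <- piv_config(magnification = mag,
                    frame_interval = config$frame_interval)
  fields <- purrr::imap(sf$fields, function(f, k) {
    im <- imaging_spec(image_shape = config$image_shape,
                       magnification = mag,
                       frame_interval = config$frame_interval,
                       seed = seed + 7L * as.integer(k))
    multipass_piv(render_particle_pair(f, im), cfg)
  })
  list(times = sf$times, fields = fields)
}

# peak lobe velocity whose half-sine E/A envelope has the requested
# time-mean 4 v^2 gradient over the flow period (a_peak = e_peak / ea_ratio;
# mean of sin^2 over a lobe = 1/2)
doppler_peak_for_gradient <- function(beat, gradient) {
  we <- beat$e_fraction; wa <- beat$a_fraction; r <- beat$ea_ratio
  sqrt(gradient * (we + wa) / (2 * (we + wa / r^2)))
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s valve, %s (seed %d, config %s)\n",
              x$unit[x$metric == "valve"], x$unit[x$metric == "condition"],
              attr(x, "seed"), substr(attr(x, "config_hash"), 1, 8)))
  NextMethod()
}

#' Compare experiment cells
#'
#' Side-by-side comparison of two runs (or two replicate groups of runs):
#' per-metric values, percent change from the first to the second, and --
#' when both sides carry replicate TVEDs -- a Welch t-test on TVED between
#' the groups.
#'
#' @param x,y `run_report` objects, or lists of replicate `run_report`s.
#' @return A `run_comparison` tibble (`metric`, `value_a`, `value_b`,
#'   `pct_change`) with the Welch test as attribute `tved_welch`.
#' @export
compare_conditions <- function(x, y) {
  xs <- if (inherits(x, "run_report")) list(x) else x
  ys <- if (inherits(y, "run_report")) list(y) else y
  stopifnot(length(xs) >= 1, length(ys) >= 1,
            all(purrr::map_lgl(c(xs, ys), inherits, "run_report")))
  schema <- xs[[1]]$metric
  ok <- purrr::every(c(xs, ys), function(r) identical(r$metric, schema))
  if (!ok) stop("reports do not share a schema", call. = FALSE)

  mean_values <- function(rs) {
    rowMeans(do.call(cbind, purrr::map(rs, "value")))
  }
  va <- mean_values(xs); vb <- mean_values(ys)
  out <- tibble::tibble(metric = schema, value_a = va, value_b = vb,
                        pct_change = ifelse(is.na(va) | va == 0, NA_real_,
                                            100 * (vb - va) / va))
  ta <- unlist(purrr::map(xs, ~ attr(.x, "tved_replicates")))
  tb <- unlist(purrr::map(ys, ~ attr(.x, "tved_replicates")))
  welch <- if (length(ta) >= 2 && length(tb) >= 2 &&
               (stats::sd(ta) > 0 || stats::sd(tb) > 0)) {
    stats::t.test(ta, tb)
  } else NULL
  structure(out, tved_welch = welch,
            class = c("run_comparison", class(out)))
}

#' Write / read a flat key:value run configuration
#'
#' @param config A [run_config()].
#' @param path Text file path.
#' @return `read_run_config()` returns a [run_config()].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  kv <- c(condition = config$condition, valve = config$valve,
          seed = config$seed, n_frames = config$n_frames,
          grid_rows = config$grid_shape[1], grid_cols = config$grid_shape[2],
          domain_m = config$domain, use_piv = config$use_piv,
          image_rows = config$image_shape[1],
          image_cols = config$image_shape[2],
          frame_interval_s = config$frame_interval,
          n_replicates = config$n_replicates,
          field_noise_sd_mps = config$field_noise_sd,
          orifice_area_cm2 = config$orifice_area_cm2,
          catheter_offset_mmhg = config$catheter_offset_mmhg,
          doppler_gradient_mmhg = config$doppler_gradient_mmhg,
          flow_period_s = config$flow_period_s,
          mu_pa_s = config$fluid$dynamic_viscosity,
          rho_kg_m3 = config$fluid$density)
  writeLines(sprintf("%s: %s", names(kv), unname(kv)), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- trimws(purrr::map_chr(kv, 1))
  vals <- trimws(purrr::map_chr(kv, ~ paste(.x[-1], collapse = ":")))
  g <- function(k) vals[match(k, keys)]
  num <- function(k) {
    v <- g(k)
    if (is.na(v) || identical(v, "NA")) NA_real_ else as.numeric(v)
  }
  run_config(condition = g("condition"), valve = g("valve"),
             seed = as.integer(num("seed")),
             n_frames = num("n_frames"),
             grid_shape = c(num("grid_rows"), num("grid_cols")),
             domain = num("domain_m"),
             use_piv = toupper(g("use_piv")) == "TRUE",
             image_shape = c(num("image_rows"), num("image_cols")),
             frame_interval = num("frame_interval_s"),
             n_replicates = num("n_replicates"),
             field_noise_sd = num("field_noise_sd_mps"),
             orifice_area_cm2 = num("orifice_area_cm2"),
             catheter_offset_mmhg = num("catheter_offset_mmhg"),
             doppler_gradient_mmhg = num("doppler_gradient_mmhg"),
             flow_period_s = num("flow_period_s"),
             fluid = fluid_props(num("mu_pa_s"), num("rho_kg_m3")))
}
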