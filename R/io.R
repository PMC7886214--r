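#' Read and write pipeline artifacts
#'
#' Delimited-text (comma) readers/writers for the package's tabular objects,
#' and grayscale TIFF output for synthetic particle images. Column contracts:
#' velocity fields `x_m, y_m, u_mps, v_mps, valid`; pressure traces
#' `t_s, p_mmHg`; Doppler envelopes `t_s, v_mps`; VED series
#' `t_s, ved_W_per_m`.
#'
#' @param field,trace,env,series,pair Objects to write.
#' @param path,path_a,path_b File paths.
#' @param site Trace site label used when reading (`"LA"` or `"LV"`).
#' @param bits TIFF bit depth, 8 or 16.
#' @param magnification,frame_interval Imaging metadata re-attached when
#'   reading an image pair.
#' @name mitralflow-io
NULL

#' @rdname mitralflow-io
#' @export
write_field_csv <- function(field, path) {
  out <- tibble::as_tibble(field)[, c("x_m", "y_m", "u_mps", "v_mps", "valid")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname mitralflow-io
#' @export
read_field_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  velocity_field(d$x_m, d$y_m, d$u_mps, d$v_mps,
                 valid = d$valid %||% TRUE, mask = FALSE)
}

#' @rdname mitralflow-io
#' @export
write_trace_csv <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace)[, c("t_s", "p_mmHg")], path)
  invisible(path)
}

#' @rdname mitralflow-io
#' @export
read_trace_csv <- function(path, site = c("LA", "LV")) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  pressure_trace(d$t_s, d$p_mmHg, match.arg(site))
}

#' @rdname mitralflow-io
#' @export
write_envelope_csv <- function(env, path) {
  readr::write_csv(tibble::as_tibble(env)[, c("t_s", "v_mps")], path)
  invisible(path)
}

#' @rdname mitralflow-io
#' @export
read_envelope_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  doppler_envelope(d$t_s, d$v_mps)
}

#' @rdname mitralflow-io
#' @export
write_ved_csv <- function(series, path) {
  readr::write_csv(tibble::as_tibble(series)[, c("t_s", "ved_W_per_m")], path)
  invisible(path)
}

#' @rdname mitralflow-io
#' @export
read_ved_csv <- function(path, cycle_period, condition = NA_character_) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  new_ved_series(d$t_s, d$ved_W_per_m, cycle_period, condition)
}

#' @rdname mitralflow-io
#' @export
write_image_pair_tiff <- function(pair, path_a, path_b, bits = 16) {
  stopifnot(bits %in% c(8, 16))
  tiff::writeTIFF(pair$frame_a, path_a, bits.per.sample = bits)
  tiff::writeTIFF(pair$frame_b, path_b, bits.per.sample = bits)
  invisible(c(path_a, path_b))
}

#' @rdname mitralflow-io
#' @export
read_image_pair <- function(path_a, path_b, magnification, frame_interval) {
  read_one <- function(p) {
    img <- tiff::readTIFF(p)
    if (length(dim(img)) == 3) img <- img[, , 1]
    img
  }
  structure(list(frame_a = read_one(path_a), frame_b = read_one(path_b),
                 magnification = magnification,
                 frame_interval = frame_interval,
                 imaging = NULL),
            class = "particle_image_pair")
}
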