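#' Broom-style tidiers
#'
#' `tidy()` returns one row per estimated quantity; `glance()` a one-row
#' model-level summary.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @name mitralflow-tidiers
NULL

#' @rdname mitralflow-tidiers
#' @export
tidy.ved_anova <- function(x, ...) {
  tibble::tibble(term = "recording",
                 statistic = x$statistic,
                 p.value = x$p.value,
                 df = x$df[1], df.residual = x$df[2])
}

#' @rdname mitralflow-tidiers
#' @export
glance.ved_anova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p.value,
                 n_recordings = x$n_recordings, n_samples = x$n_samples)
}

#' @rdname mitralflow-tidiers
#' @export
tidy.run_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname mitralflow-tidiers
#' @export
glance.run_report <- function(x, ...) {
  v <- function(m) x$value[x$metric == m]
  tibble::tibble(
    condition = x$unit[x$metric == "condition"],
    valve = x$unit[x$metric == "valve"],
    mva_cm2 = v("mva_calculated"),
    gradient_catheter_mmhg = v("mean_gradient_catheter"),
    gradient_doppler_mmhg = v("mean_gradient_doppler"),
    tved_J_per_m = v("tved"),
    n_replicates = length(attr(x, "tved_replicates")),
    seed = attr(x, "seed"),
    config_hash = attr(x, "config_hash")
  )
}

#' @rdname mitralflow-tidiers
#' @export
tidy.ved_peaks <- function(x, ...) {
  tibble::as_tibble(x)
}
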