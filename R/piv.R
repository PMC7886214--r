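#' Multi-pass FFT cross-correlation PIV
#'
#' Estimates the planar velocity field of a particle-image pair by coarse-to-
#' fine interrogation. Each pass tiles the first frame with interrogation
#' windows (spacing `window * (1 - overlap)`), offsets the corresponding
#' window of the second frame by the integer-rounded predictor from the
#' previous pass (discrete window shifting), cross-correlates the
#' mean-subtracted windows by FFT (zero-padded to twice the window to
#' suppress circular wrap-around), locates the correlation maximum within the
#' half-window search radius, refines it with a three-point subpixel fit, and
#' validates the vector field with the normalized-median test before it
#' serves as the next pass's predictor.
#'
#' Windows without image texture, or whose correlation peak falls on the
#' search border, are flagged invalid rather than raising an error; invalid
#' vectors are replaced by the median of their valid neighbours (and remain
#' flagged).
#'
#' @param pair A `particle_image_pair` (from [render_particle_pair()] or
#'   [read_image_pair()]).
#' @param config A [piv_config()]. Its `magnification`/`frame_interval`
#'   default to the pair's own values when the pair carries them.
#' @return A [velocity_field()] tibble; node coordinates follow the physical
#'   convention of [render_particle_pair()] (y up, so the sign of the row
#'   displacement is flipped when converting to `v`).
#' @export
multipass_piv <- function(pair, config = NULL) {
  stopifnot(inherits(pair, "particle_image_pair") ||
              (is.list(pair) && !is.null(pair$frame_a)))
  a <- pair$frame_a; b <- pair$frame_b
  if (!all(dim(a) == dim(b))) {
    stop("frames must have identical dimensions", call. = FALSE)
  }
  if (is.null(config)) config <- piv_config()
  mag <- pair$magnification %||% config$magnification
  dt <- pair$frame_interval %||% config$frame_interval
  h <- nrow(a); w <- ncol(a)

  prev <- NULL
  for (win in config$pass_windows) {
    step <- max(1L, as.integer(round(win * (1 - config$overlap_fraction))))
    nodes <- piv_nodes(h, w, win, step)
    pred <- predict_displacement(prev, nodes)
    res <- correlate_pass(a, b, nodes, win, pred, config$subpixel)
    res <- nmt_filter(res, nodes, config$validation_threshold,
                      config$validation_eps)
    prev <- list(nodes = nodes, dx = res$dx, dy = res$dy)
  }

  x <- rep(nodes$cx, each = nodes$nrn) * mag
  y <- rep((h - nodes$cy), times = nodes$ncn) * mag
  velocity_field(x = x, y = y,
                 u = as.vector(res$dx) * mag / dt,
                 v = -as.vector(res$dy) * mag / dt,
                 valid = as.vector(res$valid),
                 mask = FALSE, spacing = nodes$step * mag)
}

# node layout of one pass: window corners and centres (continuous px coords)
piv_nodes <- function(h, w, win, step) {
  nrn <- floor((h - win) / step) + 1L
  ncn <- floor((w - win) / step) + 1L
  if (nrn < 1 || ncn < 1) stop("image smaller than interrogation window",
                               call. = FALSE)
  r0 <- 1L + (seq_len(nrn) - 1L) * step
  c0 <- 1L + (seq_len(ncn) - 1L) * step
  list(r0 = r0, c0 = c0, nrn = nrn, ncn = ncn, win = win, step = step,
       cx = c0 + win / 2 - 0.5, cy = r0 + win / 2 - 0.5)
}

# interpolate the previous pass's displacement at the new node centres
predict_displacement <- function(prev, nodes) {
  zero <- list(dx = matrix(0, nodes$nrn, nodes$ncn),
               dy = matrix(0, nodes$nrn, nodes$ncn))
  if (is.null(prev)) return(zero)
  px <- prev$nodes$cx; py <- prev$nodes$cy
  gx <- rep(nodes$cx, each = nodes$nrn)
  gy <- rep(nodes$cy, times = nodes$ncn)
  dx <- bilinear_interp(px, py, prev$dx, gx, gy)
  dy <- bilinear_interp(px, py, prev$dy, gx, gy)
  list(dx = matrix(dx, nodes$nrn, nodes$ncn),
       dy = matrix(dy, nodes$nrn, nodes$ncn))
}

correlate_pass <- function(a, b, nodes, win, pred, subpixel) {
  h <- nrow(a); w <- ncol(a)
  n2 <- 2L * win
  search <- win / 2
  lag_of <- function(i) ((i - 1L + n2 / 2) %% n2) - n2 / 2
  # index positions in the padded correlation plane for lags -search..search
  lags <- -search:search
  idx <- (lags %% n2) + 1L
  # unbiased estimator: divide out the per-lag overlap area of the
  # zero-padded windows (removes the bias toward small displacements)
  overlap_norm <- outer(win - abs(lags), win - abs(lags))
  dx <- matrix(0, nodes$nrn, nodes$ncn)
  dy <- matrix(0, nodes$nrn, nodes$ncn)
  valid <- matrix(TRUE, nodes$nrn, nodes$ncn)
  for (i in seq_len(nodes$nrn)) {
    for (j in seq_len(nodes$ncn)) {
      r0 <- nodes$r0[i]; c0 <- nodes$c0[j]
      sx <- as.integer(round(pred$dx[i, j]))
      sy <- as.integer(round(pred$dy[i, j]))
      # clamp the shifted window of frame B inside the image
      sy <- min(max(sy, 1L - r0), h - win + 1L - r0)
      sx <- min(max(sx, 1L - c0), w - win + 1L - c0)
      wa <- a[r0:(r0 + win - 1L), c0:(c0 + win - 1L)]
      wb <- b[(r0 + sy):(r0 + sy + win - 1L), (c0 + sx):(c0 + sx + win - 1L)]
      if (stats::sd(wa) == 0 || stats::sd(wb) == 0) {
        valid[i, j] <- FALSE
        dx[i, j] <- sx; dy[i, j] <- sy
        next
      }
      cc <- xcorr_fft(wa, wb)
      sub <- cc[idx, idx] / overlap_norm
      pk <- arrayInd(which.max(sub), dim(sub))
      if (pk[1] == 1 || pk[1] == length(lags) ||
          pk[2] == 1 || pk[2] == length(lags)) {
        valid[i, j] <- FALSE
        dx[i, j] <- sx + lags[pk[2]]
        dy[i, j] <- sy + lags[pk[1]]
        next
      }
      off <- subpixel_offset_2d(sub, pk, subpixel, quiet = TRUE)
      dx[i, j] <- sx + lags[pk[2]] + off[1]
      dy[i, j] <- sy + lags[pk[1]] + off[2]
    }
  }
  list(dx = dx, dy = dy, valid = valid)
}

# circular cross-correlation C(dy, dx) = sum_a A(r, c) * B(r + dy, c + dx),
# mean-subtracted, zero-padded to 2x the window
xcorr_fft <- function(a, b) {
  n <- 2L * nrow(a)
  ap <- matrix(0, n, n); bp <- matrix(0, n, n)
  ap[seq_len(nrow(a)), seq_len(ncol(a))] <- a - mean(a)
  bp[seq_len(nrow(b)), seq_len(ncol(b))] <- b - mean(b)
  Re(stats::fft(Conj(stats::fft(ap)) * stats::fft(bp), inverse = TRUE)) / n^2
}

#' Subpixel refinement of a correlation peak
#'
#' Locates the integer maximum of a correlation plane and refines it with a
#' three-point fit per axis: a Gaussian fit on the log-values by default,
#' falling back to a parabolic fit (with a message) when any of the three
#' points is non-positive. The refined offset is at most 1 px per axis.
#'
#' @param corr_plane Numeric matrix (rows = y lag, cols = x lag).
#' @param method `"gaussian3"` or `"parabolic"`.
#' @return Named numeric vector `c(dx, dy)`: subpixel offsets of the peak
#'   from the plane's integer maximum (column and row directions).
#' @export
subpixel_peak <- function(corr_plane, method = c("gaussian3", "parabolic")) {
  method <- match.arg(method)
  stopifnot(is.matrix(corr_plane), all(dim(corr_plane) >= 3))
  pk <- arrayInd(which.max(corr_plane), dim(corr_plane))
  if (pk[1] == 1 || pk[1] == nrow(corr_plane) ||
      pk[2] == 1 || pk[2] == ncol(corr_plane)) {
    stop("correlation peak lies on the plane border; no subpixel fit possible",
         call. = FALSE)
  }
  off <- subpixel_offset_2d(corr_plane, pk, method)
  c(dx = off[1], dy = off[2])
}

subpixel_offset_2d <- function(cc, pk, method, quiet = FALSE) {
  ox <- three_point_fit(cc[pk[1], pk[2] - 1L], cc[pk[1], pk[2]],
                        cc[pk[1], pk[2] + 1L], method, quiet)
  oy <- three_point_fit(cc[pk[1] - 1L, pk[2]], cc[pk[1], pk[2]],
                        cc[pk[1] + 1L, pk[2]], method, quiet)
  c(ox, oy)
}

three_point_fit <- function(cm, c0, cp, method = "gaussian3", quiet = FALSE) {
  if (method == "gaussian3" && all(c(cm, c0, cp) > 0)) {
    lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- 2 * (lm_ - 2 * l0 + lp)
    if (den == 0) return(0)
    off <- (lm_ - lp) / den
  } else {
    if (method == "gaussian3" && !quiet) {
      message("non-positive correlation neighbours; parabolic fallback used")
    }
    den <- 2 * (cm - 2 * c0 + cp)
    if (den == 0) return(0)
    off <- (cm - cp) / den
  }
  max(min(off, 1), -1)
}

# normalized-median filtering of a pass result (displacement units: px)
nmt_filter <- function(res, nodes, threshold, eps) {
  flag <- nm_outliers(res$dx, res$valid, threshold, eps) |
    nm_outliers(res$dy, res$valid, threshold, eps)
  valid <- res$valid & !flag
  res$dx <- replace_invalid(res$dx, valid)
  res$dy <- replace_invalid(res$dy, valid)
  res$valid <- valid
  res
}

# 8-neighbour shifted copies of a matrix (NA-padded)
neighbour_stack <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  shifts <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
                 c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  arr <- array(NA_real_, c(nr, nc, 8))
  for (k in seq_along(shifts)) {
    dr <- shifts[[k]][1]; dc <- shifts[[k]][2]
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    arr[which(ok_r), which(ok_c), k] <- m[rs[ok_r], cs[ok_c]]
  }
  arr
}

# Westerweel-Scarano normalized median test on one displacement component
nm_outliers <- function(m, valid, threshold, eps) {
  mm <- m
  mm[!valid] <- NA_real_
  nb <- neighbour_stack(mm)
  med <- apply(nb, c(1, 2), stats::median, na.rm = TRUE)
  resid_nb <- abs(sweep(nb, c(1, 2), med, "-"))
  rm_ <- apply(resid_nb, c(1, 2), stats::median, na.rm = TRUE)
  norm_res <- abs(m - med) / (rm_ + eps)
  out <- norm_res > threshold
  out[is.na(out)] <- FALSE  # degenerate neighbourhoods: leave unchanged
  out
}

replace_invalid <- function(m, valid) {
  if (all(valid)) return(m)
  mm <- m
  mm[!valid] <- NA_real_
  nb <- neighbour_stack(mm)
  med <- apply(nb, c(1, 2), stats::median, na.rm = TRUE)
  bad <- !valid & !is.na(med)
  m[bad] <- med[bad]
  m
}

#' Normalized-median vector validation
#'
#' Applies the normalized-median test to a velocity field: each node's
#' velocity is compared with the median of its 8-neighbourhood; nodes whose
#' normalized residual exceeds `threshold` (on either component) are flagged
#' invalid and replaced by the median of their valid neighbours. Masked nodes
#' are never used in medians and never altered. Nodes with no valid
#' neighbours are left unchanged and flagged.
#'
#' @param field A [velocity_field()] with at least 3 x 3 nodes.
#' @param threshold Normalized residual threshold (default 2).
#' @param eps Noise floor in velocity units; defaults to `0.1 * median
#'   absolute velocity` (the conventional 0.1 px applies when displacements
#'   are expressed in px).
#' @return The field with updated `u_mps`, `v_mps`, `valid`.
#' @export
validate_vectors <- function(field, threshold = 2, eps = NULL) {
  m <- field_matrices(field)
  if (nrow(m$u) < 3 || ncol(m$u) < 3) {
    stop("validation needs at least a 3 x 3 node grid", call. = FALSE)
  }
  if (is.null(eps)) {
    scale <- stats::median(abs(c(m$u, m$v)), na.rm = TRUE)
    eps <- 0.1 * max(scale, .Machine$double.eps)
  }
  ok <- m$valid & !m$mask
  flag <- nm_outliers(m$u, ok, threshold, eps) |
    nm_outliers(m$v, ok, threshold, eps)
  flag[m$mask] <- FALSE
  valid_new <- ok & !flag
  u <- replace_component(m$u, valid_new, flag)
  v <- replace_component(m$v, valid_new, flag)
  m$u <- u; m$v <- v
  m$valid <- m$valid & !flag
  matrices_to_field(m)
}

replace_component <- function(m, valid, flag) {
  mm <- m
  mm[!valid] <- NA_real_
  nb <- neighbour_stack(mm)
  med <- apply(nb, c(1, 2), stats::median, na.rm = TRUE)
  bad <- flag & !is.na(med)
  m[bad] <- med[bad]
  m
}
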