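#' Construct a velocity field tibble
#'
#' A `velocity_field` is a tibble with one row per grid node and columns
#' `x_m`, `y_m` (node coordinates, m; y points up), `u_mps`, `v_mps`
#' (velocity components, m/s), `valid` (post-validation flag) and `mask`
#' (`TRUE` = node outside the region of interest). Nodes lie on a uniform
#' grid; the spacing is carried as the `spacing_m` attribute and the grid
#' shape as `dims` (rows = distinct y, cols = distinct x).
#'
#' @param x,y Node coordinate vectors (m), one entry per node.
#' @param u,v Velocity components (m/s), one entry per node.
#' @param valid,mask Logical vectors (recycled if length 1).
#' @param spacing Grid spacing in m; inferred from coordinates when `NULL`.
#' @return A `velocity_field` tibble.
#' @export
velocity_field <- function(x, y, u, v, valid = TRUE, mask = FALSE,
                           spacing = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, length(u) == n, length(v) == n)
  fld <- tibble::tibble(
    x_m = as.numeric(x), y_m = as.numeric(y),
    u_mps = as.numeric(u), v_mps = as.numeric(v),
    valid = rep_len(as.logical(valid), n),
    mask = rep_len(as.logical(mask), n)
  )
  fld <- dplyr::arrange(fld, dplyr::desc(.data$y_m), .data$x_m)
  xs <- sort(unique(fld$x_m))
  ys <- sort(unique(fld$y_m))
  if (is.null(spacing)) {
    dx <- if (length(xs) > 1) diff(xs) else diff(ys)
    spacing <- stats::median(dx)
  }
  stopifnot(spacing > 0, length(xs) * length(ys) == n)
  structure(fld,
            spacing_m = spacing,
            dims = c(length(ys), length(xs)),
            class = c("velocity_field", class(fld)))
}

#' @export
print.velocity_field <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("<velocity_field> %d x %d nodes, spacing %.3g m, %d valid, %d masked\n",
              d[1], d[2], attr(x, "spacing_m"), sum(x$valid & !x$mask),
              sum(x$mask)))
  NextMethod()
}

# Internal: field tibble -> list of matrices with rows ordered by ascending y
# and cols by ascending x (row i of the matrix = i-th smallest y).
field_matrices <- function(field) {
  xs <- sort(unique(field$x_m))
  ys <- sort(unique(field$y_m))
  nr <- length(ys); nc <- length(xs)
  ix <- match(field$x_m, xs)
  iy <- match(field$y_m, ys)
  idx <- cbind(iy, ix)
  grab <- function(col) {
    m <- matrix(NA_real_, nr, nc)
    m[idx] <- field[[col]]
    m
  }
  grabl <- function(col) {
    m <- matrix(NA, nr, nc)
    m[idx] <- field[[col]]
    m
  }
  list(x = xs, y = ys,
       u = grab("u_mps"), v = grab("v_mps"),
       valid = grabl("valid"), mask = grabl("mask"),
       spacing = attr(field, "spacing_m") %||%
         stats::median(diff(if (nc > 1) xs else ys)))
}

matrices_to_field <- function(m) {
  grid <- expand.grid(y_m = m$y, x_m = m$x, KEEP.OUT.ATTRS = FALSE)
  velocity_field(x = grid$x_m, y = grid$y_m,
                 u = as.vector(m$u), v = as.vector(m$v),
                 valid = as.vector(m$valid), mask = as.vector(m$mask),
                 spacing = m$spacing)
}

# bilinear interpolation on a regular grid (clamped at the edges);
# xg, yg ascending, Z indexed [y, x]
bilinear_interp <- function(xg, yg, Z, x, y) {
  nx <- length(xg); ny <- length(yg)
  clamp <- function(v, lo, hi) pmin(pmax(v, lo), hi)
  x <- clamp(x, xg[1], xg[nx]); y <- clamp(y, yg[1], yg[ny])
  jx <- clamp(findInterval(x, xg), 1L, nx - 1L)
  jy <- clamp(findInterval(y, yg), 1L, ny - 1L)
  if (nx == 1) jx <- rep(1L, length(x))
  if (ny == 1) jy <- rep(1L, length(y))
  tx <- if (nx > 1) (x - xg[jx]) / (xg[jx + 1L] - xg[jx]) else 0
  ty <- if (ny > 1) (y - yg[jy]) / (yg[jy + 1L] - yg[jy]) else 0
  jx1 <- pmin(jx + 1L, nx); jy1 <- pmin(jy + 1L, ny)
  z00 <- Z[cbind(jy, jx)]; z01 <- Z[cbind(jy, jx1)]
  z10 <- Z[cbind(jy1, jx)]; z11 <- Z[cbind(jy1, jx1)]
  (1 - ty) * ((1 - tx) * z00 + tx * z01) + ty * ((1 - tx) * z10 + tx * z11)
}
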