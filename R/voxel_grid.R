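#' Create a voxel grid
#'
#' A `voxel_grid` holds one 3D scalar intensity field at one time step,
#' together with its physical voxel spacing. Arrays are indexed `[z, y, x]`
#' (0-based voxel indices in the coordinate helpers); physical positions are
#' `(x, y, z)` in micrometres under the centre-of-voxel convention
#' `physical = (index + 0.5) * spacing`.
#'
#' @param values 3D numeric array indexed `[z, y, x]`; finite, at least 3
#'   voxels per axis for any PDE operation.
#' @param spacing numeric length-3, voxel size `(sz, sy, sx)` in micrometres;
#'   all components must be positive.
#' @param t integer time index (>= 0).
#' @param channel `"nuclei"` or `"membranes"`.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(values, spacing, t = 0L, channel = c("nuclei", "membranes")) {
  channel <- match.arg(channel)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array indexed [z, y, x]", call. = FALSE)
  if (!all(is.finite(values)))
    stop("values must be finite", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (sz, sy, sx) in um", call. = FALSE)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  structure(list(values = values, spacing = spacing, t = as.integer(t),
                 channel = channel),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_grid> %d x %d x %d (z,y,x), spacing %.3g x %.3g x %.3g um, t=%d, channel=%s\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$t, x$channel))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

.check_pde_grid <- function(grid) {
  if (!inherits(grid, "voxel_grid")) stop("expected a voxel_grid", call. = FALSE)
  if (any(dim(grid$values) < 3L))
    stop("grid must have at least 3 voxels per axis for PDE operations", call. = FALSE)
  invisible(grid)
}

#' Convert voxel indices to physical coordinates
#'
#' Centre-of-voxel convention: `physical = (index + 0.5) * spacing`, with
#' array axis order `(z, y, x)` converted to physical `(x, y, z)`.
#'
#' @param voxel_index integer vector `(z, y, x)` (0-based) or a matrix with
#'   one such row per voxel.
#' @param spacing voxel size `(sz, sy, sx)` in micrometres.
#' @return Numeric vector `(x, y, z)` in micrometres (or a matrix of rows).
#' @export
to_physical <- function(voxel_index, spacing) {
  m <- if (is.matrix(voxel_index)) voxel_index else matrix(voxel_index, nrow = 1)
  out <- cbind(x = (m[, 3] + 0.5) * spacing[3],
               y = (m[, 2] + 0.5) * spacing[2],
               z = (m[, 1] + 0.5) * spacing[1])
  if (is.matrix(voxel_index)) out else out[1, ]
}

#' Convert physical coordinates to voxel indices
#'
#' Exact inverse of [to_physical()] on voxel centres; off-centre positions
#' map to the enclosing voxel.
#'
#' @param pos numeric `(x, y, z)` in micrometres, or a matrix of rows.
#' @param spacing voxel size `(sz, sy, sx)` in micrometres.
#' @return Integer `(z, y, x)` 0-based indices (vector or matrix).
#' @export
to_index <- function(pos, spacing) {
  m <- if (is.matrix(pos)) pos else matrix(pos, nrow = 1)
  out <- cbind(z = as.integer(floor(m[, 3] / spacing[1])),
               y = as.integer(floor(m[, 2] / spacing[2])),
               x = as.integer(floor(m[, 1] / spacing[3])))
  if (is.matrix(pos)) out else out[1, ]
}

# 1-based [z,y,x] array index for a physical (x,y,z) position, clamped to grid
.pos_to_rindex <- function(pos, grid) {
  d <- dim(grid$values)
  idx0 <- to_index(pos, grid$spacing)
  pmin(pmax(idx0 + 1L, 1L), d)
}

# Physical (x,y,z) coordinates of every voxel centre along each axis
.axis_coords <- function(n, h) (seq_len(n) - 0.5) * h
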