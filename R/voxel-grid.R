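#' Define a regular voxel grid
#'
#' A `voxel_grid` describes the common (atlas-like) space all stimulation
#' masks live on: the number of voxels per axis, the voxel size in mm, and
#' the world coordinate (mm) of the *center* of voxel `(0, 0, 0)`. Voxel
#' indices are 0-based and the world coordinate of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * voxel_size` (voxel-center convention).
#'
#' @param shape Integer vector of length 3: voxels per axis (all >= 1).
#' @param voxel_size Numeric vector of length 3 (or scalar): mm per axis,
#'   all > 0.
#' @param origin Numeric vector of length 3: world mm coordinate of the
#'   center of voxel (0,0,0). Default centers the grid on the world origin.
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(32, 32, 32), 1)
#' voxel_volume(g)
#' @export
voxel_grid <- function(shape, voxel_size = 1, origin = NULL) {
  shape <- as.integer(rep(shape, length.out = 3L))
  voxel_size <- as.numeric(rep(voxel_size, length.out = 3L))
  if (any(shape < 1L)) abort("all `shape` entries must be >= 1")
  if (any(voxel_size <= 0)) abort("all `voxel_size` entries must be > 0")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  origin <- as.numeric(rep(origin, length.out = 3L))
  structure(
    list(shape = shape, voxel_size = voxel_size, origin = origin),
    class = "voxel_grid"
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(
    "<voxel_grid> ", paste(x$shape, collapse = " x "),
    " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
    " mm, origin (", paste(signif(x$origin, 4), collapse = ", "), ") mm\n",
    sep = ""
  )
  invisible(x)
}

#' Voxel volume of a grid in mm^3
#' @param grid A [voxel_grid()].
#' @return Scalar volume of one voxel (mm^3).
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

n_voxels_total <- function(grid) prod(grid$shape)

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size - b$voxel_size) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

# 0-based (i,j,k) matrix -> 1-based linear index (column-major, like R arrays)
ijk_to_linear <- function(grid, ijk) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  as.integer(1 + ijk[, 1] + ijk[, 2] * nx + ijk[, 3] * nx * ny)
}

# 1-based linear index -> 0-based (i,j,k) matrix
linear_to_ijk <- function(grid, idx) {
  nx <- grid$shape[1]; ny <- grid$shape[2]
  z <- (idx - 1L) %/% (nx * ny)
  r <- (idx - 1L) %% (nx * ny)
  cbind(i = r %% nx, j = r %/% nx, k = z)
}

# world mm coordinates (matrix) of voxel centers for linear indices
voxel_centers <- function(grid, idx) {
  ijk <- linear_to_ijk(grid, idx)
  sweep(sweep(ijk, 2, grid$voxel_size, `*`), 2, grid$origin, `+`)
}

# world mm point -> nearest 0-based voxel index (unclamped)
world_to_ijk <- function(grid, point) {
  round((point - grid$origin) / grid$voxel_size)
}

point_in_grid <- function(grid, point) {
  ijk <- (point - grid$origin) / grid$voxel_size
  all(ijk >= -0.5) && all(ijk <= grid$shape - 0.5)
}
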