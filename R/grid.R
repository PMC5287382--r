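#' Voxel grid geometry
#'
#' Defines the regular 3D voxel lattice on which all volumes live. Coordinates
#' are physical millimetres at voxel centres, axis order (x, y, z), 0-based
#' voxel indices. The default matches a 0.5 mm isotropic acquisition.
#'
#' @param shape Integer vector of length 3: voxels per axis.
#' @param voxel_size Numeric vector of length 3: voxel edge lengths in mm.
#' @param origin Physical coordinate (mm) of the centre of voxel (0, 0, 0).
#'   The default centres the grid on (0, 0, 0).
#' @return An object of class `voxel_grid`.
#' @examples
#' g <- voxel_grid(c(64, 64, 64))
#' voxel_volume(g)  # 0.125 mm^3
#' @export
voxel_grid <- function(shape = c(64L, 64L, 64L),
                       voxel_size = c(0.5, 0.5, 0.5),
                       origin = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, length(voxel_size) == 3L)
  if (any(shape < 1L)) stop("all grid shape entries must be >= 1")
  if (any(voxel_size <= 0)) stop("all voxel_size entries must be > 0")
  if (is.null(origin)) origin <- -(shape - 1) / 2 * voxel_size
  stopifnot(length(origin) == 3L)
  structure(list(shape = shape, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "voxel_grid")
}

#' @rdname voxel_grid
#' @param grid A `voxel_grid`.
#' @export
voxel_volume <- function(grid) prod(grid$voxel_size)

#' Voxel-centre coordinates along one axis
#' @param grid A `voxel_grid`.
#' @param axis Axis index 1..3.
#' @return Numeric vector of physical coordinates (mm).
#' @export
axis_coords <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$voxel_size[axis]
}

# Squared distance (mm^2) from `point` to every voxel centre, as a 3D array.
grid_dist2 <- function(grid, point) {
  dx2 <- (axis_coords(grid, 1) - point[1])^2
  dy2 <- (axis_coords(grid, 2) - point[2])^2
  dz2 <- (axis_coords(grid, 3) - point[3])^2
  r2 <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  dim(r2) <- grid$shape
  r2
}

# Physical bounding box of the grid (voxel-centre extent), 2x3 matrix.
grid_bbox <- function(grid) {
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$voxel_size
  rbind(lo = pmin(lo, hi), hi = pmax(lo, hi))
}

point_in_grid <- function(grid, point) {
  bb <- grid_bbox(grid)
  all(point >= bb["lo", ] - grid$voxel_size / 2) &&
    all(point <= bb["hi", ] + grid$voxel_size / 2)
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}
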