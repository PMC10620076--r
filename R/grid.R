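#' Voxel grid descriptor
#'
#' A lightweight descriptor shared by every volume in a phantom: grid shape
#' in voxels, isotropic voxel edge in mm, and the world (RAS, mm) position of
#' the center of voxel (1,1,1).
#'
#' @param shape integer triple, voxels per axis.
#' @param spacing_mm positive scalar, isotropic voxel edge (mm).
#' @param origin_mm numeric triple, world coordinate of the first voxel center.
#' @return An object of class `vox_grid`.
#' @export
vox_grid <- function(shape, spacing_mm, origin_mm) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L),
            length(spacing_mm) == 1L, spacing_mm > 0,
            length(origin_mm) == 3L)
  structure(list(shape = shape, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "vox_grid")
}

#' @export
print.vox_grid <- function(x, ...) {
  cat(sprintf("<vox_grid %d x %d x %d @ %g mm, origin (%g, %g, %g) mm>\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing_mm,
              x$origin_mm[1], x$origin_mm[2], x$origin_mm[3]))
  invisible(x)
}

# Voxel-center world coordinates along each axis.
grid_axes <- function(grid) {
  lapply(1:3, function(a) grid$origin_mm[a] + (seq_len(grid$shape[a]) - 1L) * grid$spacing_mm)
}

# n x 3 matrix of world coordinates for given linear voxel indices (1-based).
grid_coords <- function(grid, idx) {
  ax <- grid_axes(grid)
  ijk <- arrayInd(idx, grid$shape)
  cbind(ax[[1]][ijk[, 1]], ax[[2]][ijk[, 2]], ax[[3]][ijk[, 3]])
}

# Squared distance of every voxel center to a world point; returned as an array.
grid_dist2 <- function(grid, point_mm) {
  ax <- grid_axes(grid)
  dx2 <- (ax[[1]] - point_mm[1])^2
  dy2 <- (ax[[2]] - point_mm[2])^2
  dz2 <- (ax[[3]] - point_mm[3])^2
  outer(outer(dx2, dy2, `+`), dz2, `+`)
}

#' Voxel volume in cubic millimetres
#' @param grid a [vox_grid()].
#' @return Scalar, mm^3 per voxel.
#' @export
voxel_volume_mm3 <- function(grid) grid$spacing_mm^3

grids_equal <- function(a, b, tol = 1e-9) {
  all(a$shape == b$shape) &&
    abs(a$spacing_mm - b$spacing_mm) <= tol &&
    all(abs(a$origin_mm - b$origin_mm) <= tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b)) stop("volumes are defined on different grids", call. = FALSE)
  invisible(TRUE)
}
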