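#' Write a volume as NIfTI-1
#'
#' Encodes the grid (isotropic spacing and origin, RAS axes) in the sform
#' affine. Logical masks are written as uint8, label volumes as int16, and
#' continuous volumes as float32.
#'
#' @param vol numeric/integer/logical 3-D array (or 4-D for vector fields).
#' @param grid the [vox_grid()] the volume lives on.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, grid, path) {
  stopifnot(inherits(grid, "vox_grid"))
  d <- dim(vol)
  stopifnot(length(d) %in% c(3L, 4L), all(d[1:3] == grid$shape))
  datatype <- if (is.logical(vol)) "uint8"
  else if (is.integer(vol)) "int16"
  else "float"
  storage.mode(vol) <- if (is.logical(vol)) "integer" else storage.mode(vol)
  img <- RNifti::asNifti(vol, datatype = datatype)
  aff <- diag(c(rep(grid$spacing_mm, 3), 1))
  aff[1:3, 4] <- grid$origin_mm
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI-1 volume written by [write_volume()]
#'
#' @param path input path.
#' @return List: `data` (array) and `grid` ([vox_grid()]). Fails with a
#'   format error for non-NIfTI or anisotropic/rotated files.
#' @export
read_volume <- function(path) {
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ", path,
                                           " (", conditionMessage(e), ")",
                                           call. = FALSE))
  aff <- RNifti::xform(img)
  sp <- aff[cbind(1:3, 1:3)]
  if (any(aff[1:3, 1:3][upper.tri(diag(3)) | lower.tri(diag(3))] != 0))
    stop("rotated affines are not supported", call. = FALSE)
  if (max(abs(sp - sp[1])) > 1e-6)
    stop("anisotropic voxels are not supported", call. = FALSE)
  data <- array(c(as.array(img)), dim = dim(img))  # plain array, no image attrs
  grid <- vox_grid(dim(data)[1:3], sp[1], aff[1:3, 4])
  list(data = data, grid = grid)
}

#' Round-trip a volume through NIfTI-1 on disk
#'
#' Write-then-read; voxel data come back exactly (within float32
#' representation for continuous data) with identical grid metadata.
#'
#' @param vol array to write.
#' @param grid its [vox_grid()].
#' @param path file path to use.
#' @return The re-read volume list (`data`, `grid`).
#' @export
volume_roundtrip <- function(vol, grid, path) {
  write_volume(vol, grid, path)
  back <- read_volume(path)
  stop_if_grid_mismatch(grid, back$grid)
  back
}

#' Export channel signals as CSV
#'
#' Two-column-per-channel time series `(t, ch1, ch2)`; intended for
#' inspection and downstream DAC tooling.
#'
#' @param signals a [synthesize()] result.
#' @param path output CSV path.
#' @param thin keep every `thin`-th sample (default 1, all samples).
#' @return Invisibly, `path`.
#' @export
write_signals_csv <- function(signals, path, thin = 1L) {
  stopifnot(inherits(signals, "channel_signals"), thin >= 1)
  idx <- seq(1, length(signals$t), by = thin)
  utils::write.csv(data.frame(t = signals$t[idx], ch1 = signals$ch1[idx],
                              ch2 = signals$ch2[idx]),
                   path, row.names = FALSE)
  invisible(path)
}
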