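#' Tissue codes used in phantom label volumes
#'
#' Integer codes for the six tissue classes plus air. The deep bilateral
#' target (a striatum stand-in) is carved out of the white-matter core.
#'
#' @return Named integer vector.
#' @export
tissue_codes <- function() {
  c(air = 0L, scalp = 1L, skull = 2L, csf = 3L,
    gray = 4L, white = 5L, deep = 6L)
}

#' Default tissue conductivities (S/m)
#'
#' Low-frequency conductivities typical of the quasistatic tES modeling
#' literature. Air is exactly 0 (non-conductive). All values can be
#' overridden through [phantom_config()].
#'
#' @return Named numeric vector (S/m).
#' @export
default_conductivities <- function() {
  c(air = 0, scalp = 0.4, skull = 0.01, csf = 1.79,
    gray = 0.28, white = 0.13, deep = 0.28)
}

#' Phantom configuration
#'
#' Parameters of the layered spherical head phantom: four strictly nested
#' shells (scalp, skull, CSF, brain), a gray/white split inside the brain,
#' and a bilateral deep spherical target embedded in the white matter.
#'
#' @param spacing_mm isotropic voxel edge, mm; must lie in `[1, 4]`.
#' @param radii_mm named numeric: outer radii of `scalp`, `skull`, `csf`,
#'   `brain` shells (mm), strictly decreasing inward.
#' @param white_radius_mm outer radius of the white-matter core (mm);
#'   gray matter is the shell between this and the brain radius.
#' @param conductivities named numeric (S/m) covering every tissue code;
#'   air must be 0, all tissues positive.
#' @param target_radius_mm radius of each deep target sphere (mm).
#' @param target_offset_mm numeric triple: the right target center relative
#'   to the head center (lateral, anterior, superior, mm); the left target
#'   mirrors it across the mid-sagittal plane.
#' @param margin_mm air margin added around the scalp sphere (mm).
#' @param head_center_mm world coordinate of the head center.
#' @param seed optional integer; only consumed by the (off by default)
#'   surface jitter, so the default phantom is fully deterministic.
#' @return A validated configuration list of class `phantom_config`.
#' @export
phantom_config <- function(spacing_mm = 2,
                           radii_mm = c(scalp = 92, skull = 86, csf = 80, brain = 78),
                           white_radius_mm = 68,
                           conductivities = default_conductivities(),
                           target_radius_mm = 12,
                           target_offset_mm = c(20, 5, 5),
                           margin_mm = 4,
                           head_center_mm = c(0, 0, 0),
                           seed = NULL) {
  if (!is.numeric(spacing_mm) || spacing_mm < 1 || spacing_mm > 4)
    stop("spacing_mm must lie in [1, 4]", call. = FALSE)
  need <- c("scalp", "skull", "csf", "brain")
  if (!all(need %in% names(radii_mm)))
    stop("radii_mm must name scalp, skull, csf and brain", call. = FALSE)
  r <- radii_mm[need]
  if (any(diff(r) >= 0))
    stop("shell radii must be strictly decreasing inward (scalp > skull > csf > brain)",
         call. = FALSE)
  if (white_radius_mm <= 0 || white_radius_mm >= r["brain"])
    stop("white_radius_mm must lie strictly inside the brain radius", call. = FALSE)
  cond_need <- names(tissue_codes())
  if (!all(cond_need %in% names(conductivities)))
    stop("conductivities must cover: ", paste(cond_need, collapse = ", "), call. = FALSE)
  if (conductivities[["air"]] != 0)
    stop("air conductivity must be exactly 0", call. = FALSE)
  if (any(conductivities[setdiff(cond_need, "air")] <= 0))
    stop("all tissue conductivities must be > 0", call. = FALSE)
  structure(list(spacing_mm = spacing_mm, radii_mm = r,
                 white_radius_mm = white_radius_mm,
                 conductivities = conductivities[cond_need],
                 target_radius_mm = target_radius_mm,
                 target_offset_mm = target_offset_mm,
                 margin_mm = margin_mm,
                 head_center_mm = head_center_mm,
                 seed = seed),
            class = "phantom_config")
}

#' Build the layered spherical head phantom
#'
#' Voxelizes strictly nested spherical shells (scalp, skull, CSF, brain with
#' gray shell / white core) plus a bilateral deep target on a regular RAS
#' grid. A voxel belongs to the innermost shell containing its center. The
#' grid has an odd voxel count per axis with the head center on a voxel
#' center, so the label volume is voxel-exactly mirror-symmetric about the
#' mid-sagittal plane.
#'
#' @param config a [phantom_config()].
#' @return Object of class `head_phantom`: `labels` (integer array),
#'   `grid` ([vox_grid()]), `conductivity_table`, `layer_radii_mm`,
#'   `head_center_mm`, and the originating `config`.
#' @export
build_phantom <- function(config = phantom_config()) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  sp <- config$spacing_mm
  r <- config$radii_mm
  half <- ceiling((r[["scalp"]] + config$margin_mm) / sp)
  n <- 2L * as.integer(half) + 1L
  origin <- config$head_center_mm - half * sp
  grid <- vox_grid(c(n, n, n), sp, origin)

  d2 <- grid_dist2(grid, config$head_center_mm)
  tc <- tissue_codes()
  labels <- array(tc[["air"]], dim = grid$shape)
  labels[d2 < r[["scalp"]]^2] <- tc[["scalp"]]
  labels[d2 < r[["skull"]]^2] <- tc[["skull"]]
  labels[d2 < r[["csf"]]^2]   <- tc[["csf"]]
  labels[d2 < r[["brain"]]^2] <- tc[["gray"]]
  labels[d2 < config$white_radius_mm^2] <- tc[["white"]]

  off <- config$target_offset_mm
  for (s in c(-1, 1)) {
    ctr <- config$head_center_mm + c(s * abs(off[1]), off[2], off[3])
    td2 <- grid_dist2(grid, ctr)
    inside <- td2 < config$target_radius_mm^2
    if (any(inside & labels == tc[["air"]]))
      stop("deep target extends outside the head", call. = FALSE)
    labels[inside] <- tc[["deep"]]
  }

  structure(list(labels = labels, grid = grid,
                 conductivity_table = config$conductivities,
                 layer_radii_mm = r,
                 head_center_mm = config$head_center_mm,
                 config = config),
            class = "head_phantom")
}

#' @export
print.head_phantom <- function(x, ...) {
  cat(sprintf("<head_phantom %d^3 voxels @ %g mm; radii %s mm; %d brain voxels>\n",
              x$grid$shape[1], x$grid$spacing_mm,
              paste(x$layer_radii_mm, collapse = "/"),
              sum(brain_mask(x))))
  invisible(x)
}

#' Per-voxel conductivity volume
#' @param phantom a [build_phantom()] result.
#' @return Numeric array (S/m) on the phantom grid.
#' @export
conductivity_volume <- function(phantom) {
  tc <- tissue_codes()
  sigma <- phantom$conductivity_table[match(phantom$labels, tc)]
  array(as.numeric(sigma), dim = phantom$grid$shape)
}

#' Brain mask (gray, white and deep-target voxels)
#' @param phantom a `head_phantom`.
#' @return Logical array.
#' @export
brain_mask <- function(phantom) {
  tc <- tissue_codes()
  array(phantom$labels %in% tc[c("gray", "white", "deep")], dim = phantom$grid$shape)
}

# ---- 10-10 electrode placement -------------------------------------------

# Built-in 10-10 label table (a placement convention, not an anatomical
# reconstruction): each label is defined by a sagittal row angle `a`
# (degrees from vertex, positive anterior) and a lateral column angle `b`
# (degrees from vertex, positive right). The scalp direction is
#   d = (sin b, cos b * sin a, cos b * cos a)   in RAS coordinates,
# which puts Cz at (0,0,1), keeps left/right homologs exactly
# mirror-symmetric about the mid-sagittal plane, and places the midline
# (z-suffixed) electrodes on the x = 0 great circle.
electrode_angle_table <- function() {
  rows <- c(Fp = 72, AF = 54, F = 36, FC = 18, C = 0,
            CP = -18, P = -36, PO = -54, O = -72)
  col_angle <- function(n) 18 * ceiling(n / 2) * ifelse(n %% 2 == 1, -1, 1)
  labs <- character(0); a <- numeric(0); b <- numeric(0)
  for (rn in names(rows)) {
    # midline
    labs <- c(labs, paste0(rn, "z")); a <- c(a, rows[[rn]]); b <- c(b, 0)
    for (n in 1:10) {
      lab <- paste0(rn, n)
      # conventional temporal-chain renames
      if (rn == "C"  && n %in% 7:10) lab <- paste0("T",  n)
      if (rn == "FC" && n %in% 7:10) lab <- paste0("FT", n)
      if (rn == "CP" && n %in% 7:10) lab <- paste0("TP", n)
      labs <- c(labs, lab); a <- c(a, rows[[rn]]); b <- c(b, col_angle(n))
    }
  }
  # polar landmarks
  labs <- c(labs, "Nz", "Iz"); a <- c(a, 90, -90); b <- c(b, 0, 0)
  data.frame(label = labs, row_deg = a, col_deg = b, stringsAsFactors = FALSE)
}

label_direction <- function(row_deg, col_deg) {
  a <- row_deg * pi / 180; b <- col_deg * pi / 180
  c(sin(b), cos(b) * sin(a), cos(b) * cos(a))
}

#' Electrode specifications from 10-10 labels
#'
#' Looks labels up in the built-in 10-10 angle table and returns, for each,
#' the unit direction from the head center to its scalp position. Left/right
#' homolog labels (F3/F4, TP7/TP8, ...) are exactly mirror-symmetric about
#' the mid-sagittal plane.
#'
#' @param labels character vector of 10-10 names (e.g. `"F3"`, `"Cz"`).
#' @param phantom a `head_phantom` (carries the scalp radius).
#' @param radius_mm electrode disc radius, mm (default 7, the compact
#'   modeling electrode; 9.8 matches the enlarged experimental electrode).
#' @return List of `electrode_spec` objects (`label`, `direction`,
#'   `radius_mm`).
#' @export
electrode_positions <- function(labels, phantom, radius_mm = 7) {
  stopifnot(radius_mm > 0)
  tab <- electrode_angle_table()
  unknown <- setdiff(labels, tab$label)
  if (length(unknown) > 0)
    stop("unknown electrode label(s): ", paste(unknown, collapse = ", "),
         "; known labels: ", paste(sort(tab$label), collapse = ", "), call. = FALSE)
  lapply(labels, function(lab) {
    i <- match(lab, tab$label)
    d <- label_direction(tab$row_deg[i], tab$col_deg[i])
    structure(list(label = lab, direction = d / sqrt(sum(d^2)),
                   radius_mm = radius_mm),
              class = "electrode_spec")
  })
}

#' Scalp patch voxels of an electrode
#'
#' The electrode contact is the set of outermost-scalp-shell voxels (scalp
#' voxels with at least one 6-neighbour of air) whose centers lie within the
#' electrode radius of the ray exit point `head_center + scalp_radius *
#' direction`.
#'
#' @param phantom a `head_phantom`.
#' @param electrode an `electrode_spec`.
#' @return Integer vector of linear voxel indices (1-based); never empty.
#' @export
electrode_patch <- function(phantom, electrode) {
  tc <- tissue_codes()
  lab <- phantom$labels
  outer_scalp <- lab == tc[["scalp"]] & has_air_neighbor(lab, tc[["air"]])
  exit <- phantom$head_center_mm + phantom$layer_radii_mm[["scalp"]] * electrode$direction
  d2 <- grid_dist2(phantom$grid, exit)
  idx <- which(outer_scalp & d2 <= electrode$radius_mm^2)
  if (length(idx) == 0)
    stop("empty electrode patch for ", electrode$label,
         " (radius too small for this grid spacing?)", call. = FALSE)
  idx
}

# Logical array: does any of the 6 face neighbours carry the given code?
# Out-of-grid counts as air.
has_air_neighbor <- function(labels, air_code) {
  d <- dim(labels)
  out <- array(FALSE, dim = d)
  pad <- function(arr, axis, from) {
    # neighbour value along an axis, padding with air at the boundary
    n <- d[axis]
    idx_src <- if (from > 0) c(2:n, NA) else c(NA, 1:(n - 1))
    perm <- switch(axis, `1` = arr[idx_src, , , drop = FALSE],
                   `2` = arr[, idx_src, , drop = FALSE],
                   `3` = arr[, , idx_src, drop = FALSE])
    perm[is.na(perm)] <- air_code
    perm
  }
  for (axis in 1:3) for (s in c(-1, 1))
    out <- out | (pad(labels, axis, s) == air_code)
  out
}

# ---- ROI construction -----------------------------------------------------

#' ROI configuration for [make_roi_set()]
#'
#' @param target_radius_mm radius of the deep target spheres (mm).
#' @param target_offset_mm right-target center offset from the head center
#'   (lateral, anterior, superior, mm); the left target mirrors it.
#' @param control_labels 10-10 labels under which superficial cortical
#'   control spheres are placed (default C3/C4, a precentral-gyrus
#'   stand-in).
#' @param control_radius_mm radius of each control sphere (mm).
#' @param control_depth_frac fractional radius (of the brain radius) at
#'   which control sphere centers sit along the electrode direction.
#' @return List of class `roi_config`.
#' @export
roi_config <- function(target_radius_mm = 12,
                       target_offset_mm = c(20, 5, 5),
                       control_labels = c("C3", "C4"),
                       control_radius_mm = 8,
                       control_depth_frac = 0.9) {
  structure(list(target_radius_mm = target_radius_mm,
                 target_offset_mm = target_offset_mm,
                 control_labels = control_labels,
                 control_radius_mm = control_radius_mm,
                 control_depth_frac = control_depth_frac),
            class = "roi_config")
}

# Spherical mask clipped to an allowed region; reports the clipped fraction.
clipped_sphere_mask <- function(grid, center_mm, radius_mm, allowed, name) {
  inside <- grid_dist2(grid, center_mm) <= radius_mm^2
  n_in <- sum(inside)
  if (n_in == 0) stop("ROI '", name, "' contains no voxel centers", call. = FALSE)
  mask <- inside & allowed
  clipped <- 1 - sum(mask) / n_in
  if (clipped > 0)
    warning(sprintf("ROI '%s': %.1f%% of its volume fell outside the brain and was clipped",
                    name, 100 * clipped), call. = FALSE)
  list(mask = mask, clipped_fraction = clipped)
}

#' Build the standard ROI set
#'
#' Produces the bilateral deep-target spheres (individually and combined),
#' superficial cortical control spheres under the configured electrode
#' labels, and the full brain mask. ROIs reaching outside the brain are
#' clipped with a warning and a reported clipped fraction.
#'
#' @param phantom a `head_phantom`.
#' @param config a [roi_config()].
#' @return Object of class `roi_set`: named `masks` (logical arrays),
#'   `roles` (target/control/brain), `clipped_fraction` per ROI.
#' @export
make_roi_set <- function(phantom, config = roi_config()) {
  if (!inherits(config, "roi_config")) config <- do.call(roi_config, config)
  brain <- brain_mask(phantom)
  grid <- phantom$grid
  masks <- list(); roles <- character(0); clipped <- numeric(0)

  off <- config$target_offset_mm
  for (side in c("left", "right")) {
    s <- if (side == "left") -1 else 1
    ctr <- phantom$head_center_mm + c(s * abs(off[1]), off[2], off[3])
    nm <- paste0("target_", side)
    cs <- clipped_sphere_mask(grid, ctr, config$target_radius_mm, brain, nm)
    masks[[nm]] <- cs$mask; roles[nm] <- "target"; clipped[nm] <- cs$clipped_fraction
  }
  masks[["target"]] <- masks[["target_left"]] | masks[["target_right"]]
  roles["target"] <- "target"; clipped["target"] <- max(clipped[c("target_left", "target_right")])

  electrodes <- electrode_positions(config$control_labels, phantom)
  rbrain <- phantom$layer_radii_mm[["brain"]]
  for (el in electrodes) {
    ctr <- phantom$head_center_mm + config$control_depth_frac * rbrain * el$direction
    nm <- paste0("control_", el$label)
    cs <- clipped_sphere_mask(grid, ctr, config$control_radius_mm, brain, nm)
    masks[[nm]] <- cs$mask; roles[nm] <- "control"; clipped[nm] <- cs$clipped_fraction
  }

  masks[["brain"]] <- brain
  roles["brain"] <- "brain"; clipped["brain"] <- 0

  structure(list(masks = masks, roles = roles, clipped_fraction = clipped,
                 grid = grid),
            class = "roi_set")
}

#' Brain sphere beneath an electrode
#'
#' Projects the electrode position inward along its ray and returns the
#' sphere of the given radius at the smallest depth for which the entire
#' sphere lies within the brain mask (the convention used for
#' under-electrode control ROIs).
#'
#' @param phantom a `head_phantom`.
#' @param electrode an `electrode_spec`.
#' @param radius_mm sphere radius, mm (default 10); must satisfy
#'   `2 * radius_mm < brain radius`.
#' @return Logical mask array; the chosen center is attached as attribute
#'   `center_mm` and its depth from the head center as `center_depth_mm`.
#' @export
sphere_under_electrode <- function(phantom, electrode, radius_mm = 10) {
  rbrain <- phantom$layer_radii_mm[["brain"]]
  if (2 * radius_mm >= rbrain)
    stop("sphere diameter must be smaller than the brain radius", call. = FALSE)
  brain <- brain_mask(phantom)
  grid <- phantom$grid
  step <- grid$spacing_mm / 4
  # depth measured from the scalp exit point inward
  depths <- seq(radius_mm, phantom$layer_radii_mm[["scalp"]], by = step)
  for (depth in depths) {
    ctr <- phantom$head_center_mm +
      (phantom$layer_radii_mm[["scalp"]] - depth) * electrode$direction
    inside <- grid_dist2(grid, ctr) <= radius_mm^2
    if (!any(inside)) next
    if (all(brain[inside])) {
      mask <- inside
      attr(mask, "center_mm") <- ctr
      attr(mask, "center_depth_mm") <- sqrt(sum((ctr - phantom$head_center_mm)^2))
      return(mask)
    }
  }
  stop("no depth admits full containment of the sphere in the brain (infeasible ROI)",
       call. = FALSE)
}
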