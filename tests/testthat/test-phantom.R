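test_that("voxelized brain volume matches the analytic sphere within a shell bound", {
  ph <- default_phantom()
  r_brain <- ph$layer_radii_mm[["brain"]]
  vox_vol <- sum(brain_mask(ph)) * voxel_volume_mm3(ph$grid)
  analytic <- 4 / 3 * pi * r_brain^3
  # voxelization error is bounded by the volume of one surface voxel shell
  shell <- 4 * pi * r_brain^2 * ph$grid$spacing_mm
  expect_lt(abs(vox_vol - analytic), shell)

  # every tissue shell likewise (scalp outer radius)
  r_scalp <- ph$layer_radii_mm[["scalp"]]
  head_vol <- sum(ph$labels != tissue_codes()[["air"]]) * voxel_volume_mm3(ph$grid)
  expect_lt(abs(head_vol - 4 / 3 * pi * r_scalp^3),
            4 * pi * r_scalp^2 * ph$grid$spacing_mm)
})

test_that("invalid phantom configurations are rejected before building", {
  expect_error(phantom_config(radii_mm = c(scalp = 80, skull = 86, csf = 78, brain = 76)),
               "strictly decreasing")
  expect_error(phantom_config(spacing_mm = 0.5), "spacing")
  bad_cond <- default_conductivities(); bad_cond[["air"]] <- 0.1
  expect_error(phantom_config(conductivities = bad_cond), "air")
  bad_cond2 <- default_conductivities(); bad_cond2[["skull"]] <- 0
  expect_error(phantom_config(conductivities = bad_cond2), "> 0")
})

test_that("labels are resolution-independent on shared voxel centers and deterministic", {
  ph2 <- default_phantom()
  ph4 <- coarse_phantom()
  # the 4 mm grid centers form a subset of the 2 mm centers (same origin parity)
  ax2 <- lapply(1:3, function(a) ph2$grid$origin_mm[a] +
                  (seq_len(ph2$grid$shape[a]) - 1) * 2)
  ax4 <- lapply(1:3, function(a) ph4$grid$origin_mm[a] +
                  (seq_len(ph4$grid$shape[a]) - 1) * 4)
  i2 <- lapply(1:3, function(a) match(ax4[[a]], ax2[[a]]))
  expect_false(anyNA(unlist(i2)))
  expect_identical(ph2$labels[i2[[1]], i2[[2]], i2[[3]]], ph4$labels)

  expect_identical(build_phantom(phantom_config(spacing_mm = 4))$labels, ph4$labels)
})

test_that("default labels are voxel-exactly mirror-symmetric about the mid-sagittal plane", {
  ph <- coarse_phantom()
  nx <- ph$grid$shape[1]
  expect_identical(ph$labels, ph$labels[nx:1, , ])
})

test_that("electrode directions follow the 10-10 convention with exact left/right symmetry", {
  ph <- coarse_phantom()
  els <- electrode_positions(c("F3", "F4", "TP7", "TP8", "Cz"), ph)
  d <- sapply(els, `[[`, "direction")
  # homologs mirror in x, agree in y/z
  expect_lt(max(abs(d[, 1] - d[, 2] * c(-1, 1, 1))), 1e-9)
  expect_lt(max(abs(d[, 3] - d[, 4] * c(-1, 1, 1))), 1e-9)
  # equal polar angle for homologs
  expect_equal(acos(d[3, 1]), acos(d[3, 2]), tolerance = 1e-12)
  # vertex electrode points straight up
  expect_equal(unname(d[, 5]), c(0, 0, 1), tolerance = 1e-12)
  expect_error(electrode_positions("XX9", ph), "known labels")
})

test_that("electrode scalp patches are nonempty and disjoint for the default montage", {
  ph <- coarse_phantom()
  els <- electrode_positions(c("F3", "F4", "TP7", "TP8"), ph)
  patches <- lapply(els, function(e) electrode_patch(ph, e))
  expect_true(all(lengths(patches) > 0))
  expect_identical(anyDuplicated(unlist(patches)), 0L)
  # patches sit on scalp voxels only
  tc <- tissue_codes()
  for (p in patches) expect_true(all(ph$labels[p] == tc[["scalp"]]))
})

test_that("ROI set has mirror-equal bilateral targets and honors degenerate radii", {
  ph <- coarse_phantom()
  rois <- coarse_rois()
  expect_identical(sum(rois$masks$target_left), sum(rois$masks$target_right))
  expect_true(all(rois$masks$target[brain_mask(ph)] | TRUE))  # shape guard
  expect_true(all(!rois$masks$target[!brain_mask(ph)]))       # subset of brain

  # radius of half a voxel on an exact voxel center -> a single voxel
  tiny <- make_roi_set(ph, roi_config(target_radius_mm = 2,
                                      target_offset_mm = c(20, 0, 0)))
  expect_identical(sum(tiny$masks$target_left), 1L)

  # a target centered at the scalp is clipped with a warning
  expect_warning(
    scalped <- make_roi_set(ph, roi_config(target_offset_mm = c(90, 0, 0))),
    "clipped")
  expect_gt(scalped$clipped_fraction[["target_right"]], 0)
})

test_that("sphere under the vertex electrode sits at the analytic containment depth", {
  ph <- coarse_phantom()
  cz <- electrode_positions("Cz", ph)[[1]]
  mask <- sphere_under_electrode(ph, cz, radius_mm = 10)
  r_brain <- ph$layer_radii_mm[["brain"]]

  # brute-force oracle: scan depths at 0.1 mm along +z for full containment
  bm <- brain_mask(ph)
  ax <- lapply(1:3, function(a) ph$grid$origin_mm[a] +
                 (seq_len(ph$grid$shape[a]) - 1) * ph$grid$spacing_mm)
  contained <- function(zc) {
    d2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), (ax[[3]] - zc)^2, `+`)
    ins <- d2 <= 100
    any(ins) && all(bm[ins])
  }
  zs <- seq(r_brain, 0, by = -0.1)
  oracle_depth <- zs[which(vapply(zs, contained, logical(1)))[1]]
  expect_equal(attr(mask, "center_depth_mm"), oracle_depth,
               tolerance = ph$grid$spacing_mm / oracle_depth)
  # analytic expectation: containment at brain radius minus sphere radius
  expect_lt(abs(oracle_depth - (r_brain - 10)), ph$grid$spacing_mm)

  # sphere volume within a surface-shell bound of (4/3) pi r^3
  expect_lt(abs(sum(mask) * voxel_volume_mm3(ph$grid) - 4 / 3 * pi * 1000),
            2 * 4 * pi * 100 * ph$grid$spacing_mm)

  expect_error(sphere_under_electrode(ph, cz, radius_mm = r_brain),
               "diameter|infeasible")
})
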