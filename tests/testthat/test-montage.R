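test_that("iso-percentile threshold follows the interpolated order statistic", {
  vals <- array(0, c(10, 10, 1))
  vals[1:100] <- 1:100
  mask <- array(TRUE, c(10, 10, 1))
  thr <- iso_percentile_threshold(vals, mask, 98)
  expect_equal(thr, 98.02)
  expect_identical(sum(vals > thr), 2L)

  const <- array(3.5, c(4, 4, 1))
  cmask <- array(TRUE, c(4, 4, 1))
  expect_equal(iso_percentile_threshold(const, cmask, 98), 3.5)
  expect_identical(sum(const > 3.5), 0L)

  v3 <- array(c(1, 2, 3), c(3, 1, 1))
  expect_equal(iso_percentile_threshold(v3, array(TRUE, c(3, 1, 1)), 50), 2)

  expect_error(iso_percentile_threshold(vals, array(FALSE, c(10, 10, 1))), "empty")
  expect_error(iso_percentile_threshold(vals, mask, 0), "p must")
})

test_that("exposure metrics equal a brute-force voxel recount on a seeded toy map", {
  set.seed(5)
  dims <- c(10, 10, 10)
  vals <- array(stats::rexp(prod(dims)), dims)
  brain <- array(stats::runif(prod(dims)) < 0.8, dims)
  target <- brain & array(stats::runif(prod(dims)) < 0.15, dims)
  target[1, 1, 1] <- brain[1, 1, 1] <- TRUE  # ensure nonempty
  met <- exposure_metrics(vals, target, brain, 98)

  # independent recount by exhaustive voxel iteration
  bv <- sort(vals[brain])
  n <- length(bv); h <- (n - 1) * 0.98 + 1
  thr <- bv[floor(h)] + (h - floor(h)) * (bv[floor(h) + 1] - bv[floor(h)])
  n_supra <- 0L; n_hit <- 0L; n_tgt <- 0L
  for (i in seq_len(prod(dims))) {
    if (!brain[i]) next
    if (target[i]) n_tgt <- n_tgt + 1L
    if (vals[i] > thr) {
      n_supra <- n_supra + 1L
      if (target[i]) n_hit <- n_hit + 1L
    }
  }
  expect_equal(met$threshold_V_per_m, thr)
  expect_identical(met$suprathreshold_brain_voxels, n_supra)
  expect_equal(met$focality_pct, 100 * n_hit / n_supra)
  expect_equal(met$activation_pct, 100 * n_hit / n_tgt)
  expect_equal(met$target_exposure[["mean"]], mean(vals[target]))
  expect_equal(met$target_exposure[["sd"]], stats::sd(vals[target]))

  # all suprathreshold voxels inside the target -> focality 100%
  # (median threshold sits among the 1-valued background voxels)
  vt <- array(0, dims); vt[target] <- 2; vt[brain & !target] <- 1
  met2 <- exposure_metrics(vt, target, brain, 50)
  expect_equal(met2$focality_pct, 100)

  # target disjoint from the suprathreshold set -> both ratios zero
  vd <- array(0, dims); vd[brain & !target] <- stats::runif(sum(brain & !target))
  met3 <- exposure_metrics(vd, target, brain, 98)
  expect_equal(met3$activation_pct, 0)
  expect_equal(met3$focality_pct, 0)

  # constant map: empty suprathreshold set -> NA focality sentinel
  met4 <- exposure_metrics(array(1, dims), target, brain, 98)
  expect_true(is.na(met4$focality_pct))
  expect_equal(met4$activation_pct, 0)
})

test_that("activation is non-increasing in the percentile", {
  set.seed(6)
  dims <- c(8, 8, 8)
  vals <- array(stats::runif(prod(dims)), dims)
  brain <- array(TRUE, dims)
  target <- array(FALSE, dims); target[3:6, 3:6, 3:6] <- TRUE
  act <- vapply(c(50, 70, 90, 95, 98, 99),
                function(p) exposure_metrics(vals, target, brain, p)$activation_pct,
                numeric(1))
  expect_true(all(diff(act) <= 0))
})

test_that("montage enumeration lists the symmetric pairings with their geometry", {
  ph <- coarse_phantom()
  els4 <- electrode_positions(c("F3", "F4", "TP7", "TP8"), ph)
  ms <- enumerate_montages(els4)
  expect_length(ms, 3)
  key <- vapply(ms, function(m)
    paste(sort(c(paste(sort(m$pair1), collapse = "-"),
                 paste(sort(m$pair2), collapse = "-"))), collapse = "+"),
    character(1))
  expect_setequal(key, c("F3-F4+TP7-TP8", "F3-TP7+F4-TP8", "F3-TP8+F4-TP7"))
  cls <- stats::setNames(vapply(ms, `[[`, "", "geometry_class"), key)
  expect_identical(cls[["F3-F4+TP7-TP8"]], "parallel-coronal")
  expect_identical(cls[["F3-TP7+F4-TP8"]], "parallel-sagittal")
  expect_identical(cls[["F3-TP8+F4-TP7"]], "crossing")

  expect_error(enumerate_montages(els4[1:3]), "at least 4")

  # closed-form count 3 * choose(P, 2) for P homolog pairs
  els6 <- electrode_positions(c("F3", "F4", "TP7", "TP8", "AF3", "AF4"), ph)
  ms6 <- enumerate_montages(els6)
  expect_length(ms6, 3 * choose(3, 2))
  # brute force: all distinct unordered 2-subsets of homolog pairs, 3 pairings each
  expect_identical(anyDuplicated(vapply(ms6, function(m)
    paste(sort(c(paste(sort(m$pair1), collapse = "-"),
                 paste(sort(m$pair2), collapse = "-"))), collapse = "+"),
    character(1))), 0L)
})

test_that("pareto flags equal an independent domination scan", {
  expect_identical(pareto_front(rbind(c(1, 1, 1), c(2, 2, 2))), c(FALSE, TRUE))
  expect_identical(pareto_front(rbind(c(2, 1, 1), c(1, 2, 1))), c(TRUE, TRUE))
  # equal vectors are all flagged
  expect_identical(pareto_front(rbind(c(1, 1, 1), c(1, 1, 1))), c(TRUE, TRUE))

  set.seed(9)
  rows <- matrix(stats::runif(150), ncol = 3)
  flags <- pareto_front(rows)
  # independent scan written with vectorized comparisons
  oracle <- vapply(seq_len(nrow(rows)), function(i) {
    ge <- rows >= matrix(rows[i, ], nrow(rows), 3, byrow = TRUE)
    gt <- rows > matrix(rows[i, ], nrow(rows), 3, byrow = TRUE)
    dominators <- rowSums(ge) == 3 & rowSums(gt) >= 1
    !any(dominators[-i])
  }, logical(1))
  expect_identical(flags, oracle)
})

test_that("montage sweep scores are deterministic and the front is non-dominated", {
  ph <- coarse_phantom()
  rois <- coarse_rois()
  els <- electrode_positions(c("F3", "F4", "TP7", "TP8"), ph)
  sw <- run_sweep(ph, rois, els, currents_mA = c(1, 1))
  expect_identical(nrow(sw), 3L)
  expect_false(any(sw$failed))
  expect_true(any(sw$pareto))
  obj <- as.matrix(sw[, c("target_median", "focality_pct", "activation_pct")])
  for (i in which(!sw$pareto)) {
    dominated <- vapply(which(sw$pareto), function(j)
      all(obj[j, ] >= obj[i, ]) && any(obj[j, ] > obj[i, ]), logical(1))
    expect_true(any(dominated))
  }

  # current-scaling invariance: thresholds/exposures scale, ratios and flags fixed
  sw2 <- run_sweep(ph, rois, els, currents_mA = c(2, 2))
  expect_equal(sw2$threshold_V_per_m, 2 * sw$threshold_V_per_m, tolerance = 1e-12)
  expect_equal(sw2$target_median, 2 * sw$target_median, tolerance = 1e-12)
  expect_equal(sw2$focality_pct, sw$focality_pct)
  expect_equal(sw2$activation_pct, sw$activation_pct)
  expect_identical(sw2$pareto, sw$pareto)
})
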