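test_that("envelope closed form reproduces hand-derived and degenerate cases", {
  # collinear: twice the weaker magnitude
  expect_equal(ti_envelope_point(c(1, 0, 0), c(0.5, 0, 0)), 1.0)
  # anti-parallel: the sign-flip convention makes it collinear
  expect_equal(ti_envelope_point(c(1, 0, 0), c(-0.5, 0, 0)), 1.0)
  # one absent channel: flat envelope
  expect_equal(ti_envelope_point(c(1, 0, 0), c(0, 0, 0)), 0)
  # oblique case, frozen from the direction-scan oracle at 1e6 directions
  expect_equal(ti_envelope_point(c(1, 0, 0), c(0, 0.3, 0)), 0.5747, tolerance = 1e-3)
  # orthogonal equal vectors: optimum along the bisector
  expect_equal(ti_envelope_point(c(1, 0, 0), c(0, 1, 0)), sqrt(2), tolerance = 1e-12)
})

test_that("closed form agrees with direction-scan and time-domain oracles on random pairs", {
  set.seed(42)
  for (i in 1:250) {
    E1 <- random_field_vector(); E2 <- random_field_vector()
    cf <- ti_envelope_point(E1, E2)
    ds <- directional_modulation_oracle(E1, E2, 1e6)
    expect_lt(abs(cf - ds) / cf, 1e-3)
    # the scan is a max over a subset of directions: never above the closed form
    expect_lte(ds, cf + 1e-12)
  }
  # time-domain beat envelope along the optimal scan direction
  set.seed(43)
  for (i in 1:25) {
    E1 <- random_field_vector(); E2 <- random_field_vector()
    n <- fibonacci_sphere(2e5)
    best <- n[which.max(2 * pmin(abs(n %*% E1), abs(n %*% E2))), ]
    cf <- ti_envelope_point(E1, E2)
    td <- timedomain_envelope_oracle(E1, E2, best, 2000, 2100, 50e3)
    expect_lt(abs(td - cf) / cf, 0.01)
  }
})

test_that("time-domain oracle obeys the beat identity and degenerate cases", {
  n <- c(1, 0, 0)
  expect_equal(timedomain_envelope_oracle(c(1, 0, 0), c(0.5, 0, 0), n,
                                          2000, 2100, 100e3), 1.0, tolerance = 0.01)
  # pure tone: flat envelope
  expect_lt(timedomain_envelope_oracle(c(1, 0, 0), c(0, 0, 0), n,
                                       2000, 2100, 100e3), 0.01)
  # equal carriers (HF control): flat envelope
  expect_lt(timedomain_envelope_oracle(c(1, 0, 0), c(0.5, 0, 0), n,
                                       2000, 2000, 100e3), 0.01)
  expect_error(timedomain_envelope_oracle(c(1, 0, 0), c(1, 0, 0), n,
                                          2000, 2100, 10e3), "undersampled")
})

test_that("envelope is bounded, exchange-symmetric and rotation-invariant", {
  set.seed(7)
  rot <- function(axis, th) {
    c1 <- cos(th); s1 <- sin(th)
    if (axis == 1) matrix(c(1, 0, 0, 0, c1, s1, 0, -s1, c1), 3)
    else if (axis == 2) matrix(c(c1, 0, -s1, 0, 1, 0, s1, 0, c1), 3)
    else matrix(c(c1, s1, 0, -s1, c1, 0, 0, 0, 1), 3)
  }
  for (i in 1:200) {
    E1 <- random_field_vector(); E2 <- random_field_vector()
    v <- ti_envelope_point(E1, E2)
    m1 <- sqrt(sum(E1^2)); m2 <- sqrt(sum(E2^2))
    expect_gte(v, 0)
    expect_lte(v, 2 * min(m1, m2) + 1e-12)
    expect_lte(2 * min(m1, m2), m1 + m2)
    expect_identical(v, ti_envelope_point(E2, E1))
    R <- rot(sample(3, 1), stats::runif(1, 0, 2 * pi))
    expect_equal(ti_envelope_point(as.numeric(R %*% E1), as.numeric(R %*% E2)),
                 v, tolerance = 1e-12)
  }
})

test_that("voxelwise map matches identities and the direction-scan oracle", {
  set.seed(11)
  dims <- c(5, 5, 5)
  grid <- vox_grid(dims, 2, c(0, 0, 0))
  mk_field <- function() {
    E <- array(stats::rnorm(prod(dims) * 3), dim = c(dims, 3))
    structure(list(E = E, grid = grid, normalization_mA = 1, channel_id = "t"),
              class = "vector_field")
  }
  f1 <- mk_field(); f2 <- mk_field()

  # identical channels: collinear everywhere, map = 2 * current * |E|
  same <- ti_envelope_map(f1, f1, 1.5, 1.5)
  expect_equal(same$values, 1.5 * 2 * field_magnitude(f1), tolerance = 1e-12)

  # joint current linearity, exact
  m11 <- ti_envelope_map(f1, f2, 1, 1)
  m22 <- ti_envelope_map(f1, f2, 2, 2)
  expect_identical(m22$values, m11$values * 2)

  # voxelwise agreement with the direction-scan oracle
  for (v in sample(prod(dims), 20)) {
    ij <- arrayInd(v, dims)
    E1 <- f1$E[ij[1], ij[2], ij[3], ]; E2 <- f2$E[ij[1], ij[2], ij[3], ]
    expect_equal(m11$values[ij[1], ij[2], ij[3]],
                 directional_modulation_oracle(E1, E2, 1e4),
                 tolerance = 1e-2)
  }

  # grid / normalization contract
  f_bad <- mk_field(); f_bad$normalization_mA <- 2
  expect_error(ti_envelope_map(f1, f_bad), "normalized")
  f_off <- mk_field(); f_off$grid <- vox_grid(dims, 3, c(0, 0, 0))
  expect_error(ti_envelope_map(f1, f_off), "different grids")
})

test_that("tDCS magnitude map equals the collinear TI identity", {
  set.seed(12)
  dims <- c(4, 4, 4)
  grid <- vox_grid(dims, 2, c(0, 0, 0))
  E <- array(stats::rnorm(prod(dims) * 3), dim = c(dims, 3))
  f <- structure(list(E = E, grid = grid, normalization_mA = 1, channel_id = "t"),
                 class = "vector_field")
  tdcs <- tdcs_magnitude_map(f, 2)
  expect_equal(tdcs$values, array(2 * sqrt(rowSums(matrix(E, nrow = prod(dims))^2)),
                                  dims), tolerance = 1e-12)
  expect_equal(tdcs$values, ti_envelope_map(f, f, 2, 2)$values / 2, tolerance = 1e-12)
  zero <- f; zero$E[] <- 0
  expect_true(all(tdcs_magnitude_map(zero, 2)$values == 0))
})
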