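# Shared fixtures, built once per test run and memoised across test files.
# The coarse (4 mm) phantom keeps per-pair solves around a second; the
# default 2 mm phantom is reserved for the acceptance checks that require it.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

coarse_phantom <- function() memo("coarse_phantom",
  build_phantom(phantom_config(spacing_mm = 4)))

default_phantom <- function() memo("default_phantom", build_phantom())

coarse_rois <- function() memo("coarse_rois", make_roi_set(coarse_phantom()))

coarse_solution <- function(anode, cathode, tol = 1e-8) {
  key <- paste0("sol_", anode, "_", cathode, "_", tol)
  memo(key, {
    ph <- coarse_phantom()
    els <- electrode_positions(c(anode, cathode), ph)
    solve_channel(ph, channel_pair(els[[1]], els[[2]]), tol = tol)
  })
}

default_solution <- function(anode, cathode) {
  key <- paste0("dsol_", anode, "_", cathode)
  memo(key, {
    ph <- default_phantom()
    els <- electrode_positions(c(anode, cathode), ph)
    solve_channel(ph, channel_pair(els[[1]], els[[2]]))
  })
}

default_trace <- function(mode = "tTIS") {
  key <- paste0("trace_", mode)
  memo(key, extract_envelope(synthesize(waveform_protocol(mode = mode))))
}

# Random vector with log-uniform magnitude in [1e-3, 1] (the regime used by
# the oracle-equivalence properties).
random_field_vector <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2)) * 10^stats::runif(1, -3, 0)
}

# Depth (mm) below the scalp surface of the brain-masked arg-max of a map.
argmax_depth_mm <- function(values, phantom) {
  bm <- brain_mask(phantom)
  v <- values
  v[!bm] <- -Inf
  ij <- arrayInd(which.max(v), dim(v))
  ax <- lapply(1:3, function(a)
    phantom$grid$origin_mm[a] + (seq_len(phantom$grid$shape[a]) - 1) *
      phantom$grid$spacing_mm)
  p <- c(ax[[1]][ij[1]], ax[[2]][ij[2]], ax[[3]][ij[3]])
  phantom$layer_radii_mm[["scalp"]] -
    sqrt(sum((p - phantom$head_center_mm)^2))
}

# Field magnitude array of a channel solution.
field_magnitude <- function(field) {
  dims <- dim(field$E)[1:3]
  array(sqrt(rowSums(matrix(field$E, nrow = prod(dims))^2)), dim = dims)
}
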