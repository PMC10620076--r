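#' Stimulation channel: one electrode pair
#'
#' @param anode,cathode `electrode_spec` objects (from
#'   [electrode_positions()]); must differ.
#' @param carrier_frequency_Hz carrier frequency of this channel (Hz). The
#'   quasistatic solve itself is frequency-independent in the low-kHz range
#'   (tissue dispersion is negligible there), so the frequency is metadata
#'   used by the interference and waveform stages.
#' @param current_mA channel current, peak-to-baseline, mA.
#' @return Object of class `channel_pair`.
#' @export
channel_pair <- function(anode, cathode, carrier_frequency_Hz = 2000, current_mA = 1) {
  stopifnot(inherits(anode, "electrode_spec"), inherits(cathode, "electrode_spec"))
  if (identical(anode$label, cathode$label))
    stop("anode and cathode must be different electrodes", call. = FALSE)
  if (!is.numeric(current_mA) || current_mA <= 0)
    stop("current_mA must be > 0", call. = FALSE)
  if (!is.numeric(carrier_frequency_Hz) || carrier_frequency_Hz <= 0)
    stop("carrier_frequency_Hz must be > 0", call. = FALSE)
  structure(list(anode = anode, cathode = cathode,
                 carrier_frequency_Hz = carrier_frequency_Hz,
                 current_mA = current_mA),
            class = "channel_pair")
}

#' Low-level quasistatic potential solve
#'
#' Discretizes `div(sigma grad phi) = 0` on a regular voxel grid with a
#' 7-point stencil and face-harmonic-mean conductivities, fixes the given
#' Dirichlet voxels, and solves the symmetric positive-definite system with
#' Jacobi-preconditioned conjugate gradients. Air voxels (`sigma = 0`) are
#' excluded; tissue/air faces carry no current (insulating boundary).
#'
#' @param sigma numeric array of conductivities (S/m).
#' @param spacing_mm isotropic voxel edge, mm.
#' @param dirichlet_idx integer linear voxel indices (1-based) with fixed
#'   potential.
#' @param dirichlet_val potentials (V) at those voxels.
#' @param tol relative residual tolerance, in `(0, 1e-3]`.
#' @param max_iter iteration cap; default `20 * N^(1/3) * 100` for `N` grid
#'   voxels.
#' @return List: `phi` (potential array, V), `iterations`,
#'   `relative_residual`, `converged`.
#' @export
solve_potential <- function(sigma, spacing_mm, dirichlet_idx, dirichlet_val,
                            tol = 1e-8, max_iter = NULL) {
  stopifnot(is.array(sigma), length(dim(sigma)) == 3L,
            length(dirichlet_idx) == length(dirichlet_val),
            length(dirichlet_idx) > 0)
  if (!is.numeric(tol) || tol <= 0 || tol > 1e-3)
    stop("tol must lie in (0, 1e-3]", call. = FALSE)
  dims <- dim(sigma)
  if (is.null(max_iter)) max_iter <- ceiling(20 * prod(dims)^(1 / 3) * 100)
  res <- pcg_solve_potential(as.numeric(sigma), as.integer(dims),
                             spacing_mm / 1000,
                             as.integer(dirichlet_idx) - 1L,
                             as.numeric(dirichlet_val),
                             tol, as.integer(max_iter))
  if (!res$converged)
    stop(sprintf("solver did not converge within %d iterations (relative residual %.3g)",
                 max_iter, res$relative_residual), call. = FALSE)
  res$phi <- array(res$phi, dim = dims)
  res
}

#' Solve one stimulation channel on a phantom
#'
#' Applies Dirichlet voltages +0.5 V / -0.5 V on the anode/cathode scalp
#' patches (ideal electrode contact), solves the quasistatic potential,
#' derives `E = -grad(phi)` (central differences in the interior, one-sided
#' at tissue/air boundaries, zero in air), computes the injected current as
#' the sum of ohmic face currents leaving the anode patch, and normalizes
#' potential and field to the channel current.
#'
#' @param phantom a `head_phantom`.
#' @param pair a [channel_pair()].
#' @param tol relative residual tolerance (default 1e-8).
#' @param max_iter optional iteration cap.
#' @param normalize if `TRUE` (default) rescale the solution to
#'   `pair$current_mA`; otherwise the raw Dirichlet solution is returned
#'   with `normalization_mA` equal to the injected current.
#' @return List of class `channel_solution`: `potential`
#'   (`potential_volume`), `field` (`vector_field`), `injected_current_mA`
#'   (at the +-0.5 V boundary), `anode_current_mA`, `cathode_current_mA`,
#'   `iterations`, `relative_residual`.
#' @export
solve_channel <- function(phantom, pair, tol = 1e-8, max_iter = NULL,
                          normalize = TRUE) {
  stopifnot(inherits(phantom, "head_phantom"), inherits(pair, "channel_pair"))
  sigma <- conductivity_volume(phantom)
  patch_a <- electrode_patch(phantom, pair$anode)
  patch_c <- electrode_patch(phantom, pair$cathode)
  if (length(intersect(patch_a, patch_c)) > 0)
    stop("anode and cathode patches overlap", call. = FALSE)

  res <- solve_potential(sigma, phantom$grid$spacing_mm,
                         c(patch_a, patch_c),
                         c(rep(0.5, length(patch_a)), rep(-0.5, length(patch_c))),
                         tol = tol, max_iter = max_iter)
  dims <- dim(sigma)
  h <- phantom$grid$spacing_mm / 1000
  E <- efield_from_potential(as.numeric(res$phi), as.numeric(sigma),
                             as.integer(dims), h)
  E <- array(E, dim = c(dims, 3L))
  I_a <- patch_current(as.numeric(res$phi), as.numeric(sigma),
                       as.integer(dims), h, as.integer(patch_a) - 1L)
  I_c <- patch_current(as.numeric(res$phi), as.numeric(sigma),
                       as.integer(dims), h, as.integer(patch_c) - 1L)
  injected_mA <- I_a * 1000
  if (injected_mA <= 0)
    stop("nonpositive injected current: solver failure", call. = FALSE)

  potential <- structure(list(phi = res$phi, grid = phantom$grid,
                              patches = list(anode = patch_a, cathode = patch_c),
                              voltages = c(anode = 0.5, cathode = -0.5)),
                         class = "potential_volume")
  field <- structure(list(E = E, grid = phantom$grid,
                          normalization_mA = injected_mA,
                          channel_id = paste0(pair$anode$label, "-", pair$cathode$label)),
                     class = "vector_field")
  sol <- list(potential = potential, field = field,
              injected_current_mA = injected_mA,
              anode_current_mA = I_a * 1000,
              cathode_current_mA = -I_c * 1000,
              iterations = res$iterations,
              relative_residual = res$relative_residual)
  if (normalize) {
    ns <- normalize_current(potential, field, injected_mA, pair$current_mA)
    sol$potential <- ns$potential
    sol$field <- ns$field
  }
  class(sol) <- "channel_solution"
  sol
}

#' Rescale a solved channel to a target injected current
#'
#' The quasistatic problem is linear, so scaling the Dirichlet solution by
#' `target / injected` yields the solution at the target current exactly.
#'
#' @param potential a `potential_volume`.
#' @param field the matching `vector_field`.
#' @param injected_current_mA current injected by the unscaled solution
#'   (mA); must be > 0.
#' @param target_current_mA desired current (mA).
#' @return List with rescaled `potential` and `field`;
#'   `field$normalization_mA` becomes `target_current_mA`.
#' @export
normalize_current <- function(potential, field, injected_current_mA,
                              target_current_mA) {
  if (!is.numeric(injected_current_mA) || injected_current_mA <= 0)
    stop("injected current must be > 0 (solver failure upstream?)", call. = FALSE)
  s <- target_current_mA / injected_current_mA
  potential$phi <- potential$phi * s
  potential$voltages <- potential$voltages * s
  field$E <- field$E * s
  field$normalization_mA <- target_current_mA
  list(potential = potential, field = field)
}

#' Parallel-plate slab field oracle
#'
#' Closed-form field magnitude `V / d` of a uniform-conductivity slab with
#' full-face plate electrodes held `V` volts apart at separation `d`.
#' Used as an independent check of the finite-difference solver.
#'
#' @param V voltage difference (V).
#' @param d plate separation (m); must be > 0.
#' @return Field magnitude, V/m.
#' @export
slab_oracle <- function(V, d) {
  if (!is.numeric(d) || d <= 0) stop("plate separation d must be > 0", call. = FALSE)
  V / d
}

#' Axis potential of a homogeneous conducting sphere (series oracle)
#'
#' Truncated Legendre-series solution for two antipodal point current
#' electrodes (source `+I` at the north pole, sink `-I` at the south pole)
#' on the surface of an insulated homogeneous sphere of radius `R` and
#' conductivity `sigma`:
#' `phi(r, theta) = I / (2 pi sigma R) * sum_{n odd} (2n+1)/n (r/R)^n P_n(cos theta)`.
#' On the polar axis `P_n(cos theta) = (+-1)^n`.
#'
#' @param z signed axis positions (m), `|z| <= R`.
#' @param R_m sphere radius (m).
#' @param sigma conductivity (S/m).
#' @param I_A injected current (A).
#' @param n_terms number of odd series terms (default 400).
#' @return Potential (V) at each `z`.
#' @export
sphere_axis_oracle <- function(z, R_m, sigma, I_A, n_terms = 400) {
  stopifnot(all(abs(z) <= R_m + 1e-12), R_m > 0, sigma > 0)
  n <- seq(1, by = 2, length.out = n_terms)
  pref <- I_A / (2 * pi * sigma * R_m)
  vapply(z, function(zi) {
    x <- zi / R_m
    pref * sum((2 * n + 1) / n * sign(x)^(n %% 2) * abs(x)^n)
  }, numeric(1))
}
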