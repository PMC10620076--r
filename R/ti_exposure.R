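#' Maximum modulation envelope magnitude of two interfering fields
#'
#' The temporal-interference dosimetric quantity: the amplitude of the
#' low-frequency envelope oscillation, maximized over field direction, for
#' two sinusoidal fields with vector amplitudes `E1`, `E2` at nearby
#' carrier frequencies. Equivalently `max over unit n of
#' 2 min(|n . E1|, |n . E2|)`. After flipping the sign of `E2` when
#' `E1 . E2 < 0` (the physical envelope is phase-sign invariant) and
#' relabeling so `|E1| >= |E2|`:
#' * `2 |E2|` when `|E2| <= |E1| cos(alpha)` (the weaker field is the
#'   bottleneck along its own direction), otherwise
#' * `2 |E2 x (E1 - E2)| / |E1 - E2|`,
#' with `alpha` the angle between the sign-adjusted vectors.
#'
#' @param E1,E2 numeric 3-vectors, or `n x 3` matrices evaluated rowwise
#'   (V/m).
#' @return Envelope modulation magnitude(s), V/m; zero where either field
#'   vanishes.
#' @export
ti_envelope_point <- function(E1, E2) {
  if (is.null(dim(E1))) E1 <- matrix(E1, ncol = 3)
  if (is.null(dim(E2))) E2 <- matrix(E2, ncol = 3)
  stopifnot(ncol(E1) == 3, ncol(E2) == 3, nrow(E1) == nrow(E2),
            all(is.finite(E1)), all(is.finite(E2)))
  # sign convention: make the fields co-oriented
  flip <- rowSums(E1 * E2) < 0
  E2[flip, ] <- -E2[flip, ]
  m1 <- sqrt(rowSums(E1^2))
  m2 <- sqrt(rowSums(E2^2))
  # relabel so E1 is the stronger field
  swap <- m2 > m1
  if (any(swap)) {
    tmp <- E1[swap, , drop = FALSE]
    E1[swap, ] <- E2[swap, , drop = FALSE]
    E2[swap, ] <- tmp
    tmn <- m1[swap]; m1[swap] <- m2[swap]; m2[swap] <- tmn
  }
  out <- numeric(nrow(E1))
  nz <- m1 > 0 & m2 > 0
  if (any(nz)) {
    dotp <- rowSums(E1 * E2)
    cosa <- pmin(1, pmax(-1, dotp / (m1 * m2)))
    collinear_case <- nz & (m2 <= m1 * cosa)
    out[collinear_case] <- 2 * m2[collinear_case]
    oblique <- nz & !collinear_case
    if (any(oblique)) {
      D <- E1[oblique, , drop = FALSE] - E2[oblique, , drop = FALSE]
      B <- E2[oblique, , drop = FALSE]
      cr <- cbind(B[, 2] * D[, 3] - B[, 3] * D[, 2],
                  B[, 3] * D[, 1] - B[, 1] * D[, 3],
                  B[, 1] * D[, 2] - B[, 2] * D[, 1])
      d2 <- rowSums(D^2)
      res <- ifelse(d2 > 0, 2 * sqrt(rowSums(cr^2)) / sqrt(d2),
                    2 * sqrt(rowSums(B^2)))  # coincident vectors: collinear limit
      out[oblique] <- res
    }
  }
  out
}

#' Voxelwise TI exposure map from two channel fields
#'
#' Scales each per-mA-normalized channel field by its channel current and
#' applies [ti_envelope_point()] at every conductive voxel.
#'
#' @param field1,field2 `vector_field` objects on the same grid, normalized
#'   per mA (i.e. `normalization_mA == 1`).
#' @param current1_mA,current2_mA channel currents (mA).
#' @return Object of class `ti_exposure_map`: `values` (array, V/m),
#'   `currents_mA`, `grid`.
#' @export
ti_envelope_map <- function(field1, field2, current1_mA = 1, current2_mA = 1) {
  stopifnot(inherits(field1, "vector_field"), inherits(field2, "vector_field"))
  stop_if_grid_mismatch(field1$grid, field2$grid)
  for (f in list(field1, field2))
    if (abs(f$normalization_mA - 1) > 1e-9)
      stop("channel fields must be normalized to 1 mA before mapping", call. = FALSE)
  dims <- dim(field1$E)[1:3]
  n <- prod(dims)
  M1 <- matrix(field1$E, nrow = n) * current1_mA
  M2 <- matrix(field2$E, nrow = n) * current2_mA
  # restrict the pointwise formula to voxels where either channel is nonzero
  active <- rowSums(M1^2) + rowSums(M2^2) > 0
  vals <- numeric(n)
  if (any(active))
    vals[active] <- ti_envelope_point(M1[active, , drop = FALSE],
                                      M2[active, , drop = FALSE])
  structure(list(values = array(vals, dim = dims),
                 currents_mA = c(current1_mA, current2_mA),
                 grid = field1$grid),
            class = "ti_exposure_map")
}

#' Near-uniform unit directions on the sphere (Fibonacci lattice)
#'
#' @param n number of directions.
#' @return `n x 3` matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  stopifnot(n >= 1)
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  golden <- pi * (3 - sqrt(5))
  th <- golden * (seq_len(n) - 1)
  cbind(r * cos(th), r * sin(th), z)
}

#' Direction-scan oracle for the TI envelope
#'
#' Independent of the closed form: evaluates
#' `2 min(|n . E1|, |n . E2|)` over a deterministic Fibonacci-sphere
#' direction set and returns the maximum. Underestimates the true optimum
#' only by the angular discretization.
#'
#' @param E1,E2 numeric 3-vectors (V/m).
#' @param n_directions number of scan directions (>= 1000).
#' @return Envelope modulation magnitude, V/m.
#' @export
directional_modulation_oracle <- function(E1, E2, n_directions = 10000) {
  stopifnot(n_directions >= 1000)
  n <- cached_fibonacci(n_directions)
  max(2 * pmin(abs(n %*% E1), abs(n %*% E2)))
}

# The scan is usually called many times with the same direction count;
# keep the last lattice around instead of regenerating it per call.
.dir_cache <- new.env(parent = emptyenv())
cached_fibonacci <- function(n) {
  key <- as.character(n)
  if (is.null(.dir_cache[[key]])) {
    rm(list = ls(.dir_cache), envir = .dir_cache)  # keep at most one lattice
    .dir_cache[[key]] <- fibonacci_sphere(n)
  }
  .dir_cache[[key]]
}

#' Time-domain envelope oracle along one direction
#'
#' Synthesizes the two-tone projected signal
#' `s(t) = (n . E1) sin(2 pi f1 t) + (n . E2) sin(2 pi f2 t)`, extracts the
#' analytic-signal envelope, and returns `max - min` of the envelope over
#' whole beat cycles — a direct simulation of the beat physics that must
#' match `2 min(|n . E1|, |n . E2|)`.
#'
#' @param E1,E2 numeric 3-vectors (V/m).
#' @param n unit projection direction.
#' @param f1_Hz,f2_Hz carrier frequencies (Hz).
#' @param fs_Hz sampling rate; must be at least `20 * max(f1, f2)`.
#' @param duration_s signal duration; must cover at least 5 beat cycles
#'   when `f1 != f2`.
#' @return Envelope modulation amplitude, V/m.
#' @export
timedomain_envelope_oracle <- function(E1, E2, n, f1_Hz = 2000, f2_Hz = 2100,
                                       fs_Hz = 100e3, duration_s = NULL) {
  stopifnot(abs(sqrt(sum(n^2)) - 1) < 1e-9)
  if (fs_Hz < 20 * max(f1_Hz, f2_Hz))
    stop("undersampled: fs must be at least 20x the highest carrier", call. = FALSE)
  df <- abs(f1_Hz - f2_Hz)
  if (is.null(duration_s)) duration_s <- if (df > 0) 10 / df else 0.05
  if (df > 0 && duration_s < 5 / df)
    stop("duration must cover at least 5 beat cycles", call. = FALSE)
  a1 <- sum(n * E1); a2 <- sum(n * E2)
  # exactly duration * fs samples: whole carrier and beat periods fit the
  # FFT window, so the analytic-signal envelope is leakage-free
  t <- (seq_len(round(duration_s * fs_Hz)) - 1) / fs_Hz
  s <- a1 * sin(2 * pi * f1_Hz * t) + a2 * sin(2 * pi * f2_Hz * t)
  env <- Mod(analytic_signal(s))
  # trim carrier edge transients, then restrict to whole beat cycles
  edge <- ceiling(fs_Hz / min(f1_Hz, f2_Hz))
  env <- env[(edge + 1):(length(env) - edge)]
  if (df > 0) {
    per <- round(fs_Hz / df)
    n_cycles <- floor(length(env) / per)
    if (n_cycles < 1) stop("signal too short for one whole beat cycle", call. = FALSE)
    env <- env[seq_len(n_cycles * per)]
  }
  max(env) - min(env)
}

#' Static field-magnitude map (tDCS comparator)
#'
#' `|E| * current` per voxel: the dosimetric quantity of a conventional
#' direct-current montage, used for tTIS-vs-tDCS ROI comparisons. For any
#' field, it equals `ti_envelope_map(field, field) / 2` pointwise (the
#' collinear identity).
#'
#' @param field a per-mA-normalized `vector_field`.
#' @param current_mA applied current (mA).
#' @return Object of class `ti_exposure_map` holding `|E| * current`.
#' @export
tdcs_magnitude_map <- function(field, current_mA = 1) {
  stopifnot(inherits(field, "vector_field"))
  if (abs(field$normalization_mA - 1) > 1e-9)
    stop("field must be normalized to 1 mA", call. = FALSE)
  dims <- dim(field$E)[1:3]
  M <- matrix(field$E, nrow = prod(dims))
  vals <- sqrt(rowSums(M^2)) * current_mA
  structure(list(values = array(vals, dim = dims),
                 currents_mA = c(current_mA, NA_real_),
                 grid = field$grid),
            class = "ti_exposure_map")
}

# Analytic signal via FFT: zero negative frequencies, double positive ones.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}
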