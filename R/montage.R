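#' Volumetric iso-percentile exposure threshold
#'
#' The p-th percentile (linear interpolation between order statistics,
#' `stats::quantile` type 7) of the exposure map over brain-mask voxels.
#' The suprathreshold set used by the montage metrics is defined by strict
#' inequality (`> threshold`).
#'
#' @param map a `ti_exposure_map` (or a bare numeric array).
#' @param brain_mask logical array on the same grid; must be nonempty.
#' @param p percentile in `(0, 100)` (default 98).
#' @return Threshold, V/m.
#' @export
iso_percentile_threshold <- function(map, brain_mask, p = 98) {
  vals <- map_values(map)
  stopifnot(all(dim(vals) == dim(brain_mask)))
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  if (p <= 0 || p >= 100) stop("p must lie in (0, 100)", call. = FALSE)
  unname(stats::quantile(vals[brain_mask], p / 100, type = 7))
}

map_values <- function(map) {
  if (inherits(map, "ti_exposure_map")) map$values else map
}

#' Montage exposure metrics
#'
#' Scores one exposure map against a deep target: the percentile threshold
#' over the brain, the focality ratio (percentage of suprathreshold brain
#' volume lying inside the target), the activation ratio (percentage of the
#' target volume that is suprathreshold), and summary statistics of the
#' exposure within the target (mean, sd with n-1 denominator, median,
#' 99th percentile). Target exposure strength is the median within the
#' target, which is robust to the skewed exposure distributions these maps
#' show.
#'
#' @param map a `ti_exposure_map` (or numeric array), V/m.
#' @param target_mask,brain_mask logical arrays; target must be a nonempty
#'   subset of the brain.
#' @param p threshold percentile (default 98).
#' @return List of class `exposure_metrics`: `threshold_V_per_m`,
#'   `target_exposure` (mean/sd/median/p99), `focality_pct` (NA sentinel if
#'   the suprathreshold set is empty), `activation_pct`,
#'   `suprathreshold_brain_voxels`.
#' @export
exposure_metrics <- function(map, target_mask, brain_mask, p = 98) {
  vals <- map_values(map)
  stopifnot(all(dim(vals) == dim(target_mask)), all(dim(vals) == dim(brain_mask)))
  if (!any(target_mask)) stop("target mask is empty", call. = FALSE)
  if (any(target_mask & !brain_mask))
    stop("target mask must be a subset of the brain mask", call. = FALSE)
  thr <- iso_percentile_threshold(vals, brain_mask, p)
  supra <- vals > thr & brain_mask
  n_supra <- sum(supra)
  n_hit <- sum(supra & target_mask)
  focality <- if (n_supra > 0) 100 * n_hit / n_supra else NA_real_
  activation <- 100 * n_hit / sum(target_mask)
  tv <- vals[target_mask]
  structure(list(
    threshold_V_per_m = thr,
    target_exposure = c(mean = mean(tv), sd = stats::sd(tv),
                        median = stats::median(tv),
                        p99 = unname(stats::quantile(tv, 0.99, type = 7))),
    focality_pct = focality,
    activation_pct = activation,
    suprathreshold_brain_voxels = n_supra),
    class = "exposure_metrics")
}

# ---- montage enumeration --------------------------------------------------

# Mirror label across the mid-sagittal plane: odd <-> even column number.
mirror_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z]+)([0-9]+)$", label))[[1]]
  if (length(m) == 0) return(label)  # midline (z) labels are their own mirror
  n <- as.integer(m[3])
  paste0(m[2], if (n %% 2 == 1) n + 1L else n - 1L)
}

#' Enumerate symmetric four-electrode montages
#'
#' From the supplied electrodes, finds left/right homolog pairs and emits
#' every montage built from two distinct homolog pairs, in all three
#' pairings of the four electrodes: within-row homolog channels
#' (`parallel-coronal`), within-hemisphere channels (`parallel-sagittal`),
#' and cross-hemisphere cross-row channels (`crossing`). Duplicates under
#' channel swap and anode/cathode swap are not generated. For `P` homolog
#' pairs the count is `3 * choose(P, 2)`.
#'
#' @param electrodes list of `electrode_spec`s (>= 4, containing at least
#'   two homolog pairs).
#' @return List of `montage` objects: `pair1`, `pair2` (each
#'   `c(anode, cathode)` labels) and `geometry_class`.
#' @export
enumerate_montages <- function(electrodes) {
  if (length(electrodes) < 4) stop("at least 4 electrodes are required", call. = FALSE)
  labs <- vapply(electrodes, function(e) e$label, character(1))
  if (anyDuplicated(labs)) stop("duplicate electrode labels", call. = FALSE)
  # homolog pairs present in the set, keyed by their left member
  pairs <- list()
  for (l in labs) {
    m <- mirror_label(l)
    if (m != l && m %in% labs && !(m %in% names(pairs))) pairs[[l]] <- c(l, m)
  }
  if (length(pairs) < 2)
    stop("need at least two left/right homolog electrode pairs", call. = FALSE)
  out <- list()
  pn <- names(pairs)
  for (i in seq_len(length(pairs) - 1)) {
    for (j in (i + 1):length(pairs)) {
      a <- pairs[[pn[i]]]; b <- pairs[[pn[j]]]  # a = (L1, R1), b = (L2, R2)
      out[[length(out) + 1]] <- new_montage(c(a[1], a[2]), c(b[1], b[2]), "parallel-coronal")
      out[[length(out) + 1]] <- new_montage(c(a[1], b[1]), c(a[2], b[2]), "parallel-sagittal")
      out[[length(out) + 1]] <- new_montage(c(a[1], b[2]), c(a[2], b[1]), "crossing")
    }
  }
  out
}

new_montage <- function(pair1, pair2, geometry_class) {
  structure(list(pair1 = pair1, pair2 = pair2, geometry_class = geometry_class),
            class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage (%s) + (%s), %s>\n",
              paste(x$pair1, collapse = "-"), paste(x$pair2, collapse = "-"),
              x$geometry_class))
  invisible(x)
}

#' Pareto-optimal (non-dominated) rows
#'
#' Standard non-domination over maximized objectives: a row is flagged
#' unless some other row is at least as good on every objective and
#' strictly better on one. Rows with equal objective vectors are all
#' flagged. Rows with any non-finite objective are never flagged.
#'
#' @param objectives numeric matrix, one row per candidate, objectives in
#'   columns (all maximized).
#' @return Logical vector of Pareto flags.
#' @export
pareto_front <- function(objectives) {
  objectives <- as.matrix(objectives)
  n <- nrow(objectives)
  if (n == 0) return(logical(0))
  ok <- apply(objectives, 1, function(r) all(is.finite(r)))
  flags <- logical(n)
  for (i in which(ok)) {
    dominated <- FALSE
    for (j in which(ok)) {
      if (i == j) next
      if (all(objectives[j, ] >= objectives[i, ]) &&
          any(objectives[j, ] > objectives[i, ])) { dominated <- TRUE; break }
    }
    flags[i] <- !dominated
  }
  flags
}

#' Sweep montages and score them
#'
#' Enumerates symmetric montages over the supplied electrodes, solves each
#' distinct electrode pair once (per-mA normalization; solutions are cached
#' and reused across montages), computes the TI exposure map and the
#' threshold/focality/activation metrics per montage, and flags the
#' Pareto-optimal front on (target median exposure, focality, activation).
#' A failed solve marks its montages as failed and the sweep continues.
#'
#' @param phantom a `head_phantom`.
#' @param roi_set a [make_roi_set()] result (uses its `target` and `brain`
#'   masks).
#' @param electrodes list of `electrode_spec`s.
#' @param currents_mA length-2 numeric: channel currents (mA).
#' @param p threshold percentile (default 98).
#' @param tol solver tolerance.
#' @return `data.frame` of class `sweep_result`, one row per montage, with
#'   electrode labels, geometry class, threshold, metrics and `pareto`
#'   flag; solver provenance in `attr(, "provenance")`.
#' @export
run_sweep <- function(phantom, roi_set, electrodes, currents_mA = c(1, 1),
                      p = 98, tol = 1e-8) {
  stopifnot(inherits(roi_set, "roi_set"), length(currents_mA) == 2)
  montages <- enumerate_montages(electrodes)
  target <- roi_set$masks[["target"]]
  brain <- roi_set$masks[["brain"]]
  especs <- stats::setNames(electrodes, vapply(electrodes, `[[`, "", "label"))

  cache <- new.env(parent = emptyenv())
  get_field <- function(a_lab, c_lab) {
    key <- paste(sort(c(a_lab, c_lab)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    pair <- channel_pair(especs[[a_lab]], especs[[c_lab]], current_mA = 1)
    sol <- solve_channel(phantom, pair, tol = tol)
    cache[[key]] <- sol$field
    sol$field
  }

  rows <- lapply(montages, function(m) {
    res <- tryCatch({
      f1 <- get_field(m$pair1[1], m$pair1[2])
      f2 <- get_field(m$pair2[1], m$pair2[2])
      map <- ti_envelope_map(f1, f2, currents_mA[1], currents_mA[2])
      met <- exposure_metrics(map, target, brain, p)
      data.frame(pair1 = paste(m$pair1, collapse = "-"),
                 pair2 = paste(m$pair2, collapse = "-"),
                 geometry_class = m$geometry_class,
                 threshold_V_per_m = met$threshold_V_per_m,
                 target_median = met$target_exposure[["median"]],
                 target_mean = met$target_exposure[["mean"]],
                 target_sd = met$target_exposure[["sd"]],
                 target_p99 = met$target_exposure[["p99"]],
                 focality_pct = met$focality_pct,
                 activation_pct = met$activation_pct,
                 suprathreshold_brain_voxels = met$suprathreshold_brain_voxels,
                 failed = FALSE,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("montage (%s)+(%s) failed: %s",
                      paste(m$pair1, collapse = "-"),
                      paste(m$pair2, collapse = "-"),
                      conditionMessage(e)), call. = FALSE)
      data.frame(pair1 = paste(m$pair1, collapse = "-"),
                 pair2 = paste(m$pair2, collapse = "-"),
                 geometry_class = m$geometry_class,
                 threshold_V_per_m = NA_real_, target_median = NA_real_,
                 target_mean = NA_real_, target_sd = NA_real_,
                 target_p99 = NA_real_, focality_pct = NA_real_,
                 activation_pct = NA_real_,
                 suprathreshold_brain_voxels = NA_integer_,
                 failed = TRUE, stringsAsFactors = FALSE)
    })
    res
  })
  df <- do.call(rbind, rows)
  df$pareto <- pareto_front(as.matrix(df[, c("target_median", "focality_pct",
                                             "activation_pct")]))
  attr(df, "provenance") <- list(spacing_mm = phantom$grid$spacing_mm,
                                 tol = tol, currents_mA = currents_mA,
                                 percentile = p,
                                 n_montages = length(montages))
  class(df) <- c("sweep_result", class(df))
  df
}
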