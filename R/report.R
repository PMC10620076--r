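#' ROI exposure histogram
#'
#' Bins the exposure values of one ROI. Bins are left-closed/right-open
#' with the final bin right-closed; values strictly above `clip_max` are
#' not binned but reported in `omitted_above_range` (the presentation
#' convention of showing a [0, 1] V/m axis and noting how many voxels
#' exceeded it).
#'
#' @param map a `ti_exposure_map` or numeric array (V/m).
#' @param roi_mask logical array; must be nonempty.
#' @param bin_edges increasing numeric vector (default 50 uniform bins on
#'   `[0, 1]` V/m).
#' @param clip_max values above this are omitted from binning (default 1).
#' @return List of class `roi_histogram`: `bin_edges`, `counts`,
#'   `omitted_above_range`, `n_voxels`. Counts plus omissions always sum
#'   to the ROI voxel count (values below the first edge land in the first
#'   bin, which is degenerate with the default edges starting at 0 on a
#'   nonnegative map).
#' @export
roi_histogram <- function(map, roi_mask, bin_edges = seq(0, 1, length.out = 51),
                          clip_max = 1.0) {
  vals <- map_values(map)
  stopifnot(all(dim(vals) == dim(roi_mask)))
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be increasing", call. = FALSE)
  v <- vals[roi_mask]
  omitted <- sum(v > clip_max)
  keep <- v[v <= clip_max]
  nb <- length(bin_edges) - 1L
  counts <- integer(nb)
  if (length(keep) > 0) {
    # left-closed right-open; final bin right-closed
    bin <- findInterval(keep, bin_edges, rightmost.closed = TRUE, left.open = FALSE)
    bin[bin < 1L] <- 1L
    bin[bin > nb] <- nb
    tab <- tabulate(bin, nbins = nb)
    counts <- as.integer(tab)
  }
  structure(list(bin_edges = bin_edges, counts = counts,
                 omitted_above_range = omitted, n_voxels = sum(roi_mask)),
            class = "roi_histogram")
}

#' ROI summary statistics
#'
#' Mean, standard deviation (n-1 denominator), median, and 99th percentile
#' (linear interpolation) of the exposure over ROI voxels — the standard
#' "mean +- s.d., median, 99th percentile" dosimetry record.
#'
#' @param map a `ti_exposure_map` or numeric array (V/m).
#' @param roi_mask logical array; must be nonempty.
#' @return Named numeric vector: `n`, `mean`, `sd`, `median`, `p99`.
#' @export
roi_summary <- function(map, roi_mask) {
  vals <- map_values(map)
  stopifnot(all(dim(vals) == dim(roi_mask)))
  if (!any(roi_mask)) stop("ROI mask is empty", call. = FALSE)
  v <- vals[roi_mask]
  c(n = length(v), mean = mean(v), sd = stats::sd(v),
    median = stats::median(v),
    p99 = unname(stats::quantile(v, 0.99, type = 7)))
}

#' Full ROI dosimetry report for a map
#'
#' @param map a `ti_exposure_map`.
#' @param roi_set a [make_roi_set()] result, or a named list of logical
#'   masks.
#' @param bin_edges,clip_max forwarded to [roi_histogram()].
#' @return Object of class `roi_report`: per-ROI `summary` (data.frame,
#'   rows ordered by ROI name) and `histograms` (named list), plus
#'   `currents_mA` metadata.
#' @export
roi_report <- function(map, roi_set, bin_edges = seq(0, 1, length.out = 51),
                       clip_max = 1.0) {
  masks <- if (inherits(roi_set, "roi_set")) roi_set$masks else roi_set
  stopifnot(length(masks) > 0, !is.null(names(masks)))
  nms <- sort(names(masks))
  summ <- do.call(rbind, lapply(nms, function(nm) {
    s <- roi_summary(map, masks[[nm]])
    data.frame(roi = nm, n = s[["n"]], mean = s[["mean"]], sd = s[["sd"]],
               median = s[["median"]], p99 = s[["p99"]],
               stringsAsFactors = FALSE)
  }))
  hists <- stats::setNames(lapply(nms, function(nm)
    roi_histogram(map, masks[[nm]], bin_edges, clip_max)), nms)
  structure(list(summary = summ, histograms = hists,
                 currents_mA = if (inherits(map, "ti_exposure_map"))
                   map$currents_mA else NULL),
            class = "roi_report")
}

#' Compare two ROI reports (e.g. tTIS vs tDCS)
#'
#' Side-by-side descriptive statistics with per-ROI differences of means
#' and medians. Purely descriptive: voxels are not independent samples, so
#' no inferential statistics are computed.
#'
#' @param report_a,report_b `roi_report` objects over the same ROI names.
#' @return data.frame, one row per ROI: statistics from both reports and
#'   `mean_diff` / `median_diff` (a minus b).
#' @export
compare_conditions <- function(report_a, report_b) {
  stopifnot(inherits(report_a, "roi_report"), inherits(report_b, "roi_report"))
  a <- report_a$summary; b <- report_b$summary
  mismatch <- union(setdiff(a$roi, b$roi), setdiff(b$roi, a$roi))
  if (length(mismatch) > 0)
    stop("ROI name mismatch between reports: ", paste(mismatch, collapse = ", "),
         call. = FALSE)
  b <- b[match(a$roi, b$roi), ]
  data.frame(roi = a$roi,
             n = a$n,
             mean_a = a$mean, mean_b = b$mean, mean_diff = a$mean - b$mean,
             median_a = a$median, median_b = b$median,
             median_diff = a$median - b$median,
             sd_a = a$sd, sd_b = b$sd,
             p99_a = a$p99, p99_b = b$p99,
             stringsAsFactors = FALSE)
}

#' Write an ROI report to CSV and JSON
#'
#' Deterministic output: ROIs in sorted order, fixed 15-significant-digit
#' float formatting, so identical inputs produce byte-identical files.
#'
#' @param report a [roi_report()].
#' @param path_prefix output path prefix; writes `<prefix>_summary.csv` and
#'   `<prefix>_histograms.json`.
#' @return Invisibly, the two file paths.
#' @export
write_roi_report <- function(report, path_prefix) {
  stopifnot(inherits(report, "roi_report"))
  csv <- paste0(path_prefix, "_summary.csv")
  js <- paste0(path_prefix, "_histograms.json")
  df <- report$summary
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15, format = "g"))
  utils::write.csv(df, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(lapply(report$histograms, unclass), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(csv, js))
}
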