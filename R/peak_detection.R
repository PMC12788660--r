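## Insertion-size peak detection.
##
## The pooled insertion-size distribution is scanned for "mountains" of
## elevated local density relative to a rolling local-quantile background,
## so that families at very different copy numbers are detected on equal
## footing: a size interval is called whenever its smoothed density exceeds
## the background quantile of its own neighbourhood, regardless of absolute
## frequency.

#' Peak-detection configuration
#'
#' @param size_min,size_max Size range scanned, bp (defaults 100 and 9000).
#' @param density_window Sliding-window width for local density, bp
#'   (default 50). Windows are centred and edge-clipped, and the sum is
#'   divided by the width actually used.
#' @param background_window Width of the local background window, bp
#'   (default 500).
#' @param background_quantile Quantile of the smoothed density used as the
#'   local background threshold (default 0.75).
#' @param merge_distance Clusters separated by fewer than this many bp are
#'   consolidated (default 100).
#' @param min_peak_enrichment Minimum ratio of a cluster's peak density to
#'   the background threshold at that size for the cluster to be reported
#'   (default 3). At realistic insertion densities the smoothed density of
#'   featureless background sits many standard deviations below three
#'   times its own local 75th percentile, so this rejects
#'   quantile-exceedance noise, while genuine families (typically 5-50x
#'   their neighbourhood) clear it comfortably. Set to 0 to disable.
#' @param min_cluster_count Minimum total insertion count for a reported
#'   cluster (default 10).
#' @param sampling_threshold Per-peak sequence-sampling cap used by the
#'   clustering stage (default 200).
#' @param identity_threshold Percent-identity threshold for sequence
#'   clustering (default 0.85).
#' @param length_tolerance Relative length tolerance for length-variant
#'   pre-grouping (default 0.10).
#' @param consensus_strategy Representative-selection strategy, one of
#'   `"most_frequent"`, `"longest"`, `"median_length"`.
#' @param exclude_focal_window If `TRUE`, the background window excludes
#'   the focal density window (default `FALSE`: pure rolling quantile).
#' @param rng_seed Seed used by downstream sampling.
#' @return A list of class `peak_config`.
#' @export
peak_config <- function(size_min = 100L, size_max = 9000L,
                        density_window = 50L, background_window = 500L,
                        background_quantile = 0.75, merge_distance = 100L,
                        min_peak_enrichment = 3, min_cluster_count = 10L,
                        sampling_threshold = 200L, identity_threshold = 0.85,
                        length_tolerance = 0.10,
                        consensus_strategy = c("most_frequent", "longest",
                                               "median_length"),
                        exclude_focal_window = FALSE, rng_seed = 42L) {
  consensus_strategy <- match.arg(consensus_strategy)
  stopifnot(size_min < size_max,
            background_quantile > 0, background_quantile < 1,
            density_window >= 1L, density_window <= background_window,
            identity_threshold > 0, identity_threshold <= 1,
            merge_distance >= 0L, length_tolerance >= 0)
  structure(list(size_min = as.integer(size_min),
                 size_max = as.integer(size_max),
                 density_window = as.integer(density_window),
                 background_window = as.integer(background_window),
                 background_quantile = background_quantile,
                 merge_distance = as.integer(merge_distance),
                 min_peak_enrichment = min_peak_enrichment,
                 min_cluster_count = as.integer(min_cluster_count),
                 sampling_threshold = as.integer(sampling_threshold),
                 identity_threshold = identity_threshold,
                 length_tolerance = length_tolerance,
                 consensus_strategy = consensus_strategy,
                 exclude_focal_window = exclude_focal_window,
                 rng_seed = as.integer(rng_seed)),
            class = "peak_config")
}

#' Build the pooled insertion-size histogram
#'
#' @param calls Calls table (any number of samples pooled).
#' @param config A [peak_config()].
#' @return List of class `size_histogram` with `size_min`, `size_max`, and
#'   `counts` (integer vector, one cell per bp; calls outside the range are
#'   ignored).
#' @export
build_size_histogram <- function(calls, config = peak_config()) {
  sizes <- config$size_min:config$size_max
  len <- calls$length
  len <- len[len >= config$size_min & len <= config$size_max]
  counts <- tabulate(len - config$size_min + 1L, nbins = length(sizes))
  structure(list(size_min = config$size_min, size_max = config$size_max,
                 counts = as.integer(counts)),
            class = "size_histogram")
}

#' Local insertion density
#'
#' Centred sliding mean of the histogram counts; at the edges the window is
#' clipped to the histogram and the sum divided by the actual width used,
#' so density is commensurate across the whole range.
#'
#' @param hist A `size_histogram`.
#' @param density_window Window width, bp.
#' @return Numeric vector (insertions per bp) over the histogram's sizes.
#' @export
local_density <- function(hist, density_window = 50L) {
  stopifnot(density_window >= 1L)
  .rolling_mean_clipped_cpp(as.numeric(hist$counts),
                            as.integer(density_window %/% 2L))
}

#' Rolling local-quantile background threshold
#'
#' The threshold at size s is the empirical quantile (R type 7) of the
#' smoothed density over the background window centred at s, edge-clipped.
#'
#' @param density Numeric density vector.
#' @param background_window Window width, bp.
#' @param q Quantile in (0, 1).
#' @param exclude_half_width If positive, values within this distance of
#'   the focal size are left out of the background window.
#' @return Numeric threshold vector, same length as `density`.
#' @export
background_threshold <- function(density, background_window = 500L, q = 0.75,
                                 exclude_half_width = 0L) {
  stopifnot(q > 0, q < 1)
  h <- as.integer(background_window %/% 2L)
  if (exclude_half_width <= 0L)
    return(.rolling_quantile_clipped_cpp(as.numeric(density), h, q))
  n <- length(density)
  ex <- as.integer(exclude_half_width)
  vapply(seq_len(n), function(i) {
    idx <- max(1L, i - h):min(n, i + h)
    idx <- idx[abs(idx - i) > ex]
    if (!length(idx)) idx <- i
    stats::quantile(density[idx], q, names = FALSE)
  }, numeric(1))
}

new_size_clusters <- function(df, hist = NULL, density = NULL,
                              threshold = NULL, config = NULL) {
  structure(df, class = c("size_clusters", "data.frame"),
            hist = hist, density = density, threshold = threshold,
            config = config)
}

#' Call size clusters from density vs. threshold
#'
#' Maximal runs of sizes whose density strictly exceeds the local
#' background threshold become clusters; under a flat distribution density
#' equals threshold nowhere strictly, so nothing is called.
#'
#' @param hist A `size_histogram`.
#' @param density,threshold Vectors over the histogram's sizes.
#' @return A `size_clusters` data.frame with columns `start`, `end`
#'   (inclusive size range, bp), `peak_position` (the local maximum of the
#'   size-frequency distribution within the run -- argmax of the raw
#'   histogram counts, ties to the smaller size; the raw mode, unlike the
#'   smoothed density, localises sharp families to the bp), `total_count`,
#'   `mean_density`, and a list column `sub_peaks` (per-run maxima, kept
#'   through merging as diagnostics).
#' @export
call_size_clusters <- function(hist, density, threshold) {
  stopifnot(length(density) == length(hist$counts),
            length(threshold) == length(hist$counts))
  above <- density > threshold
  if (!any(above))
    return(new_size_clusters(empty_clusters_df(), hist, density, threshold))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  df <- do.call(rbind, lapply(runs, function(k) {
    i <- starts[k]:ends[k]
    pk <- i[which.max(hist$counts[i])]
    data.frame(start = hist$size_min + i[1L] - 1L,
               end = hist$size_min + i[length(i)] - 1L,
               peak_position = hist$size_min + pk - 1L,
               total_count = sum(hist$counts[i]),
               mean_density = sum(hist$counts[i]) / length(i))
  }))
  df$sub_peaks <- as.list(df$peak_position)
  rownames(df) <- NULL
  new_size_clusters(df, hist, density, threshold)
}

empty_clusters_df <- function() {
  df <- data.frame(start = integer(0), end = integer(0),
                   peak_position = integer(0), total_count = integer(0),
                   mean_density = numeric(0))
  df$sub_peaks <- list()
  df
}

#' Consolidate nearby size clusters
#'
#' Adjacent clusters whose gap (`next.start - prev.end - 1`) is smaller
#' than `merge_distance` are merged, transitively, into one spanning
#' cluster; counts and densities are recomputed from the histogram over the
#' merged range and the peak position is the raw-count argmax within it.
#'
#' @param clusters A `size_clusters` object (sorted, non-overlapping).
#' @param merge_distance Gap threshold, bp.
#' @param hist The `size_histogram` the clusters came from.
#' @param density Density vector (defaults to the attribute stored on
#'   `clusters`).
#' @return A merged `size_clusters` object.
#' @export
merge_clusters <- function(clusters, merge_distance, hist,
                           density = attr(clusters, "density")) {
  if (nrow(clusters) <= 1L) return(clusters)
  gap <- clusters$start[-1L] - clusters$end[-nrow(clusters)] - 1L
  grp <- cumsum(c(1L, as.integer(gap >= merge_distance)))
  if (max(grp) == nrow(clusters)) return(clusters)
  df <- do.call(rbind, lapply(split(seq_len(nrow(clusters)), grp), function(i) {
    s <- min(clusters$start[i]); e <- max(clusters$end[i])
    idx <- (s:e) - hist$size_min + 1L
    pk <- idx[which.max(hist$counts[idx])]
    out <- data.frame(start = s, end = e,
                      peak_position = hist$size_min + pk - 1L,
                      total_count = sum(hist$counts[idx]),
                      mean_density = sum(hist$counts[idx]) / length(idx))
    out$sub_peaks <- list(sort(unique(unlist(clusters$sub_peaks[i]))))
    out
  }))
  rownames(df) <- NULL
  new_size_clusters(df, hist, density, attr(clusters, "threshold"),
                    attr(clusters, "config"))
}

#' Detect insertion-size peaks
#'
#' Full composition: histogram, local density, rolling-quantile background,
#' strict-exceedance cluster calling, proximity merging, and a final
#' strength filter (`min_peak_enrichment`, `min_cluster_count`) that
#' removes quantile-exceedance noise.
#'
#' @param calls Pooled calls table.
#' @param config A [peak_config()].
#' @return A `size_clusters` object (possibly empty), ordered by `start`,
#'   with the histogram, density, threshold and config attached as
#'   attributes for plotting.
#' @export
detect_peaks <- function(calls, config = peak_config()) {
  hist <- build_size_histogram(calls, config)
  density <- local_density(hist, config$density_window)
  threshold <- background_threshold(
    density, config$background_window, config$background_quantile,
    exclude_half_width = if (config$exclude_focal_window)
      config$density_window %/% 2L else 0L)
  cl <- call_size_clusters(hist, density, threshold)
  cl <- merge_clusters(cl, config$merge_distance, hist, density)
  if (nrow(cl)) {
    idx <- cl$peak_position - hist$size_min + 1L
    enr <- ifelse(threshold[idx] > 0, density[idx] / threshold[idx], Inf)
    keep <- (enr >= config$min_peak_enrichment | density[idx] == 0) &
      cl$total_count >= config$min_cluster_count & cl$total_count > 0L
    cl <- new_size_clusters(cl[keep, , drop = FALSE], hist, density,
                            threshold, config)
    rownames(cl) <- NULL
  }
  attr(cl, "config") <- config
  cl
}

#' @export
print.size_clusters <- function(x, ...) {
  cat("Insertion-size clusters:", nrow(x), "peak(s)\n")
  if (nrow(x)) {
    df <- as.data.frame(x)
    df$sub_peaks <- vapply(df$sub_peaks, function(p)
      paste(p, collapse = ","), character(1))
    print(df, row.names = FALSE, ...)
  }
  invisible(x)
}

#' Plot the pooled size-frequency distribution with detected peaks
#'
#' Two stacked panels with linear- and log-scaled y axes; detected peak
#' positions are marked.
#'
#' @param x A `size_clusters` object from [detect_peaks()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.size_clusters <- function(x, ...) {
  hist <- attr(x, "hist")
  if (is.null(hist)) stop("no histogram attached; run detect_peaks()")
  sizes <- hist$size_min:hist$size_max
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(sizes, hist$counts, type = "h", xlab = "insertion size (bp)",
                 ylab = "count", main = "Insertion size-frequency", ...)
  if (nrow(x)) graphics::abline(v = x$peak_position, col = "red", lty = 2)
  graphics::plot(sizes, hist$counts + 1, type = "h", log = "y",
                 xlab = "insertion size (bp)", ylab = "count + 1 (log)", ...)
  if (nrow(x)) graphics::abline(v = x$peak_position, col = "red", lty = 2)
  invisible(x)
}
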