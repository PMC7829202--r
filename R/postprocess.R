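# From per-sample probabilities to discrete wave latencies: threshold the
# probability sequence, extract maximal runs of positives, merge runs closer
# than 20 samples (0.5 ms) into one characteristic-wave region, drop regions
# with too little support, and report each region's latency as the mean of
# the times of its first and last point.

#' Threshold a probability sequence
#'
#' @param probs Numeric vector of per-sample feature probabilities.
#' @param cutoff Decision threshold in (0, 1); samples with
#'   `probs >= cutoff` become 1 (the boundary is inclusive).
#' @return Integer 0/1 vector.
#' @export
binarize <- function(probs, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie strictly in (0, 1)")
  if (any(probs < -1e-12 | probs > 1 + 1e-12)) stop("probabilities outside [0, 1]")
  as.integer(probs >= cutoff)
}

#' Maximal runs of ones
#'
#' @param x Integer 0/1 vector.
#' @return Two-column matrix (`start`, `end`), 1-based inclusive, one row per
#'   maximal run, sorted and disjoint; zero rows if `x` has no ones.
#' @export
find_runs <- function(x) {
  r <- rle(as.integer(x) != 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], end = ends[keep])
}

#' Merge nearby runs into characteristic-wave regions
#'
#' Consecutive runs whose gap (number of zero samples strictly between them)
#' is below `threshold_samples` belong to the same characteristic wave; the
#' merge is transitive. The default of 20 samples equals 0.5 ms on the
#' canonical grid. Each region's `center_time` is the mean of the times of
#' its first and last sample.
#'
#' @param runs Matrix from [find_runs()] (window coordinates, 1-based).
#' @param threshold_samples Gap threshold in samples; gaps `< threshold`
#'   merge.
#' @param grid An [abr_grid()] (for region center times).
#' @param support Optional total count of positive samples per run; defaults
#'   to the run lengths.
#' @return Data frame of class `"peak_regions"` with columns `start`, `end`
#'   (window coordinates), `center_ms`, `support`, `wave` (`NA` until
#'   [assign_waves()]).
#' @export
merge_regions <- function(runs, threshold_samples = 20L, grid = abr_grid()) {
  if (threshold_samples < 0) stop("threshold must be >= 0")
  runs <- matrix(as.integer(runs), ncol = 2,
                 dimnames = list(NULL, c("start", "end")))
  n <- nrow(runs)
  empty <- data.frame(start = integer(0), end = integer(0),
                      center_ms = numeric(0), support = integer(0),
                      wave = character(0), stringsAsFactors = FALSE)
  class(empty) <- c("peak_regions", "data.frame")
  if (n == 0L) return(empty)
  runs <- runs[order(runs[, 1]), , drop = FALSE]
  group <- integer(n)
  group[1] <- 1L
  for (i in seq_len(n)[-1]) {
    gap <- runs[i, 1] - runs[i - 1, 2] - 1L
    group[i] <- if (gap < threshold_samples) group[i - 1] else group[i - 1] + 1L
  }
  win0 <- window_indices(grid)[1]  # window coordinate 1 = grid index win0
  out <- do.call(rbind, lapply(split(seq_len(n), group), function(ix) {
    s <- min(runs[ix, 1]); e <- max(runs[ix, 2])
    data.frame(
      start = s, end = e,
      center_ms = (grid_time(grid, win0 + s - 1L) +
                   grid_time(grid, win0 + e - 1L)) / 2,
      support = sum(runs[ix, 2] - runs[ix, 1] + 1L),
      wave = NA_character_, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  class(out) <- c("peak_regions", "data.frame")
  out
}

#' Drop weakly supported regions
#'
#' A region is kept only if its total positive support (number of predicted
#' feature samples) reaches `min_run_length`; regions built from too few
#' identification points are discarded as unreliable.
#'
#' @param regions A `"peak_regions"` data frame.
#' @param min_run_length Minimum support in samples (default 3).
#' @return Filtered `"peak_regions"`.
#' @export
filter_regions <- function(regions, min_run_length = 3L) {
  out <- regions[regions$support >= min_run_length, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_regions", "data.frame")
  out
}

#' Assign regions to waves I / III / V
#'
#' Latency-window gating: each wave's clinical latency window is scanned and
#' the earliest unassigned region whose center falls inside it takes the
#' label; remaining regions stay unlabeled. The binary classifier itself
#' carries no wave identity, so this step recovers it from latency alone.
#'
#' @param regions A `"peak_regions"` data frame (sorted by time).
#' @param windows Named list of `c(lo, hi)` latency windows in ms.
#' @return `regions` with the `wave` column filled where assigned.
#' @export
assign_waves <- function(regions,
                         windows = list(I = c(1.0, 2.4), III = c(3.0, 4.6),
                                        V = c(4.8, 7.0))) {
  if (nrow(regions) == 0L) return(regions)
  regions <- regions[order(regions$center_ms), , drop = FALSE]
  regions$wave <- NA_character_
  for (wv in names(windows)) {
    w <- windows[[wv]]
    cand <- which(is.na(regions$wave) &
                  regions$center_ms >= w[1] & regions$center_ms <= w[2])
    if (length(cand) > 0L) regions$wave[cand[1]] <- wv
  }
  rownames(regions) <- NULL
  class(regions) <- c("peak_regions", "data.frame")
  regions
}

#' Full postprocessing pipeline
#'
#' @param probs Per-sample feature probabilities (length 321).
#' @param cutoff Binarization threshold.
#' @param threshold_samples Region-merge gap threshold (samples).
#' @param min_run_length Minimum region support (samples).
#' @param grid An [abr_grid()].
#' @param windows Wave latency windows for [assign_waves()].
#' @return A `"peak_regions"` data frame with wave assignments.
#' @export
postprocess_probs <- function(probs, cutoff = 0.5, threshold_samples = 20L,
                              min_run_length = 3L, grid = abr_grid(),
                              windows = list(I = c(1.0, 2.4), III = c(3.0, 4.6),
                                             V = c(4.8, 7.0))) {
  runs <- find_runs(binarize(probs, cutoff))
  regions <- merge_regions(runs, threshold_samples, grid)
  regions <- filter_regions(regions, min_run_length)
  assign_waves(regions, windows)
}

#' Predicted wave latencies from a region table
#'
#' @param regions A `"peak_regions"` data frame after [assign_waves()].
#' @return Named numeric vector of latencies (ms) for the assigned waves.
#' @export
region_latencies <- function(regions) {
  keep <- !is.na(regions$wave)
  stats::setNames(regions$center_ms[keep], regions$wave[keep])
}

#' Write predictions as JSON
#'
#' Layout: `{"regions":[{"start":..,"end":..,"center_ms":..,"wave":"V"|null}]}`.
#'
#' @param regions A `"peak_regions"` data frame.
#' @param path Output path.
#' @export
write_predictions <- function(regions, path) {
  lst <- lapply(seq_len(nrow(regions)), function(i) {
    list(start = regions$start[i], end = regions$end[i],
         center_ms = regions$center_ms[i],
         wave = if (is.na(regions$wave[i])) NULL else regions$wave[i])
  })
  jsonlite::write_json(list(regions = lst), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
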