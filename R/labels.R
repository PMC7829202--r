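# Window selection and binary label construction. The analysis window is
# t in [0, 8] ms: 321 samples on the canonical grid. Labels are per-sample
# binary targets (feature point = 1); single-sample clinical marks are
# dilated by 4 samples (0.1 ms) on each side to balance the 3:318 class
# ratio and absorb marking error.

#' Extract the 0-8 ms analysis window
#'
#' Returns the 321 samples with t in \[0, 8\] ms, dropping the pre-stimulus
#' baseline and the late window where myogenic artifacts concentrate.
#'
#' @param recording An [abr_recording()] on the canonical grid.
#' @return An object of class `"windowed_trace"`: numeric vector of 321
#'   potentials with attributes `times` (ms) and `grid`.
#' @export
extract_window <- function(recording) {
  stopifnot(inherits(recording, "abr_recording"))
  grid <- recording$grid
  idx <- window_indices(grid)
  structure(recording$potentials[idx],
            times = grid_time(grid, idx),
            start_index = idx[1], grid = grid,
            class = "windowed_trace")
}

#' @export
print.windowed_trace <- function(x, ...) {
  cat(sprintf("Windowed ABR trace: %d samples, t = %g .. %g ms\n",
              length(x), attr(x, "times")[1], attr(x, "times")[length(x)]))
  invisible(x)
}

# Times of the default window without needing a recording.
default_window_times <- function(grid = abr_grid()) window_times(grid)

#' Convert an annotation to a binary label vector
#'
#' Each marked wave sets a single 1 at the window sample nearest its latency
#' (exact half-sample ties go to the lower index); all other samples are 0.
#' A full three-wave annotation therefore yields 3 ones and 318 zeros.
#'
#' @param ann A [wave_annotation()].
#' @param grid An [abr_grid()].
#' @return Integer vector of length 321 with values in \{0, 1\} and
#'   attribute `augmented = FALSE`.
#' @export
annotation_to_labels <- function(ann, grid = abr_grid()) {
  stopifnot(inherits(ann, "wave_annotation"))
  idx_win <- window_indices(grid)
  n <- length(idx_win)
  lab <- integer(n)
  for (lat in ann$latencies) {
    if (lat < 0 || lat > 8) stop("latency outside the 0-8 ms window: ", lat)
    i <- grid_index(grid, lat) - idx_win[1] + 1L
    i <- min(max(i, 1L), n)
    lab[i] <- 1L
  }
  structure(lab, augmented = FALSE)
}

#' Dilate a binary label vector
#'
#' Marks the `radius` samples (default 4, i.e. 0.1 ms) before and after each
#' original mark as feature points: binary dilation
#' `out[i] = 1 iff any in[j] = 1 with |i - j| <= radius`, clipped at the
#' window boundaries. Overlapping neighbourhoods take their union.
#'
#' @param labels Binary integer vector (0/1).
#' @param radius Dilation half-width in samples (>= 0).
#' @return Dilated binary vector with attribute `augmented = TRUE`.
#' @export
augment_labels <- function(labels, radius = 4L) {
  if (radius < 0) stop("radius must be >= 0")
  radius <- as.integer(radius)
  n <- length(labels)
  out <- integer(n)
  for (j in which(labels == 1L)) {
    lo <- max(1L, j - radius)
    hi <- min(n, j + radius)
    out[lo:hi] <- 1L
  }
  structure(out, augmented = TRUE)
}

#' Dilation half-width in ms
#'
#' @param radius Half-width in samples.
#' @param grid An [abr_grid()].
#' @return Half-width in ms (0.1 ms for the default 4 samples).
#' @export
dilation_halfwidth_ms <- function(radius = 4L, grid = abr_grid()) {
  radius * grid$dt
}

#' Per-trace z-score normalization
#'
#' Recurrent training is scale-sensitive; traces are z-scored before model
#' ingestion while raw uV values are kept for plotting and IO. A constant
#' trace maps to all zeros.
#'
#' @param trace A `"windowed_trace"` or numeric vector.
#' @return Numeric vector of the same length, mean 0 and SD 1 (unless
#'   degenerate).
#' @export
normalize_trace <- function(trace) {
  x <- as.numeric(trace)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Assemble model inputs and targets from an annotated dataset
#'
#' @param dataset An `"abr_dataset"`.
#' @param radius Label dilation half-width in samples.
#' @param denoise Optional [wavelet_spec()]; if given, each sweep is
#'   denoised with [denoise_recording()] before windowing.
#' @return List with `x` (321 x n matrix of normalized potentials) and
#'   `y` (321 x n matrix of dilated binary targets).
#' @export
prepare_training_data <- function(dataset, radius = 4L, denoise = NULL) {
  n <- length(dataset)
  grid <- dataset[[1]]$recording$grid
  x <- matrix(0, nrow = length(window_indices(grid)), ncol = n)
  y <- matrix(0L, nrow = nrow(x), ncol = n)
  for (i in seq_len(n)) {
    rec <- dataset[[i]]$recording
    if (!is.null(denoise)) rec <- denoise_recording(rec, denoise)
    x[, i] <- normalize_trace(extract_window(rec))
    y[, i] <- augment_labels(annotation_to_labels(dataset[[i]]$annotation, grid),
                             radius)
  }
  list(x = x, y = y)
}
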