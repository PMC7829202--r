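#' Canonical ABR acquisition time grid
#'
#' The acquisition grid of a click-ABR sweep: 1,024 uniformly spaced samples
#' at 0.025 ms, anchored so that the stimulus onset (t = 0) falls exactly on
#' a grid point. With the default anchoring `time(i) = dt * (i - zero_index)`
#' the grid spans -12.775 to 12.8 ms (displayed rounded as -12.78 / 12.80)
#' and contains exactly 321 samples in the analysis window \[0, 8\] ms.
#'
#' @param n_samples Number of samples per sweep (default 1024).
#' @param dt Sampling interval in ms (default 0.025).
#' @param zero_index 1-based index of the sample at which t = 0 falls
#'   (default 512).
#' @return An object of class `"abr_grid"`.
#' @examples
#' g <- abr_grid()
#' length(window_indices(g))  # 321
#' @export
abr_grid <- function(n_samples = 1024L, dt = 0.025, zero_index = 512L) {
  n_samples <- as.integer(n_samples)
  zero_index <- as.integer(zero_index)
  stopifnot(n_samples >= 1L, dt > 0, zero_index >= 1L, zero_index <= n_samples)
  structure(
    list(n_samples = n_samples, dt = dt, zero_index = zero_index),
    class = "abr_grid"
  )
}

#' @export
print.abr_grid <- function(x, ...) {
  cat(sprintf(
    "ABR time grid: %d samples, dt = %g ms, t = %.3f .. %.3f ms (t = 0 at index %d)\n",
    x$n_samples, x$dt, grid_time(x, 1L), grid_time(x, x$n_samples), x$zero_index
  ))
  invisible(x)
}

#' Sample index to time (ms)
#'
#' @param grid An [abr_grid()].
#' @param index 1-based sample index (vectorised).
#' @return Time in ms.
#' @export
grid_time <- function(grid, index) {
  stopifnot(inherits(grid, "abr_grid"))
  grid$dt * (index - grid$zero_index)
}

#' Time (ms) to nearest sample index
#'
#' Rounds to the nearest grid point; exact half-sample ties go to the lower
#' index.
#'
#' @param grid An [abr_grid()].
#' @param time_ms Time in ms (vectorised).
#' @return 1-based integer sample index.
#' @export
grid_index <- function(grid, time_ms) {
  stopifnot(inherits(grid, "abr_grid"))
  x <- time_ms / grid$dt + grid$zero_index
  # nearest with ties to the lower index; guard against representation error
  as.integer(ceiling(x - 0.5 - 1e-9))
}

#' Indices of the 0-8 ms analysis window
#'
#' @param grid An [abr_grid()].
#' @param t_min,t_max Window bounds in ms (inclusive).
#' @return Integer vector of 1-based indices (length 321 on the default grid).
#' @export
window_indices <- function(grid, t_min = 0, t_max = 8) {
  stopifnot(inherits(grid, "abr_grid"))
  t <- grid_time(grid, seq_len(grid$n_samples))
  which(t >= t_min - 1e-9 & t <= t_max + 1e-9)
}

#' Times (ms) of the analysis-window samples
#'
#' @inheritParams window_indices
#' @return Numeric vector of times in ms.
#' @export
window_times <- function(grid, t_min = 0, t_max = 8) {
  grid_time(grid, window_indices(grid, t_min, t_max))
}
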