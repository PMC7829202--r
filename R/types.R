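#' ABR sweep recording
#'
#' One averaged click-ABR sweep: potentials in microvolts on the canonical
#' acquisition grid, plus subject metadata.
#'
#' @param potentials Numeric vector of potentials in uV, one per grid sample.
#' @param grid An [abr_grid()]; defaults to the canonical 1,024-point grid.
#' @param subject_class `"normal"` or `"abnormal"` hearing.
#' @param stimulus_level Click stimulus intensity in dB nHL.
#' @return An object of class `"abr_recording"`.
#' @export
abr_recording <- function(potentials, grid = abr_grid(),
                          subject_class = c("normal", "abnormal"),
                          stimulus_level = 96) {
  subject_class <- match.arg(subject_class)
  potentials <- as.numeric(potentials)
  if (length(potentials) != grid$n_samples) {
    stop(sprintf("expected %d samples, got %d", grid$n_samples, length(potentials)))
  }
  if (!all(is.finite(potentials))) {
    stop("potentials must all be finite")
  }
  structure(
    list(potentials = potentials, grid = grid,
         subject_class = subject_class, stimulus_level = stimulus_level),
    class = "abr_recording"
  )
}

#' @export
print.abr_recording <- function(x, ...) {
  cat(sprintf(
    "ABR recording: %d samples (%.3f .. %.3f ms), %s hearing, %g dB nHL\n",
    x$grid$n_samples, grid_time(x$grid, 1L), grid_time(x$grid, x$grid$n_samples),
    x$subject_class, x$stimulus_level
  ))
  invisible(x)
}

#' Characteristic-wave annotation
#'
#' Latencies (ms, from stimulus onset) of the clinically marked waves I, III
#' and V. Any subset may be absent; present latencies must lie in \[0, 8\] ms
#' and strictly increase in the order I < III < V.
#'
#' @param latencies Named numeric vector with names among `"I"`, `"III"`,
#'   `"V"`; may be empty.
#' @return An object of class `"wave_annotation"`.
#' @examples
#' wave_annotation(c(I = 1.62, III = 3.90, V = 5.72))
#' wave_annotation(c(V = 6.1))  # only wave V marked
#' @export
wave_annotation <- function(latencies = numeric(0)) {
  latencies <- unlist(latencies)
  if (length(latencies) == 0L) {
    latencies <- numeric(0)
  } else {
    latencies <- vapply(latencies, as.numeric, numeric(1))
  }
  allowed <- c("I", "III", "V")
  if (length(latencies) > 0L) {
    if (is.null(names(latencies)) || !all(names(latencies) %in% allowed)) {
      bad <- setdiff(names(latencies), allowed)
      stop("unknown wave name(s): ", paste(bad, collapse = ", "))
    }
    if (anyDuplicated(names(latencies))) stop("duplicated wave names")
    if (any(latencies < 0 | latencies > 8)) {
      stop("wave latencies must lie in [0, 8] ms")
    }
    latencies <- latencies[order(match(names(latencies), allowed))]
    if (length(latencies) > 1L && any(diff(latencies) <= 0)) {
      stop("wave latencies must strictly increase in the order I < III < V")
    }
  }
  structure(list(latencies = latencies), class = "wave_annotation")
}

#' @export
print.wave_annotation <- function(x, ...) {
  if (length(x$latencies) == 0L) {
    cat("Wave annotation: (no waves marked)\n")
  } else {
    cat("Wave annotation:",
        paste(sprintf("%s = %.3f ms", names(x$latencies), x$latencies),
              collapse = ", "), "\n")
  }
  invisible(x)
}
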