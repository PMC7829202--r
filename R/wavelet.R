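# Discrete wavelet transform as a two-channel filter bank with symmetric
# boundary extension. Denoising decomposes a windowed trace in six levels
# and reconstructs from the level-6 approximation plus the level 4-6
# details, discarding the high-frequency bands that carry broadband noise.

# Orthogonal filter banks (decomposition low/high, reconstruction low/high).
# Coefficients are the standard Daubechies / symlet values.
wavelet_filters <- function(family) {
  tab <- list(
    haar = list(
      dec_lo = c(0.7071067811865476, 0.7071067811865476),
      dec_hi = c(-0.7071067811865476, 0.7071067811865476),
      rec_lo = c(0.7071067811865476, 0.7071067811865476),
      rec_hi = c(0.7071067811865476, -0.7071067811865476)
    ),
    db2 = list(
      dec_lo = c(-0.12940952255126037, 0.2241438680420134,
                 0.8365163037378079, 0.48296291314453416),
      dec_hi = c(-0.48296291314453416, 0.8365163037378079,
                 -0.2241438680420134, -0.12940952255126037),
      rec_lo = c(0.48296291314453416, 0.8365163037378079,
                 0.2241438680420134, -0.12940952255126037),
      rec_hi = c(-0.12940952255126037, -0.2241438680420134,
                 0.8365163037378079, -0.48296291314453416)
    ),
    db4 = list(
      dec_lo = c(-0.010597401785069032, 0.0328830116668852,
                 0.030841381835560764, -0.18703481171909309,
                 -0.027983769416859854, 0.6308807679298589,
                 0.7148465705529157, 0.2303778133088965),
      dec_hi = c(-0.2303778133088965, 0.7148465705529157,
                 -0.6308807679298589, -0.027983769416859854,
                 0.18703481171909309, 0.030841381835560764,
                 -0.0328830116668852, -0.010597401785069032),
      rec_lo = c(0.2303778133088965, 0.7148465705529157,
                 0.6308807679298589, -0.027983769416859854,
                 -0.18703481171909309, 0.030841381835560764,
                 0.0328830116668852, -0.010597401785069032),
      rec_hi = c(-0.010597401785069032, -0.0328830116668852,
                 0.030841381835560764, 0.18703481171909309,
                 -0.027983769416859854, -0.6308807679298589,
                 0.7148465705529157, -0.2303778133088965)
    ),
    sym4 = list(
      dec_lo = c(-0.07576571478927333, -0.02963552764599851,
                 0.49761866763201545, 0.8037387518059161,
                 0.29785779560527736, -0.09921954357684722,
                 -0.012603967262037833, 0.0322231006040427),
      dec_hi = c(-0.0322231006040427, -0.012603967262037833,
                 0.09921954357684722, 0.29785779560527736,
                 -0.8037387518059161, 0.49761866763201545,
                 0.02963552764599851, -0.07576571478927333),
      rec_lo = c(0.0322231006040427, -0.012603967262037833,
                 -0.09921954357684722, 0.29785779560527736,
                 0.8037387518059161, 0.49761866763201545,
                 -0.02963552764599851, -0.07576571478927333),
      rec_hi = c(-0.07576571478927333, 0.02963552764599851,
                 0.49761866763201545, -0.8037387518059161,
                 0.29785779560527736, 0.09921954357684722,
                 -0.012603967262037833, -0.0322231006040427)
    )
  )
  tab$db1 <- tab$haar
  f <- tab[[family]]
  if (is.null(f)) {
    stop("unknown wavelet family '", family, "'; available: ",
         paste(setdiff(names(tab), "db1"), collapse = ", "))
  }
  f
}

#' Wavelet preprocessing specification
#'
#' @param levels Decomposition depth (default 6).
#' @param retained_details Detail levels kept at reconstruction
#'   (default 4, 5, 6).
#' @param retain_approximation Keep the level-`levels` approximation
#'   (default `TRUE`).
#' @param family Wavelet family: `"haar"`/`"db1"`, `"db2"`, `"db4"` or
#'   `"sym4"` (default `"db4"`).
#' @return An object of class `"wavelet_spec"`.
#' @export
wavelet_spec <- function(levels = 6L, retained_details = c(4L, 5L, 6L),
                         retain_approximation = TRUE, family = "db4") {
  levels <- as.integer(levels)
  retained_details <- as.integer(retained_details)
  stopifnot(levels >= 1L)
  if (length(retained_details) > 0 &&
      any(retained_details < 1L | retained_details > levels)) {
    stop("retained detail levels must lie in 1..levels")
  }
  wavelet_filters(family)  # validates the family name
  structure(
    list(levels = levels, retained_details = retained_details,
         retain_approximation = isTRUE(retain_approximation), family = family),
    class = "wavelet_spec"
  )
}

# One analysis step: symmetric extension by (filter length - 1) samples each
# side, filtering, dyadic downsampling.
dwt_step <- function(x, filt) {
  fl <- length(filt$dec_lo)
  p <- fl - 1L
  n <- length(x)
  lp <- if (p <= n) rev(x[1:p]) else rev(rep_len(c(x, rev(x)), p))
  rp <- if (p <= n) rev(x[(n - p + 1L):n]) else rev(rep_len(c(rev(x), x), p))
  ext <- c(lp, x, rp)
  out_len <- (n + fl - 1L) %/% 2L
  conv_lo <- convolve(ext, rev(filt$dec_lo), type = "open")
  conv_hi <- convolve(ext, rev(filt$dec_hi), type = "open")
  idx <- 2L * (seq_len(out_len) - 1L) + fl + 1L
  list(cA = conv_lo[idx], cD = conv_hi[idx])
}

# One synthesis step: upsample, filter, overlap-add, trim to out_len.
idwt_step <- function(cA, cD, filt, out_len) {
  fl <- length(filt$rec_lo)
  la <- length(cA)
  up <- function(cf) {
    u <- numeric(2L * la)
    u[seq(1L, 2L * la, 2L)] <- cf
    u
  }
  full <- convolve(up(cA), rev(filt$rec_lo), type = "open") +
          convolve(up(cD), rev(filt$rec_hi), type = "open")
  full[(fl - 1L):(fl - 2L + out_len)]
}

#' Multi-level wavelet decomposition
#'
#' @param trace A `"windowed_trace"` or numeric vector.
#' @param spec A [wavelet_spec()].
#' @return An object of class `"wavelet_decomposition"` holding the
#'   approximation of level `levels`, the detail coefficients of every level,
#'   and the per-level signal lengths needed for exact inversion.
#' @export
wavelet_decompose <- function(trace, spec = wavelet_spec()) {
  stopifnot(inherits(spec, "wavelet_spec"))
  x <- as.numeric(trace)
  filt <- wavelet_filters(spec$family)
  details <- vector("list", spec$levels)
  lengths <- integer(spec$levels)
  cur <- x
  for (lvl in seq_len(spec$levels)) {
    lengths[lvl] <- length(cur)
    st <- dwt_step(cur, filt)
    details[[lvl]] <- st$cD
    cur <- st$cA
  }
  structure(
    list(approximation = cur, details = details, lengths = lengths,
         family = spec$family, levels = spec$levels, n = length(x)),
    class = "wavelet_decomposition"
  )
}

#' @export
print.wavelet_decomposition <- function(x, ...) {
  cat(sprintf("Wavelet decomposition: %s, %d levels, signal length %d\n",
              x$family, x$levels, x$n))
  invisible(x)
}

# Inverse transform with per-band retention masks.
wavelet_inverse <- function(decomp, keep_approx, keep_details) {
  filt <- wavelet_filters(decomp$family)
  a <- if (keep_approx) decomp$approximation
       else numeric(length(decomp$approximation))
  for (lvl in rev(seq_len(decomp$levels))) {
    d <- if (lvl %in% keep_details) decomp$details[[lvl]]
         else numeric(length(decomp$details[[lvl]]))
    a <- idwt_step(a, d, filt, decomp$lengths[lvl])
  }
  a
}

#' Reconstruct from retained sub-bands
#'
#' Zeroes every detail level not in `spec$retained_details` (and the
#' approximation unless retained), inverse-transforms and truncates to the
#' original length. Retaining everything inverts the decomposition exactly.
#'
#' @param decomp A `"wavelet_decomposition"`.
#' @param spec The [wavelet_spec()] used at decomposition.
#' @return Numeric vector of the original signal length.
#' @export
reconstruct_retained <- function(decomp, spec = wavelet_spec()) {
  stopifnot(inherits(decomp, "wavelet_decomposition"),
            inherits(spec, "wavelet_spec"))
  if (spec$levels != decomp$levels || spec$family != decomp$family) {
    stop("wavelet spec does not match the decomposition")
  }
  wavelet_inverse(decomp, spec$retain_approximation, spec$retained_details)
}

#' Denoise a recording by sub-band selection
#'
#' Convenience composition: extract the 0-8 ms window, decompose, reconstruct
#' from the retained sub-bands, and re-embed the smoothed window into a copy
#' of the recording. Annotations are untouched by design.
#'
#' @param recording An [abr_recording()].
#' @param spec A [wavelet_spec()].
#' @return A new [abr_recording()] with the analysis window smoothed.
#' @export
denoise_recording <- function(recording, spec = wavelet_spec()) {
  stopifnot(inherits(recording, "abr_recording"))
  win <- extract_window(recording)
  rec_win <- reconstruct_retained(wavelet_decompose(win, spec), spec)
  pot <- recording$potentials
  pot[window_indices(recording$grid)] <- rec_win
  abr_recording(pot, recording$grid, recording$subject_class,
                recording$stimulus_level)
}
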