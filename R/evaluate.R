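# Tolerance-window scoring. A predicted latency counts as correct when it
# falls within the maximum allowable error (ME; 0.1 / 0.15 / 0.2 ms) of a
# manually marked point; accuracy is matched points over total marked
# points, pooled over the dataset. The metric is recall-like: spurious
# predictions far from any mark do not change it.

# Kuhn's augmenting-path maximum bipartite matching on the |pred - truth| <=
# me adjacency; used as the optional optimal assignment mode.
max_matching <- function(truth, pred, me) {
  nt <- length(truth); np <- length(pred)
  adj <- lapply(seq_len(nt), function(i) which(abs(pred - truth[i]) <= me + 1e-12))
  match_p <- rep(NA_integer_, np)
  try_aug <- function(i, seen) {
    for (j in adj[[i]]) {
      if (!seen[j]) {
        seen[j] <- TRUE
        if (is.na(match_p[j]) || Recall(match_p[j], seen)) {
          match_p[j] <<- i
          return(TRUE)
        }
      }
    }
    FALSE
  }
  cnt <- 0L
  for (i in seq_len(nt)) {
    seen <- rep(FALSE, np)
    if (nt > 0L && try_aug(i, seen)) cnt <- cnt + 1L
  }
  matched_truth <- rep(FALSE, nt)
  matched_truth[match_p[!is.na(match_p)]] <- TRUE
  matched_truth
}

#' Match predicted latencies to annotated waves
#'
#' Annotated waves are processed in latency order; each is matched to the
#' nearest still-unmatched predicted center, and the match is accepted when
#' `|predicted - truth| <= me`. One prediction can credit at most one wave.
#' `method = "optimal"` replaces the greedy pass with a maximum bipartite
#' assignment for sensitivity analysis.
#'
#' @param predicted A `"peak_regions"` data frame or numeric vector of
#'   predicted latencies (ms).
#' @param truth A [wave_annotation()].
#' @param me Maximum allowable error in ms (> 0).
#' @param method `"greedy"` (default) or `"optimal"`.
#' @return Data frame with one row per annotated wave: `wave`, `truth_ms`,
#'   `pred_ms` (`NA` if unmatched), `matched`.
#' @export
match_peaks <- function(predicted, truth, me = 0.2,
                        method = c("greedy", "optimal")) {
  method <- match.arg(method)
  stopifnot(me > 0, inherits(truth, "wave_annotation"))
  centers <- if (is.data.frame(predicted)) predicted$center_ms
             else as.numeric(predicted)
  tl <- truth$latencies
  out <- data.frame(wave = names(tl), truth_ms = unname(tl),
                    pred_ms = NA_real_, matched = FALSE,
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L || length(centers) == 0L) return(out)
  if (method == "greedy") {
    free <- rep(TRUE, length(centers))
    for (i in order(out$truth_ms)) {
      d <- abs(centers - out$truth_ms[i])
      d[!free] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= me + 1e-12) {
        out$pred_ms[i] <- centers[j]
        out$matched[i] <- TRUE
        free[j] <- FALSE
      }
    }
  } else {
    out$matched <- max_matching(out$truth_ms, centers, me)
  }
  out
}

#' Dataset-level tolerance accuracy
#'
#' Pools matched points `r_p` and annotated points `p_n` over all sweeps
#' before dividing (micro-average), for each tolerance in `me`. Sweeps with
#' missing waves contribute fewer annotated points. A supplementary
#' false-positive count (predicted regions matching no annotation at the
#' largest ME) is reported but excluded from the accuracy.
#'
#' @param predictions List of `"peak_regions"` data frames or latency
#'   vectors, one per sweep.
#' @param annotations List of [wave_annotation()], parallel to
#'   `predictions`.
#' @param me Numeric vector of tolerances in ms.
#' @param method Matching method, see [match_peaks()].
#' @return An object of class `"abr_eval"`: per-ME accuracy, per-wave
#'   breakdown, pooled counts.
#' @export
abr_accuracy <- function(predictions, annotations, me = c(0.1, 0.15, 0.2),
                         method = "greedy") {
  stopifnot(length(predictions) == length(annotations), length(me) >= 1)
  waves <- c("I", "III", "V")
  acc <- numeric(length(me))
  rp <- integer(length(me))
  per_wave <- matrix(0L, nrow = length(me), ncol = length(waves) + 1,
                     dimnames = list(format(me), c(waves, "total")))
  pn_wave <- stats::setNames(integer(length(waves)), waves)
  pn <- 0L
  fp <- 0L
  me_max <- max(me)
  for (s in seq_along(predictions)) {
    ann <- annotations[[s]]
    pn <- pn + length(ann$latencies)
    for (wv in names(ann$latencies)) pn_wave[wv] <- pn_wave[wv] + 1L
    centers <- if (is.data.frame(predictions[[s]])) predictions[[s]]$center_ms
               else as.numeric(predictions[[s]])
    for (m in seq_along(me)) {
      mt <- match_peaks(predictions[[s]], ann, me[m], method)
      rp[m] <- rp[m] + sum(mt$matched)
      for (wv in mt$wave[mt$matched]) {
        per_wave[m, wv] <- per_wave[m, wv] + 1L
      }
    }
    if (length(centers) > 0L && length(ann$latencies) > 0L) {
      fp <- fp + sum(vapply(centers, function(cc) {
        all(abs(cc - ann$latencies) > me_max)
      }, logical(1)))
    } else {
      fp <- fp + length(centers) * (length(ann$latencies) == 0L)
    }
  }
  if (pn == 0L) stop("no annotated points in the dataset")
  per_wave[, "total"] <- rp
  structure(
    list(me = me, acc = rp / pn, r_p = rp, p_n = pn,
         per_wave_matched = per_wave, per_wave_total = pn_wave,
         false_positives = fp, n_sweeps = length(predictions)),
    class = "abr_eval"
  )
}

#' @export
print.abr_eval <- function(x, ...) {
  cat(sprintf("Tolerance accuracy over %d sweeps (%d annotated points):\n",
              x$n_sweeps, x$p_n))
  for (m in seq_along(x$me)) {
    cat(sprintf("  ACC@%.2f ms: %6.2f%%  (%d / %d matched)\n",
                x$me[m], 100 * x$acc[m], x$r_p[m], x$p_n))
  }
  cat(sprintf("  spurious regions (no mark within %.2f ms): %d\n",
              max(x$me), x$false_positives))
  invisible(x)
}

#' Fold assignment for k-fold cross-validation
#'
#' @param n Number of items.
#' @param k Number of folds (sizes differ by at most one).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in 1..k.
#' @export
kfold_assign <- function(n, k, seed = 1L) {
  if (k < 2L) stop("k must be at least 2")
  if (n < k) stop("dataset smaller than the number of folds")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Repeated k-fold cross-validation of the sequence classifier
#'
#' Each repeat reshuffles the data with a seed derived from the master seed,
#' splits it into `k` folds, trains on `k - 1` and scores the held-out fold,
#' rotating over all folds. Reported are mean and SD of the tolerance
#' accuracies and of the final training/validation losses.
#'
#' @param dataset An `"abr_dataset"`.
#' @param k Number of folds (default 9).
#' @param repeats Number of repeats (default 5).
#' @param config A [sequence_model_config()].
#' @param me Tolerances in ms.
#' @param seed Master seed.
#' @param denoise Optional [wavelet_spec()] applied before training/scoring.
#' @return Object of class `"abr_cv"`: per-fold table plus mean/SD summary.
#' @export
repeated_kfold <- function(dataset, k = 9L, repeats = 5L,
                           config = sequence_model_config(),
                           me = c(0.1, 0.15, 0.2), seed = 1L,
                           denoise = NULL) {
  set.seed(seed)
  repeat_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  rows <- list()
  for (r in seq_len(repeats)) {
    folds <- kfold_assign(length(dataset), k, repeat_seeds[r])
    for (f in seq_len(k)) {
      tr <- dataset[folds != f]
      va <- dataset[folds == f]
      class(tr) <- class(va) <- "abr_dataset"
      cfg <- config
      cfg$seed <- (repeat_seeds[r] + f) %% .Machine$integer.max
      fit <- abr_fit(tr, config = cfg, denoise = denoise, verbose = FALSE)
      preds <- predict(fit, va, type = "regions")
      ev <- abr_accuracy(preds, lapply(va, `[[`, "annotation"), me)
      log <- fit$log
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_id = r, fold = f,
        train_loss = log$train_loss[nrow(log)],
        val_loss = log$val_loss[nrow(log)],
        t(stats::setNames(ev$acc, paste0("acc_", me)))
      )
    }
  }
  tab <- do.call(rbind, rows)
  num <- tab[, -(1:2), drop = FALSE]
  structure(
    list(folds = tab,
         mean = colMeans(num),
         sd = apply(num, 2, stats::sd),
         k = k, repeats = repeats, me = me, seed = seed),
    class = "abr_cv"
  )
}

#' @export
print.abr_cv <- function(x, ...) {
  cat(sprintf("%d x %d-fold cross-validation (%d fits):\n",
              x$repeats, x$k, nrow(x$folds)))
  for (nm in names(x$mean)) {
    cat(sprintf("  %-12s %.4f (SD %.4f)\n", nm, x$mean[nm], x$sd[nm]))
  }
  invisible(x)
}
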