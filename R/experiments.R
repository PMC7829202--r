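# The three comparison experiments: architecture grid (seven structures),
# wavelet-vs-raw preprocessing under injected interference, and the
# hidden-width grid for the three-layer bidirectional network. All arms of
# an experiment share one train/test split and one master seed, so
# comparisons are paired.

config_hash <- function(obj) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(obj), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

experiment_row <- function(name, fit, ev, seed, cfg) {
  last <- fit$log[nrow(fit$log), ]
  cbind(
    data.frame(structure = name, train_loss = last$train_loss,
               val_loss = last$val_loss, stringsAsFactors = FALSE),
    t(stats::setNames(ev$acc, paste0("acc_", format(ev$me)))),
    data.frame(seed = seed, config_hash = config_hash(cfg),
               stringsAsFactors = FALSE)
  )
}

split_train_test <- function(dataset, n_train, seed) {
  man <- dataset_manifest(
    seq_along(dataset),
    vapply(dataset, function(s) s$recording$subject_class, character(1))
  )
  man <- split_dataset(man, n_train, seed)
  list(train = which(man$split == "train"), test = which(man$split == "test"))
}

fit_and_score <- function(dataset, idx, config, me, denoise = NULL,
                          verbose = FALSE) {
  tr <- dataset[idx$train]
  te <- dataset[idx$test]
  class(tr) <- class(te) <- "abr_dataset"
  fit <- abr_fit(tr, config = config, denoise = denoise, verbose = verbose)
  preds <- predict(fit, te, type = "regions")
  ev <- abr_accuracy(preds, lapply(te, `[[`, "annotation"), me)
  list(fit = fit, ev = ev)
}

#' Architecture comparison grid
#'
#' Trains each structure (by default the seven studied ones) on a shared
#' train/test split and reports final losses and tolerance accuracies.
#'
#' @param dataset An `"abr_dataset"`.
#' @param n_train Training-set size; the rest is the held-out test set.
#' @param structures Named list of [sequence_model_config()] (default
#'   [studied_structures()]).
#' @param me Tolerances in ms.
#' @param seed Master seed (split + per-structure training seeds).
#' @param denoise Optional [wavelet_spec()].
#' @param verbose Print training progress.
#' @return Data frame, one row per structure, with `train_loss`,
#'   `val_loss`, one `acc_*` column per tolerance, `seed` and `config_hash`.
#' @export
run_architecture_grid <- function(dataset, n_train,
                                  structures = studied_structures(),
                                  me = c(0.1, 0.15, 0.2), seed = 1L,
                                  denoise = NULL, verbose = FALSE) {
  idx <- split_train_test(dataset, n_train, seed)
  rows <- lapply(names(structures), function(nm) {
    cfg <- structures[[nm]]
    cfg$seed <- seed
    r <- fit_and_score(dataset, idx, cfg, me, denoise, verbose)
    experiment_row(nm, r$fit, r$ev, seed, cfg)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Wavelet-vs-raw preprocessing comparison
#'
#' Injects the same seed-reproducible interference noise into every sweep,
#' then trains each structure twice on byte-identical corrupted data: once
#' raw, once denoised with the retained-sub-band reconstruction. Rows are
#' paired by structure.
#'
#' @param dataset An `"abr_dataset"` (clean).
#' @param n_train Training-set size.
#' @param noise A [noise_spec()] for the injected interference.
#' @param spec A [wavelet_spec()] for the denoising arm.
#' @param structures Named list of configs.
#' @param me Tolerances in ms (the comparison uses 0.1 and 0.2 by default).
#' @param seed Master seed.
#' @param verbose Print training progress.
#' @return Data frame with one row per structure and arm
#'   (`arm` in `"raw"`, `"wavelet"`).
#' @export
run_wavelet_comparison <- function(dataset, n_train,
                                   noise = noise_spec(baseline_sd = 0.05,
                                                      drift_amplitude = 0.03,
                                                      late_artifact_prob = 0),
                                   spec = wavelet_spec(),
                                   structures = studied_structures(),
                                   me = c(0.1, 0.2), seed = 1L,
                                   verbose = FALSE) {
  set.seed(seed)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, length(dataset))
  noisy <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    s$recording <- add_interference_noise(s$recording, noise, noise_seeds[i])
    s
  })
  class(noisy) <- "abr_dataset"
  idx <- split_train_test(noisy, n_train, seed)
  rows <- list()
  for (nm in names(structures)) {
    cfg <- structures[[nm]]
    cfg$seed <- seed
    for (arm in c("raw", "wavelet")) {
      dn <- if (arm == "wavelet") spec else NULL
      r <- fit_and_score(noisy, idx, cfg, me, dn, verbose)
      row <- experiment_row(nm, r$fit, r$ev, seed, cfg)
      row$arm <- arm
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Hidden-width comparison grid
#'
#' Fixes the architecture (three-layer bidirectional by default) and varies
#' the hidden width over 64, 128, 256 and 512 nodes.
#'
#' @param dataset An `"abr_dataset"`.
#' @param n_train Training-set size.
#' @param hidden_nodes Widths to compare.
#' @param base_config Template [sequence_model_config()]; its width is
#'   overridden per row.
#' @param me Tolerances in ms.
#' @param seed Master seed.
#' @param verbose Print training progress.
#' @return Data frame, one row per width.
#' @export
run_hidden_grid <- function(dataset, n_train,
                            hidden_nodes = c(64L, 128L, 256L, 512L),
                            base_config = sequence_model_config("bi", 3L),
                            me = c(0.1, 0.15, 0.2), seed = 1L,
                            verbose = FALSE) {
  idx <- split_train_test(dataset, n_train, seed)
  rows <- lapply(hidden_nodes, function(h) {
    cfg <- base_config
    cfg$hidden_nodes <- as.integer(h)
    cfg$seed <- seed
    r <- fit_and_score(dataset, idx, cfg, me, NULL, verbose)
    row <- experiment_row(structure_name(cfg), r$fit, r$ev, seed, cfg)
    row$hidden_nodes <- as.integer(h)
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write an experiment table as JSON lines (plus CSV)
#'
#' @param results Data frame from one of the `run_*` functions.
#' @param path Output path for the `.jsonl`; a sibling `.csv` is written
#'   alongside.
#' @export
write_results <- function(results, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(results))) {
    writeLines(jsonlite::toJSON(as.list(results[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  }
  utils::write.csv(results, sub("\\.jsonl?$", ".csv", path), row.names = FALSE)
  invisible(path)
}
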