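# On-disk formats: CSV for traces (header `time_ms,potential_uv`), JSON for
# annotations and predictions. Units are ms and uV throughout.

#' Write / read an ABR sweep as CSV
#'
#' Two-column CSV `time_ms,potential_uv`, one row per grid sample, full
#' double precision. Reading validates the canonical grid: sample count,
#' uniform spacing (within 1e-6 ms) and numeric cells.
#'
#' @param recording An [abr_recording()].
#' @param path File path.
#' @param grid Expected [abr_grid()] on read.
#' @return `read_recording` returns an [abr_recording()];
#'   `write_recording` returns `path` invisibly.
#' @export
write_recording <- function(recording, path) {
  stopifnot(inherits(recording, "abr_recording"))
  df <- data.frame(
    time_ms = grid_time(recording$grid, seq_len(recording$grid$n_samples)),
    potential_uv = recording$potentials
  )
  utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path, grid = abr_grid()) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, colClasses = "character")
  if (!identical(names(df), c("time_ms", "potential_uv"))) {
    stop("expected header 'time_ms,potential_uv' in ", path)
  }
  tm <- suppressWarnings(as.numeric(df$time_ms))
  pv <- suppressWarnings(as.numeric(df$potential_uv))
  bad <- which(!is.finite(tm) | !is.finite(pv))
  if (length(bad) > 0L) {
    stop(sprintf("non-numeric cell at data row %d of %s", bad[1], path))
  }
  if (nrow(df) != grid$n_samples) {
    stop(sprintf("expected %d samples, found %d in %s",
                 grid$n_samples, nrow(df), path))
  }
  sp <- diff(tm)
  if (any(abs(sp - grid$dt) > 1e-6)) {
    i <- which(abs(sp - grid$dt) > 1e-6)[1]
    stop(sprintf("non-uniform spacing at row %d: %g ms (expected %g ms)",
                 i + 1L, sp[i], grid$dt))
  }
  abr_recording(pv, grid)
}

#' Write / read a wave annotation as JSON
#'
#' JSON object with optional keys `"I"`, `"III"`, `"V"` mapping to latencies
#' in ms, e.g. `{"I":1.62,"III":3.90,"V":5.72}`. Unknown keys are rejected;
#' the range and ordering invariants are enforced on read.
#'
#' @param ann A [wave_annotation()].
#' @param path File path.
#' @return `read_annotation` returns a [wave_annotation()];
#'   `write_annotation` returns `path` invisibly.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "wave_annotation"))
  jsonlite::write_json(as.list(ann$latencies), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_annotation
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::read_json(path)
  wave_annotation(unlist(obj))
}

#' Dataset manifest and train/test split
#'
#' A manifest records sweep paths (or ids), class labels and the train/test
#' assignment. `split_dataset` draws the training set uniformly at random
#' without replacement; with `stratify = TRUE` the class proportions are
#' preserved across the two sets.
#'
#' @param ids Character vector of sweep identifiers (paths or names).
#' @param classes Character vector of per-sweep class labels.
#' @return `dataset_manifest` returns an object of class `"abr_manifest"`.
#' @export
dataset_manifest <- function(ids, classes = rep("normal", length(ids))) {
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated sweep ids in manifest")
  stopifnot(length(classes) == length(ids))
  structure(
    data.frame(id = ids, class = as.character(classes), split = NA_character_,
               stringsAsFactors = FALSE),
    class = c("abr_manifest", "data.frame"), split_seed = NA_integer_
  )
}

#' @rdname dataset_manifest
#' @param manifest An `"abr_manifest"`.
#' @param n_train Number of training sweeps (must be < total).
#' @param seed Integer seed for the split.
#' @param stratify Preserve class proportions across splits.
#' @export
split_dataset <- function(manifest, n_train, seed = 1L, stratify = FALSE) {
  stopifnot(inherits(manifest, "abr_manifest"))
  n <- nrow(manifest)
  if (n_train >= n) stop(sprintf("n_train (%d) must be smaller than the dataset (%d)",
                                 n_train, n))
  if (n_train < 1L) stop("n_train must be at least 1")
  set.seed(seed)
  if (stratify) {
    idx_train <- integer(0)
    frac <- n_train / n
    for (cl in unique(manifest$class)) {
      pool <- which(manifest$class == cl)
      idx_train <- c(idx_train, sample(pool, round(length(pool) * frac)))
    }
    # adjust to the exact requested size
    while (length(idx_train) > n_train) idx_train <- idx_train[-length(idx_train)]
    if (length(idx_train) < n_train) {
      extra <- sample(setdiff(seq_len(n), idx_train), n_train - length(idx_train))
      idx_train <- c(idx_train, extra)
    }
  } else {
    idx_train <- sample(n, n_train)
  }
  manifest$split <- "test"
  manifest$split[idx_train] <- "train"
  attr(manifest, "split_seed") <- as.integer(seed)
  manifest
}

#' Write a simulated dataset to a directory
#'
#' One CSV per sweep (`sweep_0001.csv`, ...), one JSON annotation per sweep,
#' and a `manifest.csv` recording ids and class labels.
#'
#' @param dataset An `"abr_dataset"` from [simulate_dataset()].
#' @param dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "abr_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(dataset)
  ids <- sprintf("sweep_%04d", seq_len(n))
  for (i in seq_len(n)) {
    write_recording(dataset[[i]]$recording, file.path(dir, paste0(ids[i], ".csv")))
    write_annotation(dataset[[i]]$annotation, file.path(dir, paste0(ids[i], ".json")))
  }
  classes <- vapply(dataset, function(s) s$recording$subject_class, character(1))
  man <- dataset_manifest(ids, classes)
  utils::write.csv(as.data.frame(man), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(man)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.csv` plus per-sweep files.
#' @param grid Expected [abr_grid()].
#' @return An `"abr_dataset"` list.
#' @export
read_dataset <- function(dir, grid = abr_grid()) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         colClasses = "character")
  out <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    rec <- read_recording(file.path(dir, paste0(man$id[i], ".csv")), grid)
    rec$subject_class <- man$class[i]
    out[[i]] <- list(
      recording = rec,
      annotation = read_annotation(file.path(dir, paste0(man$id[i], ".json")))
    )
  }
  structure(out, class = "abr_dataset")
}
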