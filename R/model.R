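# The per-sample sequence classifier: stacks of unidirectional or
# bidirectional LSTM layers with a shared affine + softmax head applied
# independently at each of the 321 window samples, trained with per-step
# cross-entropy and Adam. The recurrent forward/backward passes live in
# compiled code (src/lstm.cpp); this file holds configuration, parameter
# initialization, the training loop and prediction.

#' Sequence model configuration
#'
#' The seven studied architectures are expressible: `LSTM`, `LSTMx2`,
#' `BiLSTM`, `BiLSTMx2` .. `BiLSTMx5`; hidden widths studied are 64, 128,
#' 256 and 512.
#'
#' @param directionality `"bi"` (default) or `"uni"`.
#' @param num_layers Number of recurrent layers, 1-5.
#' @param hidden_nodes Hidden width per direction (default 512).
#' @param learning_rate Adam learning rate.
#' @param epochs Training epochs.
#' @param batch_size Minibatch size.
#' @param val_frac Fraction of the training data carved off for per-epoch
#'   validation loss (never the test set).
#' @param seed Integer seed for initialization and batching.
#' @return An object of class `"sequence_model_config"`.
#' @export
sequence_model_config <- function(directionality = c("bi", "uni"),
                                  num_layers = 3L, hidden_nodes = 512L,
                                  learning_rate = 1e-3, epochs = 60L,
                                  batch_size = 32L, val_frac = 0.1,
                                  seed = 1L) {
  directionality <- match.arg(directionality)
  num_layers <- as.integer(num_layers)
  if (num_layers < 1L || num_layers > 5L) stop("num_layers must be in 1..5")
  stopifnot(hidden_nodes >= 1, learning_rate > 0, epochs >= 1,
            batch_size >= 1, val_frac >= 0, val_frac < 1)
  structure(
    list(directionality = directionality, num_layers = num_layers,
         hidden_nodes = as.integer(hidden_nodes),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), val_frac = val_frac,
         seed = as.integer(seed)),
    class = "sequence_model_config"
  )
}

#' Architecture name of a configuration
#' @param config A [sequence_model_config()].
#' @return Character like `"BiLSTMx3"`.
#' @export
structure_name <- function(config) {
  base <- if (config$directionality == "bi") "BiLSTM" else "LSTM"
  if (config$num_layers > 1L) paste0(base, "x", config$num_layers) else base
}

#' The seven studied network structures
#'
#' @param hidden_nodes Hidden width shared by all entries.
#' @param ... Further arguments passed to [sequence_model_config()].
#' @return Named list of seven [sequence_model_config()] objects.
#' @export
studied_structures <- function(hidden_nodes = 512L, ...) {
  specs <- list(
    list(dir = "uni", layers = 1L), list(dir = "uni", layers = 2L),
    list(dir = "bi", layers = 1L), list(dir = "bi", layers = 2L),
    list(dir = "bi", layers = 3L), list(dir = "bi", layers = 4L),
    list(dir = "bi", layers = 5L)
  )
  out <- lapply(specs, function(s) {
    sequence_model_config(s$dir, s$layers, hidden_nodes, ...)
  })
  names(out) <- vapply(out, structure_name, character(1))
  out
}

# --- parameter initialization ------------------------------------------

# Gates are stacked i, f, a (candidate), o in the 4H blocks. Forget-gate
# biases start at 1 so memory cells retain state early in training.
init_direction <- function(H, D) {
  k <- 1 / sqrt(H)
  b <- numeric(4 * H)
  b[(H + 1):(2 * H)] <- 1
  list(
    W = matrix(stats::runif(4 * H * H, -k, k), 4 * H, H),
    U = matrix(stats::runif(4 * H * D, -k, k), 4 * H, D),
    b = b
  )
}

#' Build (initialize) a sequence model
#'
#' @param config A [sequence_model_config()].
#' @param input_dim Input width per step (1 for a potential trace).
#' @return An object of class `"abr_model"` holding the parameter list.
#' @export
build_model <- function(config, input_dim = 1L) {
  stopifnot(inherits(config, "sequence_model_config"))
  set.seed(config$seed)
  H <- config$hidden_nodes
  nd <- if (config$directionality == "bi") 2L else 1L
  layers <- vector("list", config$num_layers)
  D <- as.integer(input_dim)
  for (l in seq_len(config$num_layers)) {
    layers[[l]] <- list(dirs = lapply(seq_len(nd), function(d) init_direction(H, D)))
    D <- nd * H
  }
  k <- 1 / sqrt(D)
  head <- list(V = matrix(stats::runif(2 * D, -k, k), 2, D), c = numeric(2))
  structure(
    list(layers = layers, head = head, config = config,
         input_dim = as.integer(input_dim)),
    class = "abr_model"
  )
}

n_parameters <- function(model) {
  sum(vapply(rapply(model[c("layers", "head")], length, how = "unlist"),
             identity, numeric(1)))
}

#' @export
print.abr_model <- function(x, ...) {
  cat(sprintf("Sequence model: %s, %d hidden nodes/direction, %s parameters\n",
              structure_name(x$config), x$config$hidden_nodes,
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

# --- reference LSTM cell (pure R) --------------------------------------

#' One step of the reference LSTM cell
#'
#' A literal, loop-free transcription of the gate equations: forget gate
#' `f = sigmoid(W_f h + U_f x + b_f)`, input gate `i`, candidate
#' `a = tanh(W_a h + U_a x + b_a)`, memory update
#' `C_t = C_{t-1} * f + i * a` (elementwise), output gate `o`, and
#' `h_t = o * tanh(C_t)`. Serves as the independent oracle for the compiled
#' recurrent layer.
#'
#' @param params List with `W_f, U_f, b_f, W_i, U_i, b_i, W_a, U_a, b_a,
#'   W_o, U_o, b_o` (recurrent weights H x H, input weights H x D, biases
#'   length H).
#' @param x_t Input vector (length D).
#' @param h_prev,C_prev Previous hidden state and memory cell (length H).
#' @return List with `h` and `C`.
#' @export
lstm_cell_step <- function(params, x_t, h_prev, C_prev) {
  sg <- function(z) 1 / (1 + exp(-z))
  f <- sg(params$W_f %*% h_prev + params$U_f %*% x_t + params$b_f)
  i <- sg(params$W_i %*% h_prev + params$U_i %*% x_t + params$b_i)
  a <- tanh(params$W_a %*% h_prev + params$U_a %*% x_t + params$b_a)
  C_t <- C_prev * f + i * a
  o <- sg(params$W_o %*% h_prev + params$U_o %*% x_t + params$b_o)
  h_t <- o * tanh(C_t)
  list(h = as.numeric(h_t), C = as.numeric(C_t))
}

#' Split a combined direction parameter block into named gate matrices
#'
#' @param dir One element of `model$layers[[l]]$dirs` (combined `W`, `U`,
#'   `b` with gates stacked i, f, a, o).
#' @return Parameter list in the layout [lstm_cell_step()] expects.
#' @export
split_gates <- function(dir) {
  H <- ncol(dir$W)
  rows <- function(g) ((g - 1) * H + 1):(g * H)
  list(
    W_i = dir$W[rows(1), , drop = FALSE], U_i = dir$U[rows(1), , drop = FALSE],
    b_i = dir$b[rows(1)],
    W_f = dir$W[rows(2), , drop = FALSE], U_f = dir$U[rows(2), , drop = FALSE],
    b_f = dir$b[rows(2)],
    W_a = dir$W[rows(3), , drop = FALSE], U_a = dir$U[rows(3), , drop = FALSE],
    b_a = dir$b[rows(3)],
    W_o = dir$W[rows(4), , drop = FALSE], U_o = dir$U[rows(4), , drop = FALSE],
    b_o = dir$b[rows(4)]
  )
}

#' Unroll the reference cell over a sequence
#'
#' @param dir Combined direction parameters (see [split_gates()]).
#' @param x Input matrix, T x D.
#' @param reverse Process the sequence backward in time (hidden states are
#'   still returned at their original time indices).
#' @return T x H matrix of hidden states.
#' @export
reference_layer_hidden <- function(dir, x, reverse = FALSE) {
  p <- split_gates(dir)
  H <- ncol(dir$W)
  T_ <- nrow(x)
  h <- numeric(H)
  C <- numeric(H)
  out <- matrix(0, T_, H)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (t in ord) {
    st <- lstm_cell_step(p, x[t, ], h, C)
    h <- st$h
    C <- st$C
    out[t, ] <- h
  }
  out
}

# --- training ----------------------------------------------------------

# Refill a nested parameter skeleton from a flat vector (inverse of unlist,
# preserving matrix dims).
refill_params <- function(skel, vals) {
  pos <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    n <- length(x)
    out <- vals[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (!is.null(dim(x))) dim(out) <- dim(x)
    out
  }
  walk(skel)
}

model_loss <- function(model, x, y, chunk = 64L) {
  n <- ncol(x)
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    r <- cpp_nn_loss_grad(model$layers, model$head,
                          x[, s:e, drop = FALSE], y[, s:e, drop = FALSE],
                          FALSE)
    tot <- tot + r$loss * (e - s + 1L)
  }
  tot / n
}

#' Fit the sequence classifier
#'
#' Trains with minibatch Adam on per-step softmax cross-entropy. Accepts an
#' annotated `"abr_dataset"` (windowed, z-scored, labels dilated via
#' [prepare_training_data()]) or a ready `list(x =, y =)` of 321 x n
#' matrices. A validation fraction is carved from the training data for the
#' per-epoch validation loss.
#'
#' @param data An `"abr_dataset"` or `list(x, y)`.
#' @param config A [sequence_model_config()].
#' @param denoise Optional [wavelet_spec()] applied to each sweep before
#'   windowing.
#' @param radius Label dilation half-width in samples.
#' @param grid An [abr_grid()] (kept for prediction-time postprocessing).
#' @param verbose Print per-epoch losses.
#' @return An object of class `"abr_fit"`: trained parameters, config and a
#'   per-epoch `log` data frame with `train_loss` / `val_loss`.
#' @export
abr_fit <- function(data, config = sequence_model_config(), denoise = NULL,
                    radius = 4L, grid = abr_grid(), verbose = TRUE) {
  if (inherits(data, "abr_dataset")) {
    data <- prepare_training_data(data, radius = radius, denoise = denoise)
  }
  x <- data$x
  y <- data$y
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)), ncol(x) >= 1)
  model <- build_model(config)  # seeds the RNG via config$seed
  n <- ncol(x)
  n_val <- floor(config$val_frac * n)
  val_idx <- if (n_val > 0) sample(n, n_val) else integer(0)
  tr_idx <- setdiff(seq_len(n), val_idx)

  theta <- unlist(model[c("layers", "head")], use.names = FALSE)
  m <- numeric(length(theta))
  v <- numeric(length(theta))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_loss = numeric(0))
  skel <- model[c("layers", "head")]

  for (ep in seq_len(config$epochs)) {
    ord <- sample(tr_idx)
    ep_loss <- 0
    nb <- 0L
    for (s in seq(1L, length(ord), by = config$batch_size)) {
      e <- min(s + config$batch_size - 1L, length(ord))
      bi <- ord[s:e]
      r <- cpp_nn_loss_grad(model$layers, model$head,
                            x[, bi, drop = FALSE], y[, bi, drop = FALSE],
                            TRUE)
      if (!is.finite(r$loss)) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d; try a smaller learning rate", ep))
      }
      g <- unlist(r$grads, use.names = FALSE)
      step <- step + 1L
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g * g
      mhat <- m / (1 - b1^step)
      vhat <- v / (1 - b2^step)
      theta <- theta - config$learning_rate * mhat / (sqrt(vhat) + eps)
      filled <- refill_params(skel, theta)
      model$layers <- filled$layers
      model$head <- filled$head
      ep_loss <- ep_loss + r$loss * length(bi)
      nb <- nb + length(bi)
    }
    vl <- if (length(val_idx) > 0) {
      model_loss(model, x[, val_idx, drop = FALSE], y[, val_idx, drop = FALSE])
    } else NA_real_
    log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss / nb,
                                 val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %3d  train %.4f  val %s", ep, ep_loss / nb,
                      ifelse(is.na(vl), "-", sprintf("%.4f", vl))))
    }
  }
  structure(
    list(layers = model$layers, head = model$head, config = config,
         input_dim = 1L, log = log, grid = grid, n_train = length(tr_idx),
         n_val = length(val_idx), denoise = denoise),
    class = c("abr_fit", "abr_model")
  )
}

#' Per-sample feature probabilities
#'
#' @param model An `"abr_model"` or `"abr_fit"`.
#' @param trace A `"windowed_trace"`, numeric vector of length 321, or a
#'   321 x n matrix of (already normalized) traces.
#' @return Numeric vector (or matrix) of per-sample probabilities in
#'   \[0, 1\].
#' @export
predict_probs <- function(model, trace) {
  x <- if (is.matrix(trace)) trace else matrix(as.numeric(trace), ncol = 1)
  p <- cpp_nn_predict(model$layers, model$head, x)
  if (ncol(p) == 1L) as.numeric(p) else p
}

#' Predict on new recordings
#'
#' @param object An `"abr_fit"`.
#' @param newdata An `"abr_dataset"`, a single [abr_recording()], or a
#'   321 x n matrix of normalized windowed traces.
#' @param type `"probs"` (per-sample probabilities), `"regions"` (list of
#'   postprocessed `"peak_regions"`), or `"latencies"` (list of named
#'   latency vectors).
#' @param ... Passed to [postprocess_probs()] (cutoff, merge threshold, ...).
#' @return See `type`.
#' @export
predict.abr_fit <- function(object, newdata, type = c("probs", "regions",
                                                      "latencies"), ...) {
  type <- match.arg(type)
  if (inherits(newdata, "abr_recording")) {
    newdata <- structure(list(list(recording = newdata)), class = "abr_dataset")
  }
  if (inherits(newdata, "abr_dataset")) {
    x <- vapply(newdata, function(s) {
      rec <- s$recording
      if (!is.null(object$denoise)) rec <- denoise_recording(rec, object$denoise)
      normalize_trace(extract_window(rec))
    }, numeric(length(window_indices(object$grid))))
    x <- matrix(x, ncol = length(newdata))
  } else {
    x <- if (is.matrix(newdata)) newdata else matrix(as.numeric(newdata), ncol = 1)
  }
  # chunk to bound the activation-cache memory of the compiled forward pass
  probs <- matrix(0, nrow(x), ncol(x))
  for (s in seq(1L, ncol(x), by = 64L)) {
    e <- min(s + 63L, ncol(x))
    probs[, s:e] <- cpp_nn_predict(object$layers, object$head,
                                   x[, s:e, drop = FALSE])
  }
  if (type == "probs") {
    return(if (ncol(probs) == 1L) as.numeric(probs) else probs)
  }
  regions <- lapply(seq_len(ncol(probs)), function(i) {
    postprocess_probs(probs[, i], grid = object$grid, ...)
  })
  if (type == "regions") return(regions)
  lapply(regions, region_latencies)
}

#' @export
print.abr_fit <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf(
    "Fitted ABR sequence classifier: %s, %d hidden nodes\n  %d training / %d validation sweeps, %d epochs\n  final train loss %.4f, validation loss %s\n",
    structure_name(x$config), x$config$hidden_nodes, x$n_train, x$n_val,
    nrow(x$log), last$train_loss,
    ifelse(is.na(last$val_loss), "-", sprintf("%.4f", last$val_loss))))
  invisible(x)
}

#' @export
summary.abr_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  parameters: %s\n  denoising: %s\n",
              format(n_parameters(object), big.mark = ","),
              if (is.null(object$denoise)) "none"
              else paste0(object$denoise$family, ", ",
                          object$denoise$levels, " levels")))
  invisible(object$log)
}

#' @export
coef.abr_fit <- function(object, ...) {
  unlist(object[c("layers", "head")])
}

#' Plot a recording with model predictions
#'
#' Draws the 0-8 ms trace, the per-sample feature probability and the
#' detected wave regions; annotated latencies (if given) are marked.
#'
#' @param x An `"abr_fit"`.
#' @param recording An [abr_recording()].
#' @param annotation Optional [wave_annotation()].
#' @param ... Passed to [postprocess_probs()].
#' @export
plot.abr_fit <- function(x, recording, annotation = NULL, ...) {
  win <- extract_window(recording)
  tms <- attr(win, "times")
  probs <- predict(x, recording, type = "probs")
  regions <- postprocess_probs(probs, grid = x$grid, ...)
  op <- graphics::par(mfrow = c(2, 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::plot(tms, as.numeric(win), type = "l", xlab = "", ylab = "uV")
  if (nrow(regions) > 0) {
    graphics::abline(v = regions$center_ms, col = "red", lty = 2)
    keep <- !is.na(regions$wave)
    if (any(keep)) {
      graphics::text(regions$center_ms[keep], max(win),
                     regions$wave[keep], col = "red")
    }
  }
  if (!is.null(annotation)) {
    graphics::abline(v = annotation$latencies, col = "blue", lty = 3)
  }
  graphics::plot(tms, probs, type = "l", ylim = c(0, 1),
                 xlab = "time (ms)", ylab = "P(feature)")
  graphics::abline(h = 0.5, lty = 3)
  invisible(regions)
}
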