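test_that("the reference cell reproduces hand-derived degenerate cases", {
  H <- 3L; D <- 2L
  zeros <- list(
    W_f = matrix(0, H, H), U_f = matrix(0, H, D), b_f = numeric(H),
    W_i = matrix(0, H, H), U_i = matrix(0, H, D), b_i = numeric(H),
    W_a = matrix(0, H, H), U_a = matrix(0, H, D), b_a = numeric(H),
    W_o = matrix(0, H, H), U_o = matrix(0, H, D), b_o = numeric(H)
  )
  # all-zero parameters: candidate tanh(0) = 0, so C and h stay 0
  st <- lstm_cell_step(zeros, c(1, -2), rep(0.5, H), rep(0, H))
  expect_equal(st$C, rep(0, H))
  expect_equal(st$h, rep(0, H))

  # zero weights, C_prev = c: gates are 1/2, so C = c/2, h = tanh(c/2)/2
  cp <- c(0.4, -1, 2)
  st2 <- lstm_cell_step(zeros, c(0, 0), rep(0, H), cp)
  expect_equal(st2$C, 0.5 * cp)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cp))
})

test_that("compiled layer matches the reference cell chain on random instances", {
  set.seed(40)
  worst <- 0
  for (rep in 1:100) {
    H <- sample(2:8, 1); D <- sample(1:4, 1); T_ <- sample(5:15, 1)
    dir <- abrwave:::init_direction(H, D)
    dir$W <- matrix(rnorm(4 * H * H, sd = 0.5), 4 * H, H)
    dir$U <- matrix(rnorm(4 * H * D, sd = 0.5), 4 * H, D)
    dir$b <- rnorm(4 * H, sd = 0.5)
    X <- matrix(rnorm(T_ * D), T_, D)
    rev <- rep %% 2 == 0
    got <- abrwave:::cpp_layer_hidden(dir, X, rev)
    want <- reference_layer_hidden(dir, X, rev)
    worst <- max(worst, max(abs(got - want)))
  }
  expect_lt(worst, 1e-5)
})

test_that("analytic gradients match finite differences", {
  set.seed(41)
  m <- build_model(sequence_model_config("bi", 2, 4, seed = 11))
  X <- matrix(rnorm(15 * 3), 15, 3)
  Y <- matrix(rbinom(45, 1, 0.3), 15, 3)
  r <- abrwave:::cpp_nn_loss_grad(m$layers, m$head, X, Y, TRUE)
  theta <- unlist(m[c("layers", "head")], use.names = FALSE)
  g <- unlist(r$grads, use.names = FALSE)
  skel <- m[c("layers", "head")]
  loss_at <- function(th) {
    f <- abrwave:::refill_params(skel, th)
    abrwave:::cpp_nn_loss_grad(f$layers, f$head, X, Y, FALSE)$loss
  }
  idx <- sample(length(theta), 10)
  for (i in idx) {
    h <- 1e-5
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fd <- (loss_at(tp) - loss_at(tm)) / (2 * h)
    expect_lt(abs(fd - g[i]) / max(abs(fd), abs(g[i]), 1e-8), 1e-4)
  }
})

test_that("model construction is seeded and softmax rows are normalized", {
  cfg <- sequence_model_config("uni", 1, 8, seed = 5)
  m1 <- build_model(cfg); m2 <- build_model(cfg)
  expect_identical(m1$layers, m2$layers)
  expect_identical(m1$head, m2$head)

  p <- predict_probs(m1, rnorm(321))
  expect_length(p, 321L)
  expect_true(all(p >= 0 & p <= 1))

  # symmetric zero head: equal logits, probability exactly 1/2 everywhere
  m1$head$V[] <- 0; m1$head$c[] <- 0
  expect_equal(predict_probs(m1, rnorm(321)), rep(0.5, 321))
})

test_that("the selected three-layer bidirectional architecture runs forward", {
  cfg <- sequence_model_config("bi", 3, 16, seed = 2)  # narrow for speed
  m <- build_model(cfg)
  p <- predict_probs(m, rnorm(321))
  expect_length(p, 321L)
  expect_identical(structure_name(sequence_model_config("bi", 3, 512)), "BiLSTMx3")
})

test_that("a bidirectional model with time-symmetric weights commutes with reversal", {
  cfg <- sequence_model_config("bi", 1, 6, seed = 8)
  m <- build_model(cfg)
  m$layers[[1]]$dirs[[2]] <- m$layers[[1]]$dirs[[1]]  # backward = forward weights
  # head must weight both directions identically
  H <- cfg$hidden_nodes
  m$head$V[, (H + 1):(2 * H)] <- m$head$V[, 1:H]
  set.seed(9)
  x <- rnorm(321)
  # with shared weights and a direction-symmetric head, reversing the input
  # reverses the output probabilities exactly
  expect_equal(predict_probs(m, rev(x)), rev(predict_probs(m, x)),
               tolerance = 1e-10)
})

test_that("training overfits one sweep and drives degenerate targets to zero", {
  ds <- tiny_easy_dataset(2)
  td <- prepare_training_data(ds)
  cfg <- sequence_model_config("bi", 1, 16, learning_rate = 5e-3,
                               epochs = 300, batch_size = 1, val_frac = 0,
                               seed = 3)
  fit <- abr_fit(list(x = td$x[, 1, drop = FALSE], y = td$y[, 1, drop = FALSE]),
                 cfg, verbose = FALSE)
  expect_lt(tail(fit$log$train_loss, 1), 0.05)
  p <- predict_probs(fit, td$x[, 1])
  support <- td$y[, 1] == 1L
  expect_gte(mean((p > 0.5) == support), 1 - 2 / 321)

  # all-zero labels: positive-class probability collapses
  y0 <- matrix(0L, 321, 1)
  cfg0 <- sequence_model_config("uni", 1, 8, learning_rate = 3e-2,
                                epochs = 250, batch_size = 1, val_frac = 0,
                                seed = 4)
  fit0 <- abr_fit(list(x = td$x[, 1, drop = FALSE], y = y0), cfg0,
                  verbose = FALSE)
  expect_lt(max(predict_probs(fit0, td$x[, 1])), 0.1)
})

test_that("training on an easy set halves the validation loss", {
  ds <- tiny_easy_dataset(24, seed = 77)
  cfg <- sequence_model_config("bi", 1, 24, epochs = 12, batch_size = 8,
                               val_frac = 0.25, seed = 5,
                               learning_rate = 3e-3)
  fit <- abr_fit(ds, cfg, verbose = FALSE)
  expect_lt(fit$log$val_loss[nrow(fit$log)], 0.5 * fit$log$val_loss[1])
  # determinism: same config, same data, same result
  fit2 <- abr_fit(ds, cfg, verbose = FALSE)
  expect_identical(fit$log, fit2$log)
})
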