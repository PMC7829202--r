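test_that("peak matching applies the tolerance window exactly", {
  truth <- wave_annotation(c(V = 5.70))
  m1 <- match_peaks(5.85, truth, me = 0.2)
  expect_true(m1$matched)
  m2 <- match_peaks(5.85, truth, me = 0.1)
  expect_false(m2$matched)
  m3 <- match_peaks(numeric(0), truth, me = 0.2)
  expect_false(m3$matched)
})

test_that("matching is one-to-one: a prediction credits at most one wave", {
  truth <- wave_annotation(c(III = 3.9, V = 4.1))
  m <- match_peaks(4.0, truth, me = 0.2)
  expect_identical(sum(m$matched), 1L)
})

test_that("greedy matching is within one match of the optimal assignment", {
  set.seed(50)
  for (rep in 1:100) {
    k <- sample(1:3, 1)
    lats <- sort(runif(k, 1, 7))
    while (any(diff(lats) <= 0.05)) lats <- sort(runif(k, 1, 7))
    names(lats) <- c("I", "III", "V")[seq_len(k)]
    truth <- wave_annotation(lats)
    pred <- runif(sample(0:5, 1), 1, 7)
    me <- sample(c(0.1, 0.2, 0.5), 1)
    g <- sum(match_peaks(pred, truth, me, "greedy")$matched)
    o <- sum(match_peaks(pred, truth, me, "optimal")$matched)
    expect_gte(g, o - 1L)
    expect_lte(g, o)
  }
})

test_that("accuracy pools counts across sweeps and is permutation invariant", {
  anns <- list(wave_annotation(c(I = 1.6, III = 3.9, V = 5.7)),
               wave_annotation(c(I = 1.7, III = 4.0, V = 5.8)))
  preds <- list(c(1.6, 3.9, 5.7), c(9e2))  # perfect / useless (off-scale)
  preds[[2]] <- c(7.9)                     # far from every mark
  ev <- abr_accuracy(preds, anns, me = 0.2)
  expect_equal(ev$acc, 0.5)  # 3 of 6
  expect_identical(ev$p_n, 6L)

  ev2 <- abr_accuracy(rev(preds), rev(anns), me = 0.2)
  expect_equal(ev2$acc, ev$acc)

  # perfect predictions give ACC 1 at every tolerance
  ev3 <- abr_accuracy(list(preds[[1]]), anns[1], me = c(0.1, 0.15, 0.2))
  expect_equal(ev3$acc, c(1, 1, 1))
})

test_that("accuracy is nondecreasing in the tolerance and ignores spurious peaks", {
  set.seed(51)
  for (rep in 1:200) {
    lats <- sort(1 + cumsum(runif(3, 0.5, 2)))
    names(lats) <- c("I", "III", "V")
    truth <- wave_annotation(pmin(lats, 8))
    pred <- truth$latencies + rnorm(3, 0, 0.15)
    ev <- abr_accuracy(list(pred), list(truth), me = c(0.1, 0.15, 0.2))
    expect_true(all(diff(ev$acc) >= 0))

    # recall-like: far-away spurious predictions change nothing
    ev_fp <- abr_accuracy(list(c(pred, 0.05)), list(truth),
                          me = c(0.1, 0.15, 0.2))
    expect_equal(ev_fp$acc, ev$acc)
  }
})

test_that("fold sizes differ by at most one and CV is deterministic", {
  f <- kfold_assign(491, 9, seed = 1)
  sizes <- as.integer(table(f))
  expect_true(all(sizes %in% c(54L, 55L)))
  expect_identical(f, kfold_assign(491, 9, seed = 1))
  expect_error(kfold_assign(5, 1), "at least 2")
})

test_that("repeated k-fold on a tiny model is reproducible end to end", {
  ds <- tiny_easy_dataset(12, seed = 13)
  cfg <- sequence_model_config("uni", 1, 8, epochs = 2, batch_size = 4,
                               val_frac = 0.2, seed = 1)
  cv1 <- repeated_kfold(ds, k = 3, repeats = 1, config = cfg, seed = 6)
  cv2 <- repeated_kfold(ds, k = 3, repeats = 1, config = cfg, seed = 6)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(nrow(cv1$folds), 3L)
})
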