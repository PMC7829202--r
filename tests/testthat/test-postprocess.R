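test_that("binarization applies an inclusive cutoff and is monotone", {
  expect_true(all(binarize(rep(0.5, 321), 0.5) == 1L))
  lab <- as.integer(runif(321) < 0.1)
  expect_identical(binarize(as.numeric(lab), 0.5), lab)
  set.seed(30)
  p <- runif(321)
  expect_true(all(binarize(p, 0.9) <= binarize(p, 0.5)))
  expect_error(binarize(p, 1.2), "cutoff")
})

test_that("maximal runs match a brute-force scan on random vectors", {
  expect_identical(nrow(find_runs(integer(321))), 0L)
  x <- integer(321); x[10:14] <- 1L; x[40:43] <- 1L
  expect_equal(find_runs(x), cbind(start = c(10L, 40L), end = c(14L, 43L)))

  brute <- function(v) {
    out <- NULL; i <- 1L; n <- length(v)
    while (i <= n) {
      if (v[i] == 1L) {
        j <- i
        while (j < n && v[j + 1L] == 1L) j <- j + 1L
        out <- rbind(out, c(i, j)); i <- j + 1L
      } else i <- i + 1L
    }
    if (is.null(out)) matrix(integer(0), 0, 2) else out
  }
  set.seed(31)
  for (rep in 1:50) {
    v <- as.integer(runif(80) < 0.3)
    expect_identical(unname(find_runs(v)), unname(brute(v)))
  }
})

test_that("region merging follows the 20-sample rule with documented arithmetic", {
  g <- abr_grid()
  # gap of 5 samples: merged; centre = mean of first/last sample times
  # (window coordinate i sits at t = 0.025 * (i - 1) ms)
  r <- merge_regions(cbind(c(101L, 111L), c(105L, 115L)), 20L, g)
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(101L, 115L))
  expect_equal(r$center_ms, 0.025 * (100 + 114) / 2)
  expect_equal(r$center_ms, 2.675)

  # gap of 25 samples: two regions
  r2 <- merge_regions(cbind(c(101L, 131L), c(105L, 135L)), 20L, g)
  expect_identical(nrow(r2), 2L)

  # singleton run at window index 229 sits at 5.7 ms
  r3 <- merge_regions(cbind(229L, 229L), 20L, g)
  expect_equal(r3$center_ms, 5.7)

  # boundary convention: gap == threshold is NOT merged, gap < threshold is
  rb <- merge_regions(cbind(c(10L, 51L), c(30L, 60L)), 20L, g)
  expect_identical(nrow(rb), 2L)
  rb2 <- merge_regions(cbind(c(10L, 50L), c(30L, 60L)), 20L, g)
  expect_identical(nrow(rb2), 1L)
})

test_that("region merging equals a brute-force interval-closure oracle", {
  brute_merge <- function(runs, thr) {
    if (nrow(runs) == 0L) return(runs)
    runs <- runs[order(runs[, 1]), , drop = FALSE]
    groups <- list(runs[1, , drop = FALSE])
    for (i in seq_len(nrow(runs))[-1]) {
      last <- groups[[length(groups)]]
      gap <- runs[i, 1] - max(last[, 2]) - 1L
      if (gap < thr) {
        groups[[length(groups)]] <- rbind(last, runs[i, ])
      } else {
        groups[[length(groups) + 1L]] <- runs[i, , drop = FALSE]
      }
    }
    t(vapply(groups, function(gm) c(min(gm[, 1]), max(gm[, 2])), integer(2)))
  }
  set.seed(32)
  for (rep in 1:200) {
    v <- as.integer(runif(321) < 0.08)
    runs <- find_runs(v)
    thr <- sample(c(1L, 5L, 20L, 40L), 1)
    got <- merge_regions(runs, thr)
    want <- brute_merge(runs, thr)
    if (nrow(runs) == 0L) {
      expect_identical(nrow(got), 0L)
    } else {
      expect_identical(cbind(got$start, got$end), unname(want))
    }
  }
})

test_that("weak regions are dropped by the minimum-support rule", {
  g <- abr_grid()
  r <- merge_regions(cbind(c(50L, 100L), c(50L, 108L)), 20L, g)
  kept <- filter_regions(r, 3L)
  expect_identical(nrow(kept), 1L)
  expect_identical(kept$start, 100L)
  expect_identical(nrow(filter_regions(r, 1L)), 2L)
})

test_that("wave assignment gates by latency window with earliest-first ties", {
  g <- abr_grid()
  mk <- function(centers) {
    idx <- vapply(centers, function(cc) grid_index(g, cc) - 511L, integer(1))
    filter_regions(merge_regions(cbind(idx - 2L, idx + 2L), 20L, g), 1L)
  }
  r <- assign_waves(mk(c(1.6, 3.9, 5.7)))
  expect_identical(r$wave, c("I", "III", "V"))

  r2 <- assign_waves(mk(5.9))
  expect_identical(r2$wave, "V")

  r3 <- assign_waves(mk(c(5.0, 5.9)))  # both inside the V window
  expect_identical(r3$wave, c("V", NA))
})

test_that("postprocessing is idempotent on its own output", {
  set.seed(33)
  v <- integer(321)
  v[50:58] <- 1L; v[150:160] <- 1L; v[165:170] <- 1L
  reg1 <- filter_regions(merge_regions(find_runs(v), 20L), 3L)
  rebuilt <- integer(321)
  for (i in seq_len(nrow(reg1))) rebuilt[reg1$start[i]:reg1$end[i]] <- 1L
  reg2 <- filter_regions(merge_regions(find_runs(rebuilt), 20L), 3L)
  expect_identical(reg1[c("start", "end")], reg2[c("start", "end")])
})

test_that("ground-truth labels round-trip to their annotated latencies", {
  g <- abr_grid()
  ann <- wave_annotation(c(I = 1.6, III = 3.9, V = 5.7))
  aug <- augment_labels(annotation_to_labels(ann, g), 4L)
  regions <- postprocess_probs(as.numeric(aug), grid = g)
  expect_identical(regions$wave, c("I", "III", "V"))
  expect_equal(unname(region_latencies(regions)), unname(ann$latencies))
})
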