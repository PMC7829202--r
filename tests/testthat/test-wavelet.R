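test_that("untouched decompositions reconstruct perfectly for all families", {
  set.seed(20)
  x <- rnorm(321)
  for (fam in c("haar", "db2", "db4", "sym4")) {
    spec_all <- wavelet_spec(6L, 1:6, TRUE, fam)
    dc <- wavelet_decompose(x, spec_all)
    xr <- reconstruct_retained(dc, spec_all)
    expect_lt(max(abs(xr - x)) / max(abs(x)), 1e-8)
  }
})

test_that("a unit impulse survives decomposition/reconstruction", {
  x <- numeric(321); x[160] <- 1
  spec <- wavelet_spec(6L, 1:6)
  expect_lt(max(abs(reconstruct_retained(wavelet_decompose(x, spec), spec) - x)),
            1e-8)
})

test_that("constant signals put all energy in the approximation", {
  dc <- wavelet_decompose(rep(3, 321), wavelet_spec())
  for (d in dc$details) expect_lt(max(abs(d)), 1e-10)
  expect_gt(sum(dc$approximation^2), 0)
})

test_that("an alternating signal concentrates energy in the level-1 detail", {
  x <- rep(c(1, -1), length.out = 320)
  dc <- wavelet_decompose(x, wavelet_spec(levels = 3L, retained_details = 1:3))
  e1 <- sum(dc$details[[1]]^2)
  etot <- sum(dc$approximation^2) + sum(vapply(dc$details, function(d) sum(d^2), 0))
  expect_gt(e1 / etot, 0.9)
})

test_that("retained + complement sub-bands add back to the original signal", {
  set.seed(21)
  x <- rnorm(321)
  spec <- wavelet_spec()                   # A6 + D4..D6
  comp <- wavelet_spec(6L, 1:3, FALSE)     # D1..D3, no approximation
  dc <- wavelet_decompose(x, spec)
  expect_lt(max(abs(reconstruct_retained(dc, spec) +
                    reconstruct_retained(dc, comp) - x)), 1e-8)
})

test_that("retaining nothing returns zero and denoising is linear", {
  set.seed(22)
  x <- rnorm(321); y <- rnorm(321)
  none <- wavelet_spec(6L, integer(0), FALSE)
  expect_true(all(abs(reconstruct_retained(wavelet_decompose(x, none), none)) < 1e-12))

  spec <- wavelet_spec()
  dn <- function(v) reconstruct_retained(wavelet_decompose(v, spec), spec)
  expect_lt(max(abs(dn(2 * x - 3 * y) - (2 * dn(x) - 3 * dn(y)))), 1e-8)
  expect_true(all(dn(numeric(321)) == 0))
})

test_that("denoising smooths a noisy sweep and barely shifts wave V", {
  set.seed(23)
  s <- simulate_recording(isolated_templates(), quiet_noise(),
                          visibility_floor = 0)
  noisy <- add_interference_noise(s$recording,
                                  noise_spec(0.08, 0, 30, 0, 0), seed = 1)
  den <- denoise_recording(noisy, wavelet_spec())

  ac1 <- function(v) cor(v[-1], v[-length(v)])
  w_noisy <- as.numeric(extract_window(noisy))
  w_den <- as.numeric(extract_window(den))
  expect_gt(ac1(w_den), ac1(w_noisy))

  g <- s$recording$grid
  peak_near <- function(rec, lat) {
    i <- grid_index(g, lat)
    nb <- (i - 20L):(i + 20L)
    grid_time(g, nb[which.max(rec$potentials[nb])])
  }
  vlat <- s$annotation$latencies[["V"]]
  clean_den <- denoise_recording(s$recording, wavelet_spec())
  expect_lte(abs(peak_near(clean_den, vlat) - vlat), 0.1)
})

test_that("repeated denoising contracts toward the retained subspace", {
  set.seed(24)
  rec <- abr_recording(rnorm(1024))
  spec <- wavelet_spec()
  d1 <- denoise_recording(rec, spec)
  d2 <- denoise_recording(d1, spec)
  delta1 <- sqrt(sum((d1$potentials - rec$potentials)^2))
  delta2 <- sqrt(sum((d2$potentials - d1$potentials)^2))
  expect_lt(delta2, delta1)
})

test_that("unknown wavelet families are rejected", {
  expect_error(wavelet_spec(family = "coif17"), "unknown wavelet family")
})
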