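test_that("noiseless, jitter-free sweeps peak exactly at the annotated latencies", {
  g <- abr_grid()
  set.seed(1)
  s <- simulate_recording(default_wave_templates("normal", latency_sd = 0),
                          quiet_noise(), visibility_floor = 0)
  expect_named(s$annotation$latencies, c("I", "III", "V"))
  pot <- s$recording$potentials
  for (lat in s$annotation$latencies) {
    i <- grid_index(g, lat)
    nb <- (i - 20L):(i + 20L)
    expect_identical(nb[which.max(pot[nb])], i)
  }
})

test_that("zero amplitudes give a flat trace and an empty annotation", {
  tpl <- lapply(isolated_templates(), function(tp) {
    tp$mean_amplitude <- 0; tp$amplitude_sd <- 0; tp
  })
  set.seed(2)
  s <- simulate_recording(tpl, quiet_noise(), visibility_floor = 0.01)
  expect_true(all(s$recording$potentials == 0))
  expect_length(s$annotation$latencies, 0L)
})

test_that("templates violating the latency ordering are rejected", {
  bad <- list(
    wave_template("I", 4.0, 0, 0.3, 0, 0.25),
    wave_template("III", 3.0, 0, 0.3, 0, 0.3)
  )
  expect_error(simulate_recording(bad, quiet_noise()), "increase")
})

test_that("Monte-Carlo mean realized wave-V latency matches the configured mean", {
  # isolated waves: bump centres are composite peaks, so the annotated
  # latency is the jittered centre snapped to the grid (unbiased)
  tpl <- isolated_templates(latency_sd = 0.08)
  set.seed(11)
  lats <- replicate(1000, {
    s <- simulate_recording(tpl, quiet_noise(), visibility_floor = 0)
    s$annotation$latencies[["V"]]
  })
  se <- sd(lats) / sqrt(length(lats))
  expect_lt(abs(mean(lats) - 5.7), 3 * se)
})

test_that("datasets are seed-reproducible and respect the class mix", {
  cfg <- abr_sim_config("clinical-like")
  d1 <- simulate_dataset(20, 433 / 614, cfg, seed = 7)
  d2 <- simulate_dataset(20, 433 / 614, cfg, seed = 7)
  expect_identical(d1, d2)

  d3 <- simulate_dataset(40, 433 / 614, cfg, seed = 8, stratified = TRUE)
  cls <- vapply(d3, function(s) s$recording$subject_class, character(1))
  expect_identical(sum(cls == "abnormal"), as.integer(round(40 * 433 / 614)))

  d4 <- simulate_dataset(10, 0, abr_sim_config("easy"), seed = 9)
  for (s in d4) expect_named(s$annotation$latencies, c("I", "III", "V"))
})

test_that("abnormal sweeps carry lower wave-I amplitude than normal ones", {
  cfg <- abr_sim_config(NULL)
  g <- abr_grid()
  amp_at_I <- function(class_mix) {
    d <- simulate_dataset(150, class_mix, cfg, seed = 33)
    mean(vapply(d, function(s) {
      i <- grid_index(g, 1.6)
      max(s$recording$potentials[(i - 8L):(i + 8L)])
    }, numeric(1)))
  }
  expect_gt(amp_at_I(0), amp_at_I(1))
})

test_that("interference injection is additive, seeded and matches its SD", {
  base <- abr_recording(numeric(1024))
  ns <- noise_spec(baseline_sd = 0.2, drift_amplitude = 0,
                   late_artifact_prob = 0)
  r1 <- add_interference_noise(base, ns, seed = 5)
  r2 <- add_interference_noise(base, ns, seed = 5)
  expect_identical(r1$potentials, r2$potentials)
  expect_true(all(base$potentials == 0))  # input untouched

  # zero noise is the identity
  r0 <- add_interference_noise(base, quiet_noise(), seed = 5)
  expect_identical(r0$potentials, base$potentials)

  # pooled SD of the added component within 5% of the configured sigma
  added <- unlist(lapply(1:10, function(k) {
    add_interference_noise(base, ns, seed = k)$potentials
  }))
  expect_lt(abs(sd(added) - 0.2) / 0.2, 0.05)

  # drift only: a pure sinusoid of the configured period
  nd <- noise_spec(baseline_sd = 0, drift_amplitude = 0.5, drift_period = 10,
                   late_artifact_prob = 0)
  rd <- add_interference_noise(base, nd, seed = 3)
  t <- grid_time(base$grid, seq_len(1024))
  f <- lm(rd$potentials ~ sin(2 * pi * t / 10) + cos(2 * pi * t / 10))
  expect_lt(max(abs(residuals(f))), 1e-10)
})
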