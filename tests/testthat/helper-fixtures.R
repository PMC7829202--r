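# Shared fixtures: tiny simulated datasets and noise-free configurations.

quiet_noise <- function() noise_spec(0, 0, 30, 0, 0)

# Templates for waves I, III, V only, well separated relative to their
# widths, so each bump's centre is the composite's local maximum.
isolated_templates <- function(latency_sd = 0) {
  list(
    wave_template("I",   1.6, latency_sd, 0.30, 0, 0.25, 1),
    wave_template("III", 3.9, latency_sd, 0.30, 0, 0.30, 1),
    wave_template("V",   5.7, latency_sd, 0.50, 0, 0.45, 1)
  )
}

tiny_easy_dataset <- function(n = 8, seed = 42) {
  simulate_dataset(n, class_mix = 0, config = abr_sim_config("easy"),
                   seed = seed)
}
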