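# Shared fixtures, built in code and cached per test run.

.fixture_cache <- new.env(parent = emptyenv())

# noise-free single-replicate scenario (the mean trajectories)
noise_free_params <- function(...) {
  scenario_params(cv_pigment = 0, cv_fluor = 0, n_replicates = 1, ...)
}

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# noise-free mean dataset for the Fig-6-style strains
mean_dataset <- function() {
  cached("mean_ds", generate_dataset(noise_free_params(),
                                     genotypes = c("wt", "zep2_ko")))
}

# default noisy dataset (cv = 5 %, n = 3, seed 1)
noisy_dataset <- function() {
  cached("noisy_ds", generate_dataset(scenario_params(seed = 1),
                                      genotypes = c("wt", "zep2_ko")))
}

# qE constructed from the module's own linear quenching model:
# qe = gamma * Delta(Dt + Zx + w_ax * Ax), evaluated on given pigments
linear_qe <- function(pigments, gamma = 25, w_ax = 0.5) {
  dp <- delta_pigment(pigments, cols = c("dt", "ax", "zx"))
  dp <- dp[dp$time_min >= 360, ]
  tibble::tibble(
    strain = dp$strain, replicate = dp$replicate, time_min = dp$time_min,
    qe = gamma * (dp$delta_dt + dp$delta_zx + w_ax * dp$delta_ax)
  )
}

recovery_grid <- function() c(0, 1, 3, 5, 7.5, 10, 15, 30)
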