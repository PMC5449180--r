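# Shared fixtures for the suite. Everything is generated in code at test
# time; seeds are fixed so runs are reproducible.

th303 <- thermo_state(303)

# Double-well umbrella-sampling run at the package's validation conditions:
# kBT = 4 kcal/mol so that the k = 2.5 windows are ergodic across the
# residual intra-window barriers (see the methods vignette).
wham_double_well_run <- function(seed, n_steps = 6e6, dt = 6e-4, Tsim = 2013,
                                 a = 0.25, b = 3) {
  su <- model_surface("double_well", a = a, b = b, domain = c(-4.5, 4.5))
  sched <- make_window_schedule(-4, 4, 1, 2.5)
  series <- lapply(seq_along(sched), function(i) {
    simulate_langevin(su, simulation_params(50, dt, n_steps, Tsim,
                                            seed = seed * 1000 + i),
                      bias = sched[[i]])
  })
  list(surface = su, schedule = sched, thermo = thermo_state(Tsim),
       data = biased_samples(series, sched))
}

# RMS deviation of a profile from the analytic surface over well-sampled
# bins inside the window span, after free-offset (mean) alignment.
rms_vs_surface <- function(profile, surface, z_abs_max = 4) {
  ok <- !profile$mask & abs(profile$bin_centers) <= z_abs_max
  dev <- profile$W[ok] - surface_energy(surface, profile$bin_centers[ok])
  dev <- dev - mean(dev)
  sqrt(mean(dev^2))
}

# Small harmonic umbrella dataset for block/subsampling property tests.
harmonic_umbrella_data <- function(seed, n_steps = 3e4, k_surface = 1) {
  su <- model_surface("harmonic", k = k_surface, domain = c(-5, 5))
  sched <- make_window_schedule(-4, 4, 1, 2.5)
  series <- lapply(seq_along(sched), function(i) {
    simulate_langevin(su, simulation_params(50, 1e-4, n_steps, 303,
                                            seed = seed * 100 + i),
                      bias = sched[[i]])
  })
  list(surface = su, schedule = sched,
       data = biased_samples(series, sched))
}

# Random frames of ions + oxygens for brute-force coordination checks.
random_coord_frames <- function(n_frames, seed, box = 12) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(i) {
    n_ion <- sample(1:3, 1)
    n_oxy <- sample(5:15, 1)
    make_frame(
      ions = data.frame(species = sample(c("Na", "K"), n_ion, replace = TRUE),
                        x = runif(n_ion, -box, box), y = runif(n_ion, -box, box),
                        z = runif(n_ion, -box, box)),
      oxygens = data.frame(role = sample(c("water", "backbone", "sidechain"),
                                         n_oxy, replace = TRUE),
                           residue = paste0("R", sample(1:4, n_oxy, replace = TRUE)),
                           x = runif(n_oxy, -box, box), y = runif(n_oxy, -box, box),
                           z = runif(n_oxy, -box, box)))
  })
}
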