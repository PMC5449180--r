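test_that("Boltzmann inversion recovers the harmonic well from Gaussian samples", {
  set.seed(31)
  sigma <- 1
  z <- rnorm(2e5, 0, sigma)
  prof <- boltzmann_invert(z, th303, bin_width = 0.2,
                           zero_region = c(-0.2, 0.2), min_samples = 50)
  sel <- !prof$mask & abs(prof$bin_centers) <= 2 * sigma
  expected <- th303$kBT * prof$bin_centers[sel]^2 / (2 * sigma^2)
  expected <- expected - mean(expected[abs(prof$bin_centers[sel]) <= 0.2])
  dev <- prof$W[sel] - expected
  expect_lt(sqrt(mean(dev^2)), 0.03)
  expect_lt(max(abs(dev)), 0.08)
})

test_that("Boltzmann inversion is flat on uniform samples and masks empty bins", {
  set.seed(32)
  z <- runif(1e5, -5, 5)
  prof <- boltzmann_invert(z, th303, bin_width = 0.5, zero_region = c(-5, 5))
  expect_true(all(abs(prof$W[!prof$mask]) < 0.05))
  # a gap in the samples becomes a masked bin, not -Inf
  zgap <- z[z < 2 | z > 3]
  pg <- boltzmann_invert(zgap, th303, bin_width = 0.5, zero_region = c(-5, 0))
  gap_bins <- pg$bin_centers > 2 & pg$bin_centers < 3
  expect_true(all(pg$mask[gap_bins]))
  expect_true(all(is.na(pg$W[gap_bins])))
  expect_error(boltzmann_invert(z, th303, zero_region = c(40, 50)), "zero_region")
})

test_that("WHAM on an unbiased single window equals direct inversion bin-for-bin", {
  set.seed(33)
  z <- rnorm(5e4, 0, 1.5)
  sched <- structure(list(umbrella_window(0, 0, 1L)),
                     class = c("window_schedule", "list"))
  data <- biased_samples(list(z), sched, dt = 1e-3)
  breaks <- seq(-8, 8, by = 0.2)
  pw <- wham_solve(data, th303, breaks = breaks, zero_region = c(-1, 1))
  pb <- boltzmann_invert(z, th303, breaks = breaks, zero_region = c(-1, 1))
  expect_equal(pw$W, pb$W, tolerance = 1e-9)
  expect_identical(pw$mask, pb$mask)
})

test_that("WHAM recovers the analytic double-well surface", {
  run <- wham_double_well_run(seed = 8)
  prof <- wham_solve(run$data, run$thermo, bin_width = 0.2, min_samples = 10)
  expect_true(prof$meta$converged)
  expect_lt(rms_vs_surface(prof, run$surface), 0.15)
})

test_that("WHAM recovers flat and harmonic surfaces through umbrella windows", {
  # flat surface: any structure in the recovered profile is estimator error
  su <- model_surface("flat", domain = c(-5, 5))
  sched <- make_window_schedule(-4, 4, 1, 2.5)
  series <- lapply(seq_along(sched), function(i)
    simulate_langevin(su, simulation_params(50, 1e-4, 1e5, 303, seed = 40 + i),
                      bias = sched[[i]]))
  pf <- wham_solve(biased_samples(series, sched), th303, min_samples = 20)
  expect_lt(rms_vs_surface(pf, su), 0.05)
  # harmonic surface at the same conditions
  run <- harmonic_umbrella_data(seed = 5, n_steps = 1e5)
  ph <- wham_solve(run$data, th303, min_samples = 20)
  expect_lt(rms_vs_surface(ph, run$surface), 0.05)
})

test_that("WHAM rejects window pairs with zero histogram overlap, naming them", {
  sched <- make_window_schedule(0, 30, 30, 100)  # two windows, far apart
  z1 <- rnorm(1e3, 0, 0.1)
  z2 <- rnorm(1e3, 30, 0.1)
  data <- biased_samples(list(z1, z2), sched, dt = 1e-3)
  expect_error(wham_solve(data, th303), "zero histogram overlap.*1 and 2")
})

test_that("WHAM is invariant to constant shifts of the window bias energies", {
  run <- harmonic_umbrella_data(seed = 6, n_steps = 2e4)
  p0 <- wham_solve(run$data, th303, min_samples = 10)
  shifted <- run$data
  shifted$schedule$offset <- seq(-3, 5, length.out = nrow(shifted$schedule))
  p1 <- wham_solve(shifted, th303, min_samples = 10)
  expect_equal(p0$W, p1$W, tolerance = 1e-5)
})

test_that("a non-converged WHAM run is flagged, not silent", {
  run <- harmonic_umbrella_data(seed = 7, n_steps = 5e3)
  expect_warning(p <- wham_solve(run$data, th303, tol = 1e-15, max_iter = 5),
                 "did not converge")
  expect_false(p$meta$converged)
  expect_identical(p$meta$iterations, 5L)
})

test_that("block errors vanish on repeated data and track replicate spread", {
  # identical blocks -> zero stderr
  z <- rep(rnorm(500, 0, 1), 4)
  sched <- structure(list(umbrella_window(0, 0, 1L)),
                     class = c("window_schedule", "list"))
  data <- biased_samples(list(z), sched, dt = 1e-3)
  est <- function(d) boltzmann_invert(d$z[[1]], th303, breaks = seq(-4, 4, 0.5),
                                      zero_region = c(-1, 1))
  be <- block_error(data, est, n_blocks = 4)
  expect_true(all(be$stderr[is.finite(be$stderr)] < 1e-12))
  expect_error(block_error(data, est, n_blocks = 1), ">= 2")
  expect_error(block_error(data, est, n_blocks = 1e4), "empty")

  # block stderr is within 2x of the spread over independent reruns
  breaks <- seq(-5.4, 5.4, by = 0.3)
  est2 <- function(d) wham_solve(d, th303, breaks = breaks, min_samples = 10,
                                 zero_region = c(-1, 1))
  run <- harmonic_umbrella_data(seed = 11, n_steps = 4e4)
  be2 <- block_error(run$data, est2, n_blocks = 4)
  reruns <- sapply(1:4, function(s) {
    p <- est2(harmonic_umbrella_data(seed = 20 + s, n_steps = 1e4)$data)
    setNames(ifelse(p$mask, NA, p$W), sprintf("%.6f", p$bin_centers))
  })
  key <- sprintf("%.6f", be2$z)
  common <- key %in% rownames(reruns) & is.finite(be2$stderr)
  spread <- apply(reruns[key[common], ], 1, sd) / sqrt(4)
  ratio <- be2$stderr[common] / spread
  # same per-bin order of magnitude (each side is itself a 4-sample estimate)
  expect_gt(median(ratio), 0.5)
  expect_lt(median(ratio), 2)
})

test_that("convergence series stabilises and validates checkpoints", {
  run <- harmonic_umbrella_data(seed = 9, n_steps = 6e4)
  est <- function(d) wham_solve(d, th303, breaks = seq(-5.4, 5.4, 0.3),
                                min_samples = 100, zero_region = c(-1, 1))
  total_ns <- 6e4 * 1e-4
  cs <- convergence_series(run$data, c(1, 2, 4, total_ns, total_ns), est)
  expect_length(cs$max_dW, 4)
  # duplicate final checkpoint: identical profiles
  expect_identical(cs$max_dW[4], 0)
  # estimator is consistent: late increments are small and shrink
  expect_lt(cs$max_dW[3], cs$max_dW[1])
  expect_lt(cs$max_dW[3], 0.15)
  expect_error(convergence_series(run$data, c(4, 2), est), "non-decreasing")
  expect_error(convergence_series(run$data, c(2, 100), est), "exceeds")
})

test_that("halving the data changes the profile within the reported block errors", {
  run <- harmonic_umbrella_data(seed = 13, n_steps = 4e4)
  breaks <- seq(-5.4, 5.4, by = 0.3)
  est <- function(d) wham_solve(d, th303, breaks = breaks, min_samples = 10,
                                zero_region = c(-1, 1))
  full <- est(run$data)
  half <- run$data
  half$z <- lapply(half$z, function(z) z[seq_len(length(z) %/% 2)])
  ph <- est(half)
  be <- block_error(run$data, est, n_blocks = 4)
  key <- function(x) sprintf("%.6f", x)
  w_full <- setNames(ifelse(full$mask, NA, full$W), key(full$bin_centers))
  w_half <- setNames(ifelse(ph$mask, NA, ph$W), key(ph$bin_centers))
  se <- setNames(be$stderr, key(be$z))
  common <- intersect(names(w_full)[is.finite(w_full)],
                      names(w_half)[is.finite(w_half)])
  common <- common[is.finite(se[common])]
  frac <- mean(abs(w_full[common] - w_half[common]) < 3 * se[common])
  expect_gte(frac, 0.95)
})

test_that("burn-in removal and presets behave as declared", {
  expect_identical(burnin_presets$closed_Na, 6)
  expect_identical(burnin_presets$closed_K, 7)
  expect_identical(burnin_presets$open_Na, 6)
  expect_identical(burnin_presets$open_K, 3)
  sched <- structure(list(umbrella_window(0, 0, 1L)),
                     class = c("window_schedule", "list"))
  set.seed(51)
  z <- c(rep(100, 50), rnorm(950))   # first 0.5 ns of samples are junk
  d <- biased_samples(list(z), sched, dt = 0.01, burnin = 0.5)
  prof <- wham_solve(d, th303, zero_region = c(-1, 1))
  expect_true(all(prof$bin_centers[!prof$mask] < 50))    # junk removed
  expect_error(biased_samples(list(z), sched, dt = 0.01, burnin = 20),
               "shorter than the series")
})
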