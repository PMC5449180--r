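# ionselect

Free-energy and selectivity analysis for ion-channel permeation, in R.

Narrow cation channels such as ASICs prefer Na⁺ over K⁺, and locating the
pore region responsible is a free-energy problem. The standard computational
workflow combines four analyses, each of which `ionselect` implements as a
tested, reusable estimator:

- **PMF estimation** — W(z) = −k_BT ln ρ(z) + C by direct Boltzmann
  inversion, and WHAM unbiasing of harmonic umbrella-sampling windows
  (U_b = k/2 (z − c)², k = 2.5 kcal/mol/Å² at 1 Å spacing in the production
  protocol), with block-averaged errors, burn-in handling and convergence
  series.
- **Alchemical relative binding** — the Bennett acceptance ratio (BAR)
  estimator on forward/backward work samples, single- and double-occupancy
  thermodynamic cycles, ΔΔG = ΔG_site − ΔG_bulk with quadrature error
  propagation, and cycle-closure checks.
- **Frame geometry** — radial distribution functions, first-minimum cutoffs,
  first-shell coordination profiles (cutoffs 3.2/3.6 Å for Na⁺/K⁺, bulk
  references 5.8/7.0), and classification of carboxylate-site occupancy
  (0 / 1-ion with 1–2 carboxylates / 2-tight / 2-loose / 2-disperse).
- **Electrophysiology** — leak subtraction of 160 mV voltage ramps,
  reversal-potential detection, Goldman–Hodgkin–Katz permeability ratios
  P_Na/P_X = exp(F ΔV_rev / RT) at T = 274 K, and four-parameter Hill pH₅₀
  fits.

Cluster-scale molecular dynamics is out of scope; instead a bundled
synthetic-data layer (overdamped Langevin sampling of known 1-D surfaces,
Crooks-consistent Gaussian work sets, scripted site configurations,
GHK-shaped ramp recordings) provides every input with exact ground truth, so
the whole pipeline is verifiable on a laptop. See the methods vignette
(`vignettes/ionselect-methods.Rmd`) for the models, assumptions and
numerical choices.

Intended users: simulation and channel-biophysics people who want
desk-verifiable implementations of these estimators with explicit seeds,
errors and failure modes.

## Worked example

```r
library(ionselect)

## 1. Umbrella sampling on a known double-well surface, unbiased by WHAM
surface  <- model_surface("double_well", a = 0.25, b = 3, domain = c(-4.5, 4.5))
schedule <- make_window_schedule(-4, 4, spacing = 1, k = 2.5)
th  <- thermo_state(2013)          # sampling temperature; see the vignette
series <- lapply(seq_along(schedule), function(i)
  simulate_langevin(surface,
                    simulation_params(50, 6e-4, 1e6, 2013, seed = 100 + i),
                    bias = schedule[[i]]))
profile <- wham_solve(biased_samples(series, schedule), th, min_samples = 10)
profile
#> <free_energy_profile> 49 bins (1 masked), z in [-4.9, 4.7] A, W range [-12.295, 28.976] kcal/mol

ok  <- !profile$mask & abs(profile$bin_centers) <= 4
dev <- profile$W[ok] - surface_energy(surface, profile$bin_centers[ok])
sqrt(mean((dev - mean(dev))^2))    # RMS error vs the known surface, kcal/mol
#> [1] 0.06211753

## 2. BAR on Crooks-consistent work samples with known dG = 2 kcal/mol
th303 <- thermo_state(303)
ws   <- generate_fep_work_samples(dG_true = 2, sigma = 1, n = 1e5, th303, seed = 42)
site <- bar_estimate(ws, thermo = th303)
site
#> <bar_result> dG = 1.9978 +/- 0.0024 kcal/mol (n = 100000/100000, overlap 0.97)
bulk <- bar_estimate(generate_fep_work_samples(0.5, 1, 1e5, th303, seed = 43),
                     thermo = th303)
compose_ddG(fep_leg("Na->K", site$dG, site$stderr),
            fep_leg("Na->K", bulk$dG, bulk$stderr, site = "bulk"))
#> <ddG_result> ddG = 1.501 +/- 0.003 kcal/mol (site path 1.998, bulk x1)

## 3. GHK selectivity from synthetic ramp recordings at 274 K
ramps <- synthesize_ramp_recording(c(Na = 30, K = -24.4), noise_sd = 0.005, seed = 7)
vrev  <- sapply(names(ramps), function(ion)
  find_reversal_potential(subtract_leak(ramps[[ion]]$active, ramps[[ion]]$rest)))
round(vrev, 2)
#>     Na      K
#>  30.00 -24.38
permeability_ratio(vrev["Na"], vrev["K"])
#> <permeability_ratio> dV = 54.38 mV at 274 K: P_Na/P_X = 10.005 (log10 1.000)
```

The WHAM profile reproduces the 20.25 kcal/mol double-well surface to
0.06 kcal/mol RMS; BAR recovers its prescribed ΔG within one standard error;
a 54.4 mV reversal-potential shift corresponds to a ten-fold Na⁺/K⁺
permeability ratio (RT/F = 23.61 mV at 274 K).

A configuration-driven end-to-end run (with run log, summary and checksummed
manifest) is available as

```r
run_pipeline(system.file("extdata", "demo_config.json", package = "ionselect"),
             seed = 1, out_dir = "demo_out")
```

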