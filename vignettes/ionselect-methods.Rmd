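---
title: "Free-energy and selectivity estimators in ionselect: models, assumptions, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-energy and selectivity estimators in ionselect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionselect)
```

## The problem

Acid-sensing ion channels (ASICs) conduct Na⁺ in strong preference to K⁺,
and the question of *where* in the pore that discrimination happens is a
free-energy question: how much reversible work does each ion species pay (or
gain) at each position along the pore axis, and how much more favourably does
the pore bind Na⁺ than K⁺ at candidate sites such as the Gly-Ala-Ser (GAS)
belt carbonyls or the band of acidic side chains (E18′/D21′, in pore-helix
prime numbering) at the lower pore? Answering it combines four kinds of
analysis, and `ionselect` implements each as a reusable, testable estimator:

1. **Potential-of-mean-force (PMF) estimation** — direct Boltzmann inversion
   of unbiased sampling, and WHAM unbiasing of harmonic umbrella-sampling
   windows, with block-averaged errors and convergence series.
2. **Alchemical relative binding free energies** — the Bennett acceptance
   ratio (BAR) applied to forward/backward work samples, composed into
   single- and double-occupancy thermodynamic cycles with quadrature error
   propagation, ΔΔG = ΔG_site − ΔG_bulk.
3. **Trajectory-frame geometry** — radial distribution functions, first-shell
   coordination profiles, and per-frame classification of ion occupancy at a
   carboxylate site (empty / single with 1 or 2 carboxylate contacts /
   tight, loose or disperse two-ion complexes).
4. **Electrophysiology** — leak subtraction of voltage-ramp recordings,
   reversal-potential detection, Goldman-Hodgkin-Katz (GHK) permeability
   ratios, and four-parameter Hill fits of proton dose-response curves.

Production inputs for the free-energy estimators would come from all-atom
molecular dynamics at cluster scale. The package instead ships a
**synthetic-data layer** whose ground truth is known exactly: every estimator
can therefore be validated end-to-end on a desk machine. The synthetic layer
is first-class, tested code, not a fixture.

## Estimators

### Boltzmann inversion and WHAM

The profile is defined as W(z) = −k_BT ln ρ(z) + C, with ρ the unbiased
density of the axial ion coordinate and C fixed by a bulk reference region
(`zero_region`) over which W averages zero. Empty (or under-populated) bins
are masked, never −∞.

Umbrella windows restrain the ion with U_b(z) = k/2 (z − c)². The production
protocol uses k = 2.5 kcal/mol/Å² at 1 Å spacing — 46 windows spanning −25 to
20 Å for the open-state structure and 26 spanning −25 to 0 Å for the
closed-state structure, with two extra windows (z = 9.5, 11.5 Å) and a
stiffer k = 5.14 kcal/mol/Å² where sampling is hard. `make_window_schedule()`
reproduces these counts exactly. Because the original protocol does not print
the harmonic convention, the **half-k form is fixed package-wide**; the
sampler and the WHAM unbias use the identical function, so internal
consistency holds regardless of which convention the original engine used.

`wham_solve()` iterates the standard self-consistency equations over window
histograms, anchoring the first window shift at zero and stopping when the
largest shift change falls below `tol` (default 1e-7 kcal/mol, `max_iter`
1e5; both logged in the result's `meta`). Failure to converge returns a
flagged result with a warning — never a silent one. Adjacent windows must
share at least one populated histogram bin; a disconnected pair is a hard
error naming the pair, because the relative offset across a gap is
undetermined. Histogram bin width defaults to 0.2 Å (the window spacing is
1 Å; the protocol does not state a bin width), and `min_samples` masks thin
bins. Burn-in is expressed in ns and removed per window; the production
values (6/7 ns closed-state Na⁺/K⁺, 6/3 ns open-state) are stored in
`burnin_presets`.

Errors come from `block_error()`: contiguous, equal-length time slices per
window (the production analyses used four 56-ns blocks for unbiased runs and
1-ns blocks for umbrella runs), stderr = sd(blocks)/√n. `convergence_series()`
recomputes the profile on cumulative data and reports max |ΔW| between
checkpoints.

### BAR and thermodynamic cycles

BAR solves
Σ_i f(β(M + W_F,i − ΔG)) = Σ_j f(β(W_R,j + ΔG − M)), f the Fermi function,
M = k_BT ln(n_F/n_R), by bracketed root finding (`uniroot`, bracket widened
geometrically; a persistent sign failure aborts with the overlap diagnostic).
Backward work is supplied in the direction of its own transformation — no
pre-negation. The standard error is the asymptotic BAR variance, and the
overlap diagnostic is the fraction of Fermi weights inside (0.01, 0.99). In
the one-sided limit BAR reduces to the exponential (Zwanzig) estimator, which
the tests verify on constructed data.

The λ-schedule metadata records the production protocol: λ pulled 0→1 and
1→0 in 40 steps total (Δλ = 0.05, i.e. 20 per direction) of 0.2 ns each,
plus 2 ns production per window — 80 ns of production per calculation. Note
the schedule invariant is **per direction**: (n_windows/directions)·Δλ = 1.
The estimator itself consumes work samples regardless of provenance.

Cycle composition: ΔΔG(Na⁺→K⁺) = ΔG_site − ΔG_bulk for single occupancy; for
double occupancy the site term is the path sum of the two sequential
single-ion legs (e.g. Na⁺Na⁺→K⁺Na⁺ then K⁺Na⁺→K⁺K⁺). The bulk term is
scaled by the number of site legs (`bulk_scale`, overridable): a two-ion
transformation consumes two bulk references, one per alchemical mutation.
Standard errors combine in quadrature under an independence assumption —
the production protocol reports combined values without stating a rule, and
quadrature is the standard choice. `cycle_closure_check()` verifies state
bookkeeping around a loop and passes when |residual| ≤ 2× the propagated
error. Per-leg ΔG values from production MD are not available at desk scale, and
combined ΔΔG numbers derived from hundreds of ns of all-atom sampling
cannot be — and are not — numerically reproduced here; the cycles are instead
validated against synthetic work data with known ground truth.

### Geometry analysis

First-shell cutoffs follow the first minima of the ion-oxygen radial
distribution functions: 3.2 Å (Na⁺) and 3.6 Å (K⁺), with bulk coordination
references 5.8 and 7.0 used to offset pore profiles for display.
`first_minimum_cutoff()` anchors at the dominant maximum of g(r) (the first
shell peak) and returns the first interior minimum after it; detection on a
monotone curve is an error, and an optional moving-average smoothing window
is available for noisy curves.

Site occupancy uses a sphere of radius 2.75 Å around the carboxylate-group
centre of mass — the same radius as the flat-bottom constraint that maintains
occupancy in the alchemical runs, since no separate analysis radius is
printed. Two-ion frames are classified *tight* (ion-ion distance below the
tight threshold **and** at least one carboxylate contacting both ions),
*loose* (below the loose threshold), else *disperse*. The numeric thresholds
behind these classes are not part of the printed protocol (the classes are
defined from the radial distribution function of the data at hand); the defaults 3.5 /
4.5 Å were chosen once so that every class is geometrically realisable
inside the 2.75 Å site (two in-site ions can be at most 5.5 Å apart) and
should be overridden from the ion-ion g(r) of real data. Because the
thresholds are configuration rather than protocol, occupancy distributions
from production trajectories are not treated as numeric targets.

### Electrophysiology

Reversal potentials come from leak-subtracted 160 mV ramps; detection
requires exactly one sign change and interpolates linearly between the
bracketing samples (multiple crossings — noise or bad subtraction — are
rejected rather than guessed). Relative permeability uses the bi-ionic GHK
relation at the recording temperature T = 274 K (RT/F = 23.61 mV):

P_Na/P_X = exp(F (V_rev,Na − V_rev,X) / RT).

A 54.4 mV shift therefore corresponds to a ten-fold preference. Both ratio
orientations and the log10 value are returned (ratios are conventionally
plotted on a log axis). The orientation follows the standard bi-ionic
derivation — a more positive reversal under external Na⁺ means the channel
prefers Na⁺ — and is multiplicative over ion chains by construction.

pH₅₀ values come from the four-parameter Hill equation fitted in proton
concentration but parameterised in pH units,
I(pH) = floor + (ceiling − floor)/(1 + 10^{n (pH − pH₅₀)}),
via Levenberg-Marquardt least squares (`minpack.lm::nlsLM`) with data-driven
starting values and asymptotic 95% confidence intervals. Flat data and
non-convergence yield a flagged failure, never fabricated parameters.

## The synthetic-data layer

**Langevin sampler.** `simulate_langevin()` integrates overdamped (Brownian)
dynamics on a 1-D model surface — flat, harmonic, double-well a(z²−b²)², or
tabulated — with optional harmonic bias and reflecting walls. Inertia is
deliberately omitted: only stationary statistics feed the estimators. The
integrator is the Leimkuhler-Matthews (BAOAB-limit) scheme, whose stationary
configurational density is accurate to O(dt²); a stability check on
α = D·k_max·dt/k_BT warns above 1 and aborts above 2. Forces are analytic
for parametric surfaces and centered finite differences (step 1e-4 Å) of the
linear interpolant for tabulated ones. The production protocol has no
toy-dynamics parameters (it used full MD), so D = 50 Å²/ns and dt defaults
are arbitrary documented choices; D and dt affect efficiency, not the
sampled distribution.

**Work samples.** `generate_fep_work_samples()` draws forward work from
N(ΔG + σ²/2k_BT, σ²) and backward work from N(−ΔG + σ²/2k_BT, σ²) — the
Gaussian work model, which satisfies the Crooks fluctuation relation
P_F(W)/P_R(−W) = e^{β(W−ΔG)} exactly and hence gives BAR a known ground
truth. σ = 0 degenerates to point masses at ±ΔG.

**Site configurations.** `build_site_configurations()` emits frames from
geometric templates, one per prescribed occupancy state, built so that
`classify_site_occupancy()` with the same thresholds reproduces the
prescription exactly at zero jitter; each template carries a geometric
margin, and a jitter large enough to threaten the smallest margin of the
requested states is rejected up front rather than silently corrupting the
ground truth.

**Recordings.** Ramp traces combine a linear leak (reversing at 0 mV) with a
GHK-shaped channel current whose nominal external concentration is chosen so
the current reverses exactly at the prescribed potential; dose-response
curves lie exactly on the four-parameter logistic before noise. All
generators take an explicit seed and are bitwise-reproducible; none touches
global RNG state.

**What passing tests do and do not show.** The synthetic layer validates the
*estimators*: that WHAM recovers a known surface, BAR a known ΔG, the
classifier a known occupancy script, the fitting chain known reversal
potentials and pH₅₀. It does not emulate force-field error, solvent
structure, slow conformational dynamics, electrode artifacts, or rundown —
so green tests certify the analysis machinery, not any biological
conclusion drawn from real trajectories or recordings.

## Numerical choices worth knowing

- **WHAM-oracle validation conditions.** The double-well test surface
  (a = 0.25 kcal/mol/Å⁴, b = 3 Å) has a 20.25 kcal/mol barrier whose top has
  curvature −9 kcal/mol/Å², so the prescribed k = 2.5 windows cannot locally
  confine there; at 303 K the residual intra-window barriers are ~17 k_BT and
  the biased dynamics would be non-ergodic (adjacent windows would share no
  histogram support and `wham_solve()` would correctly refuse). The
  validation therefore samples at k_BT = 4 kcal/mol (T ≈ 2013 K), chosen
  from that curvature analysis so the reduced window barriers are 2.5-4.5
  k_BT; W(z) recovered from Boltzmann-consistent samples is independent of
  the sampling temperature, so the oracle stays exact. Windows span −4 to
  4 Å at 1 Å spacing over a [−4.5, 4.5] Å domain with 6×10⁶ steps per window
  at dt = 6×10⁻⁴ ns — a budget set so the remaining seed-to-seed
  lobe-equilibration noise sits well below the 0.15 kcal/mol RMS validation
  bound. Comparison is over bins inside the window span with ≥ 10 pooled
  samples, after free-offset alignment (W is defined up to a constant).
- **Zero region.** Default bulk reference: the 5 Å of the profile at the
  high-z end of the sampled range, since the protocol anchors the profile in bulk
  electrolyte without numeric bounds; always configurable and recorded in
  the profile object.
- **No Jacobian correction** is applied for the radial flat-bottom cylinder
  confinement (the production protocol is silent on it); absolute profile
  offsets between differently-confined runs therefore carry an unquantified
  entropic constant. A limitation, documented rather than invented around.
- **Degenerate inputs.** A zero-force-constant window makes WHAM collapse,
  by construction, to direct Boltzmann inversion (tested bin-for-bin);
  σ = 0 work sets give BAR the exact degenerate answer with zero stderr;
  identical repeated blocks give exactly zero block error.
- **Problem sizes.** The shipped test-suite and acceptance runs use: 9
  umbrella windows × 6×10⁶ steps (WHAM oracle), 10⁵ work samples per
  direction across ΔG ∈ {−2, 0, 2} and σ ∈ {0.5, 1, 2} (BAR grid), 1000
  scripted frames (occupancy round trip), 201-point ramps for four ion
  conditions, and 100 replicate 8-point dose-response fits at 2% noise.
  These sizes were chosen so each check's statistical floor sits comfortably
  inside its assertion while completing on a single CPU in seconds.

## Orchestration

`run_pipeline()` drives synth → pmf/fep/struct → ephys from a single flat
JSON config (unknown keys rejected with their path, every defaulted
parameter echoed into the run log), writes plain-text tables, a
human-readable summary and a manifest with parameters, seeds and md5
checksums, and is byte-reproducible under a fixed seed. A thin command-line
wrapper (`inst/scripts/ionselect`) exposes the stages as subcommands with
exit codes 0 (success), 2 (validation error), 3 (numerical failure); the
exported functions remain the primary interface.

## Known limitations

- 1-D reaction coordinate only; no 2-D PMFs, no autocorrelation-aware error
  model beyond block averaging, no multistate (MBAR-style) estimator.
- The Gaussian work model cannot represent strongly non-Gaussian work
  distributions; BAR handles those, but the bundled generator does not
  produce them.
- Occupancy templates place carboxylate oxygens at idealised positions; they
  exercise the classifier's decision boundaries but not crystallographic
  geometry.
- The GHK analysis assumes bi-ionic conditions and monotone leak-subtracted
  traces; series-resistance and capacitance artifacts are out of scope.
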