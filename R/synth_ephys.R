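# GHK-shaped channel current (arbitrary permeability scale):
#   I(u) ∝ u (c_in - c_out e^{-u}) / (1 - e^{-u}),  u = V / (RT/F)
# with c_out chosen so the current reverses at the prescribed potential.
ghk_current_shape <- function(v_mv, vrev_mv, vt_mv, c_in = 100) {
  u <- v_mv / vt_mv
  c_out <- c_in * exp(vrev_mv / vt_mv)
  small <- abs(u) < 1e-6
  out <- numeric(length(u))
  out[!small] <- u[!small] * (c_in - c_out * exp(-u[!small])) /
    (1 - exp(-u[!small]))
  # series limit at u -> 0: u/(1-e^-u) -> 1
  out[small] <- (c_in - c_out * exp(-u[small]))
  out
}

#' Synthesize voltage-ramp recordings with known reversal potentials
#'
#' For each ion condition, generates a paired rest trace (linear leak) and an
#' active trace (leak + GHK-shaped channel current) over a voltage ramp, with
#' optional Gaussian current noise. After leak subtraction, each active trace
#' crosses zero at the prescribed reversal potential (up to noise).
#'
#' @param vrev_by_ion Named numeric vector of reversal potentials, mV (names
#'   are ion labels, e.g. `c(Na = 30, K = -24.4)`).
#' @param slope Net-current slope at the reversal potential, nA/mV.
#' @param noise_sd Gaussian current noise sd, nA (>= 0).
#' @param v_range Ramp span, mV (default -100..60, a 160 mV span; the
#'   protocol ramp covers it in 200 ms).
#' @param n_points Samples along the ramp.
#' @param leak_conductance Leak slope, nA/mV (leak reverses at 0 mV).
#' @param thermo A [thermo_state()]; default 274 K.
#' @param seed Integer seed (same seed, identical traces).
#' @return Object of class `ramp_set`: named list per ion, each with
#'   `active` and `rest` [ramp_recording()]s; ground truth in attribute
#'   `vrev`.
#' @examples
#' rs <- synthesize_ramp_recording(c(Na = 30, K = -24.4), noise_sd = 0)
#' net <- subtract_leak(rs$Na$active, rs$Na$rest)
#' find_reversal_potential(net)   # 30
#' @export
synthesize_ramp_recording <- function(vrev_by_ion, slope = 0.1, noise_sd = 0,
                                      v_range = c(-100, 60), n_points = 201,
                                      leak_conductance = 0.05,
                                      thermo = thermo_state(274), seed = NULL) {
  stopifnot(length(vrev_by_ion) >= 1, !is.null(names(vrev_by_ion)))
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  check_scalar(slope, "slope", positive = TRUE)
  if (diff(v_range) <= 0) stop("ramp span must be > 0")
  vt <- rt_over_f_mv(thermo)
  v <- seq(v_range[1], v_range[2], length.out = n_points)
  out <- with_seed(seed, {
    lapply(names(vrev_by_ion), function(ion) {
      vr <- vrev_by_ion[[ion]]
      shape <- ghk_current_shape(v, vr, vt)
      # scale so dI/dV = slope at the reversal potential
      h <- 0.01
      dshape <- (ghk_current_shape(vr + h, vr, vt) -
                   ghk_current_shape(vr - h, vr, vt)) / (2 * h)
      ichan <- shape * slope / dshape
      leak <- leak_conductance * v
      list(
        active = ramp_recording(v, leak + ichan + rnorm(n_points, 0, noise_sd),
                                "active", ion),
        rest = ramp_recording(v, leak + rnorm(n_points, 0, noise_sd),
                              "rest", ion)
      )
    })
  })
  names(out) <- names(vrev_by_ion)
  attr(out, "vrev") <- vrev_by_ion
  class(out) <- "ramp_set"
  out
}

#' Synthesize a proton dose-response curve
#'
#' Noiseless output lies exactly on the four-parameter logistic
#' `floor + (ceiling - floor) / (1 + 10^(slope * (pH - pH50)))` (the Hill
#' equation in proton concentration, written in pH units).
#'
#' @param ph50 Midpoint, pH units.
#' @param hill_slope Hill coefficient.
#' @param floor,ceiling Lower/upper asymptotes of the normalised response
#'   (`floor < ceiling`).
#' @param n_points Number of pH points (a 2-point grid triggers an
#'   underdetermined-fit warning).
#' @param noise_sd Gaussian response noise sd.
#' @param ph_range pH grid span; a grid missing `ph50` by more than 1 unit
#'   triggers an ill-conditioning warning.
#' @param seed Integer seed.
#' @return Object of class `dose_response`: data.frame `ph`, `response`,
#'   with ground-truth parameters in attribute `truth`.
#' @export
synthesize_dose_response <- function(ph50 = 6.8, hill_slope = 1, floor = 0,
                                     ceiling = 1, n_points = 8, noise_sd = 0,
                                     ph_range = ph50 + c(-1.5, 1.5),
                                     seed = NULL) {
  check_scalar(ph50, "ph50"); check_scalar(hill_slope, "hill_slope")
  check_scalar(noise_sd, "noise_sd", nonneg = TRUE)
  if (floor >= ceiling) stop("floor must be < ceiling")
  if (ph50 < min(ph_range) - 1 || ph50 > max(ph_range) + 1) {
    warning("pH grid excludes pH50 by more than 1 unit: fit will be ill-conditioned")
  }
  if (n_points < 5) warning("underdetermined: fewer points than free parameters")
  ph <- seq(min(ph_range), max(ph_range), length.out = n_points)
  resp <- floor + (ceiling - floor) / (1 + 10^(hill_slope * (ph - ph50)))
  resp <- with_seed(seed, resp + rnorm(n_points, 0, noise_sd))
  out <- data.frame(ph = ph, response = resp)
  attr(out, "truth") <- c(ph50 = ph50, slope = hill_slope,
                          floor = floor, ceiling = ceiling)
  class(out) <- c("dose_response", "data.frame")
  out
}
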