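#' Simulation parameters for the Langevin sampler
#'
#' @param diffusion_coefficient D in A^2/ns. The toy-dynamics default of
#'   50 A^2/ns is of the order of an aqueous ion's diffusivity; only the
#'   stationary statistics matter downstream, so D sets efficiency, not the
#'   sampled distribution.
#' @param timestep Integration step in ns.
#' @param n_steps Number of steps.
#' @param temperature Temperature in K.
#' @param seed Integer seed; a fixed seed gives bitwise-reproducible output.
#' @return An object of class `simulation_params`.
#' @export
simulation_params <- function(diffusion_coefficient = 50, timestep = 1e-4,
                              n_steps = 1e5, temperature = 303, seed = 1L) {
  check_scalar(diffusion_coefficient, "diffusion_coefficient", positive = TRUE)
  check_scalar(timestep, "timestep", positive = TRUE)
  check_scalar(n_steps, "n_steps", positive = TRUE)
  check_scalar(temperature, "temperature", positive = TRUE)
  obj <- list(diffusion_coefficient = diffusion_coefficient,
              timestep = timestep, n_steps = as.integer(n_steps),
              temperature = temperature, seed = as.integer(seed))
  class(obj) <- "simulation_params"
  obj
}

#' Overdamped Langevin sampling of a model surface
#'
#' Integrates the overdamped (Brownian) update
#' \deqn{z \leftarrow z - (D/k_BT)\, U'(z)\, dt + \sqrt{2 D dt}\,\xi}
#' on a [model_surface()], optionally under a harmonic umbrella bias, with
#' reflecting walls at the surface domain (plus `padding`). The stationary
#' distribution of the chain is the Boltzmann density exp(-U_tot/kBT), which
#' is what the unbiasing estimators consume; inertia is deliberately omitted.
#'
#' Integration uses the Leimkuhler-Matthews (BAOAB-limit) scheme, whose
#' stationary configurational density is accurate to O(dt^2); a stability
#' check warns when the stiffness parameter \eqn{\alpha = D k_{max} dt / k_BT}
#' (with \eqn{k_{max}} the largest local curvature of the total potential on
#' the domain) exceeds 1, and aborts above 2 where the chain is unstable.
#'
#' @param surface A [model_surface()].
#' @param params A [simulation_params()].
#' @param bias Optional [umbrella_window()] (its center must lie inside the
#'   surface domain).
#' @param z0 Starting position; defaults to the bias center, else the domain
#'   midpoint.
#' @param padding Reflecting walls are placed `padding` A outside the surface
#'   domain.
#' @param stride Keep every `stride`-th sample.
#' @return An object of class `rc_series`: list with `z` (A), `dt` (ns,
#'   sampling interval = timestep * stride), `window_id`, `reflections`, and
#'   the generating parameters.
#' @examples
#' su <- model_surface("harmonic", k = 2.5, domain = c(-6, 6))
#' ts <- simulate_langevin(su, simulation_params(n_steps = 2e4, seed = 7))
#' var(ts$z)   # ~ kBT/k
#' @export
simulate_langevin <- function(surface, params, bias = NULL, z0 = NULL,
                              padding = 0.5, stride = 1L) {
  stopifnot(inherits(surface, "model_surface"),
            inherits(params, "simulation_params"))
  th <- thermo_state(params$temperature)
  lo <- surface$domain[1] - padding
  hi <- surface$domain[2] + padding
  if (!is.null(bias)) {
    stopifnot(inherits(bias, "umbrella_window"))
    if (bias$center < surface$domain[1] || bias$center > surface$domain[2]) {
      stop("bias center lies outside the surface domain")
    }
  }
  if (is.null(z0)) z0 <- if (!is.null(bias)) bias$center else mean(surface$domain)

  # stability check: local curvature of total potential on a probe grid
  zz <- seq(lo, hi, length.out = 201)
  h <- 1e-3
  curv <- (surface_energy(surface, zz + h) - 2 * surface_energy(surface, zz) +
             surface_energy(surface, zz - h)) / h^2
  kmax <- max(abs(curv)) + if (!is.null(bias)) bias$force_constant else 0
  alpha <- params$diffusion_coefficient * kmax * params$timestep / th$kBT
  if (alpha > 2) {
    stop(sprintf("timestep too large: D*k*dt/kBT = %.2f > 2 (unstable)", alpha))
  }
  if (alpha > 1) {
    warning(sprintf("coarse timestep: D*k*dt/kBT = %.2f > 1; expect discretisation bias",
                    alpha))
  }

  form <- match(surface$form, c("flat", "harmonic", "double_well", "piecewise_table")) - 1L
  par <- switch(surface$form,
    flat = numeric(2),
    harmonic = c(surface$par$k, surface$par$center),
    double_well = c(surface$par$a, surface$par$b),
    piecewise_table = numeric(2))
  tab <- if (surface$form == "piecewise_table") surface$par$table else
    data.frame(z = c(0, 1), U = c(0, 0))

  res <- with_seed(params$seed,
    langevin_run(form, par, tab$z, tab$U,
                 if (!is.null(bias)) bias$center else 0,
                 if (!is.null(bias)) bias$force_constant else 0,
                 !is.null(bias),
                 z0, params$n_steps, params$timestep,
                 params$diffusion_coefficient, th$kBT, lo, hi,
                 as.integer(stride)))
  if (isTRUE(res$error)) {
    stop(sprintf("non-finite force encountered at z = %g (step %d)",
                 res$z_at_error, res$step))
  }
  out <- list(z = res$z, dt = params$timestep * stride,
              window_id = if (!is.null(bias)) bias$window_id else NA_integer_,
              reflections = res$reflections,
              temperature = params$temperature, seed = params$seed)
  class(out) <- "rc_series"
  out
}

#' @export
print.rc_series <- function(x, ...) {
  cat(sprintf("<rc_series> %d samples, dt = %g ns, window %s, %g reflections\n",
              length(x$z), x$dt,
              ifelse(is.na(x$window_id), "none", x$window_id), x$reflections))
  invisible(x)
}

#' Write / read reaction-coordinate time series
#'
#' Plain-text table with columns `time_ns`, `z_angstrom`, `window_id`; several
#' windows may be concatenated in one file.
#'
#' @param series An `rc_series` or list of them.
#' @param path File path.
#' @return `read_rc_series()` returns a data.frame with those columns.
#' @export
write_rc_series <- function(series, path) {
  if (inherits(series, "rc_series")) series <- list(series)
  dfs <- lapply(series, function(s) {
    data.frame(time_ns = seq_along(s$z) * s$dt, z_angstrom = s$z,
               window_id = s$window_id)
  })
  write.table(do.call(rbind, dfs), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_rc_series
#' @export
read_rc_series <- function(path) {
  read.table(path, header = TRUE, sep = "\t")
}
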