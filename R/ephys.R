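#' Voltage-ramp recordings
#'
#' A single ramp trace: strictly monotone voltage grid (from a 160 mV span /
#' 200 ms ramp by default) with the measured current, tagged by condition
#' (`rest` before activation, or `active`) and the extracellular cation.
#'
#' @param voltage Voltage grid, mV (strictly monotone).
#' @param current Current, nA.
#' @param condition `"rest"` or `"active"`.
#' @param ion Extracellular cation label (`Na`, `Li`, `K`, `Cs`).
#' @return Object of class `ramp_recording`.
#' @export
ramp_recording <- function(voltage, current, condition = c("active", "rest"),
                           ion = "Na") {
  condition <- match.arg(condition)
  stopifnot(length(voltage) == length(current), length(voltage) >= 2)
  dv <- diff(voltage)
  if (!(all(dv > 0) || all(dv < 0))) stop("voltage grid must be strictly monotone")
  obj <- list(voltage = voltage, current = current,
              condition = condition, ion = ion)
  class(obj) <- "ramp_recording"
  obj
}

#' @export
print.ramp_recording <- function(x, ...) {
  cat(sprintf("<ramp_recording> %s/%s, %d points, V in [%g, %g] mV\n",
              x$ion, x$condition, length(x$voltage),
              min(x$voltage), max(x$voltage)))
  invisible(x)
}

#' Leak subtraction
#'
#' Pointwise `active - rest` current. When the two voltage grids differ, the
#' rest trace is linearly interpolated onto the overlapping part of the
#' active grid and the result is flagged via the `interpolated` attribute.
#'
#' @param active,rest Paired [ramp_recording()]s for the same ion.
#' @return A `ramp_recording` with condition `"active"` holding the net
#'   current.
#' @export
subtract_leak <- function(active, rest) {
  stopifnot(inherits(active, "ramp_recording"), inherits(rest, "ramp_recording"))
  if (!identical(active$ion, rest$ion)) {
    stop("active and rest traces are for different ion conditions")
  }
  if (isTRUE(all.equal(active$voltage, rest$voltage))) {
    out <- ramp_recording(active$voltage, active$current - rest$current,
                          "active", active$ion)
    attr(out, "interpolated") <- FALSE
    return(out)
  }
  lo <- max(min(active$voltage), min(rest$voltage))
  hi <- min(max(active$voltage), max(rest$voltage))
  if (lo >= hi) stop("non-overlapping voltage spans")
  keep <- active$voltage >= lo & active$voltage <= hi
  rest_i <- approx(rest$voltage, rest$current, xout = active$voltage[keep])$y
  out <- ramp_recording(active$voltage[keep], active$current[keep] - rest_i,
                        "active", active$ion)
  attr(out, "interpolated") <- TRUE
  out
}

#' Reversal potential of a leak-subtracted trace
#'
#' Locates the single zero crossing of the net current by linear
#' interpolation between the bracketing samples. Traces with no sign change,
#' or more than one (noise or bad subtraction), are rejected.
#'
#' @param net A leak-subtracted [ramp_recording()].
#' @return Reversal potential, mV.
#' @export
find_reversal_potential <- function(net) {
  stopifnot(inherits(net, "ramp_recording"))
  i <- net$current
  v <- net$voltage
  s <- sign(i)
  flips <- which(s[-1] * s[-length(s)] < 0)
  zeros <- which(i == 0)
  n_cross <- length(flips) + length(zeros)
  if (n_cross == 0) stop("no reversal in span: current does not change sign")
  if (n_cross > 1) {
    stop(sprintf("multiple zero crossings (%d): noisy trace or bad subtraction", n_cross))
  }
  if (length(zeros) == 1) return(v[zeros])
  j <- flips[1]
  v[j] + (v[j + 1] - v[j]) * (0 - i[j]) / (i[j + 1] - i[j])
}

#' Goldman-Hodgkin-Katz relative permeability from reversal potentials
#'
#' Under bi-ionic conditions the shift in reversal potential between two
#' external cations gives their permeability ratio:
#' \deqn{P_{Na}/P_X = \exp\left(F (V_{rev,Na} - V_{rev,X}) / RT\right).}
#' At the recording temperature of 274 K, RT/F = 23.61 mV. Both orientations
#' of the ratio are returned; a more positive reversal in Na+ means the
#' channel prefers Na+.
#'
#' @param vrev_na,vrev_x Reversal potentials, mV.
#' @param thermo A [thermo_state()]; default at 274 K.
#' @return List of class `permeability_ratio`: `p_na_over_p_x`,
#'   `p_x_over_p_na`, `log10_p_na_over_p_x`, `dv_mv`, `temperature`.
#' @examples
#' permeability_ratio(30, -24.4)$p_na_over_p_x   # ~ 10
#' @export
permeability_ratio <- function(vrev_na, vrev_x, thermo = thermo_state(274)) {
  check_scalar(vrev_na, "vrev_na"); check_scalar(vrev_x, "vrev_x")
  stopifnot(inherits(thermo, "thermo_state"))
  vt <- rt_over_f_mv(thermo)
  ratio <- exp((vrev_na - vrev_x) / vt)
  obj <- list(p_na_over_p_x = ratio, p_x_over_p_na = 1 / ratio,
              log10_p_na_over_p_x = log10(ratio),
              dv_mv = vrev_na - vrev_x, temperature = thermo$temperature)
  class(obj) <- "permeability_ratio"
  obj
}

#' @export
print.permeability_ratio <- function(x, ...) {
  cat(sprintf("<permeability_ratio> dV = %.2f mV at %g K: P_Na/P_X = %.3f (log10 %.3f)\n",
              x$dv_mv, x$temperature, x$p_na_over_p_x, x$log10_p_na_over_p_x))
  invisible(x)
}

#' Four-parameter Hill fit of a proton dose-response curve
#'
#' Fits \deqn{I(pH) = floor + \frac{ceiling - floor}{1 + ([H^+]_{50}/[H^+])^n}}
#' by nonlinear least squares, parameterised in pH (so
#' \eqn{([H^+]_{50}/[H^+])^n = 10^{\,n\,(pH - pH_{50})}}). Reports the
#' midpoint in pH units (pH50), the Hill slope n, floor and ceiling with
#' asymptotic 95% confidence intervals. Flat data or non-convergence yields a
#' flagged failure with no parameters.
#'
#' @param ph Numeric pH grid (>= 5 points spanning the transition).
#' @param response Normalised current at each pH.
#' @return Object of class `hill_fit`: `converged`, and on success
#'   `parameters` (named vector pH50, slope, floor, ceiling), `ci` (95%
#'   asymptotic), `residual_sd`, plus the data.
#' @export
fit_hill <- function(ph, response) {
  stopifnot(length(ph) == length(response), all(is.finite(ph)),
            all(is.finite(response)))
  if (length(ph) < 5) warning("fewer than 5 points: fit may be ill-conditioned")
  fail <- function(reason) {
    structure(list(converged = FALSE, reason = reason, ph = ph,
                   response = response), class = "hill_fit")
  }
  if (sd(response) < 1e-12) return(fail("flat response"))
  start <- list(floor = min(response), ceiling = max(response),
                ph50 = ph[which.min(abs(response - mean(range(response))))],
                slope = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ floor + (ceiling - floor) / (1 + 10^(slope * (ph - ph50))),
      start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail("non-convergence"))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 4))
  ci <- cbind(lower = cf - 1.96 * se, upper = cf + 1.96 * se)
  if (cf[["floor"]] >= cf[["ceiling"]]) return(fail("floor >= ceiling in fit"))
  obj <- list(converged = TRUE,
              parameters = c(ph50 = unname(cf[["ph50"]]),
                             slope = unname(cf[["slope"]]),
                             floor = unname(cf[["floor"]]),
                             ceiling = unname(cf[["ceiling"]])),
              ci = ci, residual_sd = sd(stats::resid(fit)),
              fit = fit, ph = ph, response = response)
  class(obj) <- "hill_fit"
  obj
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat(sprintf("<hill_fit> FAILED: %s\n", x$reason))
  } else {
    p <- x$parameters
    cat(sprintf("<hill_fit> pH50 = %.3f, slope = %.3f, floor = %.3f, ceiling = %.3f\n",
                p["ph50"], p["slope"], p["floor"], p["ceiling"]))
  }
  invisible(x)
}

#' @export
coef.hill_fit <- function(object, ...) {
  if (!object$converged) stop("fit did not converge; no parameters")
  object$parameters
}

#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  p <- coef(object)
  ph <- if (is.null(newdata)) object$ph else newdata$ph %||% newdata
  p["floor"] + (p["ceiling"] - p["floor"]) /
    (1 + 10^(p["slope"] * (ph - p["ph50"])))
}

#' Read / write ramp recordings as CSV
#'
#' Columns `voltage_mV`, `current_nA`, `condition`, `ion`; one file may hold
#' several traces.
#'
#' @param recordings List of [ramp_recording()]s.
#' @param path File path.
#' @return `read_ramp_csv()` returns a list of `ramp_recording`s.
#' @export
write_ramp_csv <- function(recordings, path) {
  if (inherits(recordings, "ramp_recording")) recordings <- list(recordings)
  df <- do.call(rbind, lapply(recordings, function(r) {
    data.frame(voltage_mV = r$voltage, current_nA = r$current,
               condition = r$condition, ion = r$ion)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ramp_csv
#' @export
read_ramp_csv <- function(path) {
  df <- utils::read.csv(path)
  keys <- unique(df[, c("condition", "ion")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- df[df$condition == keys$condition[i] & df$ion == keys$ion[i], ]
    ramp_recording(sub$voltage_mV, sub$current_nA, keys$condition[i], keys$ion[i])
  })
}
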