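#' One-dimensional model free-energy surfaces
#'
#' Defines the analytic (or tabulated) surfaces U(z) that the bundled Langevin
#' sampler draws from. These stand in for the true potential of mean force
#' along the pore axis: a known surface makes every downstream estimator
#' (Boltzmann inversion, WHAM) testable against an exact oracle.
#'
#' Supported forms:
#' \describe{
#'   \item{`flat`}{U(z) = 0.}
#'   \item{`harmonic`}{U(z) = k/2 (z - center)^2, `k` in kcal/mol/A^2.}
#'   \item{`double_well`}{U(z) = a (z^2 - b^2)^2, `a` in kcal/mol/A^4, wells at
#'     z = -b and +b, barrier a*b^4 at z = 0.}
#'   \item{`piecewise_table`}{linear interpolation of a `data.frame(z, U)`
#'     with strictly increasing z.}
#' }
#'
#' @param form One of `"flat"`, `"harmonic"`, `"double_well"`,
#'   `"piecewise_table"`.
#' @param domain Closed interval of z (Angstrom) on which the surface is
#'   defined; the sampler reflects at these bounds.
#' @param k,center Harmonic force constant (kcal/mol/A^2) and minimum position.
#' @param a,b Quartic coefficient (kcal/mol/A^4) and well position (Angstrom).
#' @param table `data.frame` with columns `z` and `U` for the tabulated form.
#' @return An object of class `model_surface`.
#' @examples
#' su <- model_surface("double_well", a = 0.25, b = 3, domain = c(-4.5, 4.5))
#' surface_energy(su, c(-3, 0, 3))   # 0, 20.25, 0
#' @export
model_surface <- function(form = c("flat", "harmonic", "double_well", "piecewise_table"),
                          domain = c(-10, 10), k = 1, center = 0,
                          a = 0.25, b = 3, table = NULL) {
  form <- match.arg(form)
  stopifnot(length(domain) == 2L, all(is.finite(domain)), domain[1] < domain[2])
  par <- switch(form,
    flat = list(),
    harmonic = {
      check_scalar(k, "k", positive = TRUE); check_scalar(center, "center")
      list(k = k, center = center)
    },
    double_well = {
      check_scalar(a, "a", positive = TRUE); check_scalar(b, "b", positive = TRUE)
      list(a = a, b = b)
    },
    piecewise_table = {
      if (is.null(table) || !all(c("z", "U") %in% names(table))) {
        stop("piecewise_table requires 'table' with columns z and U")
      }
      if (any(diff(table$z) <= 0)) stop("table z values must be strictly increasing")
      if (!all(is.finite(table$U))) stop("table energies must be finite")
      list(table = table[order(table$z), c("z", "U")])
    })
  obj <- list(form = form, domain = as.numeric(domain), par = par)
  class(obj) <- "model_surface"
  # continuity / finiteness sanity check on a probe grid
  zz <- seq(domain[1], domain[2], length.out = 101)
  if (!all(is.finite(surface_energy(obj, zz)))) {
    stop("surface energy is non-finite on its domain")
  }
  obj
}

#' Evaluate a model surface
#'
#' @param surface A [model_surface()].
#' @param z Numeric vector of positions (Angstrom).
#' @return `surface_energy()` gives U(z) in kcal/mol; `surface_force()` gives
#'   -dU/dz in kcal/mol/A (analytic for parametric forms, centered finite
#'   differences with step 1e-4 A for tabulated ones).
#' @export
surface_energy <- function(surface, z) {
  stopifnot(inherits(surface, "model_surface"))
  p <- surface$par
  switch(surface$form,
    flat = rep(0, length(z)),
    harmonic = 0.5 * p$k * (z - p$center)^2,
    double_well = p$a * (z^2 - p$b^2)^2,
    piecewise_table = approx(p$table$z, p$table$U, xout = z, rule = 2)$y)
}

#' @rdname surface_energy
#' @export
surface_force <- function(surface, z) {
  stopifnot(inherits(surface, "model_surface"))
  p <- surface$par
  switch(surface$form,
    flat = rep(0, length(z)),
    harmonic = -p$k * (z - p$center),
    double_well = -4 * p$a * z * (z^2 - p$b^2),
    piecewise_table = {
      h <- 1e-4
      -(surface_energy(surface, z + h) - surface_energy(surface, z - h)) / (2 * h)
    })
}

#' @export
print.model_surface <- function(x, ...) {
  cat(sprintf("<model_surface> form = %s, domain = [%g, %g] A\n",
              x$form, x$domain[1], x$domain[2]))
  invisible(x)
}
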