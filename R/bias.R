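#' Harmonic umbrella windows
#'
#' An umbrella window restrains the ion near a target position along the pore
#' axis with a harmonic bias U_b(z) = k/2 (z - center)^2. The production
#' schedule uses k = 2.5 kcal/mol/A^2 at 1 A spacing, with stiffer windows
#' (k = 5.14) where sampling is hard.
#'
#' @param center Window center (Angstrom along z).
#' @param force_constant Harmonic force constant k, kcal/mol/A^2 (>= 0;
#'   k = 0 denotes an unbiased window, the degenerate case in which WHAM
#'   reduces to direct Boltzmann inversion).
#' @param window_id Integer identifier, unique within a schedule.
#' @return An object of class `umbrella_window`.
#' @export
umbrella_window <- function(center, force_constant = 2.5, window_id = 1L) {
  check_scalar(center, "center")
  check_scalar(force_constant, "force_constant", nonneg = TRUE)
  obj <- list(center = center, force_constant = force_constant,
              window_id = as.integer(window_id))
  class(obj) <- "umbrella_window"
  obj
}

#' @export
print.umbrella_window <- function(x, ...) {
  cat(sprintf("<umbrella_window %d> center = %g A, k = %g kcal/mol/A^2\n",
              x$window_id, x$center, x$force_constant))
  invisible(x)
}

#' Harmonic bias energy of an umbrella window
#'
#' U_b(z) = k/2 (z - center)^2. The half-k convention is fixed package-wide so
#' that the sampler and the WHAM unbias use the identical functional form; see
#' the methods vignette.
#'
#' @param window An [umbrella_window()].
#' @param z Position(s) along the axis, Angstrom.
#' @return Bias energy in kcal/mol (vectorised over `z`).
#' @examples
#' w <- umbrella_window(0, 2.5)
#' harmonic_bias_energy(w, 1)    # 1.25
#' @export
harmonic_bias_energy <- function(window, z) {
  stopifnot(inherits(window, "umbrella_window"))
  0.5 * window$force_constant * (z - window$center)^2
}

#' Flat-bottom restraints
#'
#' A flat-bottom restraint is exactly zero inside a region (cylinder around
#' the z-axis, slab in the xy-plane, or sphere) and harmonic in the excess
#' distance outside: U = k/2 (d - size)^2 for d > size. Value and first
#' derivative are continuous at the boundary. The production geometries are a
#' 9 A cylinder (k = 10) for umbrella sampling, a 2.75 A sphere at the
#' carboxylate-site centre of mass for occupancy control, and 15 A cylinder /
#' 10 A (or 4 A) slab containments.
#'
#' @param geometry `"cylinder"` (radial distance from the z-axis through the
#'   reference), `"slab"` (|z - z_ref|, half-thickness), or `"sphere"`
#'   (distance from the reference point).
#' @param size Radius or half-thickness, Angstrom (> 0).
#' @param force_constant k in kcal/mol/A^2.
#' @param reference Name of the centre-of-mass anchor that positions the
#'   restraint; resolved against a frame's named anchor list.
#' @return An object of class `restraint_spec`.
#' @export
restraint_spec <- function(geometry = c("cylinder", "slab", "sphere"),
                           size, force_constant = 10,
                           reference = "site_com") {
  geometry <- match.arg(geometry)
  check_scalar(size, "size", positive = TRUE)
  check_scalar(force_constant, "force_constant", positive = TRUE)
  obj <- list(geometry = geometry, size = size,
              force_constant = force_constant, reference = reference)
  class(obj) <- "restraint_spec"
  obj
}

#' Flat-bottom restraint energy
#'
#' @param restraint A [restraint_spec()].
#' @param position Numeric length-3 vector (x, y, z) in Angstrom, or a matrix
#'   with three columns.
#' @param anchor Named reference point (length-3 numeric); defaults to the
#'   origin when the frame supplies no anchors.
#' @return Energy in kcal/mol, zero inside the flat region.
#' @examples
#' r <- restraint_spec("cylinder", size = 9, force_constant = 10)
#' flat_bottom_energy(r, c(5, 0, 0))      # 0
#' flat_bottom_energy(r, c(9.5, 0, 0))    # 1.25
#' @export
flat_bottom_energy <- function(restraint, position, anchor = c(0, 0, 0)) {
  stopifnot(inherits(restraint, "restraint_spec"))
  if (is.null(dim(position))) position <- matrix(position, ncol = 3, byrow = TRUE)
  stopifnot(ncol(position) == 3L, length(anchor) == 3L)
  rel <- sweep(position, 2L, as.numeric(anchor))
  d <- switch(restraint$geometry,
    cylinder = sqrt(rel[, 1]^2 + rel[, 2]^2),
    slab     = abs(rel[, 3]),
    sphere   = sqrt(rowSums(rel^2)))
  excess <- pmax(d - restraint$size, 0)
  0.5 * restraint$force_constant * excess^2
}

#' Build an umbrella-window schedule
#'
#' Regular centers from `z_min` to `z_max` inclusive at `spacing`, all with
#' force constant `k`, plus optional extra windows (each a `(center, k)` pair)
#' appended after the regular grid. The production schedules are
#' `make_window_schedule(-25, 20, 1, 2.5)` (46 windows, open state) and
#' `make_window_schedule(-25, 0, 1, 2.5)` (26 windows, closed state), the
#' latter extended by extra windows at z = 9.5 and 11.5 A (k = 5.14) to assist
#' K+ sampling.
#'
#' @param z_min,z_max Schedule span, Angstrom (`z_min < z_max`).
#' @param spacing Center spacing, Angstrom (> 0).
#' @param k Force constant for the regular windows, kcal/mol/A^2.
#' @param extras Optional list of `c(center, k)` pairs.
#' @return A `window_schedule`: a list of [umbrella_window()]s with a
#'   `as.data.frame` method.
#' @examples
#' length(make_window_schedule(-25, 20, 1, 2.5))   # 46
#' @export
make_window_schedule <- function(z_min, z_max, spacing = 1, k = 2.5,
                                 extras = list()) {
  check_scalar(z_min, "z_min"); check_scalar(z_max, "z_max")
  if (z_min >= z_max) stop("z_min must be < z_max")
  check_scalar(spacing, "spacing", positive = TRUE)
  centers <- seq(z_min, z_max, by = spacing)
  ks <- rep(k, length(centers))
  for (ex in extras) {
    stopifnot(length(ex) == 2L)
    if (any(abs(centers - ex[1]) < 1e-9)) {
      stop(sprintf("extra window at z = %g duplicates an existing center (ambiguous window id)",
                   ex[1]))
    }
    centers <- c(centers, ex[1]); ks <- c(ks, ex[2])
  }
  sched <- Map(function(c0, k0, id) umbrella_window(c0, k0, id),
               centers, ks, seq_along(centers))
  class(sched) <- c("window_schedule", "list")
  sched
}

#' @export
as.data.frame.window_schedule <- function(x, ...) {
  data.frame(
    window_id = vapply(x, `[[`, integer(1), "window_id"),
    center = vapply(x, `[[`, numeric(1), "center"),
    force_constant = vapply(x, `[[`, numeric(1), "force_constant")
  )
}

#' @export
print.window_schedule <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<window_schedule> %d windows, centers [%g, %g] A\n",
              nrow(df), min(df$center), max(df$center)))
  invisible(x)
}

#' Serialize / read a window schedule
#'
#' Plain-text table with columns `window_id`, `center`, `force_constant`.
#'
#' @param schedule A `window_schedule`.
#' @param path File path.
#' @return `read_window_schedule()` returns a `window_schedule`.
#' @export
write_window_schedule <- function(schedule, path) {
  write.table(as.data.frame(schedule), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_window_schedule
#' @export
read_window_schedule <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  sched <- Map(function(c0, k0, id) umbrella_window(c0, k0, id),
               df$center, df$force_constant, df$window_id)
  class(sched) <- c("window_schedule", "list")
  sched
}
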