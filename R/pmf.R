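#' Free-energy profile objects
#'
#' A free-energy profile W(z) on a fixed bin grid, with per-bin standard
#' errors where available and a mask for bins with no samples. W is defined up
#' to a constant; the stored profile is offset so that its average over the
#' `zero_region` (the bulk reference interval) is zero.
#'
#' @param bin_centers Bin centers, Angstrom.
#' @param W Free energy per bin, kcal/mol (NA where masked).
#' @param stderr Per-bin standard error (NA if not computed).
#' @param mask Logical, TRUE for bins with insufficient samples.
#' @param zero_region Length-2 interval of z where W averages zero.
#' @param meta Named list of provenance (iterations, residual, ...).
#' @return Object of class `free_energy_profile`.
#' @export
free_energy_profile <- function(bin_centers, W, stderr = rep(NA_real_, length(W)),
                                mask = !is.finite(W), zero_region = NULL,
                                meta = list()) {
  stopifnot(length(bin_centers) == length(W), length(W) == length(stderr))
  if (any(!is.finite(W[!mask]))) stop("W must be finite on unmasked bins")
  obj <- list(bin_centers = bin_centers, W = W, stderr = stderr, mask = mask,
              zero_region = zero_region, meta = meta)
  class(obj) <- "free_energy_profile"
  obj
}

#' @export
print.free_energy_profile <- function(x, ...) {
  ok <- !x$mask
  cat(sprintf("<free_energy_profile> %d bins (%d masked), z in [%g, %g] A, W range [%.3f, %.3f] kcal/mol\n",
              length(x$W), sum(x$mask),
              min(x$bin_centers), max(x$bin_centers),
              min(x$W[ok]), max(x$W[ok])))
  if (!is.null(x$meta$converged) && !isTRUE(x$meta$converged)) {
    cat("  WARNING: WHAM iteration did not reach tolerance\n")
  }
  invisible(x)
}

#' @export
as.data.frame.free_energy_profile <- function(x, ...) {
  data.frame(z = x$bin_centers, W = x$W, stderr = x$stderr, masked = x$mask)
}

#' @export
plot.free_energy_profile <- function(x, ...) {
  ok <- !x$mask
  plot(x$bin_centers[ok], x$W[ok], type = "l",
       xlab = "z (Angstrom)", ylab = "W(z) (kcal/mol)", ...)
  if (any(is.finite(x$stderr[ok]))) {
    s <- x$stderr[ok]; z <- x$bin_centers[ok]; w <- x$W[ok]
    fin <- is.finite(s)
    segments(z[fin], w[fin] - s[fin], z[fin], w[fin] + s[fin], col = "grey60")
  }
  invisible(x)
}

#' Write a profile as a plain-text table
#'
#' Columns `z`, `W`, `stderr`, `masked`.
#' @param profile A [free_energy_profile()].
#' @param path File path.
#' @export
write_profile <- function(profile, path) {
  write.table(as.data.frame(profile), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Per-window burn-in presets (ns)
#'
#' Named burn-in durations used for the production umbrella runs: 6 ns (Na+)
#' and 7 ns (K+) in the closed-state structure, 6 ns (Na+) and 3 ns (K+) in
#' the open-state structure.
#' @export
burnin_presets <- list(
  closed_Na = 6, closed_K = 7,
  open_Na = 6, open_K = 3
)

#' Biased sample sets for WHAM
#'
#' Couples per-window reaction-coordinate series to their umbrella schedule
#' and burn-in. Burn-in is expressed in time units (ns) and converted via each
#' series' sampling interval.
#'
#' @param series List of `rc_series` (from [simulate_langevin()]) or numeric
#'   vectors, one per window, in schedule order.
#' @param schedule A `window_schedule` (see [make_window_schedule()]).
#' @param dt Sampling interval (ns); taken from the series when they are
#'   `rc_series`.
#' @param burnin Burn-in per window in ns (scalar recycled, or vector).
#' @return Object of class `biased_sample_set`.
#' @export
biased_samples <- function(series, schedule, dt = NULL, burnin = 0) {
  stopifnot(inherits(schedule, "window_schedule"))
  if (length(series) != length(schedule)) {
    stop("one series per window required")
  }
  zs <- lapply(series, function(s) if (inherits(s, "rc_series")) s$z else as.numeric(s))
  if (is.null(dt)) {
    dts <- vapply(series, function(s) if (inherits(s, "rc_series")) s$dt else NA_real_, 0)
    if (any(is.na(dts))) stop("dt must be supplied for plain numeric series")
    dt <- dts[1]
  }
  burnin <- rep_len(burnin, length(zs))
  lens_ns <- vapply(zs, length, 0L) * dt
  if (any(burnin >= lens_ns)) {
    stop("burn-in must be shorter than the series length")
  }
  obj <- list(z = zs, schedule = as.data.frame(schedule), dt = dt, burnin = burnin)
  class(obj) <- "biased_sample_set"
  obj
}

#' @export
print.biased_sample_set <- function(x, ...) {
  cat(sprintf("<biased_sample_set> %d windows, dt = %g ns, %s samples total\n",
              length(x$z), x$dt, format(sum(lengths(x$z)), big.mark = ",")))
  invisible(x)
}

# Post-burn-in series.
trim_burnin <- function(data) {
  Map(function(z, b) {
    drop <- floor(b / data$dt)
    if (drop > 0) z[-seq_len(drop)] else z
  }, data$z, data$burnin)
}

# Shared histogram grid.
make_breaks <- function(zs, bin_width) {
  rng <- range(unlist(zs, use.names = FALSE))
  lo <- floor(rng[1] / bin_width) * bin_width
  hi <- ceiling(rng[2] / bin_width) * bin_width
  seq(lo, hi + bin_width / 2, by = bin_width)
}

# Default bulk reference: the 5 A of the profile at the high-z (bulk) end.
default_zero_region <- function(bin_centers, width = 5) {
  c(max(bin_centers) - width, max(bin_centers) + 1e-9)
}

apply_zero <- function(W, bin_centers, mask, zero_region) {
  inz <- bin_centers >= zero_region[1] & bin_centers <= zero_region[2] & !mask
  if (!any(inz)) stop("no sampled bins in the zero_region (bulk reference empty)")
  W - mean(W[inz])
}

#' Free-energy profile by direct Boltzmann inversion
#'
#' For unbiased sampling, W(z) = -kBT ln rho(z) + C where rho is the empirical
#' probability density of the reaction coordinate; C is chosen so W averages
#' zero over the `zero_region`. Empty bins are masked, never -Inf.
#'
#' @param z Numeric vector of unbiased samples (Angstrom), or an `rc_series`.
#' @param thermo A [thermo_state()].
#' @param bin_width Histogram bin width, Angstrom (default 0.2).
#' @param zero_region Length-2 bulk interval; default the top 5 A of the
#'   sampled range.
#' @param breaks Optional explicit bin edges (overrides `bin_width`).
#' @param min_samples Bins with fewer samples than this are masked (default
#'   1: only empty bins).
#' @return A [free_energy_profile()].
#' @export
boltzmann_invert <- function(z, thermo = thermo_state(), bin_width = 0.2,
                             zero_region = NULL, breaks = NULL,
                             min_samples = 1) {
  if (inherits(z, "rc_series")) z <- z$z
  stopifnot(length(z) > 0, all(is.finite(z)))
  if (is.null(breaks)) breaks <- make_breaks(list(z), bin_width)
  z <- z[z >= breaks[1] & z <= breaks[length(breaks)]]  # explicit-breaks clip
  if (!length(z)) stop("no samples fall inside the supplied breaks")
  counts <- graphics::hist(z, breaks = breaks, plot = FALSE)$counts
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  mask <- counts < max(min_samples, 1)
  dens <- counts / (sum(counts) * diff(breaks))
  W <- ifelse(mask, NA_real_, -thermo$kBT * log(dens))
  zero_region <- zero_region %||% default_zero_region(centers[!mask])
  W <- apply_zero(W, centers, mask, zero_region)
  free_energy_profile(centers, W, mask = mask, zero_region = zero_region,
                      meta = list(method = "boltzmann_invert",
                                  n_samples = length(z), bin_width = bin_width))
}

#' WHAM unbiasing of umbrella-sampling windows
#'
#' Solves the weighted-histogram self-consistency equations
#' \deqn{\rho(z_b) = \frac{\sum_i n_i(b)}{\sum_i N_i e^{-\beta (U_i(z_b) - f_i)}},
#'       \qquad e^{-\beta f_i} = \sum_b \rho(z_b)\, e^{-\beta U_i(z_b)}}
#' by direct iteration, where U_i is the harmonic bias of window i evaluated
#' at the bin centers. Iteration stops when the largest change in the window
#' shifts f_i (anchored to f_1 = 0) falls below `tol`; hitting `max_iter`
#' returns a result flagged `converged = FALSE` with a warning, never
#' silently. Adjacent windows (by center) must share at least one populated
#' bin, otherwise the offending pair is named and the call rejected.
#'
#' @param data A [biased_samples()] set (burn-in is removed here, per its
#'   `burnin` field).
#' @param thermo A [thermo_state()].
#' @param bin_width Histogram bin width, Angstrom (default 0.2 A; window
#'   spacing in the production schedule is 1 A).
#' @param tol Convergence tolerance on the window shifts, kcal/mol.
#' @param max_iter Maximum iterations.
#' @param zero_region Bulk interval where W is anchored to zero; default the
#'   top 5 A of the sampled range.
#' @param breaks Optional explicit bin edges.
#' @param min_samples Bins with fewer pooled samples than this are masked
#'   (default 1: only empty bins).
#' @return A [free_energy_profile()] whose `meta` records iterations, final
#'   residual, window shifts and the configuration used.
#' @export
wham_solve <- function(data, thermo = thermo_state(), bin_width = 0.2,
                       tol = 1e-7, max_iter = 1e5, zero_region = NULL,
                       breaks = NULL, min_samples = 1) {
  stopifnot(inherits(data, "biased_sample_set"))
  zs <- trim_burnin(data)
  sched <- data$schedule
  nwin <- length(zs)
  if (is.null(breaks)) breaks <- make_breaks(zs, bin_width)
  centers <- (head(breaks, -1) + tail(breaks, -1)) / 2
  zs <- lapply(zs, function(z) z[z >= breaks[1] & z <= breaks[length(breaks)]])
  if (any(lengths(zs) == 0)) stop("a window has no samples inside the supplied breaks")
  counts <- vapply(zs, function(z) graphics::hist(z, breaks = breaks, plot = FALSE)$counts,
                   integer(length(centers)))
  counts <- matrix(counts, ncol = nwin)       # bins x windows
  N <- colSums(counts)

  # adjacent-window overlap check along the schedule
  if (nwin > 1) {
    ord <- order(sched$center)
    for (j in seq_len(nwin - 1)) {
      a <- ord[j]; b <- ord[j + 1]
      if (!any(counts[, a] > 0 & counts[, b] > 0)) {
        stop(sprintf("zero histogram overlap between windows %d and %d (centers %g and %g A)",
                     sched$window_id[a], sched$window_id[b],
                     sched$center[a], sched$center[b]))
      }
    }
  }

  beta <- thermo$beta
  # bias energies at bin centers (bins x windows); optional per-window offset
  off <- if (!is.null(sched$offset)) sched$offset else rep(0, nwin)
  U <- outer(centers, seq_len(nwin),
             function(z, i) 0.5 * sched$force_constant[i] * (z - sched$center[i])^2 +
               off[i])
  B <- exp(-beta * U)
  nb <- rowSums(counts)
  f <- rep(0, nwin)
  iter <- 0L
  resid <- Inf
  repeat {
    iter <- iter + 1L
    denom <- as.vector(B %*% (N * exp(beta * f)))
    rho <- ifelse(denom > 0, nb / denom, 0)
    fnew <- -log(as.vector(crossprod(B, rho))) / beta
    fnew <- fnew - fnew[1]
    resid <- max(abs(fnew - f))
    f <- fnew
    if (resid < tol || iter >= max_iter) break
  }
  converged <- resid < tol
  if (!converged) {
    warning(sprintf("WHAM did not converge: residual %.3g after %d iterations", resid, iter))
  }
  mask <- nb < max(min_samples, 1)
  dens <- rho / sum(rho * diff(breaks))
  W <- ifelse(mask, NA_real_, -thermo$kBT * log(dens))
  zero_region <- zero_region %||% default_zero_region(centers[!mask])
  W <- apply_zero(W, centers, mask, zero_region)
  free_energy_profile(centers, W, mask = mask, zero_region = zero_region,
                      meta = list(method = "wham", iterations = iter,
                                  residual = resid, converged = converged,
                                  shifts = f, tol = tol, max_iter = max_iter,
                                  bin_width = bin_width,
                                  n_samples = sum(N)))
}

#' Block-averaged standard errors for a profile estimator
#'
#' Splits each window's post-burn-in series into `n_blocks` contiguous,
#' equal-length time slices, applies the estimator to each block and reports
#' the per-bin standard error sd(block estimates)/sqrt(n_blocks). The
#' production analyses used four 56-ns blocks (unbiased inversion) and 1-ns
#' blocks (umbrella runs).
#'
#' @param data A [biased_samples()] set.
#' @param estimator Function `(biased_sample_set) -> free_energy_profile`;
#'   it should use fixed `breaks` so block profiles share a grid (profiles are
#'   aligned on bin centers).
#' @param n_blocks Number of blocks (>= 2).
#' @return A data.frame with `z`, `W_mean`, `stderr`, `n_blocks_present` per
#'   bin (bins missing from some block get NA stderr).
#' @export
block_error <- function(data, estimator, n_blocks = 4) {
  stopifnot(inherits(data, "biased_sample_set"), is.function(estimator))
  if (n_blocks < 2) stop("n_blocks must be >= 2")
  zs <- trim_burnin(data)
  blocks <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    sub <- lapply(zs, function(z) {
      len <- floor(length(z) / n_blocks)
      if (len < 1) stop("a block is empty for some window (unbalanced blocks)")
      z[((b - 1) * len + 1):(b * len)]
    })
    d <- data
    d$z <- sub
    d$burnin <- rep(0, length(sub))
    blocks[[b]] <- estimator(d)
  }
  centers <- sort(unique(unlist(lapply(blocks, function(p) p$bin_centers))))
  key <- function(x) sprintf("%.6f", x)
  Wmat <- sapply(blocks, function(p) {
    w <- setNames(ifelse(p$mask, NA_real_, p$W), key(p$bin_centers))
    w[key(centers)]
  })
  Wmat <- matrix(Wmat, nrow = length(centers))
  npresent <- rowSums(is.finite(Wmat))
  se <- apply(Wmat, 1L, function(w) {
    if (all(is.finite(w))) sd(w) / sqrt(length(w)) else NA_real_
  })
  data.frame(z = centers,
             W_mean = rowMeans(Wmat, na.rm = TRUE),
             stderr = se, n_blocks_present = npresent)
}

#' Convergence series of cumulative-data profiles
#'
#' Recomputes the profile on cumulative post-burn-in data up to each
#' checkpoint duration and reports the largest |delta W| between successive
#' checkpoints over bins sampled at both.
#'
#' @param data A [biased_samples()] set.
#' @param checkpoints Strictly increasing durations (ns), each within the
#'   post-burn-in series length (equal consecutive values are allowed and
#'   yield identical profiles).
#' @param estimator Function `(biased_sample_set) -> free_energy_profile`.
#' @return List of class `convergence_series`: `profiles` (one per
#'   checkpoint), `checkpoints`, `max_dW` (length `length(checkpoints) - 1`).
#' @export
convergence_series <- function(data, checkpoints, estimator) {
  stopifnot(inherits(data, "biased_sample_set"), is.function(estimator))
  if (any(diff(checkpoints) < 0)) stop("checkpoints must be non-decreasing")
  zs <- trim_burnin(data)
  avail <- min(vapply(zs, length, 0L)) * data$dt
  if (any(checkpoints > avail + 1e-9)) {
    stop(sprintf("checkpoint %g ns exceeds available data (%g ns)",
                 max(checkpoints), avail))
  }
  profiles <- lapply(checkpoints, function(cp) {
    d <- data
    d$z <- lapply(zs, function(z) z[seq_len(max(1L, floor(cp / data$dt)))])
    d$burnin <- rep(0, length(d$z))
    estimator(d)
  })
  max_dW <- numeric(0)
  if (length(profiles) > 1) {
    max_dW <- vapply(seq_len(length(profiles) - 1L), function(i) {
      a <- profiles[[i]]; b <- profiles[[i + 1L]]
      common <- intersect(sprintf("%.6f", a$bin_centers[!a$mask]),
                          sprintf("%.6f", b$bin_centers[!b$mask]))
      wa <- setNames(a$W, sprintf("%.6f", a$bin_centers))[common]
      wb <- setNames(b$W, sprintf("%.6f", b$bin_centers))[common]
      max(abs(wa - wb))
    }, 0)
  }
  obj <- list(profiles = profiles, checkpoints = checkpoints, max_dW = max_dW)
  class(obj) <- "convergence_series"
  obj
}

#' @export
print.convergence_series <- function(x, ...) {
  cat(sprintf("<convergence_series> %d checkpoints; max |dW| between successive: %s kcal/mol\n",
              length(x$checkpoints),
              paste(sprintf("%.3f", x$max_dW), collapse = ", ")))
  invisible(x)
}
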