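#' Alchemical lambda schedule bookkeeping
#'
#' Carries the per-calculation schedule metadata: number of coupling-parameter
#' windows, their spacing, and equilibration/production time per window. The
#' production protocol pulls lambda from 0 to 1 (forward) and 1 to 0
#' (backward) in 40 steps total (delta_lambda = 0.05, i.e. 20 windows per
#' direction) of 0.2 ns each, followed by 2 ns of production per window — 80
#' ns of production per calculation. The invariant is per direction:
#' `(n_windows / directions) * delta_lambda` must equal 1. The BAR estimator
#' consumes work samples regardless of this provenance; the schedule is
#' reported, not enforced.
#'
#' @param n_windows Total number of lambda windows across all directions.
#' @param delta_lambda Window spacing along lambda.
#' @param directions 2 for a paired forward/backward schedule, 1 for one-way.
#' @param equilibration_per_window,production_per_window ns (>= 0).
#' @return An object of class `lambda_schedule` with a `production_ns` field
#'   (total production time).
#' @examples
#' lambda_schedule()$production_ns   # 80
#' @export
lambda_schedule <- function(n_windows = 40, delta_lambda = 0.05,
                            directions = 2,
                            equilibration_per_window = 0.2,
                            production_per_window = 2) {
  check_scalar(n_windows, "n_windows", positive = TRUE)
  check_scalar(delta_lambda, "delta_lambda", positive = TRUE)
  if (!directions %in% c(1, 2)) stop("directions must be 1 or 2")
  check_scalar(equilibration_per_window, "equilibration_per_window", nonneg = TRUE)
  check_scalar(production_per_window, "production_per_window", nonneg = TRUE)
  if (abs(n_windows / directions * delta_lambda - 1) > 1e-9) {
    stop("(n_windows / directions) * delta_lambda must equal 1 exactly")
  }
  obj <- list(n_windows = as.integer(n_windows), delta_lambda = delta_lambda,
              directions = as.integer(directions),
              equilibration_per_window = equilibration_per_window,
              production_per_window = production_per_window,
              production_ns = n_windows * production_per_window,
              total_ns = n_windows * (equilibration_per_window + production_per_window))
  class(obj) <- "lambda_schedule"
  obj
}

#' Bennett acceptance ratio (BAR) free-energy estimate
#'
#' Solves the BAR self-consistency equation
#' \deqn{\sum_i f(\beta(M + W^F_i - \Delta G)) =
#'       \sum_j f(\beta(W^R_j + \Delta G - M))}
#' with \eqn{f} the Fermi function and \eqn{M = k_BT \ln(n_F/n_R)}, by
#' bracketed root finding. Backward work is given in the direction of its own
#' transformation (no pre-negation). The standard error is the asymptotic BAR
#' variance; an overlap diagnostic reports the fraction of Fermi weights
#' falling in (0.01, 0.99) at the solution — values near 0 flag poor phase-
#' space overlap and an unreliable estimate.
#'
#' @param forward,backward Numeric work vectors in kcal/mol, or a single
#'   `work_set_pair` passed as `forward`.
#' @param thermo A [thermo_state()].
#' @param tol Root-finding tolerance on Delta G (kcal/mol).
#' @return An object of class `bar_result`: `dG`, `stderr`, `overlap`,
#'   `n_forward`, `n_backward`, `temperature`.
#' @examples
#' th <- thermo_state(303)
#' ws <- generate_fep_work_samples(2, 1, 2e4, th, seed = 3)
#' bar_estimate(ws, thermo = th)
#' @export
bar_estimate <- function(forward, backward = NULL, thermo = thermo_state(),
                         tol = 1e-10) {
  if (inherits(forward, "work_set_pair")) {
    backward <- forward$backward
    forward <- forward$forward
  }
  if (length(forward) < 2 || length(backward) < 2) {
    stop("need at least 2 work samples in each direction")
  }
  stopifnot(all(is.finite(forward)), all(is.finite(backward)),
            inherits(thermo, "thermo_state"))
  beta <- thermo$beta
  nF <- length(forward); nR <- length(backward)
  M <- log(nF / nR) / beta
  fermi <- function(x) stats::plogis(-x)   # 1/(1+exp(x))
  g <- function(dG) {
    sum(fermi(beta * (M + forward - dG))) -
      sum(fermi(beta * (backward + dG - M)))
  }
  c0 <- (mean(forward) - mean(backward)) / 2
  width <- max(1, 2 * (sd(forward) + sd(backward)), na.rm = TRUE)
  lo <- c0 - width; hi <- c0 + width
  tries <- 0
  while (g(lo) * g(hi) > 0 && tries < 60) {
    lo <- lo - width; hi <- hi + width; width <- width * 2; tries <- tries + 1
  }
  if (g(lo) == 0 && g(hi) == 0) {
    dG <- c0   # flat objective only when both sides are exactly balanced
  } else if (g(lo) * g(hi) > 0) {
    fF <- fermi(beta * (M + forward - c0))
    stop(sprintf(paste0("BAR bracketing failed: no sign change after widening; ",
                        "overlap fraction %.3f suggests disjoint work distributions"),
                 mean(fF > 0.01 & fF < 0.99)))
  } else {
    dG <- uniroot(g, c(lo, hi), tol = tol)$root
  }
  fF <- fermi(beta * (M + forward - dG))
  fR <- fermi(beta * (backward + dG - M))
  varb <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
          (mean(fR^2) / mean(fR)^2 - 1) / nR
  overlap <- mean(c(fF, fR) > 0.01 & c(fF, fR) < 0.99)
  obj <- list(dG = dG, stderr = sqrt(max(varb, 0)) / beta, overlap = overlap,
              n_forward = nF, n_backward = nR,
              temperature = thermo$temperature)
  class(obj) <- "bar_result"
  obj
}

#' @export
print.bar_result <- function(x, ...) {
  cat(sprintf("<bar_result> dG = %.4f +/- %.4f kcal/mol (n = %d/%d, overlap %.2f)\n",
              x$dG, x$stderr, x$n_forward, x$n_backward, x$overlap))
  invisible(x)
}

#' An alchemical transformation leg
#'
#' @param label Transformation, e.g. `"Na->K"` (single occupancy) or
#'   `"NaNa->NaK"` (one ion of a double-occupancy pair). States are strings
#'   over \{Na, K\}; exactly one ion changes per leg.
#' @param dG,stderr Free-energy change and its standard error, kcal/mol.
#' @param site `"site"` (the carboxylate or carbonyl binding site) or
#'   `"bulk"` (aqueous reference).
#' @param structure Optional structure tag, e.g. `"open-state"`.
#' @return An object of class `fep_leg` with parsed `from`/`to` states.
#' @export
fep_leg <- function(label, dG, stderr = 0, site = "site", structure = NA_character_) {
  states <- parse_leg_label(label)
  check_scalar(dG, "dG")
  check_scalar(stderr, "stderr", nonneg = TRUE)
  obj <- list(label = label, from = states$from, to = states$to,
              direction = states$direction, dG = dG, stderr = stderr,
              site = site, structure = structure)
  class(obj) <- "fep_leg"
  obj
}

#' @export
print.fep_leg <- function(x, ...) {
  cat(sprintf("<fep_leg> %s [%s%s]: dG = %g +/- %g kcal/mol\n", x$label, x$site,
              if (is.na(x$structure)) "" else paste0(", ", x$structure),
              x$dG, x$stderr))
  invisible(x)
}

# Split "NaK->KK" into from/to states and the single-ion direction of the
# mutation (Na->K or K->Na). Exactly one ion may change.
parse_leg_label <- function(label) {
  parts <- strsplit(label, "->", fixed = TRUE)[[1]]
  if (length(parts) != 2L) stop(sprintf("malformed leg label '%s'", label))
  split_state <- function(s) regmatches(s, gregexpr("Na|K", s))[[1]]
  from <- split_state(parts[1]); to <- split_state(parts[2])
  if (length(from) != length(to) || length(from) < 1L) {
    stop(sprintf("leg '%s' does not conserve ion count", label))
  }
  changed <- which(from != to)
  if (length(changed) != 1L) {
    stop(sprintf("leg '%s' must change exactly one ion", label))
  }
  list(from = parts[1], to = parts[2],
       direction = paste0(from[changed], "->", to[changed]))
}

#' Enumerate the thermodynamic-cycle legs for a site
#'
#' For each structure: two single-occupancy legs (Na->K, K->Na) and/or eight
#' double-occupancy legs — four transforming the first ion of the pair
#' (NaNa->NaK, NaNa->KNa, KK->KNa, KK->NaK) and four transforming the second
#' once the first has reached its end state (NaK->KK, KNa->KK, KNa->NaNa,
#' NaK->NaNa). Single + double over two structures gives the full set of 20
#' site calculations. Order is deterministic.
#'
#' @param occupancies Character subset of `c("single", "double")`.
#' @param structures Character vector of structure tags.
#' @return A data.frame with columns `structure`, `occupancy`, `label`,
#'   `direction` (of the mutated ion).
#' @examples
#' nrow(enumerate_cycle_legs(c("single", "double"),
#'                           c("open-state", "closed-state")))   # 20
#' @export
enumerate_cycle_legs <- function(occupancies = c("single", "double"),
                                 structures = "open-state") {
  bad <- setdiff(occupancies, c("single", "double"))
  if (length(bad)) stop(sprintf("unknown occupancy keyword: %s", bad[1]))
  single <- c("Na->K", "K->Na")
  dbl <- c("NaNa->NaK", "NaNa->KNa", "KK->KNa", "KK->NaK",
           "NaK->KK", "KNa->KK", "KNa->NaNa", "NaK->NaNa")
  rows <- list()
  for (st in structures) {
    if ("single" %in% occupancies) {
      rows[[length(rows) + 1L]] <- data.frame(structure = st, occupancy = "single",
                                              label = single)
    }
    if ("double" %in% occupancies) {
      rows[[length(rows) + 1L]] <- data.frame(structure = st, occupancy = "double",
                                              label = dbl)
    }
  }
  out <- do.call(rbind, rows)
  out$direction <- vapply(out$label, function(l) parse_leg_label(l)$direction, "")
  rownames(out) <- NULL
  out
}

#' Relative binding free energy from site and bulk legs
#'
#' Composes \deqn{\Delta\Delta G = \Delta G_{site} - m\,\Delta G_{bulk}} where
#' the site contribution is a single leg, or for double occupancy the path sum
#' of the two sequential legs, and `m` (default: the number of site legs) is
#' the number of single-ion mutations the bulk reference must account for.
#' Standard errors combine in quadrature, treating legs as independent.
#'
#' @param site_legs One [fep_leg()] or a list of sequential legs forming a
#'   path (end state of each must match the start of the next).
#' @param bulk_leg The bulk-reference [fep_leg()] (site `"bulk"`), sharing the
#'   single-ion transformation direction with every site leg.
#' @param bulk_scale Multiplier on the bulk leg; defaults to the number of
#'   site legs.
#' @return A list with `ddG`, `stderr`, `site_total`, `site_stderr`,
#'   `bulk_scale`, of class `ddG_result`.
#' @examples
#' s <- fep_leg("Na->K", 2.0, 0.3)
#' b <- fep_leg("Na->K", 0.5, 0.2, site = "bulk")
#' compose_ddG(s, b)   # 1.5 +/- 0.36
#' @export
compose_ddG <- function(site_legs, bulk_leg, bulk_scale = NULL) {
  if (inherits(site_legs, "fep_leg")) site_legs <- list(site_legs)
  stopifnot(length(site_legs) >= 1L, inherits(bulk_leg, "fep_leg"))
  if (!identical(bulk_leg$site, "bulk")) {
    stop("bulk reference leg missing (bulk_leg$site must be 'bulk')")
  }
  dirs <- vapply(site_legs, `[[`, "", "direction")
  if (any(dirs != bulk_leg$direction)) {
    stop(sprintf("mixed transformation directions: site %s vs bulk %s",
                 paste(unique(dirs), collapse = ","), bulk_leg$direction))
  }
  if (length(site_legs) > 1L) {
    for (i in seq_len(length(site_legs) - 1L)) {
      if (!identical(site_legs[[i]]$to, site_legs[[i + 1L]]$from)) {
        stop(sprintf("site legs do not chain: %s then %s",
                     site_legs[[i]]$label, site_legs[[i + 1L]]$label))
      }
    }
  }
  m <- bulk_scale %||% length(site_legs)
  site_total <- sum(vapply(site_legs, `[[`, 0, "dG"))
  site_var <- sum(vapply(site_legs, `[[`, 0, "stderr")^2)
  obj <- list(ddG = site_total - m * bulk_leg$dG,
              stderr = sqrt(site_var + (m * bulk_leg$stderr)^2),
              site_total = site_total, site_stderr = sqrt(site_var),
              bulk_scale = m)
  class(obj) <- "ddG_result"
  obj
}

#' @export
print.ddG_result <- function(x, ...) {
  cat(sprintf("<ddG_result> ddG = %.3f +/- %.3f kcal/mol (site path %.3f, bulk x%g)\n",
              x$ddG, x$stderr, x$site_total, x$bulk_scale))
  invisible(x)
}

#' Thermodynamic-cycle closure check
#'
#' Verifies that the legs chain head-to-tail into a closed loop in state
#' space, then reports the signed sum of their free-energy changes around the
#' loop. The loop passes when |residual| <= 2 x the quadrature-propagated
#' standard error.
#'
#' @param legs List of [fep_leg()]s in loop order (each leg traversed in its
#'   own direction; include reversed legs with negated dG if needed).
#' @return List of class `cycle_check`: `residual`, `stderr`, `pass`.
#' @export
cycle_closure_check <- function(legs) {
  stopifnot(length(legs) >= 2L, all(vapply(legs, inherits, TRUE, "fep_leg")))
  n <- length(legs)
  for (i in seq_len(n)) {
    nxt <- legs[[if (i == n) 1L else i + 1L]]
    if (!identical(legs[[i]]$to, nxt$from)) {
      stop(sprintf("open loop: transition %s -> %s is broken after leg '%s'",
                   legs[[i]]$to, nxt$from, legs[[i]]$label))
    }
  }
  residual <- sum(vapply(legs, `[[`, 0, "dG"))
  se <- sqrt(sum(vapply(legs, `[[`, 0, "stderr")^2))
  obj <- list(residual = residual, stderr = se,
              pass = abs(residual) <= 2 * se + 1e-12)
  class(obj) <- "cycle_check"
  obj
}

#' @export
print.cycle_check <- function(x, ...) {
  cat(sprintf("<cycle_check> residual = %.4f +/- %.4f kcal/mol: %s\n",
              x$residual, x$stderr, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
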