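#' Generate Crooks-consistent alchemical work samples
#'
#' Draws forward and backward work samples from Gaussian distributions
#' constructed to satisfy the Crooks fluctuation relation
#' \deqn{P_F(W) / P_R(-W) = e^{\beta (W - \Delta G)}}
#' exactly for a prescribed free-energy difference: forward work is
#' N(dG_true + sigma^2/(2 kBT), sigma^2) and backward work (reported in the
#' direction of its own transformation) is N(-dG_true + sigma^2/(2 kBT),
#' sigma^2). This is the standard Gaussian work model in which the
#' dissipated work is sigma^2/(2 kBT) in each direction, and it gives BAR a
#' known ground truth.
#'
#' @param dG_true Ground-truth free-energy difference, kcal/mol.
#' @param sigma Work standard deviation, kcal/mol (>= 0; 0 gives degenerate
#'   distributions at exactly +/- dG_true).
#' @param n Samples per direction (>= 2).
#' @param thermo A [thermo_state()].
#' @param seed Integer seed (same seed, same samples).
#' @return An object of class `work_set_pair`: list with numeric vectors
#'   `forward` and `backward` (kcal/mol), plus `dG_true`, `sigma`,
#'   `temperature`.
#' @examples
#' th <- thermo_state(303)
#' ws <- generate_fep_work_samples(2, 1, 1e4, th, seed = 1)
#' mean(ws$forward) - 1^2 / (2 * th$kBT)   # ~ 2
#' @export
generate_fep_work_samples <- function(dG_true, sigma, n, thermo = thermo_state(),
                                      seed = NULL) {
  check_scalar(dG_true, "dG_true")
  check_scalar(sigma, "sigma", nonneg = TRUE)
  check_scalar(n, "n")
  if (n < 2) stop("n must be >= 2 (estimator undefined for fewer samples)")
  stopifnot(inherits(thermo, "thermo_state"))
  shift <- sigma^2 / (2 * thermo$kBT)
  samples <- with_seed(seed, {
    list(forward = rnorm(n, mean = dG_true + shift, sd = sigma),
         backward = rnorm(n, mean = -dG_true + shift, sd = sigma))
  })
  obj <- c(samples, list(dG_true = dG_true, sigma = sigma,
                         temperature = thermo$temperature))
  class(obj) <- "work_set_pair"
  obj
}

#' @export
print.work_set_pair <- function(x, ...) {
  cat(sprintf("<work_set_pair> n = %d/%d, mean fwd = %.3f, mean bwd = %.3f kcal/mol\n",
              length(x$forward), length(x$backward),
              mean(x$forward), mean(x$backward)))
  invisible(x)
}

#' Write / read alchemical work tables
#'
#' Plain-text table with columns `direction` (`fwd`/`bwd`) and
#' `work_kcal_mol`.
#'
#' @param work A `work_set_pair` (or list with `forward`/`backward`).
#' @param path File path.
#' @return `read_work_table()` returns a list with `forward` and `backward`.
#' @export
write_work_table <- function(work, path) {
  df <- rbind(
    data.frame(direction = "fwd", work_kcal_mol = work$forward),
    data.frame(direction = "bwd", work_kcal_mol = work$backward)
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_work_table
#' @export
read_work_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t")
  list(forward = df$work_kcal_mol[df$direction == "fwd"],
       backward = df$work_kcal_mol[df$direction == "bwd"])
}
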