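# Config-driven orchestration: synth -> pmf / fep / struct -> ephys, with a
# machine-readable manifest and full parameter echo. Validation failures are
# signalled as classed conditions ("ionselect_config_error") so a command-line
# wrapper can map them to a distinct exit code.

config_error <- function(msg, key = NULL) {
  if (!is.null(key)) msg <- sprintf("%s (at key '%s')", msg, key)
  stop(structure(class = c("ionselect_config_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

default_config <- function() {
  list(
    stages = c("synth", "pmf", "fep", "struct", "ephys"),
    seed = 1L,
    out_dir = NULL,
    synth = list(
      surface = list(form = "double_well", a = 0.25, b = 3,
                     domain = c(-4.5, 4.5)),
      temperature = 2013,
      diffusion_coefficient = 50,
      timestep = 6e-4,
      n_steps_per_window = 30000
    ),
    pmf = list(z_min = -4, z_max = 4, spacing = 1, k = 2.5,
               bin_width = 0.2, tol = 1e-7, max_iter = 1e5, n_blocks = 4),
    fep = list(dG_true = 2, sigma = 1, n = 10000, temperature = 303,
               bulk_dG_true = 0.5),
    struct = list(n_frames = 240,
                  state_weights = c("0" = 0.1, "1-1carb" = 0.25,
                                    "1-2carb" = 0.15, "2-tight" = 0.25,
                                    "2-loose" = 0.15, "2-disperse" = 0.1),
                  jitter = 0),
    ephys = list(vrev = c(Na = 30, K = -24.4, Li = 25, Cs = -35),
                 slope = 0.1, noise_sd = 0.005,
                 ph50 = 6.7, hill_slope = 1, dose_noise_sd = 0.02,
                 dose_points = 9, temperature = 274)
  )
}

# Recursively merge user config over defaults, rejecting unknown keys.
merge_config <- function(user, defaults, path = "") {
  if (!is.list(user)) return(user)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    config_error("unknown configuration key",
                 key = paste0(path, unknown[1]))
  }
  for (k in names(user)) {
    defaults[[k]] <- if (is.list(defaults[[k]]) && is.list(user[[k]]) &&
                           !is.null(names(defaults[[k]]))) {
      merge_config(user[[k]], defaults[[k]], paste0(path, k, "."))
    } else user[[k]]
  }
  defaults
}

#' Run the synthetic-to-report analysis pipeline
#'
#' Executes the requested stages in dependency order: `synth` (generate all
#' inputs with known ground truth), `pmf` (umbrella sampling + WHAM + block
#' errors), `fep` (work generation, BAR, thermodynamic-cycle composition),
#' `struct` (occupancy classification), `ephys` (ramps, reversal potentials,
#' GHK ratios, Hill fit). Every defaulted parameter is echoed into the run
#' log; outputs are plain-text tables plus a JSON manifest with seeds,
#' parameters and md5 checksums. Identical config + seed gives byte-identical
#' numeric tables.
#'
#' @param config Path to a JSON config file, or a nested list. Unknown keys
#'   are rejected with their key path. See `default_config` in the package
#'   source for the schema; all parameters are optional.
#' @param seed Overrides the config seed.
#' @param out_dir Output directory (created if needed); overrides the config.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config = list(), seed = NULL, out_dir = tempfile("ionselect_run_"),
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error(sprintf("config file '%s' not found", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) config_error("config must be a list or a JSON file path")
  cfg <- merge_config(config, default_config())
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(cfg$out_dir) && missing(out_dir)) out_dir <- cfg$out_dir
  cfg$out_dir <- out_dir
  stages <- cfg$stages
  bad <- setdiff(stages, c("synth", "pmf", "fep", "struct", "ephys"))
  if (length(bad)) config_error("unknown stage", key = paste0("stages.", bad[1]))
  for (st in setdiff(stages, "synth")) {
    if (!"synth" %in% stages) {
      config_error(sprintf("stage '%s' requires upstream stage 'synth' (no window data without it)", st))
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(out_dir, "run_log.txt")
  logcon <- file(logfile, open = "wt")
  on.exit(close(logcon), add = TRUE)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    writeLines(msg, logcon)
    if (!quiet) message(msg)
  }
  say("ionselect pipeline, seed = %d", cfg$seed)
  say("parameter echo (defaults filled): %s",
      jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")], auto_unbox = TRUE, digits = NA))
  results <- list()
  t_all <- proc.time()[3]

  if ("pmf" %in% stages) {
    t0 <- proc.time()[3]
    sp <- cfg$synth; pp <- cfg$pmf
    surface <- do.call(model_surface, sp$surface)
    sched <- make_window_schedule(pp$z_min, pp$z_max, pp$spacing, pp$k)
    th <- thermo_state(sp$temperature)
    series <- lapply(seq_along(sched), function(i) {
      simulate_langevin(surface,
                        simulation_params(sp$diffusion_coefficient, sp$timestep,
                                          sp$n_steps_per_window, sp$temperature,
                                          seed = derive_seed(cfg$seed, i)),
                        bias = sched[[i]])
    })
    data <- biased_samples(series, sched)
    prof <- wham_solve(data, th, bin_width = pp$bin_width, tol = pp$tol,
                       max_iter = pp$max_iter)
    blocks <- block_error(data, function(d) wham_solve(d, th, bin_width = pp$bin_width,
                                                       tol = pp$tol, max_iter = pp$max_iter,
                                                       breaks = NULL),
                          n_blocks = pp$n_blocks)
    write_window_schedule(sched, file.path(out_dir, "windows.tsv"))
    write_profile(prof, file.path(out_dir, "profile.tsv"))
    write.table(format(blocks, digits = 10), file.path(out_dir, "profile_blocks.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    results$pmf <- list(profile = prof, blocks = blocks, schedule = sched)
    say("pmf: %d windows, WHAM %d iterations (residual %.2e), %.1fs",
        length(sched), prof$meta$iterations, prof$meta$residual,
        proc.time()[3] - t0)
  }

  if ("fep" %in% stages) {
    t0 <- proc.time()[3]
    fp <- cfg$fep
    th <- thermo_state(fp$temperature)
    site_ws <- generate_fep_work_samples(fp$dG_true, fp$sigma, fp$n, th,
                                         seed = derive_seed(cfg$seed, 101))
    bulk_ws <- generate_fep_work_samples(fp$bulk_dG_true, fp$sigma, fp$n, th,
                                         seed = derive_seed(cfg$seed, 102))
    rev_ws <- generate_fep_work_samples(-fp$dG_true, fp$sigma, fp$n, th,
                                        seed = derive_seed(cfg$seed, 103))
    site_bar <- bar_estimate(site_ws, thermo = th)
    bulk_bar <- bar_estimate(bulk_ws, thermo = th)
    rev_bar <- bar_estimate(rev_ws, thermo = th)
    ddg <- compose_ddG(fep_leg("Na->K", site_bar$dG, site_bar$stderr),
                       fep_leg("Na->K", bulk_bar$dG, bulk_bar$stderr, site = "bulk"))
    legs <- enumerate_cycle_legs(c("single", "double"),
                                 c("open-state", "closed-state"))
    # independent forward and reverse estimates of the same site leg close a loop
    cyc <- cycle_closure_check(list(
      fep_leg("Na->K", site_bar$dG, site_bar$stderr),
      fep_leg("K->Na", rev_bar$dG, rev_bar$stderr)))
    report <- list(
      lambda_schedule = unclass(lambda_schedule()),
      site = unclass(site_bar), bulk = unclass(bulk_bar),
      ddG = unclass(ddg), legs = legs,
      closure = unclass(cyc),
      ground_truth = list(site_dG = fp$dG_true, bulk_dG = fp$bulk_dG_true))
    jsonlite::write_json(report, file.path(out_dir, "fep_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$fep <- report
    say("fep: site dG = %.3f +/- %.3f (truth %.2f), ddG = %.3f, %d legs enumerated, %.1fs",
        site_bar$dG, site_bar$stderr, fp$dG_true, ddg$ddG, nrow(legs),
        proc.time()[3] - t0)
  }

  if ("struct" %in% stages) {
    t0 <- proc.time()[3]
    sp <- cfg$struct
    w <- sp$state_weights
    script <- with_seed(derive_seed(cfg$seed, 201),
                        sample(names(w), sp$n_frames, replace = TRUE,
                               prob = as.numeric(w)))
    cfgset <- build_site_configurations(site_definition(), script,
                                        jitter = sp$jitter,
                                        seed = derive_seed(cfg$seed, 202))
    occ <- classify_site_occupancy(cfgset)
    write.csv(occ$records, file.path(out_dir, "occupancy.csv"), row.names = FALSE)
    write.csv(data.frame(state = names(occ$distribution),
                         frequency = as.numeric(occ$distribution),
                         prescribed = as.numeric(table(factor(script, levels = names(occ$distribution)))) /
                           length(script)),
              file.path(out_dir, "occupancy_distribution.csv"), row.names = FALSE)
    results$struct <- list(occupancy = occ, script = script)
    say("struct: %d frames classified; states: %s; %.1fs", sp$n_frames,
        paste(names(occ$distribution), collapse = " "), proc.time()[3] - t0)
  }

  if ("ephys" %in% stages) {
    t0 <- proc.time()[3]
    ep <- cfg$ephys
    th <- thermo_state(ep$temperature)
    ramps <- synthesize_ramp_recording(unlist(ep$vrev), slope = ep$slope,
                                       noise_sd = ep$noise_sd, thermo = th,
                                       seed = derive_seed(cfg$seed, 301))
    vrev <- vapply(ramps, function(r) {
      find_reversal_potential(subtract_leak(r$active, r$rest))
    }, 0)
    others <- setdiff(names(vrev), "Na")
    ghk <- data.frame(
      ion = others,
      vrev_mV = vrev[others],
      vrev_Na_mV = vrev[["Na"]],
      p_na_over_p_x = vapply(others, function(x) {
        permeability_ratio(vrev[["Na"]], vrev[[x]], th)$p_na_over_p_x
      }, 0))
    write.csv(ghk, file.path(out_dir, "ghk.csv"), row.names = FALSE)
    dr <- synthesize_dose_response(ep$ph50, ep$hill_slope,
                                   n_points = ep$dose_points,
                                   noise_sd = ep$dose_noise_sd,
                                   seed = derive_seed(cfg$seed, 302))
    hf <- fit_hill(dr$ph, dr$response)
    jsonlite::write_json(list(converged = hf$converged,
                              parameters = as.list(hf$parameters),
                              truth = as.list(attr(dr, "truth"))),
                         file.path(out_dir, "hill.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    results$ephys <- list(vrev = vrev, ghk = ghk, hill = hf)
    say("ephys: vrev recovered %s mV; P_Na/P_K = %.2f; pH50 fit = %.3f; %.1fs",
        paste(sprintf("%s=%.2f", names(vrev), vrev), collapse = " "),
        if ("K" %in% others) ghk$p_na_over_p_x[ghk$ion == "K"] else NA,
        if (hf$converged) hf$parameters[["ph50"]] else NA,
        proc.time()[3] - t0)
  }

  # summary + manifest
  outfiles <- setdiff(list.files(out_dir), c("manifest.json", "run_log.txt", "summary.txt"))
  sums <- tools::md5sum(file.path(out_dir, outfiles))
  manifest <- list(
    package = "ionselect",
    version = as.character(utils::packageVersion("ionselect")),
    seed = cfg$seed,
    stages = stages,
    parameters = cfg[setdiff(names(cfg), c("out_dir", "stages", "seed"))],
    checksums = as.list(setNames(unname(sums), outfiles)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    sprintf("ionselect pipeline summary (seed %d)", cfg$seed),
    if (!is.null(results$pmf)) sprintf("PMF: %d-window WHAM profile, converged = %s",
                                       length(results$pmf$schedule),
                                       results$pmf$profile$meta$converged),
    if (!is.null(results$fep)) sprintf("FEP: ddG = %.3f +/- %.3f kcal/mol",
                                       results$fep$ddG$ddG, results$fep$ddG$stderr),
    if (!is.null(results$struct)) sprintf("Occupancy states observed: %s",
                                          paste(names(results$struct$occupancy$distribution),
                                                collapse = ", ")),
    if (!is.null(results$ephys)) sprintf("GHK: P_Na/P_K = %.3f",
                                         results$ephys$ghk$p_na_over_p_x[results$ephys$ghk$ion == "K"]))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  say("done in %.1fs; outputs in %s", proc.time()[3] - t_all, out_dir)
  invisible(list(results = results, manifest = manifest, config = cfg,
                 out_dir = out_dir))
}
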