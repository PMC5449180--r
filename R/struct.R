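#' Coordination analysis settings
#'
#' First-shell cutoffs are taken from the first minima of the ion-oxygen
#' radial distribution functions: 3.2 A for Na+ and 3.6 A for K+. Bulk
#' coordination numbers (used to offset pore profiles for display) are 5.8
#' (Na+) and 7.0 (K+).
#'
#' @param cutoff_Na,cutoff_K First-shell cutoffs, Angstrom.
#' @param bulk_reference_Na,bulk_reference_K Bulk coordination numbers.
#' @return Object of class `coordination_spec`.
#' @export
coordination_spec <- function(cutoff_Na = 3.2, cutoff_K = 3.6,
                              bulk_reference_Na = 5.8, bulk_reference_K = 7.0) {
  check_scalar(cutoff_Na, "cutoff_Na", positive = TRUE)
  check_scalar(cutoff_K, "cutoff_K", positive = TRUE)
  obj <- list(cutoff = c(Na = cutoff_Na, K = cutoff_K),
              bulk_reference = c(Na = bulk_reference_Na, K = bulk_reference_K))
  class(obj) <- "coordination_spec"
  obj
}

#' Binding-site definition for occupancy analysis
#'
#' The site is a sphere around a named centre-of-mass anchor (the carboxyl
#' groups of the acidic residues); its default 2.75 A radius matches the
#' flat-bottom constraint used to maintain occupancy in the alchemical
#' calculations. Double-occupancy classes are separated by ion-ion distance
#' thresholds (defaults 3.5 / 4.5 A, configurable; they are not printed
#' protocol values and should be set from the ion-ion g(r) of the data at
#' hand when available) together with shared-carboxylate contacts.
#'
#' @param center_anchor Name of the anchor holding the site center.
#' @param occupancy_radius Site radius, Angstrom.
#' @param tight_threshold,loose_threshold Ion-ion distance thresholds
#'   (tight < loose; both must be < 2 x occupancy_radius to be reachable).
#' @param contact_cutoff Named vector of per-species carboxylate-contact
#'   cutoffs (defaults to the first-shell cutoffs).
#' @return Object of class `site_definition`.
#' @export
site_definition <- function(center_anchor = "site_com", occupancy_radius = 2.75,
                            tight_threshold = 3.5, loose_threshold = 4.5,
                            contact_cutoff = c(Na = 3.2, K = 3.6)) {
  check_scalar(occupancy_radius, "occupancy_radius", positive = TRUE)
  check_scalar(tight_threshold, "tight_threshold", positive = TRUE)
  check_scalar(loose_threshold, "loose_threshold", positive = TRUE)
  if (tight_threshold >= loose_threshold) {
    stop("tight_threshold must be < loose_threshold")
  }
  obj <- list(center_anchor = center_anchor, occupancy_radius = occupancy_radius,
              tight_threshold = tight_threshold, loose_threshold = loose_threshold,
              contact_cutoff = contact_cutoff)
  class(obj) <- "site_definition"
  obj
}

#' Build a coordinate frame of ions and oxygens
#'
#' Frames are plain data.frames with columns `kind` (`ion`/`oxygen`),
#' `species` (Na/K, ions only), `role` (water/backbone/sidechain, oxygens
#' only), `residue` (required for sidechain oxygens), `x`, `y`, `z`
#' (Angstrom).
#'
#' @param ions data.frame with columns `species`, `x`, `y`, `z`.
#' @param oxygens data.frame with columns `role`, `residue`, `x`, `y`, `z`.
#' @return A frame data.frame.
#' @export
make_frame <- function(ions = NULL, oxygens = NULL) {
  out <- list()
  if (!is.null(ions) && nrow(ions)) {
    if (!all(ions$species %in% c("Na", "K"))) stop("ion species must be Na or K")
    out$ions <- data.frame(kind = "ion", species = ions$species,
                           role = NA_character_, residue = NA_character_,
                           x = ions$x, y = ions$y, z = ions$z)
  }
  if (!is.null(oxygens) && nrow(oxygens)) {
    if (!all(oxygens$role %in% c("water", "backbone", "sidechain"))) {
      stop("oxygen role must be water, backbone or sidechain")
    }
    res <- oxygens$residue %||% NA_character_
    if (any(oxygens$role == "sidechain" & is.na(res))) {
      stop("sidechain oxygens require a residue identity")
    }
    out$oxy <- data.frame(kind = "oxygen", species = NA_character_,
                          role = oxygens$role, residue = res,
                          x = oxygens$x, y = oxygens$y, z = oxygens$z)
  }
  if (!length(out)) stop("empty frame")
  do.call(rbind, unname(out))
}

#' A set of coordinate frames with named anchors
#'
#' @param frames List of frame data.frames (see [make_frame()]).
#' @param anchors Named list of length-3 reference points (e.g. `site_com`,
#'   `axis_origin`).
#' @return Object of class `configuration_set`.
#' @export
configuration_set <- function(frames, anchors = list(site_com = c(0, 0, 0),
                                                     axis_origin = c(0, 0, 0))) {
  stopifnot(is.list(frames), length(frames) >= 1L)
  obj <- list(frames = frames, anchors = anchors)
  class(obj) <- "configuration_set"
  obj
}

#' @export
print.configuration_set <- function(x, ...) {
  cat(sprintf("<configuration_set> %d frames, anchors: %s\n",
              length(x$frames), paste(names(x$anchors), collapse = ", ")))
  invisible(x)
}

select_atoms <- function(frame, kind = NULL, species = NULL, role = NULL) {
  sel <- rep(TRUE, nrow(frame))
  if (!is.null(kind)) sel <- sel & frame$kind %in% kind
  if (!is.null(species)) sel <- sel & !is.na(frame$species) & frame$species %in% species
  if (!is.null(role)) sel <- sel & !is.na(frame$role) & frame$role %in% role
  frame[sel, , drop = FALSE]
}

pair_distances <- function(a, b, same, box = NULL) {
  am <- as.matrix(a[, c("x", "y", "z")]); bm <- as.matrix(b[, c("x", "y", "z")])
  if (is.null(box)) {
    if (same) {
      if (nrow(am) < 2) return(numeric(0))
      return(as.vector(stats::dist(am)))
    }
    d2 <- outer(rowSums(am^2), rep(1, nrow(bm))) +
      outer(rep(1, nrow(am)), rowSums(bm^2)) - 2 * am %*% t(bm)
    return(sqrt(pmax(as.vector(d2), 0)))
  }
  # minimum-image convention in a periodic orthorhombic box
  d2 <- matrix(0, nrow(am), nrow(bm))
  for (k in 1:3) {
    dk <- outer(am[, k], bm[, k], "-")
    dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk^2
  }
  if (same) d2 <- d2[upper.tri(d2)]
  sqrt(as.vector(d2))
}

#' Radial distribution function over a frame set
#'
#' g(r) between two atom selections, normalised against the uniform-density
#' expectation: bin counts divided by `n_frames * n_pairs * v_shell / volume`.
#' When the two selections are identical (e.g. ion-ion), unordered pairs are
#' counted once.
#'
#' @param config A [configuration_set()].
#' @param sel1,sel2 Selections: named lists with any of `kind`, `species`,
#'   `role` (passed to the internal selector).
#' @param breaks Radial bin edges, Angstrom.
#' @param volume Reference volume of the analysis region, A^3; defaults to
#'   the bounding box of all atoms in the first frame (or `prod(box)`).
#' @param box Optional length-3 periodic box (A); distances then use the
#'   minimum-image convention, which removes boundary bias for homogeneous
#'   systems.
#' @return Object of class `rdf_table`: data.frame `r`, `g`, `count`.
#' @export
compute_rdf <- function(config, sel1, sel2 = sel1,
                        breaks = seq(0, 10, by = 0.1), volume = NULL,
                        box = NULL) {
  stopifnot(inherits(config, "configuration_set"))
  same <- identical(sel1, sel2)
  counts <- rep(0, length(breaks) - 1L)
  npair_tot <- 0
  seen <- FALSE
  if (!is.null(box) && is.null(volume)) volume <- prod(box)
  for (fr in config$frames) {
    a <- do.call(select_atoms, c(list(fr), sel1))
    b <- if (same) a else do.call(select_atoms, c(list(fr), sel2))
    if (nrow(a) == 0 || nrow(b) == 0) next
    if (same && nrow(a) < 2) next
    seen <- TRUE
    d <- pair_distances(a, b, same, box = box)
    counts <- counts + graphics::hist(d[d >= min(breaks) & d < max(breaks)],
                                      breaks = breaks, plot = FALSE)$counts
    npair_tot <- npair_tot + if (same) nrow(a) * (nrow(a) - 1) / 2 else nrow(a) * nrow(b)
  }
  if (!seen) stop("empty pair selection: no frame contains both selections")
  if (is.null(volume)) {
    f1 <- config$frames[[1L]]
    volume <- prod(apply(f1[, c("x", "y", "z")], 2L, function(v) diff(range(v))))
  }
  r_lo <- head(breaks, -1); r_hi <- tail(breaks, -1)
  vshell <- 4 / 3 * pi * (r_hi^3 - r_lo^3)
  expected <- npair_tot * vshell / volume
  g <- ifelse(expected > 0, counts / expected, NA_real_)
  out <- data.frame(r = (r_lo + r_hi) / 2, g = g, count = counts)
  class(out) <- c("rdf_table", "data.frame")
  out
}

#' First-minimum cutoff from a radial distribution function
#'
#' Locates the first interior local minimum after the first peak of the
#' (optionally smoothed) g(r); this is the standard definition of a
#' first-shell cutoff.
#'
#' @param g An `rdf_table` or data.frame with columns `r` and `g`.
#' @param smoothing Odd moving-average window length in bins (0/1 = none).
#' @return The minimum location, Angstrom.
#' @export
first_minimum_cutoff <- function(g, smoothing = 0) {
  r <- g$r; y <- g$g
  ok <- is.finite(y)
  r <- r[ok]; y <- y[ok]
  if (length(y) < 3) stop("g(r) too short for minimum detection")
  if (smoothing > 1) {
    k <- as.integer(smoothing)
    if (k %% 2L == 0L) k <- k + 1L
    y <- stats::filter(y, rep(1 / k, k), sides = 2)
    keep <- !is.na(y)
    r <- r[keep]; y <- as.numeric(y[keep])
  }
  n <- length(y)
  # the first-shell peak is the dominant maximum of g(r); anchoring there is
  # robust to baseline noise before the contact distance
  peak <- which.max(y)
  if (peak >= n - 1) {
    stop("no interior minimum: g(r) is monotone up to its end (no peak before a minimum)")
  }
  for (i in (peak + 1):(n - 1)) {
    if (y[i] < y[i - 1] && y[i] <= y[i + 1]) return(r[i])
  }
  stop("no interior minimum found after the first peak of g(r)")
}

#' Axial first-shell coordination profile
#'
#' For each axial bin, the mean number of oxygens within the species'
#' first-shell cutoff of an ion located in that bin, decomposed by donor role
#' (water / backbone / sidechain). The axial coordinate is the signed z
#' distance from the `axis_origin` anchor. With `offset = TRUE` the total is
#' reported relative to the species' bulk coordination number.
#'
#' @param config A [configuration_set()].
#' @param spec A [coordination_spec()].
#' @param axial_breaks Bin edges for the axial coordinate, Angstrom.
#' @param species Ion species to profile (`"Na"` or `"K"`).
#' @param offset Subtract the bulk reference from the total column?
#' @return data.frame `z`, `water`, `backbone`, `sidechain`, `total`,
#'   `n_obs`; ions falling outside the axial range are tallied in the
#'   `overflow` attribute and logged via a message.
#' @export
coordination_profile <- function(config, spec = coordination_spec(),
                                 axial_breaks, species = "Na", offset = TRUE) {
  stopifnot(inherits(config, "configuration_set"),
            inherits(spec, "coordination_spec"))
  cutoff <- spec$cutoff[[species]]
  origin_z <- (config$anchors$axis_origin %||% c(0, 0, 0))[3]
  nb <- length(axial_breaks) - 1L
  acc <- matrix(0, nrow = nb, ncol = 3,
                dimnames = list(NULL, c("water", "backbone", "sidechain")))
  nobs <- rep(0L, nb)
  overflow <- 0L
  for (fr in config$frames) {
    ions <- select_atoms(fr, kind = "ion", species = species)
    oxy <- select_atoms(fr, kind = "oxygen")
    if (!nrow(ions)) next
    for (i in seq_len(nrow(ions))) {
      zax <- ions$z[i] - origin_z
      bin <- findInterval(zax, axial_breaks, rightmost.closed = TRUE)
      if (bin < 1 || bin > nb) { overflow <- overflow + 1L; next }
      if (nrow(oxy)) {
        d <- sqrt((oxy$x - ions$x[i])^2 + (oxy$y - ions$y[i])^2 +
                    (oxy$z - ions$z[i])^2)
        inshell <- d <= cutoff
        for (rl in c("water", "backbone", "sidechain")) {
          acc[bin, rl] <- acc[bin, rl] + sum(inshell & oxy$role == rl)
        }
      }
      nobs[bin] <- nobs[bin] + 1L
    }
  }
  if (overflow > 0) message(sprintf("coordination_profile: %d ion(s) outside the axial range (overflow bin)", overflow))
  mean_counts <- sweep(acc, 1L, pmax(nobs, 1L), "/")
  mean_counts[nobs == 0L, ] <- NA_real_
  total <- rowSums(mean_counts)
  if (offset) total <- total - spec$bulk_reference[[species]]
  out <- data.frame(z = (head(axial_breaks, -1) + tail(axial_breaks, -1)) / 2,
                    water = mean_counts[, "water"],
                    backbone = mean_counts[, "backbone"],
                    sidechain = mean_counts[, "sidechain"],
                    total = total, n_obs = nobs)
  attr(out, "overflow") <- overflow
  attr(out, "offset") <- offset
  out
}

# Distinct acidic residues with a sidechain oxygen within the species contact
# cutoff of position p.
residue_contacts <- function(frame, p, species, contact_cutoff) {
  oxy <- select_atoms(frame, kind = "oxygen", role = "sidechain")
  if (!nrow(oxy)) return(character(0))
  d <- sqrt((oxy$x - p[1])^2 + (oxy$y - p[2])^2 + (oxy$z - p[3])^2)
  unique(oxy$residue[d <= contact_cutoff[[species]]])
}

#' Classify per-frame site occupancy
#'
#' Counts ions inside the site sphere. Single occupancy is annotated with the
#' number of distinct carboxylates contacted (1 vs 2). Double occupancy is
#' classified from the ion-ion distance and shared-carboxylate contacts:
#' `2-tight` (distance below the tight threshold and at least one carboxylate
#' contacting both ions), `2-loose` (below the loose threshold), `2-disperse`
#' (the remainder — ions bound to distant groups). Frames with three or more
#' ions in the site are tallied as `2+` and logged.
#'
#' @param config A [configuration_set()].
#' @param site A [site_definition()].
#' @return Object of class `occupancy_result`: `records` (per-frame
#'   data.frame with `frame`, `n_ions`, `carboxylate_count`, `pair_class`,
#'   `state`) and `distribution` (named relative frequencies summing to 1).
#' @export
classify_site_occupancy <- function(config, site = site_definition()) {
  stopifnot(inherits(config, "configuration_set"),
            inherits(site, "site_definition"))
  center <- config$anchors[[site$center_anchor]]
  if (is.null(center)) stop(sprintf("anchor '%s' not found in configuration set", site$center_anchor))
  recs <- lapply(seq_along(config$frames), function(fi) {
    fr <- config$frames[[fi]]
    ions <- select_atoms(fr, kind = "ion")
    din <- if (nrow(ions)) sqrt((ions$x - center[1])^2 + (ions$y - center[2])^2 +
                                  (ions$z - center[3])^2) else numeric(0)
    inside <- ions[din <= site$occupancy_radius, , drop = FALSE]
    n <- nrow(inside)
    carb <- NA_integer_; pair <- "n/a"; state <- NA_character_
    if (n == 0L) {
      state <- "0"
    } else if (n == 1L) {
      contacts <- residue_contacts(fr, c(inside$x, inside$y, inside$z),
                                   inside$species, site$contact_cutoff)
      carb <- min(length(contacts), 2L)
      state <- sprintf("1-%dcarb", carb)
    } else if (n == 2L) {
      d <- sqrt(sum((as.numeric(inside[1, c("x", "y", "z")]) -
                       as.numeric(inside[2, c("x", "y", "z")]))^2))
      c1 <- residue_contacts(fr, as.numeric(inside[1, c("x", "y", "z")]),
                             inside$species[1], site$contact_cutoff)
      c2 <- residue_contacts(fr, as.numeric(inside[2, c("x", "y", "z")]),
                             inside$species[2], site$contact_cutoff)
      shared <- length(intersect(c1, c2)) > 0
      pair <- if (d <= site$tight_threshold && shared) "tight"
              else if (d <= site$loose_threshold) "loose"
              else "disperse"
      carb <- min(length(union(c1, c2)), 2L)
      state <- paste0("2-", pair)
    } else {
      state <- "2+"
    }
    data.frame(frame = fi, n_ions = min(n, 3L),
               carboxylate_count = carb, pair_class = pair, state = state)
  })
  records <- do.call(rbind, recs)
  nplus <- sum(records$state == "2+")
  if (nplus > 0) message(sprintf("classify_site_occupancy: %d frame(s) with >= 3 ions in site (tallied as '2+')", nplus))
  tab <- table(records$state)
  obj <- list(records = records, distribution = as.numeric(tab) / nrow(records))
  names(obj$distribution) <- names(tab)
  class(obj) <- "occupancy_result"
  obj
}

#' @export
print.occupancy_result <- function(x, ...) {
  cat(sprintf("<occupancy_result> %d frames\n", nrow(x$records)))
  print(round(x$distribution, 4))
  invisible(x)
}

#' Write / read frame sets as labeled XYZ tables
#'
#' TSV dialect: columns `frame`, `kind`, `species`, `role`, `residue`, `x`,
#' `y`, `z`; Angstrom units, one row per atom.
#'
#' @param config A [configuration_set()].
#' @param path File path.
#' @param anchors Anchor list used when reading.
#' @return `read_frames()` returns a [configuration_set()].
#' @export
write_frames <- function(config, path) {
  dfs <- Map(function(fr, i) cbind(frame = i, fr),
             config$frames, seq_along(config$frames))
  write.table(do.call(rbind, dfs), path, sep = "\t", row.names = FALSE,
              quote = FALSE, na = ".")
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path, anchors = list(site_com = c(0, 0, 0),
                                             axis_origin = c(0, 0, 0))) {
  df <- read.table(path, header = TRUE, sep = "\t", na.strings = ".",
                   colClasses = c(species = "character", role = "character",
                                  residue = "character"))
  configuration_set(split(df[, setdiff(names(df), "frame")], df$frame),
                    anchors = anchors)
}
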