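test_that("rdf concentrates in one bin for a fixed pair and rejects empty selections", {
  fr <- make_frame(ions = data.frame(species = c("Na", "Na"),
                                     x = c(0, 3.05), y = 0, z = 0))
  cfg <- configuration_set(rep(list(fr), 5))
  g <- compute_rdf(cfg, list(kind = "ion"), breaks = seq(0, 5, 0.1), volume = 1000)
  expect_identical(sum(g$count > 0), 1L)
  expect_equal(g$r[g$count > 0], 3.05)
  expect_error(compute_rdf(cfg, list(species = "K"), breaks = seq(0, 5, 0.1)),
               "empty pair selection")
})

test_that("rdf of an ideal gas is unity in a periodic box", {
  set.seed(61)
  L <- 20
  frames <- lapply(1:300, function(i) {
    make_frame(oxygens = data.frame(role = "water", residue = NA,
                                    x = runif(40, 0, L), y = runif(40, 0, L),
                                    z = runif(40, 0, L)))
  })
  g <- compute_rdf(configuration_set(frames), list(role = "water"),
                   breaks = seq(0, 8, 0.5), box = c(L, L, L))
  mid <- g$r >= 3 & g$r <= 8
  expect_lt(max(abs(g$g[mid] - 1)), 0.1)
  expect_lt(abs(mean(g$g[mid]) - 1), 0.02)
})

test_that("first-minimum detection finds the constructed minimum", {
  r <- seq(1, 6, by = 0.1)
  shape <- (1 + 2 * exp(-((r - 2.3) / 0.3)^2) - 0.8 * exp(-((r - 3.2) / 0.35)^2))
  g <- data.frame(r = r, g = shape * stats::plogis((r - 1.8) / 0.08))
  expect_equal(first_minimum_cutoff(g), 3.2, tolerance = 0.11)
  set.seed(62)
  gn <- g
  gn$g <- gn$g + rnorm(nrow(gn), 0, 0.002)
  m0 <- first_minimum_cutoff(gn)
  m5 <- first_minimum_cutoff(gn, smoothing = 5)
  expect_lt(abs(m0 - m5), 0.11)   # within one bin
  mono <- data.frame(r = r, g = r)
  expect_error(first_minimum_cutoff(mono), "minimum")
})

test_that("paper coordination defaults are carried by the spec object", {
  cs <- coordination_spec()
  expect_equal(unname(cs$cutoff["Na"]), 3.2)
  expect_equal(unname(cs$cutoff["K"]), 3.6)
  expect_equal(unname(cs$bulk_reference["Na"]), 5.8)
  expect_equal(unname(cs$bulk_reference["K"]), 7.0)
})

test_that("coordination counting matches a constructed frame and the bulk offset", {
  # Na+ with exactly 4 oxygens at 3.0 A and 2 at 3.4 A: count 4 at cutoff 3.2
  ang <- seq(0, 2 * pi, length.out = 5)[1:4]
  oxy <- data.frame(role = "water", residue = NA,
                    x = c(3.0 * cos(ang), 3.4, -3.4),
                    y = c(3.0 * sin(ang), 0, 0),
                    z = 0)
  fr <- make_frame(ions = data.frame(species = "Na", x = 0, y = 0, z = 0),
                   oxygens = oxy)
  cfg <- configuration_set(list(fr))
  prof <- coordination_profile(cfg, coordination_spec(),
                               axial_breaks = c(-1, 1), offset = FALSE)
  expect_equal(prof$total, 4)
  # offset mode: total equal to the bulk reference maps to zero
  oxy58 <- data.frame(role = "water", residue = NA,
                      x = 2.5 * cos(seq(0, 2 * pi, length.out = 7)[1:6]),
                      y = 2.5 * sin(seq(0, 2 * pi, length.out = 7)[1:6]), z = 0)
  fr2 <- make_frame(ions = data.frame(species = "Na", x = 0, y = 0, z = 0),
                    oxygens = oxy58)
  cfg2 <- configuration_set(list(fr2))
  sp <- coordination_spec(bulk_reference_Na = 6)
  prof2 <- coordination_profile(cfg2, sp, axial_breaks = c(-1, 1), offset = TRUE)
  expect_equal(prof2$total, 0)
})

test_that("coordination profile equals an exhaustive all-pairs count on random frames", {
  frames <- random_coord_frames(30, seed = 63)
  cfg <- configuration_set(frames)
  breaks <- seq(-12, 12, by = 4)
  for (species in c("Na", "K")) {
    spec <- coordination_spec()
    prof <- coordination_profile(cfg, spec, breaks, species = species,
                                 offset = FALSE)
    # independent brute force
    acc <- matrix(0, length(breaks) - 1, 3,
                  dimnames = list(NULL, c("water", "backbone", "sidechain")))
    nobs <- rep(0, length(breaks) - 1)
    for (fr in frames) {
      ions <- fr[fr$kind == "ion" & fr$species == species, ]
      oxy <- fr[fr$kind == "oxygen", ]
      if (!nrow(ions)) next
      for (i in seq_len(nrow(ions))) {
        b <- findInterval(ions$z[i], breaks, rightmost.closed = TRUE)
        if (b < 1 || b > length(nobs)) next
        d <- sqrt((oxy$x - ions$x[i])^2 + (oxy$y - ions$y[i])^2 +
                    (oxy$z - ions$z[i])^2)
        for (rl in colnames(acc)) {
          acc[b, rl] <- acc[b, rl] + sum(d <= spec$cutoff[[species]] & oxy$role == rl)
        }
        nobs[b] <- nobs[b] + 1
      }
    }
    expected <- sweep(acc, 1, pmax(nobs, 1), "/")
    expected[nobs == 0, ] <- NA_real_
    expect_equal(prof$water, expected[, "water"], tolerance = 1e-12)
    expect_equal(prof$backbone, expected[, "backbone"], tolerance = 1e-12)
    expect_equal(prof$sidechain, expected[, "sidechain"], tolerance = 1e-12)
    expect_identical(prof$n_obs, as.integer(nobs))
  }
})

test_that("rdf and coordination agree on a homogeneous system", {
  set.seed(64)
  L <- 16
  rho <- 80 / L^3
  frames <- lapply(1:200, function(i) {
    make_frame(ions = data.frame(species = "Na", x = L / 2, y = L / 2, z = L / 2),
               oxygens = data.frame(role = "water", residue = NA,
                                    x = runif(80, 0, L), y = runif(80, 0, L),
                                    z = runif(80, 0, L)))
  })
  cfg <- configuration_set(frames,
                           anchors = list(axis_origin = c(L / 2, L / 2, L / 2)))
  cutoff <- 3.2
  prof <- coordination_profile(cfg, coordination_spec(),
                               axial_breaks = c(-1, 1), offset = FALSE)
  mean_coord <- prof$total
  breaks <- seq(0, 4, by = 0.2)
  g <- compute_rdf(cfg, list(kind = "ion"), list(role = "water"),
                   breaks = breaks, box = c(L, L, L))
  shell <- 4 / 3 * pi * diff(breaks^3)
  integral <- sum((g$g * rho * shell)[g$r <= cutoff])
  expect_equal(integral, mean_coord, tolerance = 0.05)
})

test_that("coordination counts are invariant under rigid rotation and translation", {
  frames <- random_coord_frames(10, seed = 65)
  cfg <- configuration_set(frames)
  theta <- 0.7
  R <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
  shift <- c(5, -3, 2)
  moved <- lapply(frames, function(fr) {
    xyz <- as.matrix(fr[, c("x", "y", "z")]) %*% R
    fr$x <- xyz[, 1] + shift[1]; fr$y <- xyz[, 2] + shift[2]
    fr$z <- xyz[, 3] + shift[3]
    fr
  })
  cfg2 <- configuration_set(moved)
  wide <- c(-1e6, 1e6)   # one axial bin: rotation moves z but not distances
  p1 <- coordination_profile(cfg, axial_breaks = wide, offset = FALSE)
  p2 <- coordination_profile(cfg2, axial_breaks = wide, offset = FALSE)
  expect_equal(p1$total, p2$total, tolerance = 1e-12)
})

test_that("prescribed occupancy states are reclassified identically at zero jitter", {
  states <- c("0", "1-1carb", "1-2carb", "2-tight", "2-loose", "2-disperse")
  set.seed(66)
  script <- sample(states, 1000, replace = TRUE)
  cfg <- build_site_configurations(site_definition(), script)
  occ <- classify_site_occupancy(cfg)
  expect_identical(occ$records$state, script)
  # aggregate frequencies equal the prescription exactly
  expect_equal(occ$distribution[states],
               table(factor(script, levels = states))[states] / 1000,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("occupancy classification is a partition and handles edge cases", {
  cfg <- build_site_configurations(site_definition(),
                                   c("0", "2-tight", "1-2carb"), jitter = 0.02,
                                   seed = 8)
  occ <- classify_site_occupancy(cfg)
  expect_equal(sum(occ$distribution), 1)
  expect_false(any(is.na(occ$records$state)))
  # pair_class is n/a exactly when n_ions != 2
  expect_identical(occ$records$pair_class == "n/a", occ$records$n_ions != 2L)
  # excessive jitter is rejected up front
  expect_error(build_site_configurations(site_definition(), "2-disperse",
                                         jitter = 1), "jitter")
  expect_error(build_site_configurations(site_definition(), "7-weird"),
               "unknown occupancy state")
  # three ions in the site are tallied as 2+
  fr <- make_frame(ions = data.frame(species = "Na", x = c(0, 1, -1), y = 0, z = 0))
  expect_message(o3 <- classify_site_occupancy(configuration_set(list(fr))),
                 "2\\+")
  expect_identical(o3$records$state, "2+")
})

test_that("frame sets survive a round trip through the XYZ-table format", {
  cfg <- build_site_configurations(site_definition(),
                                   c("2-loose", "0", "1-1carb"), jitter = 0.01,
                                   seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_frames(cfg, path)
  back <- read_frames(path)
  expect_length(back$frames, 3)
  o1 <- classify_site_occupancy(cfg)
  o2 <- classify_site_occupancy(back)
  expect_identical(o1$records$state, o2$records$state)
})
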