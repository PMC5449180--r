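# Geometric templates for prescribed occupancy states. Each template places
# ions and carboxylate (sidechain) oxygens around the site center so that
# classify_site_occupancy() with the same site definition reproduces the
# prescribed state by construction; `margin` is the smallest geometric slack
# (A) separating the construction from any decision boundary.
occupancy_templates <- function(site) {
  r <- site$occupancy_radius       # 2.75 by default
  ox_pair <- function(res, cx, cy, cz) {
    data.frame(role = "sidechain", residue = res,
               x = cx, y = cy, z = c(cz + 0.8, cz - 0.8))
  }
  far_ring <- function(res, radius = 8) {
    do.call(rbind, Map(function(rr, th) {
      data.frame(role = "sidechain", residue = rr,
                 x = radius * cos(th), y = radius * sin(th), z = c(0.8, -0.8))
    }, res, seq(0, 2 * pi, length.out = length(res) + 1)[seq_along(res)]))
  }
  list(
    "0" = list(
      ions = data.frame(species = "Na", x = 15, y = 0, z = 0),
      oxy = far_ring(c("E18'.A", "D21'.A", "E18'.B", "D21'.B")),
      margin = 15 - r),
    "1-1carb" = list(
      ions = data.frame(species = "Na", x = 0.4, y = 0, z = 0),
      oxy = rbind(ox_pair("E18'.A", 2.7, 0, 0),    # 2.43 A from the ion
                  far_ring(c("D21'.A", "E18'.B", "D21'.B"))),
      margin = 0.7),
    "1-2carb" = list(
      ions = data.frame(species = "Na", x = 0, y = 0, z = 0),
      oxy = rbind(ox_pair("E18'.A", 2.4, 0, 0),
                  ox_pair("D21'.B", -2.4, 0, 0),
                  far_ring(c("D21'.A", "E18'.B"))),
      margin = 0.6),
    "2-tight" = list(
      ions = data.frame(species = "Na", x = c(-1.5, 1.5), y = 0, z = 0),
      oxy = rbind(ox_pair("E18'.A", 0, 2.0, 0),    # shared by both ions
                  ox_pair("D21'.B", 0, -2.0, 0),
                  far_ring(c("D21'.A", "E18'.B"))),
      margin = 0.5),
    "2-loose" = list(
      ions = data.frame(species = "Na", x = c(-2.0, 2.0), y = 0, z = 0),
      oxy = rbind(ox_pair("E18'.A", 4.3, 0.8, 0),
                  ox_pair("D21'.B", -4.3, -0.8, 0),
                  far_ring(c("D21'.A", "E18'.B"))),
      margin = 0.5),
    "2-disperse" = list(
      ions = data.frame(species = "Na", x = c(-2.55, 2.55), y = 0, z = 0),
      oxy = rbind(ox_pair("E18'.A", 4.85, 0.8, 0),
                  ox_pair("D21'.B", -4.85, -0.8, 0),
                  far_ring(c("D21'.A", "E18'.B"))),
      margin = r - 2.55)
  )
}

#' Generate configuration frames with prescribed occupancy states
#'
#' Emits one frame per entry of `occupancy_script`, each constructed so that
#' [classify_site_occupancy()] with the same `site` definition reproduces the
#' prescribed state. States: `"0"`, `"1-1carb"`, `"1-2carb"` (single ion
#' contacting one or two distinct carboxylates), `"2-tight"`, `"2-loose"`,
#' `"2-disperse"`. Gaussian positional jitter of sd `jitter` is added to every
#' coordinate; a jitter large enough to threaten a prescribed state's
#' geometric margin is rejected.
#'
#' @param site A [site_definition()].
#' @param occupancy_script Character vector of prescribed states.
#' @param jitter Positional noise sd, Angstrom.
#' @param seed Integer seed.
#' @return A [configuration_set()] with anchors `site_com` and `axis_origin`
#'   at the origin, carrying the script as attribute `prescribed`.
#' @examples
#' cfg <- build_site_configurations(site_definition(),
#'                                  c("0", "2-tight", "1-1carb"))
#' classify_site_occupancy(cfg)$records$state
#' @export
build_site_configurations <- function(site = site_definition(),
                                      occupancy_script, jitter = 0,
                                      seed = NULL) {
  stopifnot(inherits(site, "site_definition"))
  check_scalar(jitter, "jitter", nonneg = TRUE)
  tpl <- occupancy_templates(site)
  bad <- setdiff(occupancy_script, names(tpl))
  if (length(bad)) {
    stop(sprintf("unknown occupancy state '%s' (allowed: %s)", bad[1],
                 paste(names(tpl), collapse = ", ")))
  }
  margins <- vapply(tpl[unique(occupancy_script)], `[[`, 0, "margin")
  if (jitter > 0 && 6 * jitter > min(margins)) {
    stop(sprintf("jitter %.3g too large: 6*jitter exceeds the smallest geometric margin (%.3g A) of the prescribed states; states no longer guaranteed",
                 jitter, min(margins)))
  }
  frames <- with_seed(seed, lapply(occupancy_script, function(st) {
    t0 <- tpl[[st]]
    fr <- make_frame(t0$ions, t0$oxy)
    if (jitter > 0) {
      n <- nrow(fr)
      fr$x <- fr$x + rnorm(n, 0, jitter)
      fr$y <- fr$y + rnorm(n, 0, jitter)
      fr$z <- fr$z + rnorm(n, 0, jitter)
    }
    fr
  }))
  cfg <- configuration_set(frames)
  attr(cfg, "prescribed") <- occupancy_script
  cfg
}
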