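test_that("BAR solves the degenerate and Gaussian cases", {
  # sigma = 0: every forward sample +mu, every backward -mu -> dG = mu exactly
  ws0 <- generate_fep_work_samples(2.0, 0, 100, th303, seed = 1)
  b0 <- bar_estimate(ws0, thermo = th303)
  expect_equal(b0$dG, 2.0, tolerance = 1e-9)
  expect_equal(b0$stderr, 0, tolerance = 1e-9)
  # Crooks-consistent Gaussian construction recovers the ground truth
  ws <- generate_fep_work_samples(2.0, 1, 1e5, th303, seed = 2)
  b <- bar_estimate(ws, thermo = th303)
  expect_lt(abs(b$dG - 2.0), 3 * b$stderr)
  expect_gt(b$overlap, 0.5)
  expect_error(bar_estimate(c(1), c(1, 2), thermo = th303), "at least 2")
})

test_that("BAR is antisymmetric under swapping forward and backward sets", {
  ws <- generate_fep_work_samples(1.3, 0.8, 5e3, th303, seed = 3)
  b1 <- bar_estimate(ws$forward, ws$backward, thermo = th303)
  b2 <- bar_estimate(ws$backward, ws$forward, thermo = th303)
  expect_equal(b1$dG, -b2$dG, tolerance = 1e-8)
  expect_equal(b1$stderr, b2$stderr, tolerance = 1e-8)
})

test_that("BAR reduces to the exponential (Zwanzig) estimator in the one-sided limit", {
  set.seed(4)
  fwd <- rnorm(2e4, 5, 1)
  bwd <- rep(-80, 2)   # reverse direction overwhelmingly favourable
  b <- bar_estimate(fwd, bwd, thermo = th303)
  zw <- -th303$kBT * log(mean(exp(-th303$beta * fwd)))
  expect_equal(b$dG, zw, tolerance = 1e-3)
})

test_that("BAR bias decays with sample size", {
  ns <- c(1e2, 1e3, 1e4, 1e5)
  med_err <- sapply(ns, function(n) {
    errs <- sapply(1:20, function(s) {
      ws <- generate_fep_work_samples(1, 1, n, th303, seed = 100 * s + log10(n))
      abs(bar_estimate(ws, thermo = th303)$dG - 1)
    })
    median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})

test_that("leg enumeration is exhaustive, ordered and duplicate-free", {
  expect_identical(enumerate_cycle_legs("single", "open-state")$label,
                   c("Na->K", "K->Na"))
  dbl <- enumerate_cycle_legs("double", "open-state")
  expect_identical(nrow(dbl), 8L)
  expect_identical(dbl$label[1:4],
                   c("NaNa->NaK", "NaNa->KNa", "KK->KNa", "KK->NaK"))
  both <- enumerate_cycle_legs(c("single", "double"),
                               c("open-state", "closed-state"))
  expect_identical(nrow(both), 20L)
  expect_false(any(duplicated(both[c("structure", "label")])))
  expect_error(enumerate_cycle_legs("triple"), "unknown occupancy")
})

test_that("lambda schedule bookkeeping enforces its invariant", {
  ls <- lambda_schedule()
  expect_identical(ls$n_windows, 40L)
  expect_equal(ls$delta_lambda, 0.05)
  expect_equal(ls$production_ns, 80)
  expect_error(lambda_schedule(n_windows = 40, delta_lambda = 0.04), "equal 1")
})

test_that("ddG composition subtracts the bulk reference with quadrature errors", {
  s <- fep_leg("Na->K", 2.0, 0.3)
  b <- fep_leg("Na->K", 0.5, 0.2, site = "bulk")
  r <- compose_ddG(s, b)
  expect_equal(r$ddG, 1.5)
  expect_equal(r$stderr, sqrt(0.3^2 + 0.2^2), tolerance = 1e-12)
  # double-occupancy path: site legs sum before subtraction
  p1 <- fep_leg("NaNa->NaK", 1.2, 0.1)
  p2 <- fep_leg("NaK->KK", 1.8, 0.1)
  r2 <- compose_ddG(list(p1, p2), b)
  expect_equal(r2$site_total, 3.0)
  expect_equal(r2$ddG, 3.0 - 2 * 0.5)
  expect_error(compose_ddG(s, fep_leg("K->Na", 0.5, 0.2, site = "bulk")),
               "mixed transformation directions")
  expect_error(compose_ddG(s, fep_leg("Na->K", 0.5, 0.2)), "bulk")
  expect_error(compose_ddG(list(p2, p1), b), "chain")
})

test_that("alternative double-occupancy paths agree on synthetic work data", {
  # common ground truth: NaNa->KK totals 3.0 kcal/mol via either ion order
  truths <- list(c("NaNa->NaK" = 1.2, "NaK->KK" = 1.8),
                 c("NaNa->KNa" = 0.9, "KNa->KK" = 2.1))
  bulk_ws <- generate_fep_work_samples(0.4, 0.8, 4e4, th303, seed = 60)
  bulk_bar <- bar_estimate(bulk_ws, thermo = th303)
  bulk <- fep_leg("Na->K", bulk_bar$dG, bulk_bar$stderr, site = "bulk")
  paths <- lapply(seq_along(truths), function(i) {
    legs <- lapply(seq_along(truths[[i]]), function(j) {
      ws <- generate_fep_work_samples(truths[[i]][[j]], 0.8, 4e4, th303,
                                      seed = 60 + 10 * i + j)
      bb <- bar_estimate(ws, thermo = th303)
      fep_leg(names(truths[[i]])[j], bb$dG, bb$stderr)
    })
    compose_ddG(legs, bulk)
  })
  diff_se <- sqrt(paths[[1]]$stderr^2 + paths[[2]]$stderr^2)
  expect_lt(abs(paths[[1]]$ddG - paths[[2]]$ddG), 3 * diff_se)
})

test_that("cycle closure passes on consistent legs and fails on corrupted ones", {
  exact <- list(fep_leg("Na->K", 1.7, 0), fep_leg("K->Na", -1.7, 0))
  cc <- cycle_closure_check(exact)
  expect_equal(cc$residual, 0)
  expect_true(cc$pass)
  # estimated legs with a shared ground truth close within error
  f <- generate_fep_work_samples(2, 1, 5e4, th303, seed = 71)
  r <- generate_fep_work_samples(-2, 1, 5e4, th303, seed = 72)
  bf <- bar_estimate(f, thermo = th303)
  br <- bar_estimate(r, thermo = th303)
  cc2 <- cycle_closure_check(list(fep_leg("Na->K", bf$dG, bf$stderr),
                                  fep_leg("K->Na", br$dG, br$stderr)))
  expect_true(cc2$pass)
  # flipping one leg's sign breaks the loop
  cc3 <- cycle_closure_check(list(fep_leg("Na->K", bf$dG, bf$stderr),
                                  fep_leg("K->Na", -br$dG, br$stderr)))
  expect_false(cc3$pass)
  # an open loop is rejected with the broken transition named
  expect_error(cycle_closure_check(list(fep_leg("Na->K", 1, 0),
                                        fep_leg("NaK->KK", 1, 0))),
               "open loop")
})

test_that("work tables round-trip through the text format", {
  ws <- generate_fep_work_samples(1, 0.5, 200, th303, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_work_table(ws, path)
  back <- read_work_table(path)
  expect_equal(back$forward, ws$forward, tolerance = 1e-12)
  expect_equal(back$backward, ws$backward, tolerance = 1e-12)
})
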