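# Ladder regression with the substrate-competition correction, the
# screening triage, fold changes, and the boundary diagnostic.

test_that("noiseless ladders invert exactly, including the correction", {
  for (s_over_km in c(0.5, 1, 2)) {
    KM <- 1e-4; S <- s_over_km * KM
    I <- design_ladder(2e5, S, KM, duration = 600)
    kobs <- kobs_from_second_order(2e5, I, S, KM)
    est <- second_order_constant(data.frame(I = I, k_obs = kobs), S = S,
                                 KM = KM)
    expect_false(est$bounded)
    expect_equal(est$kinact_over_KI, 2e5, tolerance = 1e-9)
    expect_equal(est$correction_factor, 1 + s_over_km)
    expect_gt(est$r2_origin, 1 - 1e-12)
  }
})

test_that("halving S with fixed KM doubles k_obs but not the constant", {
  KM <- 1e-4; k2 <- 5e5
  I <- design_ladder(k2, KM, KM, duration = 600)
  k_full <- kobs_from_second_order(k2, I, KM, KM)
  k_half <- kobs_from_second_order(k2, I, KM / 2, KM)
  expect_equal(k_half / k_full, rep(2 / 1.5, length(I)), tolerance = 1e-12)
  est_full <- second_order_constant(data.frame(I = I, k_obs = k_full),
                                    S = KM, KM = KM)
  est_half <- second_order_constant(data.frame(I = I, k_obs = k_half),
                                    S = KM / 2, KM = KM)
  expect_equal(est_half$kinact_over_KI, est_full$kinact_over_KI,
               tolerance = 1e-12)
})

test_that("dead ladders give a bounded result, missing KM a hard error", {
  flat <- data.frame(I = c(1e-6, 2e-6, 5e-6), k_obs = c(0, 0, 0))
  est <- second_order_constant(flat, S = 4e-5, KM = 8e-5)
  expect_true(est$bounded)
  expect_match(est$reason, "no measurable inactivation")
  expect_true(is.na(est$kinact_over_KI))
  unres <- data.frame(I = 1e-6, k_obs = 0.1, status = "linear_unresolvable")
  expect_true(second_order_constant(unres, S = 0, KM = 1e-4)$bounded)
  expect_error(second_order_constant(flat, S = 4e-5, KM = NULL), "KM")
  expect_error(second_order_constant(flat, S = 4e-5), "KM")
})

test_that("seeded noisy ladder recovers the truth within 15%", {
  k2 <- 2e6; KM <- 8e-5; S <- 4e-5
  I <- design_ladder(k2, S, KM, duration = 600)
  kobs <- kobs_from_second_order(k2, I, S, KM)
  noisy <- withr::with_seed(17, kobs * (1 + 0.08 * stats::rnorm(length(I))))
  est <- second_order_constant(data.frame(I = I, k_obs = noisy), S = S,
                               KM = KM)
  expect_lt(abs(est$kinact_over_KI - k2) / k2, 0.15)
})

test_that("saturating (hyperbolic) ladders are flagged, not refitted", {
  KI <- 5e-6; kinact <- 0.5
  I <- c(1, 2, 5, 10, 20, 50) * 1e-6
  kobs <- kinact * I / (KI + I)   # strongly saturating
  est <- second_order_constant(data.frame(I = I, k_obs = kobs), S = 0,
                               KM = 1e-4, r2_threshold = 0.9)
  expect_true(est$saturating)
})

test_that("inhibition fraction clips and flags noise-driven excursions", {
  expect_equal(as.numeric(inhibition_fraction(1, 1)), 0)
  expect_equal(as.numeric(inhibition_fraction(0.6, 1)), 0.4)
  over <- inhibition_fraction(1.08, 1)   # noise pushed v above control
  expect_equal(as.numeric(over), 0)
  expect_true(attr(over, "clipped"))
  expect_false(attr(inhibition_fraction(0.6, 1), "clipped"))
  expect_error(inhibition_fraction(0.5, 0), "positive")
})

test_that("triage bands follow the screening decision tree", {
  expect_identical(as.character(triage(c(0.03, 0.20, 0.60))),
                   c("no_inhibition", "bounded_below_50", "quantify"))
  # boundary values belong to the bounded (closed-interval) class
  expect_identical(as.character(triage(c(0.05, 0.40))),
                   c("bounded_below_50", "bounded_below_50"))
  # monotone in the fraction
  fr <- seq(0, 1, by = 0.01)
  expect_true(all(diff(as.integer(triage(fr))) >= 0))
  expect_error(triage(1.2))
})

test_that("fold changes reproduce the printed potency ratios", {
  expect_identical(fold_change(1626200, 229000), 7.1)
  expect_identical(fold_change(4236800, 1626200), 2.6)
  expect_identical(fold_change(229000, 101800), 2.2)
  expect_identical(fold_change(5, 5), 1.0)
  # antisymmetry on the unrounded values
  a <- 304300; b <- 125250
  expect_equal(fold_change(a, b, rounded = FALSE) *
                 fold_change(b, a, rounded = FALSE), 1)
  expect_error(fold_change(1, 0), "positive")
})

test_that("screen boundary diagnostic reports the documented tension", {
  note <- screen_boundary_note(quiet = TRUE)
  expect_equal(note$inhibition_at_bound, 1 - exp(-1.125), tolerance = 1e-12)
  expect_gt(note$inhibition_at_bound, 0.40)   # bound falls above the band edge
  expect_equal(note$implied_constant_at_band, -log(0.6) / (25e-6 * 900),
               tolerance = 1e-12)
  expect_lt(note$implied_constant_at_band, 50)
  expect_message(screen_boundary_note(), "boundary")
})

test_that("replicate scatter of recovered constants respects the 10% rule", {
  # relative_sd = 0.05 per point keeps across-replicate CV under 10%
  cond <- hne_condition()
  cmp <- compound_spec("x", list(HNE = 2e5))
  cvs <- withr::with_seed(7, {
    vapply(1:20, function(i) {
      ds <- simulate_determination(cond, cmp,
                                   noise = noise_model(0.05, seed = 5000 + i))
      ests <- estimate_second_order(ds, per_replicate = TRUE)
      ks <- vapply(ests, function(e) e$kinact_over_KI, numeric(1))
      stats::sd(ks) / mean(ks)
    }, numeric(1))
  })
  expect_gte(mean(cvs < 0.10), 0.95)
})
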