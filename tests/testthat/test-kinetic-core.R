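# Closed-form progress model, pseudo-first-order relation, and the
# mass-action mechanism oracle.

test_that("closed-form progress curve matches limits and exact arithmetic", {
  # plateau at v_i / k_obs
  expect_equal(progress_closed_form(1e6, v_i = 1, k_obs = 0.01), 100,
               tolerance = 1e-9)
  # linear control limit at k_obs = 0
  expect_identical(progress_closed_form(120, v_i = 5, k_obs = 0), 600)
  # high-precision arithmetic oracle for a generic point
  expect_equal(progress_closed_form(300, v_i = 2, k_obs = 0.005),
               400 * (1 - exp(-1.5)), tolerance = 1e-12)
  # non-decreasing in t and bounded by the plateau
  tt <- seq(0, 3000, by = 7)
  p <- progress_closed_form(tt, v_i = 1.3, k_obs = 0.004)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p <= 1.3 / 0.004 + 1e-12))
  expect_error(progress_closed_form(-1, 1, 0.01), "negative time")
})

test_that("small-k_obs series limit agrees with the exponential to 1e-9", {
  tt <- seq(1, 600, by = 13)
  v_i <- 2.7
  for (k in c(1e-12, 1e-10, 1e-9)) {
    stopifnot(k * max(tt) < 1e-6)
    p <- progress_closed_form(tt, v_i, k)
    expect_lt(max(abs(p - v_i * tt) / (v_i * tt)), 1e-9)
  }
})

test_that("pseudo-first-order relation: arithmetic and competition factor", {
  expect_equal(kobs_from_second_order(229000, 1e-6, S = 0, KM = 8e-5), 0.229)
  expect_identical(kobs_from_second_order(5e5, 0, S = 4e-5, KM = 8e-5), 0)
  # S = KM makes the competition factor exactly 2
  expect_equal(kobs_from_second_order(200000, 2e-6, S = 1e-4, KM = 1e-4), 0.2)
  expect_error(kobs_from_second_order(1e5, 1e-6, S = 0, KM = 0), "KM")
})

test_that("rate_parameters enforces the split-ratio invariant", {
  r <- rate_parameters(kinact_over_KI = 2e5)
  expect_equal(r$kinact / r$KI, 2e5, tolerance = 1e-12)
  expect_equal(r$KI, 1e-4)     # default non-saturating split
  ok <- rate_parameters(kinact_over_KI = 2e5, kinact = 0.02, KI = 1e-7)
  expect_equal(ok$kinact_over_KI, 2e5)
  expect_error(rate_parameters(kinact_over_KI = 2e5, kinact = 0.02, KI = 1e-6),
               "disagrees")
  expect_error(rate_parameters(kinact = 0.02), "together")
  # KI alone pins the saturation scale under the lumped constant
  lin <- rate_parameters(kinact_over_KI = 50, KI = 1)
  expect_equal(lin$kinact, 50)
})

test_that("mechanism derivatives conserve enzyme, substrate and inhibitor", {
  r <- rate_parameters(kinact = 0.05, KI = 1e-4, kcat = 20, KM = 8e-5)
  # all-zero state has all-zero derivatives
  z <- mechanism_state(E = 0, S = 0, I = 0)
  expect_true(all(mechanism_rhs(z, r) == 0))
  # no inhibitor: covalent complex does not form
  s_noI <- mechanism_state(E = 1e-9, S = 4e-5, I = 0)
  expect_identical(unname(mechanism_rhs(s_noI, r)[["EIx"]]), 0)
  # analytic conservation on a generic occupied state
  st <- mechanism_state(E = 5e-10, S = 3e-5, I = 4e-6, ES = 3e-10,
                        EI = 1e-10, EIx = 1e-10, P = 1e-6)
  d <- mechanism_rhs(st, r)
  scale <- max(abs(d))
  expect_lt(abs(d[["E"]] + d[["ES"]] + d[["EI"]] + d[["EIx"]]), 1e-12 * scale)
  expect_lt(abs(d[["S"]] + d[["ES"]] + d[["P"]]), 1e-12 * scale)
  expect_lt(abs(d[["I"]] + d[["EI"]] + d[["EIx"]]), 1e-12 * scale)
})

test_that("integrated mechanism keeps mass balances and monotone product", {
  r <- rate_parameters(kinact = 2e5 * 1e-3, KI = 1e-3, kcat = 20, KM = 8e-5)
  s0 <- mechanism_state(E = 1e-9, S = 4e-5, I = 5e-6)
  tg <- seq(0, 600, by = 10)
  tr <- integrate_mechanism(s0, r, tg)
  expect_true(all(diff(tr$P) >= -1e-18))
  e_tot <- tr$E + tr$ES + tr$EI + tr$EIx
  s_tot <- tr$S + tr$ES + tr$P
  expect_lt(max(abs(e_tot - 1e-9)) / 1e-9, 1e-9)
  expect_lt(max(abs(s_tot - 4e-5)) / 4e-5, 1e-9)
  expect_error(integrate_mechanism(s0, r, c(1, 2, 3)), "start at 0")
})

test_that("ODE trajectory matches the closed form under pseudo-first-order", {
  # [I] >= 100 [E], [I] << KI (linear regime), substrate depletion < 10%
  k2 <- 2e5
  r <- rate_parameters(kinact = k2 * 1e-3, KI = 1e-3, kcat = 20, KM = 8e-5)
  s0 <- mechanism_state(E = 1e-9, S = 4e-5, I = 5e-6)
  tg <- seq(0, 600, by = 10)
  tr <- integrate_mechanism(s0, r, tg)
  expect_lt((4e-5 - min(tr$S)) / 4e-5, 0.10)
  kobs <- kobs_from_second_order(k2, 5e-6, S = 4e-5, KM = 8e-5)
  vi <- 20 * 1e-9 * 4e-5 / (4e-5 + 8e-5)
  cf <- progress_closed_form(tg, vi, kobs)
  rms <- sqrt(mean((tr$P - cf)^2)) / max(cf)
  expect_lt(rms, 0.02)
})

test_that("control trajectory is initially linear and velocity scales with enzyme", {
  r <- rate_parameters(kinact = 0.05, KI = 1e-4, kcat = 20, KM = 8e-5)
  tg <- seq(0, 60, by = 2.5)
  tr1 <- integrate_mechanism(mechanism_state(E = 1e-9, S = 4e-5, I = 0), r, tg)
  # early product accumulation linear to ~0.5% (depletion is negligible)
  vi <- (tr1$P[3] - tr1$P[2]) / 2.5
  pred <- vi * tg[-1]
  expect_lt(max(abs(tr1$P[-1] - pred) / max(pred)), 0.005)
  tr2 <- integrate_mechanism(mechanism_state(E = 2e-9, S = 4e-5, I = 0), r, tg)
  v1 <- (tr1$P[5] - tr1$P[2]) / 7.5
  v2 <- (tr2$P[5] - tr2$P[2]) / 7.5
  expect_equal(v2 / v1, 2, tolerance = 0.01)
})

test_that("round trip: kobs ladder regenerated then inverted is exact", {
  for (k2 in c(5e3, 2e5, 2e6)) {
    for (s_over_km in c(0.5, 1, 2)) {
      KM <- 8e-5; S <- s_over_km * KM
      I <- design_ladder(k2, S, KM, duration = 600)
      kobs <- kobs_from_second_order(k2, I, S, KM)
      est <- second_order_constant(data.frame(I = I, k_obs = kobs),
                                   S = S, KM = KM)
      expect_lt(abs(est$kinact_over_KI - k2) / k2, 1e-9)
    }
  }
})
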