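# The plate-reader simulator: control linearity, plateau oracle,
# determinism, ladder design, screening mode, and the library fixture.

test_that("noiseless control curve is a straight line through the baseline", {
  cond <- hne_condition()
  cv <- simulate_progress_curve(cond, 2e5, I = 0)
  expect_identical(cv$role, "control")
  expect_equal(cv$signal[1], cond$baseline)
  slopes <- diff(cv$signal) / diff(cv$time_s)
  expect_lt(diff(range(slopes)) / mean(slopes), 1e-9)
})

test_that("long-duration curve plateaus at baseline + gain * v_i/k_obs", {
  cond <- hne_condition(duration = 36000, read_interval = 600)
  k2 <- 2e6; I <- 25e-6
  cv <- simulate_progress_curve(cond, k2, I = I)
  kobs <- kobs_from_second_order(k2, I, cond$S, cond$KM)
  vi_molar <- cond$kcat * cond$enzyme_conc * cond$S / (cond$KM + cond$S)
  plateau <- cond$baseline + cond$gain * vi_molar / kobs
  expect_equal(max(cv$signal), plateau, tolerance = 0.01)
  tr <- attr(cv, "truth")
  expect_equal(tr$k_obs, kobs)
})

test_that("identical seeds give bit-identical curves, different seeds differ", {
  cond <- hne_condition()
  a <- simulate_progress_curve(cond, 2e5, I = 2e-6, noise = noise_model(0.05, seed = 7))
  b <- simulate_progress_curve(cond, 2e5, I = 2e-6, noise = noise_model(0.05, seed = 7))
  c <- simulate_progress_curve(cond, 2e5, I = 2e-6, noise = noise_model(0.05, seed = 8))
  expect_identical(a$signal, b$signal)
  expect_false(identical(a$signal, c$signal))
})

test_that("determination has the designed structure and identifiable ladder", {
  cond <- hne_condition()
  ds <- simulate_determination(cond, compound_spec("27", list(HNE = 229000)))
  expect_s3_class(ds, "assay_dataset")
  expect_length(ds$ladder, 7)
  expect_identical(nrow(ds$layout), 24L)  # (7 samples + 1 control) x 3
  expect_identical(sum(ds$layout$role == "control"), 3L)
  # designed noiseless k_obs * duration inside the identifiable window
  kd <- ds$truth$kobs_by_I$k_obs * cond$duration
  expect_true(all(kd >= 0.5 - 1e-9 & kd <= 5 + 1e-9))
  expect_error(simulate_determination(cond, 2e5, ladder = 1e-6),
               "at least 2")
})

test_that("ODE-generated curves show saturation the closed form lacks", {
  # [I] = KI: the mechanistic inactivation rate is kinact I / (KI(1+S/KM)+I),
  # 40% below the linear pseudo-first-order prediction kinact I / (KI(1+S/KM))
  cond <- hne_condition(duration = 30, read_interval = 0.5)
  rates <- rate_parameters(kinact = 2e4 * 1e-5, KI = 1e-5, kcat = cond$kcat,
                           KM = cond$KM)
  lin <- simulate_progress_curve(cond, rates, I = 1e-5)
  ode <- simulate_progress_curve(cond, rates, I = 1e-5, method = "ode")
  f_lin <- fit_kobs(lin)
  f_ode <- fit_kobs(ode)
  expect_identical(f_lin$status, "ok")
  expect_identical(f_ode$status, "ok")
  k_sat <- rates$kinact * 1e-5 / (rates$KI * (1 + cond$S / cond$KM) + 1e-5)
  expect_equal(f_ode$k_obs, k_sat, tolerance = 0.05)
  expect_lt(f_ode$k_obs, 0.75 * f_lin$k_obs)
})

test_that("screen mode reproduces the substrate-free inactivation oracle", {
  cond <- hne_condition()
  # inert compound
  expect_equal(simulate_screen(cond, 0), 1.0)
  # linear regime at the inactivity bound: exp(-50 * 25e-6 * 900)
  weak <- rate_parameters(kinact_over_KI = 50, KI = 1)  # KI >> I: linear
  expect_equal(simulate_screen(cond, weak), exp(-1.125), tolerance = 1e-4)
  expect_equal(simulate_screen(cond, weak), 0.325, tolerance = 0.002)
  # effectively infinite rate wipes out activity
  hot <- rate_parameters(kinact_over_KI = 1e9, KI = 1)
  expect_lt(simulate_screen(cond, hot), 1e-6)
  # endpoint readout also penalizes inactivation during the read
  expect_lt(simulate_screen(cond, weak, readout = "endpoint"),
            simulate_screen(cond, weak, readout = "rate"))
})

test_that("library fixture carries the transcribed constants and bounds", {
  lib <- nsp_compound_library()
  get <- function(id, enz) lib[lib$compound_id == id & lib$enzyme == enz, ]
  expect_equal(get("78", "HNE")$kinact_over_KI, 1626200)
  expect_equal(get("113", "PR3")$kinact_over_KI, 8951600)
  expect_equal(get("27", "HNE")$kinact_over_KI, 229000)
  need <- c("2", "27", "29", "62", "65", "70", "75", "77", "78", "79", "80",
            "100", "111", "113")
  expect_true(all(need %in% lib$compound_id))
  catg <- lib[lib$enzyme == "CatG", ]
  expect_true(all(catg$censored))
  expect_true(all(catg$bound == 50))
  expect_true(all(is.na(catg$kinact_over_KI)))
  # synthetic extension is seeded, in range, and reproducible
  lib2 <- nsp_compound_library(n_synthetic = 5, seed = 3)
  syn <- lib2[lib2$source == "synthetic" & !lib2$censored, ]
  expect_true(all(syn$kinact_over_KI >= 50 & syn$kinact_over_KI <= 9e6))
  expect_identical(lib2, nsp_compound_library(n_synthetic = 5, seed = 3))
  expect_error(nsp_compound_library(n_synthetic = 2), "seed")
})

test_that("noiseless determination round-trips to the true constant", {
  # generator -> fitting pipeline inversion at 0.1% (here: much tighter)
  cond <- condition_with_ratio(1)
  ds <- simulate_determination(cond, 2e5, replicates = 1)
  est <- estimate_second_order(ds)
  expect_lt(abs(est$kinact_over_KI - 2e5) / 2e5, 1e-3)
})
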