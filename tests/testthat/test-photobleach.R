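test_that("focus-count decay: exact recovery, flags, errors", {
  t <- (0:99) * 0.1
  f <- fit_focus_count_decay(50 * exp(-t / 6), t)
  expect_equal(f$tau_s, 6, tolerance = 1e-6)
  expect_true(f$decaying)
  cflat <- fit_focus_count_decay(rep(5, 20), (0:19) * 0.1)
  expect_false(cflat$decaying)
  expect_equal(cflat$tau_s, Inf)
  expect_error(fit_focus_count_decay(rep(0, 20), (0:19) * 0.1), "zero")
  expect_error(fit_focus_count_decay(1:5, (0:4) * 0.1), ">= 10")
})

test_that("two-exponential fits recover noiseless curves to 1e-4", {
  t <- (0:299) * 0.034
  for (tau2 in c(30, 45, 60, 90, 200)) {
    y <- 100 * exp(-t / 6) + 50 * exp(-t / tau2)
    ft <- fit_two_exponential(y, t, tau1_fixed = 6)
    expect_equal(ft$A1, 100, tolerance = 1e-4)
    expect_equal(ft$A2, 50, tolerance = 1e-4)
    expect_equal(ft$tau2, tau2, tolerance = 1e-4)
  }
})

test_that("degenerate decays: pure autofluorescence and pure bleaching", {
  t <- (0:299) * 0.034
  # wild-type analogue: no fluorophore component
  ft <- fit_two_exponential(50 * exp(-t / 60), t)
  expect_equal(ft$A1, 0, tolerance = 1e-6)
  expect_equal(ft$tau2, 60, tolerance = 1e-3)
  # pure fast component: A2 ~ 0
  ft2 <- fit_two_exponential(100 * exp(-t / 6), t)
  expect_equal(ft2$A1, 100, tolerance = 1e-3)
  expect_equal(ft2$A2, 0, tolerance = 1e-3 * 100)
  expect_error(fit_two_exponential(1:5, (0:4) * 0.1), ">= 20")
})

test_that("single-molecule calibration is robust to gross outliers", {
  expect_error(calibrate_single_molecule(rep(1850, 10)), "return events")
  cal <- calibrate_single_molecule(rep(1850, 40))
  expect_equal(cal$I_sm, 1850)
  expect_equal(cal$sd, 0)
  set.seed(61)
  ev <- rnorm(100, 1850, 150)
  cal1 <- calibrate_single_molecule(ev)
  cal2 <- calibrate_single_molecule(c(ev, 18500))
  expect_equal(cal2$n_excluded, 1)
  expect_lt(abs(cal2$I_sm - cal1$I_sm) / cal1$I_sm, 0.005)
})

test_that("calibration from 200 rendered return events is within 2%", {
  cfg <- sim_config(autofluor_amplitude = 0)
  cs <- rect_cellset(21, 21)
  set.seed(63)
  ints <- vapply(1:200, function(i) {
    mol <- data.frame(cell = 1, mol = 1,
                      x_nm = 1050 + runif(1, -50, 50),
                      y_nm = 1050 + runif(1, -50, 50), state = "tight")
    img <- render_frame(mol, cs, cfg, noise = TRUE) - cfg$camera_offset
    fit_gaussian_2d(img, 11, 11)$integrated_au
  }, 0)
  cal <- calibrate_single_molecule(ints[is.finite(ints)])
  expect_gte(cal$n, 150)
  expect_equal(cal$I_sm, 1850, tolerance = 0.02)
})

test_that("copy number and concentration follow the calibration algebra", {
  cal <- calibrate_single_molecule(rep(1850, 40), reference_exposure_ms = 34)
  expect_equal(copy_number(1850 / 100, 100, cal), 1)
  # linearity: doubling brightness and calibration together is invariant
  cal2 <- calibrate_single_molecule(rep(3700, 40), reference_exposure_ms = 34)
  expect_equal(copy_number(2 * 1850 / 100, 100, cal2), 1)
  # exposure scaling: measured at 68 ms, calibrated at 34 ms
  expect_equal(copy_number(2 * 1850 / 100, 100, cal, exposure_ms = 68), 1)
  # concentrations
  expect_equal(concentration(0, 5), 0)
  expect_equal(concentration(20, 5.53), 6.0, tolerance = 1e-3)
  # printed copy-number/concentration pairs imply a ~2.46x volume ratio
  v_plateau <- 279 / (34 * 1e-9 * 6.02214076e23) * 1e15
  v_base <- 20 / (6 * 1e-9 * 6.02214076e23) * 1e15
  expect_equal(v_plateau / v_base, 2.46, tolerance = 0.01)
  expect_error(concentration(5, 0), "volume")
})

test_that("change-point analysis: exact cases and oracle equivalence", {
  # constant trace: no change points
  f0 <- changepoint_steps(rep(5, 30))
  expect_equal(length(f0$changepoints), 0)
  expect_equal(f0$n_steps_down, 0)
  # noiseless staircase 3700 -> 1850 -> 0 at exact frames
  y <- c(rep(3700, 20), rep(1850, 20), rep(0, 20))
  fs <- changepoint_steps(y, sigma = 50)
  expect_equal(fs$changepoints, c(20, 40))
  expect_equal(fs$levels, c(3700, 1850, 0))
  expect_equal(fs$n_steps_down, 2)
  expect_equal(fs$initial_level, 3700)
  # dynamic programme equals exhaustive search (traces <= 60 pts, <= 3 cps)
  set.seed(62)
  for (i in 1:30) {
    n <- sample(c(20, 40, 60), 1)
    k <- sample(0:3, 1)
    cp <- sort(sample(seq(3, n - 3), k))
    lev <- cumsum(c(10, runif(k, -6, 6)))
    y <- rep(lev, diff(c(0, cp, n))) + rnorm(n, 0, 1)
    fit <- changepoint_steps(y, penalty = 4)
    orc <- oracle_changepoints(y, fit$penalty_value, kmax = 3)
    if (length(fit$changepoints) <= 3) {
      expect_equal(fit$changepoints, orc$cp)
    }
  }
})

test_that("molecules per focus rounds against the calibration", {
  cal <- calibrate_single_molecule(rep(1850, 40))
  expect_equal(molecules_per_focus(1850, cal)$n_molecules, 1L)
  expect_equal(molecules_per_focus(3700, cal)$n_molecules, 2L)
  expect_equal(molecules_per_focus(3700, cal)$ratio, 2)
  expect_equal(molecules_per_focus(500, cal)$n_molecules, 1L)  # floor at 1
  expect_error(molecules_per_focus(-5, cal), "non-positive")
  st <- changepoint_steps(c(rep(3700, 20), rep(0, 20)), sigma = 10)
  expect_equal(molecules_per_focus(st, cal)$n_molecules, 2L)
})
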