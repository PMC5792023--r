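test_that("noise-free rendering is photometrically linear to 0.1%", {
  cfg <- sim_config(autofluor_amplitude = 0, field_px = 96)
  set.seed(2)
  cs <- simulate_cells(cfg, 4)
  mol <- place_molecules(cs, 5, cfg, place_replisomes(cs, cfg))
  mol <- mol[mol$state != "free", ]
  img <- render_frame(mol, cs, cfg, noise = FALSE)
  expect_equal(sum(img - cfg$camera_offset), nrow(mol) * cfg$I_single,
               tolerance = 1e-3)
  # linear in exposure
  img2 <- render_frame(mol, cs, cfg, exposure_ms = 68, noise = FALSE)
  expect_equal(sum(img2 - cfg$camera_offset),
               2 * nrow(mol) * cfg$I_single, tolerance = 1e-3)
})

test_that("empty, noise-free frame is exactly the camera offset", {
  cfg <- sim_config(autofluor_amplitude = 0, read_noise_sd = 0,
                    field_px = 64)
  set.seed(4)
  cs <- simulate_cells(cfg, 2)
  none <- place_molecules(cs, 0, cfg, NULL)
  img <- render_frame(none, cs, cfg, noise = FALSE)
  expect_true(all(img == cfg$camera_offset))
  # with noise on but zero signal and zero read noise, Poisson(0) = 0
  imgn <- render_frame(none, cs, cfg, noise = TRUE)
  expect_true(all(imgn == cfg$camera_offset))
})

test_that("free-molecule smears have Brownian extent and raise no foci", {
  cfg <- sim_config(autofluor_amplitude = 0, field_px = 400,
                    D_free = 100)
  labels <- matrix(1L, 400, 400)
  cs <- cells_from_labels(labels, 100)
  # 60 free molecules all starting at the field centre
  mol <- data.frame(cell = 1, mol = 1:60, x_nm = 20000, y_nm = 20000,
                    state = "free")
  set.seed(6)
  img <- render_frame(mol, cs, cfg, noise = FALSE, free_mode = "substep")
  w <- img - cfg$camera_offset
  w[w < 0] <- 0
  xs <- (col(w) - 0.5) * 100; ys <- (row(w) - 0.5) * 100
  rms_nm <- sqrt(sum(w * ((xs - 20000)^2 + (ys - 20000)^2)) / sum(w))
  # smear positions sample the path uniformly: E[r^2] = 4 D t (ns+1)/(2 ns)
  ns <- cfg$free_substeps
  expected <- sqrt(4 * 100 * 0.034 * (ns + 1) / (2 * ns)) * 1000
  expect_equal(rms_nm, expected, tolerance = 0.25)
  expect_gt(rms_nm, 10 * cfg$psf_sigma_px * 100)  # far wider than the PSF
  # the focus detector must not fire on free-molecule smears in real cells
  cfg2 <- sim_config(field_px = 96, f_tight = 0, f_loose = 0,
                     f_dispersed = 0, D_free = 100)
  set.seed(7)
  cs2 <- simulate_cells(cfg2, 4)
  free <- place_molecules(cs2, 10, cfg2, NULL)
  expect_true(all(free$state == "free"))
  fired <- 0
  for (i in 1:5) {
    imgn <- render_frame(free, cs2, cfg2, noise = TRUE,
                         free_mode = "substep") - cfg2$camera_offset
    fired <- fired + nrow(detect_peaks(imgn, cs2, threshold_sd = 5))
  }
  expect_lte(fired / (5 * 4), 0.1)   # at most the noise-only false-positive rate
})

test_that("bleaching survival is exponential with the configured lifetime", {
  cfg <- sim_config()
  mol <- data.frame(cell = 1, mol = seq_len(10000), x_nm = 0, y_nm = 0,
                    state = "dispersed")
  set.seed(8)
  mol <- simulate_bleaching(mol, cfg, n_frames = 300)
  surv6 <- mean(mol$bleach_time_s > 6)
  expect_equal(surv6, exp(-1), tolerance = 0.015 / exp(-1) * 3)
  ks <- stats::ks.test(mol$bleach_time_s, "pexp", 1 / 6)
  expect_gt(ks$p.value, 0.01)
  # no bleaching when tau is infinite
  cfg_inf <- cfg; cfg_inf$tau_bleach_s <- Inf
  m2 <- simulate_bleaching(mol[1:100, 1:5], cfg_inf, n_frames = 300)
  expect_true(all(m2$bleach_frame == 301L))
})

test_that("unbleached count is non-increasing when return_rate = 0", {
  cfg <- sim_config(return_rate = 0)
  mol <- data.frame(cell = 1, mol = 1:500, x_nm = 0, y_nm = 0,
                    state = "dispersed")
  set.seed(9)
  mol <- simulate_bleaching(mol, cfg, n_frames = 100)
  expect_equal(nrow(attr(mol, "return_events")), 0)
  alive <- vapply(1:100, function(k) sum(mol$bleach_frame > k), 0)
  expect_true(all(diff(alive) <= 0))
})

test_that("bound-molecule steps have RMS sqrt(4 D dt) (1e4 steps)", {
  set.seed(10)
  tr <- diffusion_track(0, 0, D = 1e-5, dt_s = 0.034, n_steps = 10000)
  steps <- sqrt(diff(tr$x_nm)^2 + diff(tr$y_nm)^2)
  expect_equal(sqrt(mean(steps^2)), sqrt(4 * 1e-5 * 0.034) * 1000,
               tolerance = 0.05)
})

test_that("rapid acquisition has the configured schedule", {
  cfg <- quick_cfg()
  sim <- generate_rapid_acquisition(cfg, "undamaged", n_cells = 3,
                                    n_frames = 12)
  expect_equal(dim(sim$stack$data)[3], 12)
  expect_equal(sim$stack$timestamps_s, (0:11) * 0.034)
  expect_equal(sim$stack$exposure_ms, 34)
  # full default schedule: 300 x 34 ms = 10.2 s
  cfg_full <- sim_config()
  expect_equal(cfg_full$n_frames_rapid * cfg_full$frame_interval_s, 10.2)
})

test_that("time-lapse series: 37 points, channel lag, constant baseline", {
  cfg <- quick_cfg(autofluor_amplitude = 5)
  tl <- generate_timelapse(cfg, "undamaged", n_cells = 4, noise = FALSE)
  expect_equal(length(tl$time_min), 37)
  expect_equal(tl$time_min, seq(0, 180, by = 5))
  p <- tl$points[[3]]
  expect_equal(p$stacks$yfp$timestamps_s - p$stacks$bf$timestamps_s, 2)
  expect_equal(p$stacks$red$timestamps_s - p$stacks$yfp$timestamps_s, 2)
  expect_equal(p$stacks$yfp$exposure_ms, 50)
  expect_equal(p$stacks$red$exposure_ms, 100)
  # undamaged: expected copy number constant at baseline
  n_per_point <- vapply(tl$points, function(q) nrow(q$molecules), 0)
  expect_equal(mean(n_per_point) / 4, cfg$N_baseline, tolerance = 0.2)
  expect_lt(stats::sd(n_per_point) / mean(n_per_point), 0.5)
  # undamaged cells do not grow
  expect_equal(tl$points[[1]]$cells$cells$length_um,
               tl$points[[37]]$cells$cells$length_um)
})

test_that("damage time-lapse shows filamentation and up-regulation", {
  cfg <- quick_cfg(field_px = 128)
  tl <- generate_timelapse(cfg, "damage", n_cells = 4, noise = FALSE)
  len0 <- mean(tl$points[[1]]$cells$cells$length_um)
  len36 <- mean(tl$points[[37]]$cells$cells$length_um)
  expect_gt(len36 / len0, 1.5)
  n0 <- mean(vapply(tl$points[1:4], function(q) nrow(q$molecules), 0))
  n36 <- mean(vapply(tl$points[34:37], function(q) nrow(q$molecules), 0))
  expect_gt(n36 / n0, 8)   # ~14x expected, Poisson noise on 4 cells
})
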