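# build a test image: constant background + pixel-integrated Gaussians
gauss_image <- function(n, centers, A = 10, sigma_px = 1.5, bg = 0) {
  img <- matrix(bg, n, n)
  for (i in seq_len(nrow(centers)))
    img <- smfoci:::.add_psf(img, centers[i, 1], centers[i, 2],
                             A * 2 * pi * sigma_px^2, sigma_px, 100)
  img
}

test_that("2D Gaussian fit recovers the closed-form integrated intensity", {
  img <- gauss_image(21, cbind(1050, 1050), A = 10, sigma_px = 1.5, bg = 3)
  f <- fit_gaussian_2d(img, 11, 11, window = 13)
  expect_equal(f$status, "ok")
  expect_equal(f$integrated_au, 2 * pi * 10 * 1.5^2, tolerance = 1e-4)
  expect_equal(f$amplitude, 10, tolerance = 1e-3)
  expect_equal(f$background, 3, tolerance = 1e-3)
  expect_equal(f$x_nm, 1050, tolerance = 1e-3)
  # internal consistency: integrated = 2 pi A sx sy (sigmas in px)
  expect_equal(f$integrated_au,
               2 * pi * f$amplitude * (f$sigma_x_nm / 100) *
                 (f$sigma_y_nm / 100), tolerance = 1e-6)
})

test_that("fits are rejected on flat background, edges and bad windows", {
  flat <- matrix(5, 21, 21)
  set.seed(51)
  noisy <- flat + rnorm(441, 0, 0.5)
  f <- fit_gaussian_2d(noisy, 11, 11)
  expect_false(f$status == "ok")
  expect_equal(fit_gaussian_2d(noisy, 2, 11)$status, "edge_clipped")
  expect_error(fit_gaussian_2d(noisy, 11, 11, window = 6), "odd")
  expect_error(fit_gaussian_2d(noisy, 11, 11, window = 5), "odd and >= 7")
})

test_that("detection finds molecules and merges close candidates", {
  # one bright molecule at 10:1 SNR
  set.seed(52)
  img <- gauss_image(41, cbind(2050, 2050), A = 10) + rnorm(41 * 41, 0, 1)
  cand <- detect_peaks(img, threshold_sd = 5)
  expect_equal(nrow(cand), 1)
  expect_lt(abs(cand$row - 21) + abs(cand$col - 21), 2)
  # two molecules 150 nm apart with 300 nm merge radius -> one candidate
  img2 <- gauss_image(41, rbind(c(2000, 2050), c(2150, 2050)), A = 10)
  cand2 <- detect_peaks(img2, threshold_sd = 5, min_separation_nm = 300)
  expect_equal(nrow(cand2), 1)
})

test_that("false-positive rate on noise-only cells is below 0.1 per cell", {
  cfg <- sim_config(field_px = 256, f_tight = 0, f_loose = 0)
  set.seed(53)
  total_fp <- 0; total_cells <- 0
  for (rep_i in 1:2) {
    cs <- simulate_cells(cfg, 50)
    none <- place_molecules(cs, 0, cfg, NULL)
    img <- render_frame(none, cs, cfg, noise = TRUE) - cfg$camera_offset
    cand <- detect_peaks(img, cs, threshold_sd = 5)
    total_fp <- total_fp + nrow(cand)
    total_cells <- total_cells + 50
  }
  expect_lt(total_fp / total_cells, 0.1)
})

test_that("integrated intensity is unbiased (<3%) and centroids <30 nm RMS", {
  cfg <- sim_config(autofluor_amplitude = 0)
  cs <- rect_cellset(25, 25)
  set.seed(54)
  ints <- numeric(0); errs <- numeric(0)
  for (i in 1:500) {
    x <- 1250 + runif(1, -50, 50); y <- 1250 + runif(1, -50, 50)
    mol <- data.frame(cell = 1, mol = 1, x_nm = x, y_nm = y,
                      state = "tight")
    img <- render_frame(mol, cs, cfg, noise = TRUE) - cfg$camera_offset
    f <- fit_gaussian_2d(img, 13, 13, window = 11)
    if (f$status != "ok") next
    ints <- c(ints, f$integrated_au)
    errs <- c(errs, (f$x_nm - x)^2 + (f$y_nm - y)^2)
  }
  expect_gt(length(ints), 450)
  expect_equal(mean(ints), 1850, tolerance = 0.03)
  expect_lt(sqrt(mean(errs)), 30)       # nm RMS, supports the 200 nm radius
})

test_that("ring background correction matches analytic Gaussian integrals", {
  cs_dummy <- NULL
  # uniform image -> corrected intensity 0
  u <- matrix(12, 21, 21)
  lb <- local_background_correct(u, 11, 11, roi = 5)
  expect_equal(lb$corrected, 0, tolerance = 1e-12)
  expect_equal(lb$background, 12)
  # Gaussian on constant offset: corrected ~ analytic mass inside the ROI
  sigma <- 1.3
  img <- gauss_image(21, cbind(1050, 1050), A = 20, sigma_px = sigma,
                     bg = 100)
  lb2 <- local_background_correct(img, 11, 11, roi = 5)
  total <- 2 * pi * 20 * sigma^2
  inroi <- total * (pnorm(2.5 / sigma) - pnorm(-2.5 / sigma))^2
  # ring contains some Gaussian flux, biasing the background slightly up
  expect_equal(lb2$corrected, inroi, tolerance = 0.07)
  # linear gradient cancels to first order
  gr <- matrix(rep(seq(0, 10, length.out = 21), each = 21), 21, 21)
  lb3 <- local_background_correct(gr + img - 100, 11, 11, roi = 5)
  expect_lt(abs(lb3$corrected - inroi) / total, 0.07)
  # clipped ring is an error
  expect_error(local_background_correct(u, 2, 11), "clipped")
})

test_that("trajectories track bleaching and single-frame binding events", {
  # constant stack -> constant trajectory
  dat <- array(50, c(15, 15, 4))
  st <- movie_stack(dat, 100, 34, (0:3) * 0.034)
  tr <- extract_trajectory(st, 8, 8)
  expect_s3_class(tr, "intensity_trajectory")
  expect_equal(tr$intensity, rep(0, 4), tolerance = 1e-12)
  # molecule present until frame k, then gone; plus a 1-frame return spike
  base <- matrix(10, 21, 21)
  spot <- gauss_image(21, cbind(1050, 1050), A = 20, bg = 10)
  dat2 <- array(NA_real_, c(21, 21, 10))
  for (k in 1:10) dat2[, , k] <- if (k <= 4 || k == 8) spot else base
  st2 <- movie_stack(dat2, 100, 34, (0:9) * 0.034)
  tr2 <- extract_trajectory(st2, 11, 11)
  expect_true(all(tr2$intensity[1:4] > 100))
  expect_true(all(abs(tr2$intensity[c(5:7, 9:10)]) < 10))
  expect_gt(tr2$intensity[8], 100)   # transient single-frame event
})

test_that("focus density and per-cell counts follow their definitions", {
  cs <- rect_cellset(20, 20)   # one 4 um^2 cell
  expect_equal(foci_density(data.frame(cell = integer(0)), cs)$density_per_um2, 0)
  f4 <- data.frame(cell = rep(1, 2))
  expect_equal(foci_density(f4, cs)$density_per_um2, 0.5)
  # three cells with 0, 1, 2 foci: mean 1, SEM 1/sqrt(3)
  labs <- matrix(0L, 30, 10)
  labs[1:10, ] <- 1L; labs[11:20, ] <- 2L; labs[21:30, ] <- 3L
  cs3 <- cells_from_labels(labs, 100)
  foci <- data.frame(cell = c(2, 3, 3))
  fp <- foci_per_cell(foci, cs3)
  expect_equal(fp$mean, 1)
  expect_equal(fp$sem, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(fp$n_unassigned, 0)
  fp2 <- foci_per_cell(data.frame(cell = c(1, NA)), cs3)
  expect_equal(fp2$n_unassigned, 1)
})

test_that("find_foci assigns centroids to the enclosing cell", {
  cfg <- sim_config(autofluor_amplitude = 0, field_px = 96)
  set.seed(55)
  cs <- simulate_cells(cfg, 4)
  sites <- place_replisomes(cs, cfg)
  mol <- place_molecules(cs, 3, cfg, sites)
  mol$state <- "dispersed"
  img <- render_frame(mol, cs, cfg, noise = TRUE) - cfg$camera_offset
  foci <- find_foci(img, cs, threshold_sd = 5)
  expect_gt(nrow(foci), 0)
  expect_true(all(!is.na(foci$cell)))
  # every reported centroid lies inside its assigned cell's mask
  pr <- floor(foci$y_nm / 100) + 1
  pc <- floor(foci$x_nm / 100) + 1
  expect_true(all(cs$labels[cbind(pr, pc)] == foci$cell))
})
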