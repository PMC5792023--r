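test_that("offset and flat-field correction follows its definition", {
  img <- matrix(1100, 8, 8)
  expect_equal(correct_offset_and_flatten(img, 100), matrix(1000, 8, 8))
  # a pixel with doubled excitation (mean-normalised) is halved
  ff <- matrix(1, 8, 8); ff[3, 4] <- 2
  corr <- correct_offset_and_flatten(img, 100, ff)
  ffn <- ff / mean(ff)
  expect_equal(corr[3, 4], 1000 / ffn[3, 4])
  expect_equal(corr[1, 1], 1000 / ffn[1, 1])
  # idempotent with offset 0 and uniform flatfield
  expect_equal(correct_offset_and_flatten(corr, 0, matrix(1, 8, 8)), corr)
  # errors
  bad <- matrix(1, 8, 8); bad[5, 6] <- 0
  expect_error(correct_offset_and_flatten(img, 0, bad), "row 5, col 6")
  expect_error(correct_offset_and_flatten(img, 0, matrix(1, 4, 4)),
               "same shape")
})

test_that("correction restores photometric linearity under vignetting", {
  cfg <- sim_config(autofluor_amplitude = 0, field_px = 96)
  set.seed(21)
  cs <- simulate_cells(cfg, 4)
  mol <- place_molecules(cs, 6, cfg, place_replisomes(cs, cfg))
  mol <- mol[mol$state != "free", ]
  clean <- render_frame(mol, cs, cfg, noise = FALSE) - cfg$camera_offset
  # apply a synthetic (unit-mean) vignette + offset, then correct it away
  xs <- (col(clean) - 48.5) / 96; ys <- (row(clean) - 48.5) / 96
  vig <- 1 - 0.4 * (xs^2 + ys^2)
  vig <- vig / mean(vig)
  raw <- clean * vig + 100
  corr <- correct_offset_and_flatten(raw, 100, vig)
  expect_equal(sum(corr), nrow(mol) * cfg$I_single, tolerance = 5e-3)
  expect_equal(max(abs(corr - clean)) / max(clean), 0, tolerance = 5e-3)
})

test_that("spherocylinder volume matches closed forms and is monotone", {
  expect_equal(cell_volume(1, 1), 4 / 3 * pi * 0.125, tolerance = 1e-12)
  expect_equal(cell_volume(1, 1), 0.5236, tolerance = 1e-4)
  expect_equal(cell_volume(3, 1), pi * 0.25 * 2 + 4 / 3 * pi * 0.125,
               tolerance = 1e-12)
  expect_equal(cell_volume(3, 1), 2.0944, tolerance = 1e-4)
  expect_error(cell_volume(0.8, 1), "length")
  expect_true(all(diff(cell_volume(seq(1, 5, 0.5), 1)) > 0))
  expect_true(cell_volume(3, 1.2) > cell_volume(3, 1))
})

test_that("segmentation recovers simulated cells (>=95% at IoU >= 0.8)", {
  cfg <- sim_config(field_px = 256)
  found <- 0; total <- 0; area_err <- numeric(0)
  for (s in 1:2) {                       # 2 fields of 25 cells
    set.seed(30 + s)
    cs <- simulate_cells(cfg, 25)
    bf <- smfoci:::.render_brightfield(cs, cfg)
    seg <- segment_cells(bf, 100)
    total <- total + 25
    for (id in cs$cells$cell) {
      tm <- cs$labels == id
      best <- 0; area <- NA
      for (sid in seg$cells$cell) {
        sm <- seg$labels == sid
        iou <- sum(sm & tm) / sum(sm | tm)
        if (iou > best) { best <- iou; area <- sum(sm) }
      }
      if (best >= 0.8) {
        found <- found + 1
        area_err <- c(area_err, abs(area - sum(tm)) / sum(tm))
      }
    }
  }
  expect_gte(found / total, 0.95)
  expect_lt(max(area_err), 0.10)   # area within 10% for recovered cells
})

test_that("blank images give empty cell sets, touching cells are excluded", {
  blank <- matrix(1000, 64, 64)
  expect_equal(nrow(segment_cells(blank, 100)$cells), 0)
  # two crossed rods render as one merged component -> rod heuristic drops it
  cfg <- sim_config()
  labels <- matrix(0L, 96, 96)
  for (ang in c(0.4, 1.9)) {
    px <- smfoci:::.rasterise_rod(4800, 4800, ang, 3500, 1000, 100, 96, 96)
    labels[(px[, "col"] - 1L) * 96L + px[, "row"]] <- 1L
  }
  cs <- cells_from_labels(labels, 100)
  bf <- smfoci:::.render_brightfield(cs, cfg, noise = FALSE)
  seg <- segment_cells(bf, 100)
  expect_equal(nrow(seg$cells), 0)
  expect_true("not_rod_shaped" %in% attr(seg, "excluded")$reason)
})

test_that("mean cell intensity matches the photometric oracle", {
  u <- matrix(7.5, 32, 32)
  cs <- rect_cellset(32, 32)
  expect_equal(mean_cell_intensity(u, cs, 1), 7.5)
  expect_error(mean_cell_intensity(u, cs, 99), "empty mask")
  # N molecules, noise off: mean = N * I_single / area_px within 1%
  cfg <- sim_config(autofluor_amplitude = 0, field_px = 96,
                    f_tight = 0, f_loose = 0, f_dispersed = 1)
  set.seed(41)
  sim_cs <- simulate_cells(cfg, 1)
  n_mol <- 300
  mol <- place_molecules(sim_cs, n_mol, cfg, NULL)
  img <- render_frame(mol, sim_cs, cfg, noise = FALSE) - cfg$camera_offset
  m <- mean_cell_intensity(img, sim_cs, sim_cs$cells$cell[1])
  # PSF flux spills outside the outline; the capture fraction is the
  # analytic aperture term for uniform-in-mask emitters
  capt <- mask_capture_fraction(sim_cs, cfg$psf_sigma_px)
  expected <- n_mol * cfg$I_single * capt / sim_cs$cells$area_px[1]
  expect_lt(abs(capt - 1), 0.3)
  expect_gt(capt, 0.7)
  expect_equal(m, expected, tolerance = 0.02)  # n_mol sampling error
})

test_that("average projection averages and tracks effective exposure", {
  dat <- array(0, c(8, 8, 9))
  for (k in 1:9) dat[, , k] <- k
  st <- movie_stack(dat, 100, 34, (0:8) * 0.034)
  expect_equal(average_projection(st, 1)$data[, , 1], matrix(1, 8, 8))
  pj <- average_projection(st, 9)
  expect_equal(pj$data[, , 1], matrix(5, 8, 8))
  expect_equal(pj$exposure_ms, 306)
  expect_error(average_projection(st, 0), "at least one")
  expect_error(average_projection(st, 10), "available")
})

test_that("label masks and stacks round-trip through text files", {
  dir <- tempfile(); dir.create(dir)
  labels <- matrix(sample(0:3, 64 * 64, TRUE), 64, 64)
  write_labels_txt(labels, file.path(dir, "lab.txt"))
  expect_identical(read_labels_txt(file.path(dir, "lab.txt")), labels)
  dat <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  st <- movie_stack(dat, 100, 50, c(0, 2, 4), "yfp")
  write_stack_txt(st, file.path(dir, "mv"))
  st2 <- read_stack_txt(file.path(dir, "mv"))
  expect_equal(st2$data, st$data, tolerance = 1e-12)
  expect_equal(st2$exposure_ms, 50)
  expect_equal(st2$timestamps_s, c(0, 2, 4))
  expect_equal(st2$channel, "yfp")
})

test_that("polygon outlines rasterise to the expected mask", {
  f <- tempfile(fileext = ".csv")
  # a 10x6 px axis-aligned rectangle: x in [4,14], y in [8,14]
  poly <- data.frame(cell = 1,
                     x_px = c(4, 14, 14, 4), y_px = c(8, 8, 14, 14))
  utils::write.csv(poly, f, row.names = FALSE)
  cs <- read_polygon_cells(f, c(32, 32), 100)
  expect_equal(nrow(cs$cells), 1)
  expect_equal(sum(cs$labels == 1), 10 * 6)
  expect_true(all(cs$labels[9:14, 5:14] == 1))
})

test_that("per-cell trajectories agree with mean_cell_intensity", {
  cfg <- quick_cfg(field_px = 64)
  sim <- generate_rapid_acquisition(cfg, "undamaged", n_cells = 3,
                                    n_frames = 5)
  tr <- per_cell_trajectories(sim$stack, sim$truth$cells)
  expect_equal(dim(tr$means), c(5, 3))
  expect_equal(tr$means[2, 1],
               mean_cell_intensity(sim$stack, sim$truth$cells,
                                   tr$cells[1], frame = 2))
})
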