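test_that("nearest-neighbour distances match the brute-force oracle", {
  a <- data.frame(cell = 1, x_nm = 0, y_nm = 0)
  b <- data.frame(cell = 1, x_nm = 150, y_nm = 0)
  expect_equal(nn_distances(a, b)$nn_nm, 150)
  # cell with no partner focus: unmatched, kept in the table
  a2 <- data.frame(cell = c(1, 2), x_nm = c(0, 0), y_nm = c(0, 0))
  nn <- nn_distances(a2, b)
  expect_equal(nn$matched, c(TRUE, FALSE))
  set.seed(71)
  fa <- data.frame(cell = sample(1:10, 1000, TRUE),
                   x_nm = runif(1000, 0, 5000), y_nm = runif(1000, 0, 5000))
  fb <- data.frame(cell = sample(1:10, 800, TRUE),
                   x_nm = runif(800, 0, 5000), y_nm = runif(800, 0, 5000))
  expect_equal(nn_distances(fa, fb)$nn_nm, oracle_nn(fa, fb))
})

test_that("equal-area shells: boundaries, 218 nm edge, CSR uniformity", {
  h <- equal_area_histogram(c(0), n_shells = 3)
  expect_equal(h$count, c(1, 0, 0))          # distance 0 in shell 1
  # a distance exactly on a shell boundary falls in the inner shell
  r1 <- sqrt(3e4 / pi)
  h2 <- equal_area_histogram(c(r1), n_shells = 3)
  expect_equal(h2$count[1], 1)
  # 218 nm is within shell 5; cumulative area 15e4 nm^2
  h3 <- equal_area_histogram(c(218), shell_area_nm2 = 3e4, n_shells = 6)
  expect_equal(which(h3$count == 1), 5)
  expect_equal(h3$outer_radius_nm[5], sqrt(15e4 / pi), tolerance = 1e-12)
  expect_equal(h3$outer_radius_nm[5], 218.5, tolerance = 1e-3)
  # CSR: uniform-in-disc distances fill equal-area shells uniformly
  set.seed(72)
  nsh <- 10
  R <- sqrt(nsh * 3e4 / pi)
  d <- R * sqrt(runif(10000))
  h4 <- equal_area_histogram(d, 3e4, n_shells = nsh)
  expect_equal(sum(h4$count) + attr(h4, "overflow"), 10000)
  expect_gt(stats::chisq.test(h4$count)$p.value, 0.01)
})

test_that("bidirectional fractions on worked examples", {
  one <- data.frame(cell = 1, x_nm = c(0, 500), y_nm = c(0, 0))
  rec <- colocalised_fractions(one, one, 200)
  expect_equal(rec$frac_A_with_B, 1)
  expect_equal(rec$frac_B_with_A, 1)
  a <- data.frame(cell = 1, x_nm = c(0, 1000, 5000), y_nm = c(0, 0, 5000))
  b <- data.frame(cell = 1, x_nm = c(150, 4000), y_nm = c(0, 0))
  rec2 <- colocalised_fractions(a, b, 200)
  expect_equal(rec2$frac_A_with_B, 1 / 3)
  expect_equal(rec2$frac_B_with_A, 1 / 2)
  expect_equal(rec2$se_A, sqrt((1 / 3) * (2 / 3) / 3))
  # zero foci in one channel: undefined, not zero
  none <- data.frame(cell = integer(0), x_nm = numeric(0),
                     y_nm = numeric(0))
  rec3 <- colocalised_fractions(none, b, 200)
  expect_true(is.na(rec3$frac_A_with_B))
  expect_true(rec3$undefined_A)
  expect_false(rec3$undefined_B)
})

test_that("colocalised fraction is monotone in radius and symmetric", {
  set.seed(73)
  fa <- data.frame(cell = sample(1:5, 200, TRUE),
                   x_nm = runif(200, 0, 4000), y_nm = runif(200, 0, 4000))
  fb <- data.frame(cell = sample(1:5, 200, TRUE),
                   x_nm = runif(200, 0, 4000), y_nm = runif(200, 0, 4000))
  fr <- vapply(c(50, 100, 200, 400, 800),
               function(r) colocalised_fractions(fa, fb, r)$frac_A_with_B, 0)
  expect_true(all(diff(fr) >= 0))
  rec <- colocalised_fractions(fa, fa, 200)
  expect_equal(rec$frac_A_with_B, rec$frac_B_with_A)
  expect_equal(rec$frac_A_with_B, 1)   # identical sets colocalise fully
})

test_that("chance level: disc algebra on hand-computable masks", {
  cs <- rect_cellset(25, 40)   # 10 um^2 rectangle
  none <- data.frame(cell = integer(0), x_nm = numeric(0), y_nm = numeric(0))
  expect_equal(chance_colocalisation(cs, none)$chance, 0)
  mid <- data.frame(cell = 1, x_nm = 2000, y_nm = 1250)
  ch <- chance_colocalisation(cs, mid, radius_nm = 200)
  expect_equal(ch$chance, pi * 0.2^2 / 10, tolerance = 0.01)
  # two coincident discs equal one disc (union, not sum)
  two <- rbind(mid, mid)
  expect_equal(chance_colocalisation(cs, two)$chance, ch$chance)
  expect_equal(chance_colocalisation(cs, two, method = "sum")$chance,
               2 * ch$chance)
  # disc overlapping the cell edge covers less area
  edge <- data.frame(cell = 1, x_nm = 50, y_nm = 1250)
  expect_lt(chance_colocalisation(cs, edge)$chance, ch$chance)
})

test_that("replicate aggregation reproduces hand-computed SEMs", {
  recs <- do.call(rbind, lapply(1:3, function(i)
    data.frame(time_min = c(0, 5), replicate = i,
               frac_A_with_B = c(0.10, c(0.08, 0.10, 0.12)[i]),
               frac_B_with_A = 0.05, se_A = 0.01, se_B = 0.01,
               chance = 0.04)))
  cv <- coloc_time_series(recs)
  expect_equal(cv$mean_frac_A_with_B, c(0.10, 0.10))
  expect_equal(cv$sem_A[1], 0)
  expect_equal(cv$sem_A[2], 0.02 / sqrt(3), tolerance = 1e-9)
  expect_equal(cv$mean_chance, c(0.04, 0.04))
})

test_that("CSR placement measures at chance; double labels are tight", {
  cfg <- sim_config(seed = 74)
  set.seed(74)
  cs <- simulate_cells(cfg, 20, field_px = 192)
  # CSR: measured fraction equals the chance level within binomial error
  tc <- simulate_two_colour_foci(cfg, cs, focus_density_per_um2 = 3,
                                 csr = TRUE)
  rec <- colocalised_fractions(tc$fociA, tc$fociB, 200)
  ch <- chance_colocalisation(cs, tc$fociB, 200)$chance
  expect_gt(rec$n_A, 80)
  expect_lt(abs(rec$frac_A_with_B - ch), 3 * sqrt(ch * (1 - ch) / rec$n_A))
  # doubly-labelled replisomes: both directions ~1 at 200 nm
  tc2 <- simulate_two_colour_foci(cfg, cs, double_label = TRUE)
  rec2 <- colocalised_fractions(tc2$fociA, tc2$fociB, 200)
  expect_gt(rec2$frac_A_with_B, 0.97)
  expect_gt(rec2$frac_B_with_A, 0.97)
})

test_that("a loose component broadens the distance histogram (KS)", {
  cfg_t <- sim_config(f_tight = 1, f_loose = 0, f_dispersed = 0, seed = 75)
  cfg_l <- sim_config(f_tight = 0, f_loose = 1, f_dispersed = 0,
                      loose_offset_sigma_nm = 300, seed = 75)
  set.seed(75)
  cs <- simulate_cells(cfg_t, 25, field_px = 224)
  set.seed(76)
  tight <- simulate_two_colour_foci(cfg_t, cs, focus_density_per_um2 = 3)
  loose <- simulate_two_colour_foci(cfg_l, cs, focus_density_per_um2 = 3)
  d_t <- nn_distances(tight$fociA, tight$fociB)$nn_nm
  d_l <- nn_distances(loose$fociA, loose$fociB)$nn_nm
  expect_gt(length(d_t), 100)
  # tight-only distances stay within ~220 nm shells
  expect_gt(mean(d_t <= 220, na.rm = TRUE), 0.95)
  ks <- stats::ks.test(d_t, d_l)
  expect_lt(ks$p.value, 0.01)
  expect_gt(stats::median(d_l, na.rm = TRUE),
            stats::median(d_t, na.rm = TRUE))
})
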