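# Independent oracles and small fixtures shared across test files.

# small, fast configuration for image-based tests (overridable defaults)
quick_cfg <- function(...) {
  args <- utils::modifyList(list(field_px = 96, n_frames_rapid = 40,
                                 seed = 1), list(...))
  do.call(sim_config, args)
}

# exhaustive-search change-point oracle: minimise RSS + beta * k over all
# placements of k = 0..kmax change points (a change point after index i
# splits y[1..i] | y[(i+1)..n])
oracle_changepoints <- function(y, beta, kmax = 3) {
  n <- length(y)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  segrss <- function(a, b)   # RSS of y[a..b] around its mean, O(1)
    (cs2[b + 1] - cs2[a]) - (cs[b + 1] - cs[a])^2 / (b - a + 1)
  best <- list(obj = segrss(1, n), cp = integer(0))
  for (k in seq_len(kmax)) {
    if (k > n - 1) break
    combs <- utils::combn(n - 1, k)
    for (j in seq_len(ncol(combs))) {
      cp <- combs[, j]
      bounds <- c(0, cp, n)
      obj <- k * beta + sum(segrss(bounds[-length(bounds)] + 1, bounds[-1]))
      if (obj < best$obj - 1e-9) best <- list(obj = obj, cp = cp)
    }
  }
  best
}

# brute-force nearest-neighbour distances (same-cell pairs only)
oracle_nn <- function(fociA, fociB) {
  vapply(seq_len(nrow(fociA)), function(i) {
    ib <- which(fociB$cell == fociA$cell[i])
    if (!length(ib)) return(NA_real_)
    min(sqrt((fociB$x_nm[ib] - fociA$x_nm[i])^2 +
             (fociB$y_nm[ib] - fociA$y_nm[i])^2))
  }, 0)
}

# photobleaching trace of a focus holding n_mol fluorophores: level drops
# by one single-molecule intensity at each (exponential) bleaching time
sim_step_trace <- function(n_mol = 2, I = 1850, snr = 5, n = 300,
                           dt = 0.034, tau = 6) {
  bt <- stats::rexp(n_mol, 1 / tau)
  lev <- vapply(seq_len(n) * dt, function(t) sum(bt > t), 0) * I
  list(y = lev + stats::rnorm(n, 0, I / snr),
       true_steps = sum(bt < n * dt))
}

# one-cell cell_set covering a rows x cols rectangle (for photometry tests)
rect_cellset <- function(rows, cols, pixel_size_nm = 100) {
  labels <- matrix(1L, rows, cols)
  cells_from_labels(labels, pixel_size_nm)
}
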