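# Frame rendering and photobleaching for the synthetic-movie generator.
#
# Photometric model: one fluorophore integrates to I_single a.u. at the
# reference exposure; intensities scale linearly with exposure. Bound
# molecules render as pixel-integrated 2D Gaussians (PSF), free molecules as
# motion-blurred Brownian smears (or, on the cell scale, a uniform in-cell
# haze), autofluorescence as a uniform in-cell signal. The detector adds a
# constant electronic offset, Poisson shot noise on the signal and Gaussian
# read noise, and clips at the bit depth.

# add a pixel-integrated isotropic Gaussian of given integral to img
.add_psf <- function(img, x_nm, y_nm, integral, sigma_px, psz) {
  s_nm <- sigma_px * psz
  hw <- ceiling(6 * sigma_px) + 1L
  c_mid <- floor(x_nm / psz) + 1L
  r_mid <- floor(y_nm / psz) + 1L
  c0 <- max(1L, c_mid - hw); c1 <- min(ncol(img), c_mid + hw)
  r0 <- max(1L, r_mid - hw); r1 <- min(nrow(img), r_mid + hw)
  if (c0 > c1 || r0 > r1) return(img)   # stamp entirely off-field
  cc <- c0:c1
  rr <- r0:r1
  wx <- stats::pnorm((cc * psz - x_nm) / s_nm) -
        stats::pnorm(((cc - 1) * psz - x_nm) / s_nm)
  wy <- stats::pnorm((rr * psz - y_nm) / s_nm) -
        stats::pnorm(((rr - 1) * psz - y_nm) / s_nm)
  img[rr, cc] <- img[rr, cc] + integral * (wy %o% wx)
  img
}

# detector stage: offset + shot noise + read noise + clipping
.detect <- function(signal, cfg, noise = TRUE) {
  if (noise) {
    out <- cfg$camera_offset +
      matrix(stats::rpois(length(signal), pmax(signal, 0)), nrow(signal)) +
      matrix(stats::rnorm(length(signal), 0, cfg$read_noise_sd), nrow(signal))
  } else {
    out <- cfg$camera_offset + signal
  }
  pmin(pmax(out, 0), 2^cfg$bit_depth - 1)
}

#' Render one fluorescence frame from molecule ground truth
#'
#' Bound (non-free, unbleached) molecules are rendered as pixel-integrated
#' 2D Gaussian PSFs whose integral is \code{I_single} scaled linearly by
#' \code{exposure_ms / reference_exposure_ms}. Free molecules are rendered
#' either as sub-stepped Brownian smears (\code{free_mode = "substep"},
#' \code{free_substeps} stamps of 1/substeps weight each along a random
#' walk with \code{D_free}) or as a uniform haze over their cell mask
#' (\code{free_mode = "uniform"}; with D_free = 100 um^2/s the per-frame RMS
#' displacement of ~3.7 um exceeds a cell, so the smear is uniform on the
#' cell scale). Autofluorescence adds \code{af_scale *
#' autofluor_amplitude} (exposure-scaled) to every cell pixel. The detector
#' then applies offset, shot noise, read noise and bit-depth clipping.
#'
#' @param molecules data.frame from [place_molecules()]; rows with
#'   \code{bleached = TRUE} (if the column exists) are skipped.
#' @param cellset the \code{cell_set} the molecules live in.
#' @param cfg a [sim_config()].
#' @param channel "yfp" or "red" (selects the single-fluorophore intensity).
#' @param exposure_ms exposure, ms (> 0).
#' @param noise apply shot/read noise (default TRUE).
#' @param free_mode "substep" or "uniform" (see above).
#' @param af_scale multiplier on the autofluorescence amplitude (used to
#'   decay it across a movie); default 1.
#' @return A numeric image matrix, same shape as the cell labels.
#' @export
render_frame <- function(molecules, cellset, cfg, channel = "yfp",
                         exposure_ms = cfg$reference_exposure_ms,
                         noise = TRUE,
                         free_mode = c("substep", "uniform"),
                         af_scale = 1) {
  stopifnot(exposure_ms > 0)
  free_mode <- match.arg(free_mode)
  psz <- cfg$pixel_size_nm
  labels <- cellset$labels
  sig <- matrix(0, nrow(labels), ncol(labels))
  sc <- exposure_ms / cfg$reference_exposure_ms
  I1 <- if (channel == "red") cfg$I_single_red else cfg$I_single
  I <- I1 * sc
  if (nrow(molecules)) {
    vis <- if ("bleached" %in% names(molecules)) !molecules$bleached
           else rep(TRUE, nrow(molecules))
    bound <- vis & molecules$state != "free"
    for (i in which(bound))
      sig <- .add_psf(sig, molecules$x_nm[i], molecules$y_nm[i], I,
                      cfg$psf_sigma_px, psz)
    freei <- which(vis & molecules$state == "free")
    if (length(freei)) {
      if (free_mode == "substep") {
        ns <- cfg$free_substeps
        step_sd <- sqrt(2 * cfg$D_free * (exposure_ms / 1000) / ns) * 1000
        for (i in freei) {
          x <- molecules$x_nm[i] + cumsum(stats::rnorm(ns, 0, step_sd))
          y <- molecules$y_nm[i] + cumsum(stats::rnorm(ns, 0, step_sd))
          for (k in seq_len(ns))
            sig <- .add_psf(sig, x[k], y[k], I / ns, cfg$psf_sigma_px, psz)
        }
      } else {
        haze <- matrix(0, nrow(labels), ncol(labels))
        per_cell <- table(factor(molecules$cell[freei],
                                 levels = cellset$cells$cell))
        for (j in seq_len(nrow(cellset$cells))) {
          nfree <- as.numeric(per_cell[j])
          if (nfree == 0) next
          id <- cellset$cells$cell[j]
          idx <- cellset$labels == id
          haze[idx] <- haze[idx] + nfree * I / cellset$cells$area_px[j]
        }
        # in-cell haze is itself imaged through the PSF, so it spills
        # beyond the outline like any other emission
        sig <- sig + .blur_gaussian_raw(haze, cfg$psf_sigma_px)
      }
    }
  }
  if (cfg$autofluor_amplitude > 0 && af_scale > 0) {
    af <- matrix(0, nrow(labels), ncol(labels))
    af[labels > 0] <- cfg$autofluor_amplitude * sc * af_scale
    sig <- sig + .blur_gaussian_raw(af, cfg$psf_sigma_px)
  }
  .detect(sig, cfg, noise)
}

#' Brownian position track of a molecule
#'
#' Frame-to-frame positions of a molecule diffusing with coefficient
#' \code{D}: per-axis displacements are N(0, 2 D dt), so the RMS planar
#' step is \eqn{\sqrt{4 D \Delta t}}. Used for the ground-truth motion of
#' DNA-bound molecules (D ~ 1e-5 um^2/s, i.e. ~1 nm per 34 ms frame —
#' far below the pixel size, which is why rendering treats bound molecules
#' as static) and for the channel-lag jitter of replisome sites.
#'
#' @param x0_nm,y0_nm start position, nm.
#' @param D diffusion coefficient, um^2/s.
#' @param dt_s time step, s.
#' @param n_steps number of steps.
#' @return data.frame with \code{n_steps + 1} rows: step, x_nm, y_nm.
#' @export
diffusion_track <- function(x0_nm, y0_nm, D, dt_s, n_steps) {
  sd_nm <- sqrt(2 * D * dt_s) * 1000
  data.frame(step = 0:n_steps,
             x_nm = x0_nm + c(0, cumsum(stats::rnorm(n_steps, 0, sd_nm))),
             y_nm = y0_nm + c(0, cumsum(stats::rnorm(n_steps, 0, sd_nm))))
}

#' Draw photobleaching times and transient return events
#'
#' Each fluorophore's bleaching time is exponential with mean
#' \code{tau_bleach_s}, counted in \emph{illuminated} time (continuous
#' excitation in rapid acquisitions makes illuminated time equal to movie
#' time). After bleaching, a fluorophore may transiently return to the
#' bright state at \code{return_rate} events per illuminated second; each
#' return lasts a single frame.
#'
#' @param molecules data.frame from [place_molecules()].
#' @param cfg a [sim_config()].
#' @param n_frames number of frames in the illumination schedule.
#' @param frame_interval_s illuminated time per frame, s.
#' @return \code{molecules} with columns \code{bleach_time_s} (illuminated
#'   time) and \code{bleach_frame} (first frame in which the molecule is
#'   dark; \code{n_frames + 1} if it survives the movie), plus an attribute
#'   \code{"return_events"}: data.frame (row = one single-frame return)
#'   with columns \code{mol_row}, \code{frame}.
#' @export
simulate_bleaching <- function(molecules, cfg, n_frames = cfg$n_frames_rapid,
                               frame_interval_s = cfg$frame_interval_s) {
  n <- nrow(molecules)
  bt <- if (is.finite(cfg$tau_bleach_s))
    stats::rexp(n, 1 / cfg$tau_bleach_s) else rep(Inf, n)
  bf <- pmin(floor(bt / frame_interval_s) + 1L, n_frames + 1L)
  molecules$bleach_time_s <- bt
  molecules$bleach_frame <- as.integer(bf)
  ev <- data.frame(mol_row = integer(0), frame = integer(0))
  if (cfg$return_rate > 0 && n > 0) {
    nrem <- pmax(n_frames - molecules$bleach_frame + 1L, 0L)
    p <- min(cfg$return_rate * frame_interval_s, 1)
    k <- stats::rbinom(n, nrem, p)
    for (i in which(k > 0)) {
      fr <- molecules$bleach_frame[i] - 1L +
        sort(sample.int(nrem[i], k[i]))
      ev <- rbind(ev, data.frame(mol_row = i, frame = fr))
    }
  }
  attr(molecules, "return_events") <- ev
  molecules
}

#' Generate a rapid-acquisition photobleaching movie
#'
#' Simulates a field of cells, draws per-cell molecule counts from the
#' expression curve, assigns binding classes and positions, draws bleaching
#' times under continuous excitation, and renders every frame (default
#' 300 x 34 ms). Rendering is event-driven: the noise-free bound-molecule
#' image is updated only when a molecule bleaches or transiently returns,
#' free molecules contribute a per-cell uniform haze (or sub-stepped smears),
#' and autofluorescence decays with \code{tau_autofluor_s}; detector noise
#' is drawn fresh per frame.
#'
#' @param cfg a [sim_config()]; \code{cfg$seed} fixes all randomness.
#' @param scenario one of \code{"undamaged"} (baseline expression),
#'   \code{"damage"} (expression and filamentation at \code{t_min} after
#'   treatment), \code{"dead"} (catalytically dead analogue: same expression
#'   but no DNA binding, all molecules free), \code{"noise_only"} (no
#'   molecules at all).
#' @param n_cells cells to simulate.
#' @param t_min minutes after damage (used by "damage"/"dead"; default 120).
#' @param field_px field edge, px.
#' @param free_mode free-molecule rendering mode (default "uniform"; see
#'   [render_frame()]).
#' @param noise apply detector noise (default TRUE).
#' @param n_frames number of frames (default from config).
#' @return A list of class \code{sim_rapid}: \code{stack} (a
#'   [movie_stack()]), \code{brightfield} (single-frame synthetic
#'   bright-field stack for segmentation), \code{truth} (list: \code{cells}
#'   the \code{cell_set}, \code{molecules} with states and bleach times,
#'   \code{sites}, \code{return_events}), and \code{config}.
#' @export
generate_rapid_acquisition <- function(cfg,
                                       scenario = c("undamaged", "damage",
                                                    "dead", "noise_only"),
                                       n_cells = 20,
                                       t_min = NULL,
                                       field_px = cfg$field_px,
                                       free_mode = "uniform",
                                       noise = TRUE,
                                       n_frames = cfg$n_frames_rapid) {
  scenario <- match.arg(scenario)
  if (is.null(t_min))
    t_min <- if (scenario %in% c("damage", "dead")) 120 else 0
  withr::with_seed(cfg$seed, {
    cells <- simulate_cells(cfg, n_cells, t_min, field_px)
    sites <- place_replisomes(cells, cfg)
    nexp <- if (scenario == "noise_only") 0 else
      expression_time_course(cfg, t_min)
    npc <- stats::rpois(n_cells, nexp)
    cfg_use <- cfg
    if (scenario == "dead") {  # no DNA binding at all
      cfg_use$f_tight <- cfg_use$f_loose <- cfg_use$f_dispersed <- 0
    }
    mol <- place_molecules(cells, npc, cfg_use, sites, t_min)
    mol <- simulate_bleaching(mol, cfg, n_frames, cfg$frame_interval_s)
    ev <- attr(mol, "return_events")
    .render_rapid(mol, ev, cells, cfg, n_frames, free_mode, noise,
                  sites = sites)
  })
}

# event-driven renderer shared by generate_rapid_acquisition
.render_rapid <- function(mol, ev, cells, cfg, n_frames, free_mode, noise,
                          sites = NULL) {
  psz <- cfg$pixel_size_nm
  labels <- cells$labels
  dimn <- dim(labels)
  dt <- cfg$frame_interval_s
  I <- cfg$I_single * dt * 1000 / cfg$reference_exposure_ms
  bound <- which(mol$state != "free")
  free <- which(mol$state == "free")
  # initial bound-signal image: all bound molecules alive in frame 1
  bimg <- matrix(0, dimn[1], dimn[2])
  for (i in bound[mol$bleach_frame[bound] > 1L])
    bimg <- .add_psf(bimg, mol$x_nm[i], mol$y_nm[i], I, cfg$psf_sigma_px, psz)
  # per-frame free-molecule counts per cell
  cids <- cells$cells$cell
  # per-cell PSF-blurred mask patch: the in-cell haze (free molecules,
  # autofluorescence) is imaged through the PSF and spills beyond the
  # outline; cached once since cells are static
  pad <- ceiling(6 * cfg$psf_sigma_px) + 1L
  patches <- lapply(seq_along(cids), function(j) {
    idx <- which(labels == cids[j], arr.ind = TRUE)
    r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(dimn[1], max(idx[, 1]) + pad)
    c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(dimn[2], max(idx[, 2]) + pad)
    ind <- matrix(0, r1 - r0 + 1L, c1 - c0 + 1L)
    ind[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- 1
    list(rr = r0:r1, cc = c0:c1,
         blur = .blur_gaussian_raw(ind, cfg$psf_sigma_px))
  })
  frames <- array(0, c(dimn[1], dimn[2], n_frames))
  add_ev <- split(ev$mol_row, ev$frame)
  for (k in seq_len(n_frames)) {
    if (k > 1) {
      died <- bound[mol$bleach_frame[bound] == k]
      for (i in died)
        bimg <- .add_psf(bimg, mol$x_nm[i], mol$y_nm[i], -I,
                         cfg$psf_sigma_px, psz)
    }
    sig <- bimg
    rows <- add_ev[[as.character(k)]]
    for (i in rows) {  # transient single-frame returns (bound molecules
      if (mol$state[i] == "free") next  # only; a free return is a blur)
      sig <- .add_psf(sig, mol$x_nm[i], mol$y_nm[i], I, cfg$psf_sigma_px, psz)
    }
    t_ill <- (k - 1) * dt
    af <- cfg$autofluor_amplitude * (dt * 1000 / cfg$reference_exposure_ms) *
      exp(-t_ill / cfg$tau_autofluor_s)
    alive_free <- free[mol$bleach_frame[free] > k]
    if (free_mode == "substep" && length(alive_free)) {
      ns <- cfg$free_substeps
      step_sd <- sqrt(2 * cfg$D_free * dt / ns) * 1000
      for (i in alive_free) {
        x <- mol$x_nm[i] + cumsum(stats::rnorm(ns, 0, step_sd))
        y <- mol$y_nm[i] + cumsum(stats::rnorm(ns, 0, step_sd))
        for (s in seq_len(ns))
          sig <- .add_psf(sig, x[s], y[s], I / ns, cfg$psf_sigma_px, psz)
      }
    }
    nf <- if (free_mode == "uniform" && length(alive_free))
      tabulate(match(mol$cell[alive_free], cids), length(cids))
    else rep(0, length(cids))
    for (j in seq_along(cids)) {   # per-cell haze: uniform free + autofluor
      amp <- af + nf[j] * I / cells$cells$area_px[j]
      if (amp == 0) next
      p <- patches[[j]]
      sig[p$rr, p$cc] <- sig[p$rr, p$cc] + amp * p$blur
    }
    frames[, , k] <- .detect(sig, cfg, noise)
  }
  stack <- movie_stack(frames, psz, dt * 1000,
                       (seq_len(n_frames) - 1) * dt, "yfp")
  bf <- movie_stack(.render_brightfield(cells, cfg), psz,
                    cfg$exposure_bf_ms, -1, "bf")
  structure(list(stack = stack, brightfield = bf,
                 truth = list(cells = cells, molecules = mol,
                              sites = sites, return_events = ev),
                 config = cfg),
            class = "sim_rapid")
}

# synthetic bright-field: inverted soft-edged mask (cells dark on light
# background), enough for the simple threshold segmenter
.render_brightfield <- function(cellset, cfg, noise = TRUE) {
  base <- 1000
  depth <- 400
  img <- matrix(base, nrow(cellset$labels), ncol(cellset$labels))
  incell <- cellset$labels > 0
  img[incell] <- base - depth
  img <- .blur_gaussian(img, 1)   # soft edges
  if (noise)
    img <- img + matrix(stats::rnorm(length(img), 0, 5), nrow(img))
  img
}

#' Generate a two-colour time-lapse series
#'
#' At each time point (default every 5 min for 3 h, i.e. 37 points) three
#' images are recorded: synthetic bright-field (34 ms), yellow channel
#' (50 ms) and red channel (100 ms), the two fluorescence channels offset by
#' \code{channel_lag_s}. Cells keep their identity and placement across the
#' series and filament according to the growth law in the damage scenario;
#' per-cell molecule numbers are resampled at each point from the
#' expression curve (synthesis and exchange between points outpace the
#' ~50 ms of illumination per point, so no cumulative photobleaching is
#' applied). The red channel shows the replisome sites. Site positions in
#' the red channel are jittered by bound-site diffusion over the channel
#' lag.
#'
#' @param cfg a [sim_config()]; \code{cfg$seed} fixes all randomness.
#' @param scenario "undamaged" (constant baseline expression, no growth) or
#'   "damage" (treatment at t = 0).
#' @param n_cells cells to simulate.
#' @param field_px field edge, px.
#' @param noise apply detector noise (default TRUE).
#' @return A list of class \code{sim_timelapse}: \code{time_min} (vector of
#'   time points), \code{points} (one list per time point: \code{t_min},
#'   \code{cells}, \code{stacks} = list(bf, yfp, red) of single-frame
#'   [movie_stack()]s, \code{molecules}, \code{sites}), and \code{config}.
#' @export
generate_timelapse <- function(cfg, scenario = c("undamaged", "damage"),
                               n_cells = 20, field_px = cfg$field_px,
                               noise = TRUE) {
  scenario <- match.arg(scenario)
  tps <- seq(0, cfg$timelapse_duration_min, by = cfg$timelapse_interval_min)
  withr::with_seed(cfg$seed, {
    # reserve space at the final (filamented) size so growth never overlaps
    t_reserve <- if (scenario == "damage") cfg$timelapse_duration_min else 0
    final <- simulate_cells(cfg, n_cells, t_reserve, field_px)
    base_geom <- final$cells
    gf_final <- .growth_volume_factor(cfg, t_reserve)
    pts <- vector("list", length(tps))
    for (j in seq_along(tps)) {
      t <- tps[j]
      gf <- if (scenario == "damage") .growth_volume_factor(cfg, t) else 1
      cells_t <- .regrow_cells(final, base_geom, cfg, gf, gf_final)
      sites <- place_replisomes(cells_t, cfg)
      nexp <- if (scenario == "damage")
        expression_time_course(cfg, t) else cfg$N_baseline
      npc <- stats::rpois(n_cells, nexp)
      mol <- place_molecules(cells_t, npc, cfg, sites,
                             t_min = if (scenario == "damage") t else 0)
      bf <- .render_brightfield(cells_t, cfg, noise)
      yfp <- render_frame(mol, cells_t, cfg, "yfp", cfg$exposure_yfp_ms,
                          noise, free_mode = "uniform")
      jit <- sqrt(2 * cfg$D_bound * cfg$channel_lag_s) * 1000
      sites_red <- sites
      sites_red$x_nm <- sites$x_nm + stats::rnorm(nrow(sites), 0, jit)
      sites_red$y_nm <- sites$y_nm + stats::rnorm(nrow(sites), 0, jit)
      repmol <- data.frame(cell = sites_red$cell, mol = seq_len(nrow(sites_red)),
                           x_nm = sites_red$x_nm, y_nm = sites_red$y_nm,
                           state = "tight")
      red <- render_frame(repmol, cells_t, cfg, "red", cfg$exposure_red_ms,
                          noise, free_mode = "uniform")
      t0 <- t * 60
      mk <- function(img, exp_ms, ts, ch)
        movie_stack(img, cfg$pixel_size_nm, exp_ms, ts, ch)
      pts[[j]] <- list(
        t_min = t, cells = cells_t,
        stacks = list(bf = mk(bf, cfg$exposure_bf_ms, t0, "bf"),
                      yfp = mk(yfp, cfg$exposure_yfp_ms, t0 + cfg$channel_lag_s, "yfp"),
                      red = mk(red, cfg$exposure_red_ms, t0 + 2 * cfg$channel_lag_s, "red")),
        molecules = mol, sites = sites,
        sites_red = sites_red)
    }
    structure(list(time_min = tps, points = pts, config = cfg),
              class = "sim_timelapse")
  })
}

# re-rasterise cells of a placed field at an earlier growth stage
.regrow_cells <- function(final, base_geom, cfg, gf, gf_final) {
  psz <- final$pixel_size_nm
  n1 <- nrow(final$labels); n2 <- ncol(final$labels)
  labels <- matrix(0L, n1, n2)
  cells <- base_geom
  for (i in seq_len(nrow(base_geom))) {
    g <- base_geom[i, ]
    v_final <- cell_volume(g$length_um, g$width_um)
    v0 <- v_final / gf_final
    L <- .length_for_volume(v0 * gf, g$width_um)
    px <- .rasterise_rod(g$cx_nm, g$cy_nm, g$angle_rad, L * 1000,
                         g$width_um * 1000, psz, n1, n2)
    labels[(px[, "col"] - 1L) * n1 + px[, "row"]] <- g$cell
    cells$length_um[i] <- L
    cells$area_px[i] <- nrow(px)
    cells$area_um2[i] <- nrow(px) * (psz / 1000)^2
    cells$volume_fl[i] <- cell_volume(L, g$width_um)
  }
  structure(list(labels = labels, cells = cells, pixel_size_nm = psz),
            class = "cell_set")
}

#' Simulate two-colour focus positions directly from ground truth
#'
#' A light-weight path for colocalisation statistics that skips image
#' rendering and fitting: replisome sites form the red-channel foci, and
#' per-cell yellow-channel focus sites are drawn with the (time-effective)
#' tight/loose/dispersed class weights (free molecules do not form foci).
#' Both channels receive isotropic localisation noise
#' (\code{loc_noise_nm} per axis), and the red channel additionally the
#' bound-site diffusion jitter accumulated over the channel lag.
#'
#' Uses the R random number stream; wrap in [withr::with_seed()] for
#' reproducibility.
#'
#' @param cfg a [sim_config()].
#' @param cellset a \code{cell_set} (e.g. from [simulate_cells()]).
#' @param t_min minutes after damage (controls the late-stage switch).
#' @param focus_density_per_um2 expected yellow foci per um^2 of cell area
#'   (default 0.5); the per-cell count is Poisson.
#' @param csr if TRUE, ignore class weights and place the yellow foci
#'   completely spatially randomly (uniform in each cell) — the null used to
#'   calibrate chance colocalisation.
#' @param double_label if TRUE, emulate a doubly-labelled-replisome strain:
#'   both channels mark every replisome site and differ only by
#'   localisation noise and channel-lag jitter (the tight-colocalisation
#'   control).
#' @return list: \code{fociA} (yellow; data.frame cell, x_nm, y_nm),
#'   \code{fociB} (red), \code{sites} (true replisome positions).
#' @export
simulate_two_colour_foci <- function(cfg, cellset, t_min = 0,
                                     focus_density_per_um2 = 0.5,
                                     csr = FALSE, double_label = FALSE) {
  sites <- place_replisomes(cellset, cfg)
  if (double_label) {
    ln <- cfg$loc_noise_nm
    jit <- sqrt(2 * cfg$D_bound * cfg$channel_lag_s) * 1000
    n <- nrow(sites)
    fociA <- data.frame(cell = sites$cell,
                        x_nm = sites$x_nm + stats::rnorm(n, 0, ln),
                        y_nm = sites$y_nm + stats::rnorm(n, 0, ln))
    fociB <- data.frame(cell = sites$cell,
                        x_nm = sites$x_nm + stats::rnorm(n, 0, jit) +
                          stats::rnorm(n, 0, ln),
                        y_nm = sites$y_nm + stats::rnorm(n, 0, jit) +
                          stats::rnorm(n, 0, ln))
    return(list(fociA = fociA, fociB = fociB, sites = sites))
  }
  fr <- effective_fractions(cfg, t_min)
  wb <- fr[c("tight", "loose", "dispersed")]
  if (sum(wb) <= 0 && !csr)
    stop("simulate_two_colour_foci: all bound-class fractions are zero")
  outA <- vector("list", nrow(cellset$cells))
  for (i in seq_len(nrow(cellset$cells))) {
    cl <- cellset$cells[i, ]
    k <- stats::rpois(1, focus_density_per_um2 * cl$area_um2)
    if (k == 0) next
    if (csr) {
      xy <- .uniform_in_mask(cellset, cl$cell, k)
      outA[[i]] <- data.frame(cell = cl$cell, x_nm = xy[, 1], y_nm = xy[, 2])
      next
    }
    st <- sample(names(wb), k, replace = TRUE, prob = wb)
    xy <- matrix(NA_real_, k, 2)
    sit <- st %in% c("tight", "loose")
    if (any(sit)) {
      s <- sites[sites$cell == cl$cell, , drop = FALSE]
      pick <- s[sample.int(nrow(s), sum(sit), replace = TRUE), ]
      xy[sit, 1] <- pick$x_nm; xy[sit, 2] <- pick$y_nm
      lo <- which(st == "loose")
      if (length(lo)) {
        xy[lo, 1] <- xy[lo, 1] + stats::rnorm(length(lo), 0, cfg$loose_offset_sigma_nm)
        xy[lo, 2] <- xy[lo, 2] + stats::rnorm(length(lo), 0, cfg$loose_offset_sigma_nm)
      }
    }
    disp <- which(!sit)
    if (length(disp))
      xy[disp, ] <- .uniform_in_mask(cellset, cl$cell, length(disp))
    outA[[i]] <- data.frame(cell = cl$cell, x_nm = xy[, 1], y_nm = xy[, 2])
  }
  fociA <- do.call(rbind, outA)
  if (is.null(fociA))
    fociA <- data.frame(cell = integer(0), x_nm = numeric(0), y_nm = numeric(0))
  jit <- sqrt(2 * cfg$D_bound * cfg$channel_lag_s) * 1000
  fociB <- data.frame(cell = sites$cell,
                      x_nm = sites$x_nm + stats::rnorm(nrow(sites), 0, jit),
                      y_nm = sites$y_nm + stats::rnorm(nrow(sites), 0, jit))
  ln <- cfg$loc_noise_nm
  if (ln > 0) {
    fociA$x_nm <- fociA$x_nm + stats::rnorm(nrow(fociA), 0, ln)
    fociA$y_nm <- fociA$y_nm + stats::rnorm(nrow(fociA), 0, ln)
    fociB$x_nm <- fociB$x_nm + stats::rnorm(nrow(fociB), 0, ln)
    fociB$y_nm <- fociB$y_nm + stats::rnorm(nrow(fociB), 0, ln)
  }
  list(fociA = fociA, fociB = fociB, sites = sites)
}
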