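# Pipeline orchestration: simulate -> correct -> segment -> detect ->
# quantify -> colocalise, with manifest, logging and summary statistics.

#' Summary statistics in the mean +/- SEM reporting convention
#'
#' @param x numeric vector (n >= 1).
#' @return list: mean, sd (n-1 denominator), sem (sd/sqrt(n)), n. With a
#'   single value, sd and sem are NA and \code{degenerate} is TRUE.
#' @examples
#' summarise_values(c(1, 2, 3))   # mean 2, sd 1, sem 0.577
#' @export
summarise_values <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n == 0) stop("summarise_values: no values")
  s <- if (n > 1) stats::sd(x) else NA_real_
  list(mean = mean(x), sd = s,
       sem = if (n > 1) s / sqrt(n) else NA_real_,
       n = n, degenerate = n == 1)
}

#' Standard error of a proportion
#'
#' @param k successes; @param n trials (> 0).
#' @return list: p, se = sqrt(p(1-p)/n), n.
#' @export
summarise_proportion <- function(k, n) {
  if (n <= 0) stop("summarise_proportion: n must be > 0")
  p <- k / n
  list(p = p, se = sqrt(p * (1 - p) / n), n = n)
}

#' Single-molecule calibration from the late frames of a bleaching movie
#'
#' After a few bleaching lifetimes most fluorophores are dark and
#' transient, single-frame focus appearances are individual molecules
#' returning to the bright state. The late frames are scanned with
#' [detect_peaks()]; a candidate qualifies as a return event only if no
#' focus was detected within \code{match_radius_nm} of its position in the
#' previous or next frame (persistent foci — surviving fluorophores — are
#' thereby excluded). Qualifying events are fitted with
#' [fit_gaussian_2d()] and the integrated intensities fed to
#' [calibrate_single_molecule()].
#'
#' @param sim a \code{sim_rapid} from [generate_rapid_acquisition()].
#' @param cellset segmentation to restrict detection to cells (defaults to
#'   the ground-truth masks carried by the simulation).
#' @param after_lifetimes start scanning after this many bleaching
#'   lifetimes of illuminated time (default 3).
#' @param threshold_sd detection threshold (default 5).
#' @param match_radius_nm radius used to decide whether a candidate was
#'   already present in an adjacent frame (default 300).
#' @param min_events passed to [calibrate_single_molecule()].
#' @return A \code{calibration_constant} (intensities scaled to the
#'   configuration's reference exposure).
#' @export
calibrate_from_movie <- function(sim, cellset = sim$truth$cells,
                                 after_lifetimes = 3, threshold_sd = 5,
                                 match_radius_nm = 300, min_events = 30) {
  cfg <- sim$config
  stack <- correct_offset_and_flatten(sim$stack, cfg$camera_offset)
  k0 <- ceiling(after_lifetimes * cfg$tau_bleach_s / cfg$frame_interval_s)
  nk <- n_frames(stack)
  if (k0 + 2 > nk)
    stop("calibrate_from_movie: movie shorter than ", after_lifetimes,
         " bleaching lifetimes")
  cand <- vector("list", nk)
  for (k in k0:nk)
    cand[[k]] <- detect_peaks(stack$data[, , k], cellset,
                              threshold_sd = threshold_sd,
                              psf_sigma_px = cfg$psf_sigma_px,
                              pixel_size_nm = cfg$pixel_size_nm)
  has_neighbour <- function(x, y, other) {
    if (is.null(other) || nrow(other) == 0) return(FALSE)
    any((other$x_nm - x)^2 + (other$y_nm - y)^2 <= match_radius_nm^2)
  }
  roi_val <- function(k, r, c) {
    v <- try(local_background_correct(stack$data[, , k], r, c, roi = 5L),
             silent = TRUE)
    if (inherits(v, "try-error")) NA_real_ else v$corrected
  }
  ints <- numeric(0)
  for (k in (k0 + 1):(nk - 1)) {
    ck <- cand[[k]]
    if (nrow(ck) == 0) next
    bgsub <- NULL
    for (i in seq_len(nrow(ck))) {
      if (has_neighbour(ck$x_nm[i], ck$y_nm[i], cand[[k - 1]])) next
      if (has_neighbour(ck$x_nm[i], ck$y_nm[i], cand[[k + 1]])) next
      # photometric transience check: a true single-frame return carries no
      # intensity at this position in the adjacent frames, whereas a
      # persistent focus flickering around the detection threshold does
      v0 <- roi_val(k, ck$row[i], ck$col[i])
      vm <- roi_val(k - 1, ck$row[i], ck$col[i])
      vp <- roi_val(k + 1, ck$row[i], ck$col[i])
      if (!is.finite(v0) || !is.finite(vm) || !is.finite(vp)) next
      if (v0 <= 0 || vm > 0.5 * v0 || vp > 0.5 * v0) next
      # temporal background subtraction: the adjacent frames hold the same
      # cellular background (autofluorescence, unbound haze) without the
      # single-frame event, so the difference isolates the molecule
      if (is.null(bgsub))
        bgsub <- stack$data[, , k] -
          (stack$data[, , k - 1] + stack$data[, , k + 1]) / 2
      f <- fit_gaussian_2d(bgsub, ck$row[i], ck$col[i],
                           pixel_size_nm = cfg$pixel_size_nm)
      if (f$status == "ok") ints <- c(ints, f$integrated_au)
    }
  }
  # frames share the rapid-acquisition exposure = reference exposure
  scale <- cfg$reference_exposure_ms / (cfg$frame_interval_s * 1000)
  calibrate_single_molecule(ints * scale, min_events = min_events,
                            reference_exposure_ms = cfg$reference_exposure_ms,
                            label = "YPet")
}

#' Per-cell copy numbers and concentrations from a bleaching movie
#'
#' The copy-number pipeline on one rapid acquisition: offset correction,
#' per-cell mean-intensity decays, two-exponential fits with the fast
#' lifetime fixed (optionally re-estimated from the focus-count decay when
#' that estimate is precise), and conversion to molecules per cell and nM
#' via the single-molecule calibration and spherocylinder volume.
#'
#' @param sim a \code{sim_rapid}.
#' @param cellset cell outlines; defaults to the simulation's ground-truth
#'   masks (use [segment_cells()] on a bright-field image for the
#'   segmentation route).
#' @param cal a \code{calibration_constant}; NULL attempts
#'   [calibrate_from_movie()] and falls back to the configured
#'   single-molecule intensity if too few return events are present.
#' @param tau1_s fast lifetime, s; NULL uses the focus-count decay estimate
#'   when its SE is below 20\%, else the configured 6 s.
#' @param estimate_tau1 run the (slower) per-frame focus counting to
#'   re-estimate tau1 (default FALSE).
#' @param tau2 "population" (default): estimate the slow (autofluorescence)
#'   lifetime once from the population-mean decay, where it is well
#'   identified, then solve each cell's amplitudes by non-negative least
#'   squares with both lifetimes fixed; "per_cell": free tau2 in every
#'   cell's fit (requires bright cells — with dim ones the per-cell
#'   two-exponential fit is degenerate and biases A1 down).
#' @param aperture_correction divide each cell's copy number by its
#'   [mask_capture_fraction()] to compensate PSF flux spilling outside the
#'   outline (default TRUE).
#' @param tau2_fixed_s a known slow lifetime, s (e.g. measured once from
#'   wild-type-analogue cells carrying no fluorophore, the way the 60 s
#'   autofluorescence constant is obtained); overrides the \code{tau2}
#'   strategy when given.
#' @return list: \code{table} (data.frame cell_id, A1, A2, tau2, area_um2,
#'   volume_fL, N_molecules, conc_nM), \code{cal}, \code{tau1_s},
#'   \code{tau2_s} (population estimate, NA for per-cell fits).
#' @export
quantify_copy_numbers <- function(sim, cellset = sim$truth$cells, cal = NULL,
                                  tau1_s = NULL, estimate_tau1 = FALSE,
                                  tau2 = c("population", "per_cell"),
                                  aperture_correction = TRUE,
                                  tau2_fixed_s = NULL) {
  tau2 <- match.arg(tau2)
  cfg <- sim$config
  stack <- correct_offset_and_flatten(sim$stack, cfg$camera_offset)
  if (is.null(cal)) {
    cal <- tryCatch(calibrate_from_movie(sim, cellset),
                    error = function(e) {
                      structure(list(I_sm = cfg$I_single, sd = NA_real_,
                                     n = 0L, n_excluded = 0L,
                                     reference_exposure_ms =
                                       cfg$reference_exposure_ms,
                                     label = "configured"),
                                class = "calibration_constant")
                    })
  }
  if (is.null(tau1_s)) {
    tau1_s <- cfg$tau_bleach_s
    if (estimate_tau1) {
      fc <- count_foci_per_frame(stack, cellset,
                                 psf_sigma_px = cfg$psf_sigma_px)
      est <- try(fit_focus_count_decay(fc$n_foci, fc$time_s), silent = TRUE)
      if (!inherits(est, "try-error") && est$decaying &&
          is.finite(est$se) && est$se / est$tau_s < 0.2)
        tau1_s <- est$tau_s
    }
  }
  capture <- if (aperture_correction)
    mask_capture_fraction(cellset, cfg$psf_sigma_px)
  else rep(1, nrow(cellset$cells))
  tr <- per_cell_trajectories(stack, cellset)
  tau2_pop <- NA_real_
  if (!is.null(tau2_fixed_s)) {
    tau2_pop <- tau2_fixed_s
    tau2 <- "population"    # amplitudes by NNLS at the fixed lifetimes
  } else if (tau2 == "population" && length(tr$cells) > 0) {
    # the slow component is autofluorescence-like: restrict the search to
    # lifetimes well separated from the bleaching decay
    pop <- fit_two_exponential(rowMeans(tr$means), tr$times_s, tau1_s,
                               tau2_min = 5 * tau1_s)
    tau2_pop <- pop$tau2
  }
  rows <- lapply(seq_along(tr$cells), function(j) {
    if (tau2 == "population") {
      amp <- .nnls2(tr$means[, j], exp(-tr$times_s / tau1_s),
                    exp(-tr$times_s / tau2_pop))
      ft <- list(A1 = amp$A1, A2 = amp$A2, tau2 = tau2_pop)
      class(ft) <- "decay_fit"
    } else {
      ft <- try(fit_two_exponential(tr$means[, j], tr$times_s, tau1_s),
                silent = TRUE)
      if (inherits(ft, "try-error")) return(NULL)
    }
    cl <- cellset$cells[j, ]
    nmol <- copy_number(ft, cl$area_px, cal,
                        exposure_ms = stack$exposure_ms) / capture[j]
    data.frame(cell_id = cl$cell, A1 = ft$A1, A2 = ft$A2, tau2 = ft$tau2,
               area_um2 = cl$area_um2, volume_fL = cl$volume_fl,
               capture = capture[j], N_molecules = nmol,
               conc_nM = concentration(nmol, cl$volume_fl))
  })
  list(table = do.call(rbind, rows), cal = cal, tau1_s = tau1_s,
       tau2_s = tau2_pop)
}

#' Simulated time-resolved colocalisation experiment
#'
#' Repeats, per technical replicate, the two-colour focus simulation over
#' the time-lapse schedule and measures bidirectional colocalised fractions
#' and chance levels, aggregated with [coloc_time_series()]. Cells keep
#' their identity across the series and filament according to the growth
#' law (\code{grow = TRUE}); since the replisome count per cell stays
#' constant while the area grows, the chance level declines over the
#' measurement, as in damage time-lapse experiments.
#'
#' @param cfg a [sim_config()]; the tight/loose/dispersed fractions and the
#'   late-stage switch define the scenario.
#' @param n_replicates technical replicates (default 3).
#' @param n_cells cells per replicate.
#' @param radius_nm colocalisation radius (default 200).
#' @param focus_density_per_um2 yellow-focus density (default 0.5).
#' @param chance_every compute the (slow) chance level every k-th time
#'   point and carry it forward (default 4).
#' @param grow apply the filamentation law across the series (default
#'   TRUE).
#' @return list: \code{records} (per replicate x time point),
#'   \code{curves} (from [coloc_time_series()]).
#' @export
run_coloc_experiment <- function(cfg, n_replicates = 3, n_cells = 15,
                                 radius_nm = 200,
                                 focus_density_per_um2 = 0.5,
                                 chance_every = 4, grow = TRUE) {
  tps <- seq(0, cfg$timelapse_duration_min, by = cfg$timelapse_interval_min)
  t_reserve <- if (grow) max(tps) else 0
  gf_final <- .growth_volume_factor(cfg, t_reserve)
  recs <- list()
  for (rep_i in seq_len(n_replicates)) {
    with_stage_seed(cfg$seed, 1000 + rep_i, {
      final <- simulate_cells(cfg, n_cells, t_min = t_reserve)
      chance <- NA_real_
      for (j in seq_along(tps)) {
        t <- tps[j]
        cells <- if (grow)
          .regrow_cells(final, final$cells, cfg,
                        .growth_volume_factor(cfg, t), gf_final)
        else final
        tc <- simulate_two_colour_foci(cfg, cells, t_min = t,
                                       focus_density_per_um2 =
                                         focus_density_per_um2)
        rec <- colocalised_fractions(tc$fociA, tc$fociB, radius_nm,
                                     time_min = t, replicate = rep_i)
        if (j %% chance_every == 1 || is.na(chance))
          chance <- chance_colocalisation(cells, tc$fociB,
                                          radius_nm)$chance
        rec$chance <- chance
        recs[[length(recs) + 1]] <- rec
      }
    })
  }
  records <- do.call(rbind, recs)
  list(records = records, curves = coloc_time_series(records))
}

.stage_error <- function(stage, e) {
  stop(structure(class = c("pipeline_stage_error", "error", "condition"),
                 list(message = sprintf("pipeline stage '%s' failed: %s",
                                        stage, conditionMessage(e)),
                      call = NULL, stage = stage)))
}

#' Run the full reproducible pipeline
#'
#' Executes the requested stages in order (\code{simulate},
#' \code{analyze}, \code{coloc}, \code{report}), writing each stage's
#' outputs (plain-text stacks, ground-truth and result CSVs, summary JSON)
#' under \code{out_dir} before the next stage starts, plus a run manifest
#' (config hash, seed, per-stage outputs and record counts). A stage
#' failure aborts with the failing stage named; outputs of completed stages
#' are retained. Identical config and seed reproduce identical outputs.
#'
#' @param cfg a [sim_config()] or path to a YAML config file.
#' @param scenario "undamaged" or "damage".
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stages to run.
#' @param n_cells cells to simulate (default 20).
#' @param n_frames rapid-acquisition frames (default from config).
#' @param n_replicates colocalisation replicates (default 3).
#' @param quiet suppress progress messages.
#' @return The manifest (list), invisibly; also written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(cfg, scenario = c("undamaged", "damage"),
                         out_dir,
                         stages = c("simulate", "analyze", "coloc", "report"),
                         n_cells = 20, n_frames = NULL, n_replicates = 3,
                         quiet = FALSE) {
  scenario <- match.arg(scenario)
  if (is.character(cfg)) cfg <- read_sim_config(cfg)
  validate_sim_config(cfg)
  if (is.null(n_frames)) n_frames <- cfg$n_frames_rapid
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_ <- function(...) if (!quiet) message(sprintf(...))
  manifest <- list(
    package = "smfoci",
    version = as.character(utils::packageVersion("smfoci")),
    seed = cfg$seed, scenario = scenario,
    config_hash = .config_hash(cfg),
    stages = list())
  sim <- NULL; quant <- NULL; coloc <- NULL
  add_stage <- function(name, outputs, counts) {
    manifest$stages[[name]] <<- list(outputs = outputs, counts = counts)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  if ("simulate" %in% stages) {
    tryCatch({
      sim <- generate_rapid_acquisition(
        cfg, if (scenario == "damage") "damage" else "undamaged",
        n_cells = n_cells, n_frames = n_frames)
      write_stack_txt(sim$stack, file.path(out_dir, "rapid_yfp"))
      write_labels_txt(sim$truth$cells$labels,
                       file.path(out_dir, "truth_labels.txt"))
      utils::write.csv(sim$truth$molecules,
                       file.path(out_dir, "truth_molecules.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$truth$cells$cells,
                       file.path(out_dir, "truth_cells.csv"),
                       row.names = FALSE)
      utils::write.csv(sim$truth$sites,
                       file.path(out_dir, "truth_replisomes.csv"),
                       row.names = FALSE)
      add_stage("simulate",
                c("rapid_yfp_meta.json", "truth_labels.txt",
                  "truth_molecules.csv", "truth_cells.csv",
                  "truth_replisomes.csv"),
                list(cells = n_cells, frames = n_frames,
                     molecules = nrow(sim$truth$molecules)))
      log_("simulate: %d cells, %d molecules, %d frames", n_cells,
           nrow(sim$truth$molecules), n_frames)
    }, error = function(e) .stage_error("simulate", e))
  }

  if ("analyze" %in% stages) {
    tryCatch({
      if (is.null(sim)) stop("no simulation in memory (run 'simulate')")
      quant <- quantify_copy_numbers(sim)
      utils::write.csv(quant$table,
                       file.path(out_dir, "per_cell_quant.csv"),
                       row.names = FALSE)
      add_stage("analyze", "per_cell_quant.csv",
                list(cells_quantified = nrow(quant$table),
                     calibration_events = quant$cal$n,
                     I_sm = quant$cal$I_sm, tau1_s = quant$tau1_s))
      log_("analyze: %d cells quantified (I_sm = %.0f a.u., %d events)",
           nrow(quant$table), quant$cal$I_sm, quant$cal$n)
    }, error = function(e) .stage_error("analyze", e))
  }

  if ("coloc" %in% stages) {
    tryCatch({
      cfg2 <- cfg
      if (scenario == "undamaged") cfg2$switch_scale <- 1  # no switch
      coloc <- run_coloc_experiment(cfg2, n_replicates = n_replicates,
                                    n_cells = max(5, n_cells %/% 2))
      utils::write.csv(coloc$records,
                       file.path(out_dir, "coloc_records.csv"),
                       row.names = FALSE)
      utils::write.csv(coloc$curves,
                       file.path(out_dir, "coloc_curves.csv"),
                       row.names = FALSE)
      add_stage("coloc", c("coloc_records.csv", "coloc_curves.csv"),
                list(records = nrow(coloc$records),
                     time_points = nrow(coloc$curves)))
      log_("coloc: %d records over %d time points", nrow(coloc$records),
           nrow(coloc$curves))
    }, error = function(e) .stage_error("coloc", e))
  }

  if ("report" %in% stages) {
    tryCatch({
      rep_ <- list()
      if (!is.null(quant) && nrow(quant$table)) {
        rep_$copy_number <- summarise_values(quant$table$N_molecules)
        rep_$concentration_nM <- summarise_values(quant$table$conc_nM)
      }
      if (!is.null(coloc)) {
        pre <- coloc$curves[coloc$curves$time_min < cfg$switch_time_min &
                            coloc$curves$time_min >= cfg$onset_min, ]
        if (nrow(pre))
          rep_$coloc_pre_switch <- mean(pre$mean_frac_A_with_B, na.rm = TRUE)
      }
      jsonlite::write_json(rep_, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      add_stage("report", "summary.json", list(fields = length(rep_)))
      log_("report: %d summary fields", length(rep_))
    }, error = function(e) .stage_error("report", e))
  }
  invisible(manifest)
}

# order-stable hash of the configuration (no external digest dependency:
# polynomial rolling hash over the serialised JSON, mod a Mersenne prime)
.config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE,
                        digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Command-line entry point
#'
#' Thin front-end used by the \code{inst/exec/smfoci} script. Subcommands:
#' \code{simulate}, \code{analyze}, \code{coloc}, \code{report} (each runs
#' the pipeline up to and including that stage). Exit status: 0 on success,
#' 2 on a configuration error, 3 on a stage failure.
#'
#' @param args character vector of command-line arguments
#'   (\code{<subcommand> [--config F] [--scenario S] [--seed N] [--out D]
#'   [--cells N] [--frames N] [--replicates N]}).
#' @return Integer exit status (returned, not called with \code{quit()}, so
#'   it is testable in-process).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: smfoci <simulate|analyze|coloc|report> --out DIR [--config FILE] [--scenario undamaged|damage] [--seed N] [--cells N] [--frames N] [--replicates N]"
  if (!length(args)) { message(usage); return(2L) }
  sub <- args[1]
  stage_sets <- list(simulate = "simulate",
                     analyze = c("simulate", "analyze"),
                     coloc = "coloc",
                     report = c("simulate", "analyze", "coloc", "report"))
  if (!sub %in% names(stage_sets)) { message(usage); return(2L) }
  opt <- list(config = NULL, scenario = "damage", seed = NULL, out = NULL,
              cells = 20L, frames = NULL, replicates = 3L)
  rest <- args[-1]
  i <- 1
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[i])
    if (!key %in% names(opt) || i == length(rest)) {
      message(usage); return(2L)
    }
    opt[[key]] <- rest[i + 1]
    i <- i + 2
  }
  if (is.null(opt$out)) { message("--out is required\n", usage); return(2L) }
  cfg <- tryCatch({
    c0 <- if (is.null(opt$config)) sim_config() else
      read_sim_config(opt$config)
    if (!is.null(opt$seed)) c0$seed <- as.integer(opt$seed)
    validate_sim_config(c0)
    c0
  }, error = function(e) { message("config error: ",
                                   conditionMessage(e)); NULL })
  if (is.null(cfg)) return(2L)
  res <- tryCatch({
    run_pipeline(cfg, opt$scenario, opt$out, stages = stage_sets[[sub]],
                 n_cells = as.integer(opt$cells),
                 n_frames = if (is.null(opt$frames)) NULL else
                   as.integer(opt$frames),
                 n_replicates = as.integer(opt$replicates))
    0L
  }, pipeline_stage_error = function(e) {
    message(conditionMessage(e)); 3L
  }, error = function(e) {
    message("error: ", conditionMessage(e)); 3L
  })
  res
}
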