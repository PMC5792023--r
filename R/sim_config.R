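#' Simulation configuration
#'
#' Builds and validates the configuration object used by every generator in
#' the synthetic-movie module. Defaults encode the imaging regime the package
#' emulates: 100 nm pixels, rapid acquisitions of 300 x 34 ms frames under
#' continuous excitation, and three-image time-lapse sets (bright-field
#' 34 ms, yellow channel 50 ms, red channel 100 ms) every 5 min for 3 h with
#' the two fluorescence channels acquired ~2 s apart. Fluorophores bleach
#' with a 6 s lifetime in illuminated time while cellular autofluorescence
#' decays with a 60 s lifetime; a single fluorophore integrates to 1850 a.u.
#' at the 34 ms reference exposure. Damage-induced expression rises from a
#' baseline of 20 molecules per cell (onset ~20 min after treatment) to a
#' plateau of 280 molecules (reached by 90 min), while cells filament to
#' 2.5x their initial volume by 120 min.
#'
#' Binding classes: a molecule (or focus site) is either "tight" (at a
#' replisome site), "loose" (at a replisome site plus an isotropic 2D offset
#' of scale \code{loose_offset_sigma_nm}), "dispersed" (bound, uniform in the
#' cell) or free (fast-diffusing, remainder fraction). After
#' \code{switch_time_min}, the tight and loose fractions are multiplied by
#' \code{switch_scale} (default 0, i.e. stepped off) with the difference
#' moved to the dispersed class, emulating the late-stage loss of
#' replisome-proximal binding.
#'
#' @param pixel_size_nm pixel size of the camera in nm (default 100).
#' @param frame_interval_s rapid-acquisition frame time in s (default 0.034).
#' @param n_frames_rapid frames per rapid acquisition (default 300).
#' @param timelapse_interval_min minutes between time-lapse points (default 5).
#' @param timelapse_duration_min total time-lapse duration in min (default 180).
#' @param exposure_bf_ms,exposure_yfp_ms,exposure_red_ms exposures of the
#'   bright-field, yellow and red channels in ms (defaults 34, 50, 100).
#' @param channel_lag_s delay between the two fluorescence channels in s
#'   (default 2).
#' @param D_free,D_bound diffusion coefficients of free and DNA-bound
#'   molecules in um^2/s (defaults 1e2 and 1e-5).
#' @param tau_bleach_s fluorophore bleaching lifetime in illuminated seconds
#'   (default 6).
#' @param tau_autofluor_s autofluorescence decay lifetime in illuminated
#'   seconds (default 60).
#' @param I_single integrated intensity of one fluorophore, in a.u. at the
#'   reference exposure (default 1850).
#' @param I_single_red integrated intensity of one red-channel fluorophore
#'   (default 1850; only relative brightness matters).
#' @param reference_exposure_ms exposure at which \code{I_single} applies
#'   (default 34, the rapid-acquisition frame time).
#' @param return_rate rate of transient single-frame returns of bleached
#'   fluorophores, events/s per bleached molecule (default 1e-3).
#' @param psf_sigma_px isotropic Gaussian PSF sigma in pixels (default 1.3,
#'   appropriate for a 1.49-NA objective at ~540 nm with 100 nm pixels).
#' @param camera_offset electronic offset added to every pixel, a.u.
#'   (default 100).
#' @param read_noise_sd Gaussian read noise SD in a.u. (default 2).
#' @param autofluor_amplitude autofluorescence signal per cell pixel at the
#'   reference exposure, a.u. (default 20).
#' @param bit_depth detector bit depth for clipping (default 16).
#' @param N_baseline,N_plateau expected molecules per cell before damage and
#'   at the plateau (defaults 20 and 280).
#' @param onset_min,plateau_min minutes after damage at which up-regulation
#'   begins and at which the plateau is reached (defaults 20 and 90).
#' @param f_tight,f_loose,f_dispersed binding-class fractions; their sum must
#'   be <= 1, the remainder is the free fraction.
#' @param loose_offset_sigma_nm per-axis scale of the isotropic offset of
#'   loose molecules from their replisome site, nm (default 300).
#' @param replisome_foci_per_cell replisome sites per (unfilamented) cell
#'   (default 4).
#' @param switch_time_min,switch_scale time of the late-stage switch and the
#'   factor applied to the tight+loose fractions after it (defaults 100, 0).
#' @param loc_noise_nm localisation noise applied per axis when emitting
#'   ground-truth focus positions directly (default 30).
#' @param cell_width_um,cell_length_mean_um,cell_length_sd_um cell geometry:
#'   width and the (truncated normal) length distribution of undamaged
#'   cells, in um (defaults 1, 2.5, 0.4).
#' @param filament_volume_ratio,filament_ref_min filamentation law: cells
#'   grow exponentially in length after \code{onset_min} such that their
#'   volume reaches \code{filament_volume_ratio} times the undamaged volume
#'   at \code{filament_ref_min} minutes, and is capped there (defaults 2.5
#'   and 120).
#' @param free_substeps Brownian sub-steps used to render one motion-blurred
#'   free molecule within a frame (default 20).
#' @param field_px default square field edge, pixels (default 128).
#' @param seed integer seed; identical seed and config give bit-identical
#'   output.
#'
#' @return An object of class \code{sim_config} (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$tau_bleach_s
#' @export
sim_config <- function(pixel_size_nm = 100,
                       frame_interval_s = 0.034,
                       n_frames_rapid = 300,
                       timelapse_interval_min = 5,
                       timelapse_duration_min = 180,
                       exposure_bf_ms = 34,
                       exposure_yfp_ms = 50,
                       exposure_red_ms = 100,
                       channel_lag_s = 2,
                       D_free = 1e2,
                       D_bound = 1e-5,
                       tau_bleach_s = 6,
                       tau_autofluor_s = 60,
                       I_single = 1850,
                       I_single_red = 1850,
                       reference_exposure_ms = 34,
                       return_rate = 1e-3,
                       psf_sigma_px = 1.3,
                       camera_offset = 100,
                       read_noise_sd = 2,
                       autofluor_amplitude = 20,
                       bit_depth = 16,
                       N_baseline = 20,
                       N_plateau = 280,
                       onset_min = 20,
                       plateau_min = 90,
                       f_tight = 0.05,
                       f_loose = 0.05,
                       f_dispersed = 0.4,
                       loose_offset_sigma_nm = 300,
                       replisome_foci_per_cell = 4,
                       switch_time_min = 100,
                       switch_scale = 0,
                       loc_noise_nm = 30,
                       cell_width_um = 1,
                       cell_length_mean_um = 2.5,
                       cell_length_sd_um = 0.4,
                       filament_volume_ratio = 2.5,
                       filament_ref_min = 120,
                       free_substeps = 20,
                       field_px = 128,
                       seed = 1L) {
  cfg <- list(
    pixel_size_nm = pixel_size_nm,
    frame_interval_s = frame_interval_s,
    n_frames_rapid = as.integer(n_frames_rapid),
    timelapse_interval_min = timelapse_interval_min,
    timelapse_duration_min = timelapse_duration_min,
    exposure_bf_ms = exposure_bf_ms,
    exposure_yfp_ms = exposure_yfp_ms,
    exposure_red_ms = exposure_red_ms,
    channel_lag_s = channel_lag_s,
    D_free = D_free,
    D_bound = D_bound,
    tau_bleach_s = tau_bleach_s,
    tau_autofluor_s = tau_autofluor_s,
    I_single = I_single,
    I_single_red = I_single_red,
    reference_exposure_ms = reference_exposure_ms,
    return_rate = return_rate,
    psf_sigma_px = psf_sigma_px,
    camera_offset = camera_offset,
    read_noise_sd = read_noise_sd,
    autofluor_amplitude = autofluor_amplitude,
    bit_depth = as.integer(bit_depth),
    N_baseline = N_baseline,
    N_plateau = N_plateau,
    onset_min = onset_min,
    plateau_min = plateau_min,
    f_tight = f_tight,
    f_loose = f_loose,
    f_dispersed = f_dispersed,
    loose_offset_sigma_nm = loose_offset_sigma_nm,
    replisome_foci_per_cell = replisome_foci_per_cell,
    switch_time_min = switch_time_min,
    switch_scale = switch_scale,
    loc_noise_nm = loc_noise_nm,
    cell_width_um = cell_width_um,
    cell_length_mean_um = cell_length_mean_um,
    cell_length_sd_um = cell_length_sd_um,
    filament_volume_ratio = filament_volume_ratio,
    filament_ref_min = filament_ref_min,
    free_substeps = as.integer(free_substeps),
    field_px = as.integer(field_px),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks positivity of rates, times and intensities, that the binding-class
#' fractions lie in [0, 1] and sum to at most 1, and basic type sanity.
#' Called by [sim_config()]; exported so that configurations read from file
#' can be revalidated.
#'
#' @param cfg a \code{sim_config} object or plain named list.
#' @return \code{cfg}, invisibly, if valid; otherwise an error.
#' @export
validate_sim_config <- function(cfg) {
  pos <- c("pixel_size_nm", "frame_interval_s", "n_frames_rapid",
           "timelapse_interval_min", "exposure_bf_ms", "exposure_yfp_ms",
           "exposure_red_ms", "D_free", "D_bound", "tau_bleach_s",
           "tau_autofluor_s", "I_single", "I_single_red",
           "reference_exposure_ms", "psf_sigma_px",
           "cell_width_um", "cell_length_mean_um", "filament_volume_ratio",
           "filament_ref_min", "free_substeps", "field_px")
  for (f in pos) {
    v <- cfg[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("sim_config: field '", f, "' must be a single strictly positive number")
  }
  nonneg <- c("timelapse_duration_min", "channel_lag_s", "return_rate",
              "camera_offset", "read_noise_sd", "autofluor_amplitude",
              "N_baseline", "N_plateau", "onset_min", "plateau_min",
              "loose_offset_sigma_nm", "replisome_foci_per_cell",
              "switch_time_min", "switch_scale", "loc_noise_nm",
              "cell_length_sd_um")
  for (f in nonneg) {
    v <- cfg[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("sim_config: field '", f, "' must be a single non-negative number")
  }
  fr <- c(cfg$f_tight, cfg$f_loose, cfg$f_dispersed)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1 + 1e-12)
    stop("sim_config: binding-class fractions must lie in [0,1] and sum to <= 1")
  if (cfg$plateau_min < cfg$onset_min)
    stop("sim_config: plateau_min must be >= onset_min")
  if (cfg$switch_scale > 1)
    stop("sim_config: switch_scale must lie in [0,1]")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  field %d px @ %g nm/px; rapid: %d x %g s; timelapse: every %g min for %g min\n",
              x$field_px, x$pixel_size_nm, x$n_frames_rapid,
              x$frame_interval_s, x$timelapse_interval_min,
              x$timelapse_duration_min))
  cat(sprintf("  tau_bleach %g s, tau_autofluor %g s, I_single %g a.u. @ %g ms\n",
              x$tau_bleach_s, x$tau_autofluor_s, x$I_single,
              x$reference_exposure_ms))
  cat(sprintf("  expression %g -> %g molecules (onset %g min, plateau %g min)\n",
              x$N_baseline, x$N_plateau, x$onset_min, x$plateau_min))
  cat(sprintf("  fractions tight/loose/dispersed = %g/%g/%g (free %g); switch at %g min x%g\n",
              x$f_tight, x$f_loose, x$f_dispersed,
              1 - x$f_tight - x$f_loose - x$f_dispersed,
              x$switch_time_min, x$switch_scale))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}

#' Read a simulation configuration from a YAML file
#'
#' Fields present in the file override [sim_config()] defaults; unknown
#' fields are an error so that typos do not pass silently.
#'
#' @param path path to a YAML file of \code{sim_config} fields.
#' @return A validated \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown sim_config field(s) in ", path, ": ",
         paste(bad, collapse = ", "))
  do.call(sim_config, vals)
}

# Run code under a seed derived from the master seed by a fixed stage
# offset, so pipeline stages are independently reproducible.
with_stage_seed <- function(seed, stage_offset, code) {
  s <- (as.integer(seed) + as.integer(stage_offset)) %% .Machine$integer.max
  withr::with_seed(s, code)
}
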