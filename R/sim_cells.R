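# Cell geometry, expression time course and molecule placement for the
# synthetic-movie generator. Coordinate convention (package-wide): pixel
# (row r, col c) of a matrix, 1-based, has its centre at
# x = (c - 0.5) * pixel_size_nm, y = (r - 0.5) * pixel_size_nm.

# distance from points (x, y) to the central segment of a rod cell
.dist_to_segment <- function(x, y, cx, cy, angle, half_seg) {
  ux <- cos(angle); uy <- sin(angle)
  px <- x - cx; py <- y - cy
  t <- px * ux + py * uy
  t <- pmin(pmax(t, -half_seg), half_seg)
  sqrt((px - t * ux)^2 + (py - t * uy)^2)
}

# rasterise one spherocylindrical (stadium-shaped) cell; returns matrix
# row/col indices of covered pixels
.rasterise_rod <- function(cx, cy, angle, length_nm, width_nm, psz, nrow_, ncol_) {
  half_seg <- pmax(length_nm - width_nm, 0) / 2
  r <- width_nm / 2
  ext <- length_nm / 2 + psz
  c0 <- max(1L, floor((cx - ext) / psz)); c1 <- min(ncol_, ceiling((cx + ext) / psz))
  r0 <- max(1L, floor((cy - ext) / psz)); r1 <- min(nrow_, ceiling((cy + ext) / psz))
  if (c0 > c1 || r0 > r1) return(cbind(row = integer(0), col = integer(0)))
  cc <- c0:c1; rr <- r0:r1
  xs <- (cc - 0.5) * psz; ys <- (rr - 0.5) * psz
  g <- expand.grid(row = rr, col = cc)
  d <- .dist_to_segment((g$col - 0.5) * psz, (g$row - 0.5) * psz,
                        cx, cy, angle, half_seg)
  keep <- d <= r
  cbind(row = g$row[keep], col = g$col[keep])
}

# filamentation law: volume inflation factor at t minutes after damage.
# Exponential growth starting at onset, reaching filament_volume_ratio at
# filament_ref_min, capped there.
.growth_volume_factor <- function(cfg, t_min) {
  R <- cfg$filament_volume_ratio
  if (R <= 1 || t_min <= cfg$onset_min) return(1)
  span <- cfg$filament_ref_min - cfg$onset_min
  min(R, exp(log(R) * (t_min - cfg$onset_min) / span))
}

# length (um) of a spherocylinder with width w whose volume is v (fL)
.length_for_volume <- function(v, w) {
  r <- w / 2
  cap <- (4 / 3) * pi * r^3
  w + (v - cap) / (pi * r^2)
}

#' Simulate a field of non-overlapping rod-shaped cells
#'
#' Places spherocylindrical cells with random positions and orientations on
#' the image plane by rejection sampling, drawing tip-to-tip lengths from a
#' truncated normal distribution and inflating them by the filamentation law
#' for time points after damage onset (exponential growth in length reaching
#' \code{filament_volume_ratio} times the undamaged volume at
#' \code{filament_ref_min} minutes, then capped). Geometry (area, length,
#' width, spherocylinder volume) is recorded per cell along with the label
#' mask.
#'
#' Uses the R random number stream; wrap in [withr::with_seed()] (as the
#' movie generators do) for reproducibility.
#'
#' @param cfg a [sim_config()].
#' @param n_cells number of cells to place (>= 1).
#' @param t_min minutes after damage (0 = undamaged geometry).
#' @param field_px square field edge in pixels (default from config).
#' @param margin_px empty margin required between cells and around the field
#'   border, pixels (default 2).
#' @param max_tries rejection-sampling attempts per cell before giving up.
#' @return A \code{cell_set}: list with \code{labels} (integer matrix, 0 =
#'   background), \code{cells} (data.frame: cell, cx_nm, cy_nm, angle_rad,
#'   length_um, width_um, area_px, area_um2, volume_fl), and
#'   \code{pixel_size_nm}.
#' @export
simulate_cells <- function(cfg, n_cells, t_min = 0,
                           field_px = cfg$field_px, margin_px = 2L,
                           max_tries = 2000L) {
  stopifnot(n_cells >= 1)
  psz <- cfg$pixel_size_nm
  n <- as.integer(field_px)
  labels <- matrix(0L, n, n)
  occupied <- matrix(FALSE, n, n)  # includes margin
  gf <- .growth_volume_factor(cfg, t_min)
  w <- cfg$cell_width_um
  rows <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      L0 <- stats::rnorm(1, cfg$cell_length_mean_um, cfg$cell_length_sd_um)
      if (L0 < w * 1.1) next
      v0 <- cell_volume(L0, w)
      L <- .length_for_volume(v0 * gf, w)
      ang <- stats::runif(1, 0, pi)
      len_nm <- L * 1000; wid_nm <- w * 1000
      cx <- stats::runif(1, len_nm / 2, n * psz - len_nm / 2)
      cy <- stats::runif(1, len_nm / 2, n * psz - len_nm / 2)
      px <- .rasterise_rod(cx, cy, ang, len_nm, wid_nm, psz, n, n)
      if (nrow(px) == 0) next
      # dilated footprint for the margin/overlap test
      if (any(px[, "row"] <= margin_px | px[, "row"] > n - margin_px |
              px[, "col"] <= margin_px | px[, "col"] > n - margin_px)) next
      idx <- (px[, "col"] - 1L) * n + px[, "row"]
      dil <- idx
      for (dr in -margin_px:margin_px) for (dc in -margin_px:margin_px)
        dil <- c(dil, idx + dr + dc * n)
      dil <- unique(dil[dil >= 1 & dil <= n * n])
      if (any(occupied[dil])) next
      labels[idx] <- i
      occupied[dil] <- TRUE
      rows[[i]] <- data.frame(
        cell = i, cx_nm = cx, cy_nm = cy, angle_rad = ang,
        length_um = L, width_um = w,
        area_px = nrow(px),
        area_um2 = nrow(px) * (psz / 1000)^2,
        volume_fl = cell_volume(L, w))
      placed <- TRUE
      break
    }
    if (!placed)
      stop("simulate_cells: could not place cell ", i, " of ", n_cells,
           " without overlap in a ", n, "x", n,
           " px field (constraint: non-overlapping cells with ",
           margin_px, " px margin); use a larger field or fewer cells")
  }
  structure(list(labels = labels,
                 cells = do.call(rbind, rows),
                 pixel_size_nm = psz),
            class = "cell_set")
}

#' @export
print.cell_set <- function(x, ...) {
  cat(sprintf("<cell_set> %d cells on a %d x %d px field (%g nm/px)\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels), x$pixel_size_nm))
  invisible(x)
}

#' Expected molecules per cell as a function of time after damage
#'
#' Piecewise-smooth expression curve: constant at \code{N_baseline} before
#' \code{onset_min}, rising along a logistic rescaled to hit the endpoints
#' exactly, and constant at \code{N_plateau} from \code{plateau_min} onward.
#'
#' @param cfg a [sim_config()].
#' @param t_min time(s) after damage, minutes; vectorised.
#' @return Expected molecules per cell (same length as \code{t_min}).
#' @examples
#' cfg <- sim_config()
#' expression_time_course(cfg, c(0, 55, 180))
#' @export
expression_time_course <- function(cfg, t_min) {
  stopifnot(all(t_min >= 0))
  nb <- cfg$N_baseline; np <- cfg$N_plateau
  on <- cfg$onset_min; pl <- cfg$plateau_min
  if (pl == on) return(ifelse(t_min < on, nb, np))
  mid <- (on + pl) / 2
  sc <- (pl - on) / (2 * log(99))        # logistic at 1%/99% at the ends
  lg <- function(t) 1 / (1 + exp(-(t - mid) / sc))
  frac <- (lg(pmin(pmax(t_min, on), pl)) - lg(on)) / (lg(pl) - lg(on))
  nb + (np - nb) * frac
}

# binding-class fractions effective at time t (after the late-stage switch
# the tight+loose weight is scaled and the difference moved to dispersed)
effective_fractions <- function(cfg, t_min) {
  ft <- cfg$f_tight; fl <- cfg$f_loose; fd <- cfg$f_dispersed
  if (t_min >= cfg$switch_time_min) {
    s <- cfg$switch_scale
    fd <- fd + (ft + fl) * (1 - s)
    ft <- ft * s; fl <- fl * s
  }
  c(tight = ft, loose = fl, dispersed = fd,
    free = max(0, 1 - ft - fl - fd))
}

# uniform points inside a cell's mask: uniform pixel + uniform within pixel
.uniform_in_mask <- function(cellset, cell_id, k) {
  idx <- which(cellset$labels == cell_id, arr.ind = TRUE)
  psz <- cellset$pixel_size_nm
  pick <- idx[sample.int(nrow(idx), k, replace = TRUE), , drop = FALSE]
  cbind(x = (pick[, "col"] - 1 + stats::runif(k)) * psz,
        y = (pick[, "row"] - 1 + stats::runif(k)) * psz)
}

#' Place replisome sites inside cells
#'
#' Sites are distributed along the cell's long axis (uniform over the
#' cylindrical portion) with a small lateral spread, the arrangement
#' expected for replication machinery on the nucleoid. The number of sites
#' per cell is Poisson around \code{replisome_foci_per_cell} (minimum 1)
#' and does not scale with cell length: under DNA damage, filamentation
#' continues while replication initiation is blocked, so the replisome
#' count per cell stays roughly constant as cells grow — which is also why
#' the chance colocalisation level falls as cells filament.
#'
#' @param cellset a \code{cell_set} from [simulate_cells()].
#' @param cfg a [sim_config()].
#' @return data.frame: cell, site, x_nm, y_nm.
#' @export
place_replisomes <- function(cellset, cfg) {
  out <- vector("list", nrow(cellset$cells))
  for (i in seq_len(nrow(cellset$cells))) {
    cl <- cellset$cells[i, ]
    k <- max(1L, stats::rpois(1, cfg$replisome_foci_per_cell))
    half_seg <- max(cl$length_um - cl$width_um, 0.1) * 1000 / 2
    t <- stats::runif(k, -half_seg, half_seg)
    lat <- stats::rnorm(k, 0, cl$width_um * 1000 / 8)
    ux <- cos(cl$angle_rad); uy <- sin(cl$angle_rad)
    out[[i]] <- data.frame(
      cell = cl$cell, site = seq_len(k),
      x_nm = cl$cx_nm + t * ux - lat * uy,
      y_nm = cl$cy_nm + t * uy + lat * ux)
  }
  do.call(rbind, out)
}

#' Assign binding classes and positions to molecules
#'
#' Each molecule is assigned a state by the (time-effective) class
#' fractions: \emph{tight} molecules sit exactly at a replisome site,
#' \emph{loose} molecules at a replisome site plus an isotropic 2D Gaussian
#' offset of per-axis scale \code{loose_offset_sigma_nm}, \emph{dispersed}
#' bound molecules uniformly in the cell mask, and \emph{free} molecules
#' uniformly in the mask (they diffuse with \code{D_free} when rendered).
#'
#' @param cellset a \code{cell_set}.
#' @param n_per_cell integer vector (recycled) of molecules per cell.
#' @param cfg a [sim_config()].
#' @param sites replisome sites from [place_replisomes()]; may be NULL only
#'   if the tight and loose fractions are both zero.
#' @param t_min time after damage (controls the late-stage switch).
#' @return data.frame: cell, mol, x_nm, y_nm, state
#'   (tight/loose/dispersed/free).
#' @export
place_molecules <- function(cellset, n_per_cell, cfg, sites = NULL, t_min = 0) {
  fr <- effective_fractions(cfg, t_min)
  ids <- cellset$cells$cell
  n_per_cell <- rep_len(n_per_cell, length(ids))
  if (sum(n_per_cell) > 0 && fr[["tight"]] + fr[["loose"]] > 0 &&
      (is.null(sites) || nrow(sites) == 0))
    stop("place_molecules: tight/loose fractions are positive but no ",
         "replisome sites were supplied")
  out <- vector("list", length(ids))
  states <- c("tight", "loose", "dispersed", "free")
  for (i in seq_along(ids)) {
    ncell <- n_per_cell[i]
    if (ncell == 0) next
    st <- sample(states, ncell, replace = TRUE, prob = fr)
    xy <- matrix(NA_real_, ncell, 2)
    bound_site <- st %in% c("tight", "loose")
    if (any(bound_site)) {
      s <- sites[sites$cell == ids[i], , drop = FALSE]
      pick <- s[sample.int(nrow(s), sum(bound_site), replace = TRUE), ]
      xy[bound_site, 1] <- pick$x_nm
      xy[bound_site, 2] <- pick$y_nm
      loose <- which(st == "loose")
      if (length(loose)) {
        xy[loose, 1] <- xy[loose, 1] +
          stats::rnorm(length(loose), 0, cfg$loose_offset_sigma_nm)
        xy[loose, 2] <- xy[loose, 2] +
          stats::rnorm(length(loose), 0, cfg$loose_offset_sigma_nm)
      }
    }
    unif <- which(!bound_site)
    if (length(unif)) {
      xy[unif, ] <- .uniform_in_mask(cellset, ids[i], length(unif))
    }
    out[[i]] <- data.frame(cell = ids[i], mol = seq_len(ncell),
                           x_nm = xy[, 1], y_nm = xy[, 2], state = st)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell = integer(0), mol = integer(0),
                      x_nm = numeric(0), y_nm = numeric(0),
                      state = character(0))
  res
}
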