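# Focus detection, elliptical 2D Gaussian fitting, local ring background
# correction and per-cell focus statistics.

# subtract each cell's median intensity inside its mask: a rod-shaped cell
# is narrow enough that its uniform haze passes the band-pass filter, so
# it must be removed before filtering, not by it
.flatten_cell_background <- function(image, cellset) {
  incell <- cellset$labels > 0
  f <- factor(cellset$labels[incell])
  med <- tapply(image[incell], f, stats::median)
  out <- image
  out[incell] <- image[incell] - med[f]
  out
}

# binary erosion by k passes of the 4-neighbourhood
.erode_mask <- function(mask, k) {
  k <- as.integer(k)
  while (k > 0) {
    n1 <- nrow(mask); n2 <- ncol(mask)
    m <- mask
    m[-1, ] <- m[-1, ] & mask[-n1, ]
    m[-n1, ] <- m[-n1, ] & mask[-1, ]
    m[, -1] <- m[, -1] & mask[, -n2]
    m[, -n2] <- m[, -n2] & mask[, -1]
    m[1, ] <- m[n1, ] <- FALSE
    m[, 1] <- m[, n2] <- FALSE
    mask <- m
    k <- k - 1L
  }
  mask
}
#
# A "focus" is a diffraction-limited spot produced by one or more
# slow-moving labelled molecules; its integrated intensity is the volume
# under the fitted Gaussian, 2*pi*A*sigma_x*sigma_y.

#' Detect candidate foci as local maxima of a band-pass filtered image
#'
#' The image is band-pass filtered with a difference of Gaussians (sigma =
#' PSF sigma and 2x that), and local maxima exceeding a robust threshold
#' (median + \code{threshold_sd} x MAD-based SD of the filtered image,
#' computed within the cell masks when supplied) are kept. Maxima closer
#' than \code{min_separation_nm} are merged, keeping the brighter.
#'
#' @param image corrected image matrix.
#' @param cellset optional \code{cell_set}; when supplied, only maxima
#'   inside cell masks are returned and the threshold statistics are
#'   computed over in-cell pixels.
#' @param threshold_sd threshold in robust SDs above the median (default 5).
#' @param min_separation_nm merge radius, nm (default 300).
#' @param psf_sigma_px PSF sigma used for the band-pass, px (default 1.3).
#' @param pixel_size_nm pixel size, nm (default 100).
#' @param threshold absolute threshold on the band-pass image, overriding
#'   the median/MAD rule; use [peak_threshold()] to hold the threshold
#'   fixed across the frames of a movie.
#' @param erode_px restrict candidates (and the threshold statistics) to
#'   mask pixels at least this far inside the cell boundary (default 0).
#'   The band-pass filter responds to the intensity step at the outline of
#'   a bright cell, producing spurious rim maxima; eroding by ~2 px
#'   removes them at the cost of a uniform (rate-preserving) loss of
#'   near-edge foci.
#' @return data.frame: row, col, x_nm, y_nm, value (filtered amplitude),
#'   cell (NA when no cellset given). Possibly zero rows.
#' @export
detect_peaks <- function(image, cellset = NULL, threshold_sd = 5,
                         min_separation_nm = 300, psf_sigma_px = 1.3,
                         pixel_size_nm = 100, threshold = NULL,
                         erode_px = 0L) {
  if (!is.null(cellset)) image <- .flatten_cell_background(image, cellset)
  bp <- .blur_gaussian(image, psf_sigma_px) -
        .blur_gaussian(image, 2 * psf_sigma_px)
  n1 <- nrow(bp); n2 <- ncol(bp)
  region <- if (!is.null(cellset)) .erode_mask(cellset$labels > 0, erode_px)
            else NULL
  if (!is.null(threshold)) {
    above <- bp > threshold
    if (!is.null(region)) above <- above & region
  } else if (!is.null(cellset)) {
    # per-cell statistics: each cell carries its own background brightness
    # (and hence shot-noise level), so the threshold must adapt per cell
    f <- factor(cellset$labels[region])
    med <- tapply(bp[region], f, stats::median)
    md <- tapply(bp[region], f, stats::mad)
    thr_cell <- med + threshold_sd * md
    above <- matrix(FALSE, n1, n2)
    above[region] <- bp[region] > thr_cell[f]
  } else {
    above <- bp > stats::median(bp) + threshold_sd * stats::mad(bp)
  }
  # strict local maxima over the 8-neighbourhood
  pad <- matrix(-Inf, n1 + 2, n2 + 2)
  pad[2:(n1 + 1), 2:(n2 + 1)] <- bp
  ismax <- above
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    ismax <- ismax & bp >= pad[2:(n1 + 1) + dr, 2:(n2 + 1) + dc]
  }
  idx <- which(ismax)
  if (!is.null(cellset)) idx <- idx[cellset$labels[idx] > 0]
  if (!length(idx))
    return(data.frame(row = integer(0), col = integer(0), x_nm = numeric(0),
                      y_nm = numeric(0), value = numeric(0), cell = integer(0)))
  r <- (idx - 1L) %% n1 + 1L
  cc <- (idx - 1L) %/% n1 + 1L
  cand <- data.frame(row = r, col = cc,
                     x_nm = (cc - 0.5) * pixel_size_nm,
                     y_nm = (r - 0.5) * pixel_size_nm,
                     value = bp[idx],
                     cell = if (!is.null(cellset)) cellset$labels[idx]
                            else NA_integer_)
  cand <- cand[order(-cand$value), ]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!keep[i]) next
    if (i < nrow(cand)) {
      j <- (i + 1):nrow(cand)
      d2 <- (cand$x_nm[j] - cand$x_nm[i])^2 + (cand$y_nm[j] - cand$y_nm[i])^2
      keep[j[d2 < min_separation_nm^2]] <- FALSE
    }
  }
  out <- cand[keep, ]
  rownames(out) <- NULL
  out
}

#' Fit an elliptical 2D Gaussian with constant background to a focus
#'
#' Least-squares fit of a pixel-integrated elliptical Gaussian
#' \eqn{b + A \exp(-(x-x_0)^2/2\sigma_x^2 - (y-y_0)^2/2\sigma_y^2)} over a
#' square window centred on the candidate pixel (each pixel's model value
#' is the Gaussian mass falling inside the pixel, matching how a camera
#' integrates an emitter and avoiding the sigma^2 + 1/12 sampling bias of
#' point-sampled fits). The integrated intensity (the volume under the
#' fitted surface above background) is \eqn{2\pi A \sigma_x \sigma_y} with
#' the sigmas in pixel units. Fits are rejected (status != "ok") when the
#' window is clipped by the image edge, the optimiser fails, a sigma leaves
#' [0.5, 4] px, or the amplitude is consistent with zero (below
#' \code{amp_sd_reject} residual SDs).
#'
#' @param image corrected image matrix.
#' @param row,col candidate pixel (1-based).
#' @param window window edge in px, odd, >= 7 (default 9).
#' @param pixel_size_nm pixel size, nm.
#' @param amp_sd_reject amplitude significance cut (default 2).
#' @return One-row data.frame: row, col, x_nm, y_nm, sigma_x_nm, sigma_y_nm,
#'   amplitude, background, integrated_au, residual_sd, status.
#' @export
fit_gaussian_2d <- function(image, row, col, window = 9L,
                            pixel_size_nm = 100, amp_sd_reject = 2) {
  window <- as.integer(window)
  if (window < 7L || window %% 2L == 0L)
    stop("fit_gaussian_2d: window must be odd and >= 7 px")
  hw <- window %/% 2L
  fail <- function(status)
    data.frame(row = row, col = col, x_nm = NA_real_, y_nm = NA_real_,
               sigma_x_nm = NA_real_, sigma_y_nm = NA_real_,
               amplitude = NA_real_, background = NA_real_,
               integrated_au = NA_real_, residual_sd = NA_real_,
               status = status)
  if (row - hw < 1 || row + hw > nrow(image) ||
      col - hw < 1 || col + hw > ncol(image))
    return(fail("edge_clipped"))
  rr <- (row - hw):(row + hw)
  cc <- (col - hw):(col + hw)
  z <- image[rr, cc]
  b0 <- stats::median(z)
  a0 <- max(z) - b0
  if (a0 <= 0) return(fail("no_signal"))
  # p = (flux, x0, y0, sx, sy, b); pixel value = flux * mass in pixel + b
  model <- function(p) {
    wx <- stats::pnorm((cc - p[2] + 0.5) / p[4]) -
          stats::pnorm((cc - p[2] - 0.5) / p[4])
    wy <- stats::pnorm((rr - p[3] + 0.5) / p[5]) -
          stats::pnorm((rr - p[3] - 0.5) / p[5])
    p[6] + p[1] * (wy %o% wx)
  }
  obj <- function(p) sum((model(p) - z)^2)
  p0 <- c(a0 * 2 * pi * 1.3^2, col, row, 1.3, 1.3, b0)
  ft <- try(stats::optim(p0, obj, method = "L-BFGS-B",
                         lower = c(0, col - hw, row - hw, 0.3, 0.3, -Inf),
                         upper = c(Inf, col + hw, row + hw, 6, 6, Inf),
                         control = list(maxit = 500, factr = 1e2)),
            silent = TRUE)
  # code 52 (line-search failure) is how L-BFGS-B reports that it cannot
  # improve further at machine precision, common on near-zero residuals;
  # the sigma/amplitude quality gates below still apply
  if (inherits(ft, "try-error") || !ft$convergence %in% c(0L, 52L))
    return(fail("no_convergence"))
  p <- ft$par
  res_sd <- sqrt(ft$value / (length(z) - 6))
  amp <- p[1] / (2 * pi * p[4] * p[5])
  out <- data.frame(row = row, col = col,
                    x_nm = (p[2] - 0.5) * pixel_size_nm,
                    y_nm = (p[3] - 0.5) * pixel_size_nm,
                    sigma_x_nm = p[4] * pixel_size_nm,
                    sigma_y_nm = p[5] * pixel_size_nm,
                    amplitude = amp, background = p[6],
                    integrated_au = p[1],
                    residual_sd = res_sd, status = "ok")
  if (p[4] < 0.5 || p[4] > 4 || p[5] < 0.5 || p[5] > 4)
    out$status <- "sigma_out_of_range"
  else if (amp < amp_sd_reject * res_sd)
    out$status <- "amplitude_not_significant"
  out
}

#' Detect and fit all foci in an image
#'
#' [detect_peaks()] followed by [fit_gaussian_2d()] on every candidate;
#' fitted centroids are assigned to the cell whose mask contains the
#' centroid pixel (masks partition the field, so the assignment is unique).
#'
#' @inheritParams detect_peaks
#' @param window fit window, px.
#' @param keep_rejected keep non-"ok" rows (default FALSE).
#' @return Focus table: one row per focus with the [fit_gaussian_2d()]
#'   columns plus \code{cell}.
#' @export
find_foci <- function(image, cellset = NULL, threshold_sd = 5,
                      min_separation_nm = 300, psf_sigma_px = 1.3,
                      pixel_size_nm = 100, window = 9L,
                      keep_rejected = FALSE) {
  cand <- detect_peaks(image, cellset, threshold_sd, min_separation_nm,
                       psf_sigma_px, pixel_size_nm)
  if (!nrow(cand)) return(.empty_focus_df())
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i)
    fit_gaussian_2d(image, cand$row[i], cand$col[i], window, pixel_size_nm)))
  fits$cell <- NA_integer_
  ok <- fits$status == "ok"
  if (!is.null(cellset) && any(ok)) {
    pr <- pmin(pmax(floor(fits$y_nm[ok] / pixel_size_nm) + 1L, 1L),
               nrow(cellset$labels))
    pc <- pmin(pmax(floor(fits$x_nm[ok] / pixel_size_nm) + 1L, 1L),
               ncol(cellset$labels))
    fits$cell[ok] <- cellset$labels[cbind(pr, pc)]
    fits$cell[ok][fits$cell[ok] == 0L] <- NA_integer_
  }
  if (!keep_rejected) fits <- fits[ok, ]
  rownames(fits) <- NULL
  fits
}

.empty_focus_df <- function() {
  data.frame(row = integer(0), col = integer(0), x_nm = numeric(0),
             y_nm = numeric(0), sigma_x_nm = numeric(0),
             sigma_y_nm = numeric(0), amplitude = numeric(0),
             background = numeric(0), integrated_au = numeric(0),
             residual_sd = numeric(0), status = character(0),
             cell = integer(0))
}

#' Fixed detection threshold from a reference image
#'
#' Median + \code{threshold_sd} x robust SD of the band-pass (difference of
#' Gaussians) image within the cell masks. Computing this once on a
#' reference frame — typically the final, mostly-bleached frame of a rapid
#' acquisition — and passing it to [detect_peaks()] keeps the detection
#' criterion constant across a movie, so that focus counts are comparable
#' between bright early frames and dim late ones.
#'
#' @inheritParams detect_peaks
#' @return A single absolute threshold value.
#' @export
peak_threshold <- function(image, cellset = NULL, threshold_sd = 5,
                           psf_sigma_px = 1.3, erode_px = 0L) {
  if (!is.null(cellset)) image <- .flatten_cell_background(image, cellset)
  bp <- .blur_gaussian(image, psf_sigma_px) -
        .blur_gaussian(image, 2 * psf_sigma_px)
  sel <- if (!is.null(cellset))
    bp[.erode_mask(cellset$labels > 0, erode_px)]
  else as.vector(bp)
  stats::median(sel) + threshold_sd * stats::mad(sel)
}

#' Local ring background correction of a square ROI
#'
#' The background is the mean intensity within a 2-px-wide ring immediately
#' outside the ROI; the corrected intensity is the ROI sum minus background
#' times the ROI pixel count.
#'
#' @param image image matrix.
#' @param row,col ROI centre pixel.
#' @param roi ROI edge, px, odd (default 5).
#' @param ring_width ring width, px (default 2).
#' @return list: \code{background} (a.u./px), \code{corrected} (a.u.),
#'   \code{roi_sum}.
#' @export
local_background_correct <- function(image, row, col, roi = 5L,
                                     ring_width = 2L) {
  roi <- as.integer(roi)
  if (roi %% 2L == 0L) stop("roi must be odd")
  hw <- roi %/% 2L
  ho <- hw + ring_width
  if (row - ho < 1 || row + ho > nrow(image) ||
      col - ho < 1 || col + ho > ncol(image))
    stop("local_background_correct: ring clipped by image edge at (",
         row, ", ", col, ")")
  outer_ <- image[(row - ho):(row + ho), (col - ho):(col + ho)]
  inner <- image[(row - hw):(row + hw), (col - hw):(col + hw)]
  ring_sum <- sum(outer_) - sum(inner)
  ring_n <- length(outer_) - length(inner)
  bg <- ring_sum / ring_n
  list(background = bg,
       corrected = sum(inner) - bg * length(inner),
       roi_sum = sum(inner))
}

#' Extract a background-corrected ROI intensity trajectory
#'
#' Applies [local_background_correct()] at a fixed position in every frame,
#' producing the intensity-versus-time trace used for photobleaching decay
#' and step analysis (default 5 x 5 px ROI with a 2 px ring).
#'
#' @param stack a [movie_stack()].
#' @param row,col ROI centre pixel.
#' @param roi ROI edge, px (default 5).
#' @param ring_width ring width, px (default 2).
#' @return An \code{intensity_trajectory}: list with \code{times_s},
#'   \code{intensity} (a.u.), \code{row}, \code{col}, \code{roi},
#'   \code{channel}.
#' @export
extract_trajectory <- function(stack, row, col, roi = 5L, ring_width = 2L) {
  nk <- n_frames(stack)
  v <- numeric(nk)
  for (k in seq_len(nk))
    v[k] <- local_background_correct(stack$data[, , k], row, col, roi,
                                     ring_width)$corrected
  structure(list(times_s = stack$timestamps_s, intensity = v,
                 row = row, col = col, roi = roi, channel = stack$channel),
            class = "intensity_trajectory")
}

#' @export
print.intensity_trajectory <- function(x, ...) {
  cat(sprintf("<intensity_trajectory> %d points at (%d, %d), %dx%d px ROI, channel '%s'\n",
              length(x$intensity), x$row, x$col, x$roi, x$roi, x$channel))
  invisible(x)
}

#' Focus density per cell area
#'
#' @param foci focus table with a \code{cell} column.
#' @param cellset a \code{cell_set}.
#' @return data.frame: cell, n_foci, area_um2, density_per_um2.
#' @export
foci_density <- function(foci, cellset) {
  if (any(cellset$cells$area_um2 <= 0))
    stop("foci_density: cell with zero area")
  n <- vapply(cellset$cells$cell,
              function(id) sum(!is.na(foci$cell) & foci$cell == id), 0)
  data.frame(cell = cellset$cells$cell, n_foci = n,
             area_um2 = cellset$cells$area_um2,
             density_per_um2 = n / cellset$cells$area_um2)
}

#' Foci per cell with mean and SEM
#'
#' Each focus is assigned to the unique cell whose mask contains its
#' centroid (done upstream in [find_foci()]); foci outside all masks are
#' dropped and counted.
#'
#' @param foci focus table with a \code{cell} column.
#' @param cellset a \code{cell_set}.
#' @return list: \code{counts} (per-cell data.frame), \code{mean},
#'   \code{sem}, \code{n_cells}, \code{n_unassigned}.
#' @export
foci_per_cell <- function(foci, cellset) {
  ids <- cellset$cells$cell
  n <- vapply(ids, function(id) sum(!is.na(foci$cell) & foci$cell == id), 0)
  list(counts = data.frame(cell = ids, n_foci = n),
       mean = mean(n),
       sem = if (length(n) > 1) stats::sd(n) / sqrt(length(n)) else NA_real_,
       n_cells = length(n),
       n_unassigned = sum(is.na(foci$cell)))
}
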