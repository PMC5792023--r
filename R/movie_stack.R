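#' Movie stack container
#'
#' A single-channel multi-frame image stack with pixel size, per-frame
#' timestamps and exposure metadata. Frames are stored as an array
#' (rows x cols x frames) of intensities in arbitrary camera units.
#'
#' @param data numeric array (rows x cols x frames) or a matrix (one frame).
#' @param pixel_size_nm pixel size, nm (> 0).
#' @param exposure_ms exposure per frame, ms.
#' @param timestamps_s numeric vector of frame acquisition times, s;
#'   strictly increasing, one per frame.
#' @param channel channel label, e.g. "yfp", "red", "bf".
#' @return An object of class \code{movie_stack}.
#' @export
movie_stack <- function(data, pixel_size_nm, exposure_ms, timestamps_s,
                        channel = "yfp") {
  if (is.matrix(data)) data <- array(data, c(dim(data), 1L))
  stopifnot(length(dim(data)) == 3L)
  if (pixel_size_nm <= 0) stop("movie_stack: pixel_size_nm must be > 0")
  if (length(timestamps_s) != dim(data)[3])
    stop("movie_stack: need one timestamp per frame")
  if (any(diff(timestamps_s) <= 0))
    stop("movie_stack: timestamps must be strictly increasing")
  structure(list(data = data, pixel_size_nm = pixel_size_nm,
                 exposure_ms = exposure_ms,
                 timestamps_s = as.numeric(timestamps_s),
                 channel = channel),
            class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie_stack> channel '%s': %d frame(s) of %d x %d px, %g nm/px, %g ms exposure, t = %g..%g s\n",
              x$channel, d[3], d[1], d[2], x$pixel_size_nm, x$exposure_ms,
              min(x$timestamps_s), max(x$timestamps_s)))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$data)

n_frames <- function(stack) dim(stack$data)[3]

get_frame <- function(stack, frame = 1L) stack$data[, , frame]

#' Write / read a movie stack as plain-text rasters with a JSON sidecar
#'
#' One whitespace-delimited ASCII matrix file per frame
#' (\code{<prefix>_fNNNN.txt}) plus \code{<prefix>_meta.json} holding pixel
#' size, exposure, channel and per-frame timestamps. A plain-text stand-in
#' for binary multi-frame image formats so that stacks round-trip losslessly
#' through version-controlled text.
#'
#' @param stack a [movie_stack()].
#' @param prefix path prefix (directory must exist).
#' @return \code{write_stack_txt}: the sidecar path, invisibly.
#' @export
write_stack_txt <- function(stack, prefix) {
  d <- dim(stack$data)
  files <- character(d[3])
  for (k in seq_len(d[3])) {
    f <- sprintf("%s_f%04d.txt", prefix, k)
    utils::write.table(stack$data[, , k], f, row.names = FALSE,
                       col.names = FALSE)
    files[k] <- basename(f)
  }
  meta <- list(format = "smfoci-stack-txt-v1",
               channel = stack$channel,
               pixel_size_nm = stack$pixel_size_nm,
               exposure_ms = stack$exposure_ms,
               timestamps_s = stack$timestamps_s,
               n_frames = d[3], nrow = d[1], ncol = d[2],
               frame_files = files)
  side <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' @rdname write_stack_txt
#' @export
read_stack_txt <- function(prefix) {
  side <- paste0(prefix, "_meta.json")
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  dat <- array(NA_real_, c(meta$nrow, meta$ncol, meta$n_frames))
  for (k in seq_len(meta$n_frames)) {
    m <- as.matrix(utils::read.table(file.path(dirname(side),
                                               meta$frame_files[k])))
    dimnames(m) <- NULL
    dat[, , k] <- m
  }
  movie_stack(dat, meta$pixel_size_nm, meta$exposure_ms,
              meta$timestamps_s, meta$channel)
}

#' Write / read a label mask as a plain-text raster
#'
#' @param labels integer matrix (0 = background).
#' @param path file path.
#' @return \code{read_labels_txt}: an integer matrix.
#' @export
write_labels_txt <- function(labels, path) {
  utils::write.table(labels, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_labels_txt
#' @export
read_labels_txt <- function(path) {
  m <- as.matrix(utils::read.table(path))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  m
}
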