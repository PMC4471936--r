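# Movie stacks, exposure bookkeeping and MRC/MRCS input/output.
#
# MRC dialect: classic 1024-byte header, no extended header written, mode 2
# (32-bit float) output, column-fastest axis order (the first R array index
# is the MRC x/fast axis). Modes 0, 1, 2 and 6 are read.

#' Movie stack container
#'
#' An ordered stack of equally sized 2D real-valued frames with a pixel size.
#'
#' @param frames A 3D numeric array `[nx, ny, n_frames]`, or a list of equal
#'   sized matrices.
#' @param pixel_size Pixel size in Angstrom (> 0).
#' @return Object of class `movie_stack` with elements `frames` (3D array),
#'   `pixel_size`, `n_frames`.
#' @export
movie_stack <- function(frames, pixel_size) {
  if (is.list(frames)) {
    dims <- unique(lapply(frames, dim))
    if (length(dims) != 1) stop("all frames must share identical dimensions")
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[[1]], length(frames)))
  }
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  stopifnot(is.array(frames), length(dim(frames)) == 3, pixel_size > 0)
  structure(
    list(frames = frames, pixel_size = pixel_size,
         n_frames = dim(frames)[3]),
    class = "movie_stack"
  )
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Movie stack: %d frame(s) of %d x %d pixels at %.4g A/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

# Extract frame i as a matrix.
get_frame <- function(stack, i) stack$frames[, , i]

#' Exposure schedule of a movie
#'
#' Bookkeeping for the accumulated electron exposure of each frame. By
#' default a frame's accumulated exposure refers to the END of the frame
#' (pre-exposure plus every per-frame exposure up to and including it),
#' matching the convention that a frame's signal reflects the damage
#' sustained while it was recorded; `convention = "mid"` refers to the frame
#' midpoint instead.
#'
#' @param per_frame Exposure per frame in electrons/A^2; a scalar or a
#'   vector of length `n_frames`.
#' @param n_frames Number of frames (required when `per_frame` is scalar).
#' @param pre_exposure Exposure accumulated before frame 1, electrons/A^2.
#' @param convention `"end"` (default) or `"mid"`.
#' @return Object of class `exposure_schedule`.
#' @export
exposure_schedule <- function(per_frame, n_frames = length(per_frame),
                              pre_exposure = 0,
                              convention = c("end", "mid")) {
  convention <- match.arg(convention)
  stopifnot(n_frames >= 1, pre_exposure >= 0, all(per_frame > 0))
  if (length(per_frame) == 1) per_frame <- rep(per_frame, n_frames)
  if (length(per_frame) != n_frames) {
    stop("per_frame must be scalar or length n_frames")
  }
  structure(
    list(per_frame = per_frame, n_frames = n_frames,
         pre_exposure = pre_exposure, convention = convention),
    class = "exposure_schedule"
  )
}

#' Accumulated exposure at a frame
#'
#' @param schedule An [exposure_schedule()].
#' @param frame_index 1-based frame index (vectorized).
#' @return Accumulated exposure(s) in electrons/A^2 at the schedule's
#'   convention point of each frame.
#' @export
accumulated_exposure <- function(schedule, frame_index) {
  stopifnot(inherits(schedule, "exposure_schedule"))
  if (any(frame_index < 1 | frame_index > schedule$n_frames)) {
    stop(sprintf("frame index out of range 1..%d", schedule$n_frames))
  }
  cs <- schedule$pre_exposure + cumsum(schedule$per_frame)
  n <- cs[frame_index]
  if (schedule$convention == "mid") {
    n <- n - schedule$per_frame[frame_index] / 2
  }
  n
}

# ---------------------------------------------------------------------------
# MRC format

.mrc_mode_info <- function(mode) {
  switch(as.character(mode),
    "0" = list(what = "integer", size = 1L, signed = TRUE),
    "1" = list(what = "integer", size = 2L, signed = TRUE),
    "2" = list(what = "numeric", size = 4L, signed = TRUE),
    "6" = list(what = "integer", size = 2L, signed = FALSE),
    stop(sprintf("unsupported MRC mode %s (supported: 0, 1, 2, 6)", mode))
  )
}

.read_mrc_header <- function(con, endian) {
  seek(con, 0)
  w1 <- readBin(con, "integer", n = 10, size = 4, endian = endian)   # nx..mz
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  cellb <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  maps <- readBin(con, "integer", n = 3, size = 4, endian = endian)
  dstats <- readBin(con, "numeric", n = 3, size = 4, endian = endian)
  ispg <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  nsymbt <- readBin(con, "integer", n = 1, size = 4, endian = endian)
  list(nx = w1[1], ny = w1[2], nz = w1[3], mode = w1[4],
       mx = w1[8], my = w1[9], mz = w1[10],
       cella = cella, nsymbt = nsymbt, endian = endian)
}

#' Read an MRC/MRCS movie or image stack
#'
#' Reads a classic-format MRC file (modes 0, 1, 2, 6) into a
#' [movie_stack()]; 2D sections are stacked along the slow axis. The pixel
#' size comes from the header cell dimensions unless overridden.
#'
#' @param path Path to the MRC/MRCS file.
#' @param pixel_size Optional override of the header pixel size (Angstrom).
#'   When it disagrees with the header the override wins, with a warning.
#' @return A [movie_stack()].
#' @export
read_movie <- function(path, pixel_size = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  fsize <- file.size(path)
  if (is.na(fsize) || fsize < 1024) {
    stop(sprintf("'%s': not an MRC file (size %s < 1024-byte header)",
                 path, fsize))
  }
  hdr <- .read_mrc_header(con, "little")
  plausible <- function(h) {
    all(c(h$nx, h$ny, h$nz) > 0) && all(c(h$nx, h$ny, h$nz) < 1e6) &&
      h$mode %in% c(0, 1, 2, 6)
  }
  if (!plausible(hdr)) {
    hdr_be <- .read_mrc_header(con, "big")
    if (plausible(hdr_be)) hdr <- hdr_be
    else stop(sprintf(
      "'%s': malformed MRC header (nx=%d ny=%d nz=%d mode=%d at offset 0)",
      path, hdr$nx, hdr$ny, hdr$nz, hdr$mode))
  }
  info <- .mrc_mode_info(hdr$mode)
  nvox <- as.numeric(hdr$nx) * hdr$ny * hdr$nz
  data_off <- 1024 + max(hdr$nsymbt, 0)
  need <- data_off + nvox * info$size
  if (fsize < need) {
    stop(sprintf(
      "'%s': truncated data: file has %d bytes, need %d (%d sections of %dx%d, mode %d, data at offset %d)",
      path, fsize, need, hdr$nz, hdr$nx, hdr$ny, hdr$mode, data_off))
  }
  seek(con, data_off)
  v <- readBin(con, info$what, n = nvox, size = info$size,
               signed = info$signed, endian = hdr$endian)
  frames <- array(as.numeric(v), dim = c(hdr$nx, hdr$ny, hdr$nz))
  ps_header <- if (hdr$mx > 0 && hdr$cella[1] > 0) hdr$cella[1] / hdr$mx else NA
  ps <- pixel_size
  if (is.null(ps)) {
    ps <- if (is.finite(ps_header) && ps_header > 0) ps_header else 1
  } else if (is.finite(ps_header) && ps_header > 0 &&
             abs(ps - ps_header) > 1e-4 * ps_header) {
    warning(sprintf(
      "pixel size override %.4g A differs from header %.4g A; using override",
      ps, ps_header))
  }
  movie_stack(frames, pixel_size = ps)
}

#' Write a movie stack or image as MRC (mode 2)
#'
#' @param x A [movie_stack()] or a single real matrix.
#' @param path Output path.
#' @param pixel_size Pixel size in Angstrom; taken from the stack when `x`
#'   is a `movie_stack`.
#' @return `path`, invisibly.
#' @export
write_movie <- function(x, path, pixel_size = NULL) {
  if (inherits(x, "movie_stack")) {
    frames <- x$frames
    if (is.null(pixel_size)) pixel_size <- x$pixel_size
  } else if (is.matrix(x)) {
    frames <- array(x, dim = c(dim(x), 1L))
    if (is.null(pixel_size)) pixel_size <- 1
  } else stop("x must be a movie_stack or a matrix")
  d <- dim(frames)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  wf <- function(v) writeBin(as.numeric(v), con, size = 4, endian = "little")
  wi(c(d[1], d[2], d[3], 2L))            # nx ny nz mode
  wi(c(0L, 0L, 0L))                      # nxstart nystart nzstart
  wi(c(d[1], d[2], d[3]))                # mx my mz
  wf(d * pixel_size)                     # cell a b c
  wf(c(90, 90, 90))                      # cell angles
  wi(c(1L, 2L, 3L))                      # mapc mapr maps
  wf(c(min(frames), max(frames), mean(frames)))
  wi(c(0L, 0L))                          # ispg nsymbt
  writeBin(raw(100), con)                # extra
  wf(c(0, 0, 0))                         # origin
  writeChar("MAP ", con, 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst, little endian
  wf(stats::sd(frames))
  wi(1L)                                 # nlabl
  lab <- sprintf("%-80s", "doseweight")
  writeChar(substr(lab, 1, 80), con, 80, eos = NULL)
  writeBin(raw(9 * 80), con)
  writeBin(as.numeric(frames), con, size = 4, endian = "little")
  invisible(path)
}
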